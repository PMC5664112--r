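Package: mtauth
Title: Authentication and Contamination Assessment for Ancient Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("mtauth", "developers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for authenticating ancient human mitochondrial DNA sequencing
    results. Models a circular mitochondrial reference and haplotypes in forensic
    mtDNA notation, simulates ancient-DNA reads (short fragments, strand-specific
    terminal cytosine-deamination damage with optional UDG attenuation, PCR
    duplication, sequencing error, and an admixed contaminant lineage), removes
    duplicate reads, builds circular pileups, calls a consensus genome and its
    variant table, scores haplotypes against a defining-variant haplogroup tree,
    profiles terminal misincorporation rates, and estimates contamination both by
    the pooled non-consensus base rate at haplogroup-diagnostic positions (with a
    damage-aware position filter) and by a likelihood mixture over reads against a
    contaminant panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    Rsamtools,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
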