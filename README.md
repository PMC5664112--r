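# mtauth

Authentication and contamination assessment for ancient human mitochondrial
genomes.

When a complete mtDNA genome is sequenced from archaeological bone, three
questions decide whether the result can be believed: does the damage pattern
look ancient, does the haplotype make phylogenetic sense, and how much of the
sequenced DNA is modern contamination? `mtauth` implements the standard
desk-side answers to all three against a circular mitochondrial reference,
plus a fully seeded ancient-read simulator so that every stage is testable
with known truth and no external data.

## What it computes

* **Variant model** — variants in forensic mtDNA notation (`16129A`,
  `3158.1T`, `5DEL`) on a 1-based circular reference; haplotypes applied to
  the reference to build sample genomes; difference counts with the
  conventional exclusions (position 3107, the 309.1/309.2 C-stretch slots).
* **Read handling** — SAM input via Rsamtools with mapping/base-quality
  filters; endpoint-and-strand duplicate removal for merged single-end
  fragments; a per-position pileup with insertion-slot and deletion tracking,
  circular fragments re-joined across the origin.
* **Damage profiling** — misincorporation-by-offset tables in read
  orientation: C→T from the 5′ end and G→A from the 3′ end, the two
  substitution classes produced by post-mortem cytosine deamination, with a
  geometric-decay fit `rate(k) = A·ρ^k` and fragment-length statistics.
* **Consensus and haplogroup** — majority-rule consensus calling
  (`depth ≥ min_cov`, majority fraction ≥ `min_frac`, else N) expressed as a
  variant table / FASTA / minimal VCF; scoring against a defining-variant
  haplogroup tree with missing variants, private mutations, and back-mutation
  (`!`) handling.
* **Contamination, two ways** —
  1. the pooled **non-consensus base rate** at the haplogroup-diagnostic
     positions, `ĉ = Σ non-consensus / Σ depth`, with a Wilson score (or
     position-bootstrap) interval, and a **damage-aware filter** that drops
     C/G-expected sites where deamination-type misincorporations were
     observed;
  2. a **likelihood-mixture estimator**: per read,
     `L_g = (1−ε)^matches (ε/3)^mismatches` against the endogenous genome and
     a contaminant panel, with
     `ĉ = argmax_p Σ_r log[(1−p)L_endo(r) + p·mean_g L_g(r)]` on a grid and a
     profile-likelihood interval.

The packaged fixtures (reference, haplogroup tree, endogenous and contaminant
haplotypes) are **synthetic** stand-ins, built so the structural facts match
the real analysis situation: a U1a1a-like lineage path with 50 diagnostic
substitution positions (19 of them above the reference's own branch point,
where the expected allele equals the reference base), an endogenous haplotype
at 38 variant tokens (35 after the conventional exclusions) including the
3158.1T insertion and three private mutations, and a deep-rooting
contaminant lineage.

## Worked example

```r
library(mtauth)

ref <- mt_example_reference()
sim <- simulate_reads(ref, mt_example_endogenous(), mt_example_contaminant(),
                      sim_params(n_fragments = 20000, contamination = 0.02, seed = 7))
dd  <- deduplicate(sim$reads)                       # duplicate fraction: 0.801
pu  <- build_pileup(dd$reads, ref)
misincorporation_profile(dd$reads, ref)
#> <damage_profile> K=25; 5' terminal C>T 25.02%, 3' terminal G>A 25.71%
fragment_length_stats(dd$reads)
#> <fragment_stats> n=19866, mean 68.11 bp, median 67.0 bp

cc <- call_consensus(pu, ref)
variant_table(cc)$n_diff                            # 35 (38 with 3107/309.1/309.2)
tree <- mt_example_tree()
score_haplogroups(cc$haplotype, tree, ref)
#> <haplogroup_scores> top nodes:
#>   U1a1a      51/51 (1.000)
#>   U1a1a1     51/52 (0.981) missing: 11467G
#>   ...

sites <- diagnostic_positions(tree, "U1a1a", ref)   # 50 positions
estimate_diagnostic(pu, sites)
#> <contam_estimate> diagnostic: 2.759% (95% CI 2.300%-3.307%)
fl <- damage_filter_sites(sites, pu)                # 50 -> 36 sites here
estimate_diagnostic(pu, fl$sites, method_tag = "diagnostic_filtered")
#> <contam_estimate> diagnostic_filtered: 2.323% (95% CI 1.837%-2.935%)
estimate_mixture(dd$reads, genome_vector(ref, cc$haplotype),
                 list(genome_vector(ref, mt_example_contaminant())), eps = 0.005)
#> <contam_estimate> mixture: 2.100% (95% CI 1.700%-2.500%)
```

Reading: the library was simulated with 2% contamination and full
deamination damage. The unfiltered diagnostic estimate (2.76%) is inflated by
damage masquerading as contamination at C/G-expected sites; removing
damage-affected positions brings it to 2.32%, whose interval covers the
simulated truth (2.08% realized), in agreement with the independent mixture
estimate (2.10%). This unfiltered-high / filtered-lower / mixture-concordant
pattern is exactly the signature the method is designed to expose on real
ancient libraries.

## Pipeline and CLI

`run_pipeline()` chains simulate (optional) → read/dedup → pileup → damage →
consensus → haplogroup → contamination and writes per-stage outputs plus a
deterministic `report.json`. A thin CLI wraps it:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","mtauth.R",package="mtauth"))') \
    simulate --n 50000 -c 0.02 --seed 17 --out run1
# subcommands: simulate, pileup, damage, consensus, haplogroup, contam, contam-mix, run
```

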