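# Accessors for the packaged synthetic fixtures. All of them are synthetic
# stand-ins built against synthetic_reference(): the true rCRS and the
# published haplogroup tree cannot be redistributed here, so the fixture
# world mirrors their structure (a U1a1a-like lineage path with 50
# substitution defining positions, an endogenous haplotype at 38 tokens / 35
# after the conventional exclusions, and a deep-rooting contaminant lineage)
# with synthetic alleles.

#' Path to a packaged fixture file
#'
#' @param name one of `"reference"`, `"tree"`, `"endogenous"`,
#'   `"contaminant"`, or a raw file name under `extdata/`.
#' @return file path.
#' @export
mt_fixture <- function(name) {
  file <- switch(name,
    reference = "synthetic_rcrs.fa",
    tree = "u_lineage_tree_synthetic.tsv",
    endogenous = "endogenous_haplotype_synthetic.tsv",
    contaminant = "contaminant_haplotype_synthetic.tsv",
    name
  )
  path <- system.file("extdata", file, package = "mtauth")
  if (path == "") stop("no packaged fixture: ", name)
  path
}

#' Packaged synthetic example world
#'
#' Convenience loaders for the synthetic reference, haplogroup tree, and
#' endogenous/contaminant haplotypes used throughout the examples and tests.
#'
#' @return `mt_example_reference()` a [circular_reference()];
#'   `mt_example_tree()` a `haplo_tree`; the haplotype accessors return
#'   [haplotype()] objects validated against the reference.
#' @export
mt_example_reference <- function() synthetic_reference()

#' @rdname mt_example_reference
#' @export
mt_example_tree <- function() read_haplogroup_tree(mt_fixture("tree"))

#' @rdname mt_example_reference
#' @export
mt_example_endogenous <- function() {
  read_haplotype_tsv(mt_fixture("endogenous"), ref = mt_example_reference())
}

#' @rdname mt_example_reference
#' @export
mt_example_contaminant <- function() {
  read_haplotype_tsv(mt_fixture("contaminant"), ref = mt_example_reference())
}
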