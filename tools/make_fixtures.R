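# Regenerates the packaged synthetic fixtures under inst/extdata/.
# Deterministic: depends only on synthetic_reference() and the fixed seed
# below. Run from the repository root:  Rscript tools/make_fixtures.R

devtools::load_all(".", quiet = TRUE)

ref <- synthetic_reference()
set.seed(101)

other_base <- function(pos) {
  vapply(pos, function(p) sample(setdiff(c("A", "C", "G", "T"), ref_base(ref, p)), 1L), "")
}

# --- haplogroup tree: a U1a1a-like lineage path plus decoy branches -------
# Positions above the reference/U split carry the reference allele (shared
# between the reference's own lineage and the U path); positions below it
# carry a derived allele differing from the reference.
shared <- list(
  L3 = c(769, 1018, 2758, 2885, 3594, 4104, 7146, 7256, 8468, 9042, 13650, 16278),
  N  = c(8701, 9540, 10398, 10873, 15301),
  R  = c(12705, 16223)
)
derived <- list(
  U     = c(12308, 12372),
  U1    = c(14070, 15148, 16249),
  U1a   = c(285, 1709, 13104, 16189),
  U1a1  = c(385, 980, 5198, 9667, 13422, 16093),
  U1a1a = c(627, 1290, 2218, 4811, 6026, 6371, 7581, 8155, 8901, 10750,
            11065, 12358, 13734, 14364, 15954, 16327)
)
stopifnot(length(unlist(shared)) == 19L, length(unlist(derived)) == 31L)

shared_tokens <- lapply(shared, function(p) paste0(p, ref_base(ref, p)))
derived_alts <- lapply(derived, other_base)
derived_tokens <- Map(function(p, a) paste0(p, a), derived, derived_alts)

u1a1a_tokens <- c(derived_tokens$U1a1a, "3158.1T")
tok <- function(x) paste(x, collapse = ",")
tree <- data.frame(
  node = c("ROOT", "L3", "N", "R", "U", "U1", "U1a", "U1a1", "U1a1a", "U1a1a1",
           "H", "K", "T2", "J"),
  parent = c("", "ROOT", "L3", "N", "R", "U", "U1", "U1a", "U1a1", "U1a1a",
             "R", "U", "R", "R"),
  variants = c(
    "",
    tok(shared_tokens$L3),
    tok(shared_tokens$N),
    tok(shared_tokens$R),
    tok(derived_tokens$U),
    tok(derived_tokens$U1),
    tok(derived_tokens$U1a),
    tok(derived_tokens$U1a1),
    tok(u1a1a_tokens),
    "11467G",
    tok(paste0(c(2706, 7028), ref_base(ref, c(2706, 7028)))),
    tok(paste0(c(1811, 9055, 14167), other_base(c(1811, 9055, 14167)))),
    tok(paste0(c(709, 1888, 4917, 8697, 10463, 13368, 14905, 15607, 16294),
               other_base(c(709, 1888, 4917, 8697, 10463, 13368, 14905, 15607, 16294)))),
    paste0(tok(paste0(c(4216, 13708, 16069), other_base(c(4216, 13708, 16069)))),
           ",", paste0("10398", other_base(10398), "!"))
  ),
  stringsAsFactors = FALSE
)
write.table(tree, "inst/extdata/u_lineage_tree_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# --- endogenous haplotype: full U1a1a path (reference-differing part) plus
# three private substitutions and the conventional 3107 / 309.1 / 309.2 calls
endo_tokens <- c(
  unlist(derived_tokens, use.names = FALSE), "3158.1T",
  "5480G", "8573A", "16129A",
  "3107C", "309.1C", "309.2C"
)
endo <- haplotype(endo_tokens, ref = ref)
stopifnot(nrow(endo) == 38L, diff_count(endo) == 35L)
write_haplotype_tsv(endo, "inst/extdata/endogenous_haplotype_synthetic.tsv")

# --- contaminant haplotype: a deep-rooting lineage differing from the
# endogenous genome at every diagnostic position (ancestral alleles at the
# shared positions, reference alleles along the U path) plus a few privates
shared_pos <- unlist(shared, use.names = FALSE)
contam_tokens <- c(
  paste0(shared_pos, other_base(shared_pos)),
  paste0(c(1048, 4312, 9347, 12007, 16188), other_base(c(1048, 4312, 9347, 12007, 16188))),
  "3107C"
)
contam <- haplotype(contam_tokens, ref = ref)
write_haplotype_tsv(contam, "inst/extdata/contaminant_haplotype_synthetic.tsv")

write_fasta(ref, "inst/extdata/synthetic_rcrs.fa")

# sanity summary
tr <- read_haplogroup_tree("inst/extdata/u_lineage_tree_synthetic.tsv")
dp <- suppressWarnings(diagnostic_positions(tr, "U1a1a", ref))
cat(sprintf(
  "diagnostic positions: %d (C/G-expected: %d)\n",
  nrow(dp), sum(dp$expected_allele %in% c("C", "G"))
))
ev <- genome_vector(ref, endo)
cv <- genome_vector(ref, contam)
cat(sprintf(
  "contaminant differs from endogenous at %d / %d diagnostic positions\n",
  sum(ev[dp$position] != cv[dp$position]), nrow(dp)
))
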