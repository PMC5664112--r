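# Shared helpers: toy objects, hand-built reads, and a cache for expensive
# simulations reused across tests in one run.

.mt_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .mt_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .mt_cache)
  }
  get(name, envir = .mt_cache, inherits = FALSE)
}

ex_ref <- function() cached("ref", mt_example_reference())
ex_tree <- function() cached("tree", mt_example_tree())
ex_endo <- function() cached("endo", mt_example_endogenous())
ex_contam <- function() cached("contam", mt_example_contaminant())
ex_sites <- function() {
  cached("sites", suppressWarnings(diagnostic_positions(ex_tree(), "U1a1a", ex_ref())))
}

q30 <- function(len) strrep("?", len)

make_read <- function(id, start, seq, strand = "+", cigar = NULL, qual = NULL,
                      mapq = 60L, library = "non-UDG", segment = 0L) {
  data.frame(
    id = id, start = as.integer(start), strand = strand, mapq = mapq,
    cigar = cigar %||% paste0(nchar(seq), "M"), seq = seq,
    qual = qual %||% q30(nchar(seq)), library = library,
    segment = as.integer(segment), stringsAsFactors = FALSE
  )
}

reads_df <- function(...) mtauth:::new_reads(do.call(rbind, list(...)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# a random toy reference, deterministic per seed
toy_ref <- function(len = 400L, seed = 11L, name = "toy") {
  b <- withr::with_seed(seed, sample(c("A", "C", "G", "T"), len, replace = TRUE))
  circular_reference(b, name = name)
}

# write a SAM file from raw body lines (header added)
write_sam_text <- function(body, ref, path = tempfile(fileext = ".sam")) {
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length),
    body
  ), path)
  path
}

# toy pileup built directly from a counts matrix (rows = positions)
toy_pileup <- function(counts, ref, ins = NULL) {
  stopifnot(nrow(counts) == ref$length, ncol(counts) == 6L)
  mtauth:::new_pileup(
    counts, ins %||% mtauth:::empty_ins_table(), ref$name, ref$length
  )
}

expect_same_haplotype <- function(a, b) {
  expect_identical(a$notation, b$notation)
}

# a large noise-free mixed simulation shared by several tests
noise_free_50k <- function() {
  cached("sim_c05_noise_free", simulate_reads(
    ex_ref(), ex_endo(), ex_contam(),
    params = sim_params(
      n_fragments = 50000L, contamination = 0.05, delta5 = 0, delta3 = 0,
      seq_error = 0, duplication_rate = 0, seed = 21
    )
  ))
}

# a large damaged simulation shared by the damage tests
damaged_50k <- function() {
  cached("sim_damage_50k", simulate_reads(
    ex_ref(), ex_endo(),
    params = sim_params(
      n_fragments = 50000L, contamination = 0, delta5 = 0.25, delta3 = 0.25,
      rho = 0.6, seq_error = 0, duplication_rate = 0, seed = 42
    )
  ))
}
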