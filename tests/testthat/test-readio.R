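# SAM reading/filtering, duplicate removal, pileup construction.

test_that("read_alignments filters and masks as specified", {
  ref <- toy_ref(300L)
  # header-only SAM -> empty collection
  empty <- read_alignments(write_sam_text(character(0), ref))
  expect_equal(nrow(empty), 0L)
  # one record below the mapq threshold is dropped
  body <- c(
    paste("r1", 0, ref$name, 10, 60, "5M", "*", 0, 0, "ACGTA", "IIIII", "LB:Z:non-UDG", sep = "\t"),
    paste("r2", 0, ref$name, 20, 10, "5M", "*", 0, 0, "ACGTA", "IIIII", "LB:Z:non-UDG", sep = "\t"),
    paste("r3", 16, ref$name, 30, 60, "5M", "*", 0, 0, "ACGTA", "IIIII", sep = "\t")
  )
  got <- read_alignments(write_sam_text(body, ref), min_mapq = 30L, min_baseq = 0L)
  expect_setequal(got$id, c("r1", "r3"))
  expect_equal(got$strand[got$id == "r3"], "-")
  expect_equal(got$library[got$id == "r3"], "unknown")
  # low-quality bases are masked to N ('#' = Q2, 'I' = Q40)
  body2 <- paste("r4", 0, ref$name, 10, 60, "5M", "*", 0, 0, "ACGTA", "II#II", sep = "\t")
  got2 <- read_alignments(write_sam_text(body2, ref), min_mapq = 0L, min_baseq = 20L)
  expect_equal(got2$seq, "ACNTA")
  # unmapped and secondary records are excluded
  body3 <- c(
    paste("r5", 4, "*", 0, 0, "*", "*", 0, 0, "ACGTA", "IIIII", sep = "\t"),
    paste("r6", 256, ref$name, 10, 60, "5M", "*", 0, 0, "ACGTA", "IIIII", sep = "\t")
  )
  expect_equal(nrow(read_alignments(write_sam_text(body3, ref), 0L, 0L)), 0L)
})

test_that("malformed SAM input raises a parse error", {
  bad <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "this is not a SAM record"), bad)
  expect_error(read_alignments(bad), "parse error")
  expect_error(read_alignments(tempfile(fileext = ".sam")), "no such file")
})

test_that("deduplicate keeps one representative per endpoint/strand group", {
  distinct <- reads_df(
    make_read("a", 10L, strrep("A", 30)),
    make_read("b", 50L, strrep("C", 30)),
    make_read("c", 50L, strrep("C", 30), strand = "-")
  )
  dd <- deduplicate(distinct)
  expect_equal(dd$duplicate_fraction, 0)
  expect_setequal(dd$reads$id, c("a", "b", "c"))

  copies <- do.call(rbind, lapply(1:10, function(i) {
    make_read(sprintf("dup%02d", i), 100L, strrep("G", 40),
              qual = if (i == 7L) strrep("J", 40) else q30(40))
  }))
  dd2 <- deduplicate(mtauth:::new_reads(copies))
  expect_equal(dd2$duplicate_fraction, 0.9)
  expect_equal(dd2$reads$id, "dup07") # highest total base quality wins
  ties <- mtauth:::new_reads(do.call(rbind, lapply(c("z2", "z1"), function(id) {
    make_read(id, 5L, strrep("T", 20))
  })))
  expect_equal(deduplicate(ties)$reads$id, "z1") # lexicographic tie-break
  # idempotence
  dd3 <- deduplicate(dd2$reads)
  expect_equal(dd3$duplicate_fraction, 0)
  expect_identical(dd3$reads, dd2$reads)
  # empty input
  expect_equal(deduplicate(distinct[0, ])$duplicate_fraction, 0)
})

test_that("duplicate fraction matches the Poisson duplication model", {
  lambda <- 4
  sim <- simulate_reads(
    ex_ref(), ex_endo(),
    params = sim_params(
      n_fragments = 10000L, contamination = 0, duplication_rate = lambda,
      delta5 = 0, delta3 = 0, seq_error = 0, seed = 77
    )
  )
  dd <- deduplicate(sim$reads)
  # exact oracle: distinct (start, end, strand) keys computed from the truth
  tr <- sim$truth$reads
  truth_keys <- unique(paste(tr$frag_start, tr$frag_end, tr$strand))
  expect_equal(dd$duplicate_fraction, 1 - length(truth_keys) / nrow(tr))
  # and the closed-form expectation lambda/(1+lambda), allowing for the
  # small upward shift from coincidental endpoint collisions
  expect_lt(abs(dd$duplicate_fraction - lambda / (1 + lambda)), 0.01)
})

test_that("pileup counts bases, insertions, and deletions correctly", {
  ref <- toy_ref(60L)
  one <- reads_df(make_read("r", 5L, "ACG"))
  pu <- build_pileup(one, ref)
  expect_equal(unname(pu$counts[5, "A"]), 1L)
  expect_equal(unname(pu$counts[6, "C"]), 1L)
  expect_equal(unname(pu$counts[7, "G"]), 1L)
  expect_equal(sum(pu$counts), 3L)

  expect_equal(sum(build_pileup(one[0, ], ref)$counts), 0L)

  indel <- reads_df(
    make_read("i", 10L, "ACTTGG", cigar = "2M2I2M"),
    make_read("d", 20L, "ACGG", cigar = "2M2D2M")
  )
  pu2 <- build_pileup(indel, ref)
  expect_equal(pu2$ins$position, c(11L, 11L))
  expect_equal(pu2$ins$ins_index, c(1L, 2L))
  expect_equal(pu2$ins$T, c(1L, 1L))
  expect_equal(unname(pu2$counts[22, "del"]), 1L)
  expect_equal(unname(pu2$counts[23, "del"]), 1L)
  expect_equal(unname(pu2$counts[12, "G"]), 1L)
  expect_equal(unname(pu2$counts[24, "G"]), 1L)

  # walking off the reference without the circular tag is an error
  off <- reads_df(make_read("x", 55L, strrep("A", 20)))
  expect_error(build_pileup(off, ref), "without a circular split tag")
})

test_that("pileup conserves bases and is order-independent", {
  sim <- simulate_reads(
    ex_ref(), ex_endo(), ex_contam(),
    params = sim_params(n_fragments = 1500L, contamination = 0.1, seed = 19)
  )
  pu <- build_pileup(sim$reads, ex_ref())
  base_total <- sum(pu$counts[, c("A", "C", "G", "T", "N")])
  ins_total <- sum(as.matrix(pu$ins[, c("A", "C", "G", "T", "N")]))
  expect_equal(base_total + ins_total, sum(nchar(sim$reads$seq)))
  perm <- withr::with_seed(1, sample(nrow(sim$reads)))
  pu2 <- build_pileup(sim$reads[perm, ], ex_ref())
  expect_identical(pu$counts, pu2$counts)
  expect_equal(pu$ins, pu2$ins)
})

test_that("per-position depth equals a brute-force interval count", {
  sim <- simulate_reads(
    ex_ref(), ex_endo(),
    params = sim_params(
      n_fragments = 1000L, contamination = 0, delta5 = 0, delta3 = 0,
      seq_error = 0, duplication_rate = 0, seed = 23
    )
  )
  pu <- build_pileup(sim$reads, ex_ref())
  depth <- pileup_depth(pu)
  L <- ex_ref()$length
  oracle <- integer(L)
  tr <- sim$truth$reads
  for (i in seq_len(nrow(tr))) {
    fs <- tr$frag_start[i]; fe <- tr$frag_end[i]
    covered <- if (fe >= fs) fs:fe else c(fs:L, 1:fe)
    oracle[covered] <- oracle[covered] + 1L
  }
  # insertion slots consume read bases but no reference positions
  expect_equal(depth, oracle)
})

test_that("pileup TSV round-trips", {
  sim <- simulate_reads(
    ex_ref(), ex_endo(),
    params = sim_params(n_fragments = 300L, contamination = 0, seed = 3)
  )
  pu <- build_pileup(sim$reads, ex_ref())
  tsv <- tempfile(fileext = ".tsv")
  write_pileup_tsv(pu, tsv)
  back <- read_pileup_tsv(tsv)
  expect_identical(unname(back$counts), unname(pu$counts))
  expect_equal(back$ins, pu$ins)
  expect_equal(back$ref_name, pu$ref_name)
})
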