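# Majority-rule consensus calling and the variant table.

test_that("majority rule, depth gate, and ties behave as specified", {
  ref <- toy_ref(6L, seed = 2)
  counts <- matrix(0L, nrow = 6L, ncol = 6L)
  counts[1, ] <- c(0L, 98L, 0L, 2L, 0L, 0L)   # C 98 / T 2 -> call C
  counts[2, ] <- c(2L, 0L, 0L, 1L, 0L, 0L)    # depth 3 < min_cov -> N
  counts[3, ] <- c(30L, 30L, 0L, 0L, 0L, 0L)  # exact tie -> N
  counts[4, ] <- c(7L, 3L, 0L, 0L, 0L, 0L)    # 0.7 == min_frac -> call A
  counts[5, ] <- c(2L, 0L, 0L, 0L, 0L, 18L)   # deletion majority -> call del
  counts[6, ] <- c(6L, 4L, 0L, 0L, 0L, 0L)    # 0.6 < min_frac -> N
  pu <- toy_pileup(counts, ref)
  cc <- call_consensus(pu, ref, min_cov = 5L, min_frac = 0.7)
  expect_equal(cc$calls, c("C", "N", "N", "A", "-", "N"))
  expect_error(call_consensus(pu, ref, min_frac = 0.5), "min_frac")
  expect_error(call_consensus(pu, ref, min_cov = 0L), "min_cov")
  # variants: only where the call differs from the reference, never for N
  hap <- cc$haplotype
  expect_true(all(hap$kind %in% c("substitution", "deletion")))
  expect_true("5DEL" %in% hap$notation)
  expect_false(any(grepl("^2|^3|^6", hap$notation)))
})

test_that("insertion slots require support relative to the anchor depth", {
  ref <- toy_ref(5L, seed = 3)
  counts <- matrix(0L, nrow = 5L, ncol = 6L)
  counts[2, 1] <- 100L
  ins <- data.frame(position = 2L, ins_index = c(1L, 2L),
                    A = c(0L, 0L), C = c(90L, 40L), G = 0L, T = 0L, N = 0L)
  cc <- call_consensus(toy_pileup(counts, ref, ins), ref, min_cov = 10L, min_frac = 0.7)
  # k=1 passes (90/100), k=2 fails (40/100) and breaks the chain
  expect_equal(cc$insertions$ins_index, 1L)
  expect_true("2.1C" %in% cc$haplotype$notation)
  expect_false("2.2C" %in% cc$haplotype$notation)
})

test_that("a planted haplotype is recovered exactly from a clean simulation", {
  sim <- simulate_reads(
    ex_ref(), ex_endo(),
    params = sim_params(
      n_fragments = 6000L, contamination = 0, delta5 = 0, delta3 = 0,
      seq_error = 0, duplication_rate = 0, seed = 31
    )
  )
  pu <- build_pileup(sim$reads, ex_ref())
  cc <- call_consensus(pu, ex_ref())
  expect_same_haplotype(cc$haplotype, ex_endo())
  vt <- variant_table(cc)
  expect_equal(vt$n_diff, 35L)
  expect_equal(vt$n_total, 38L)
  # consensus idempotence: simulating off the called haplotype and
  # re-calling reproduces the same haplotype
  sim2 <- simulate_reads(
    ex_ref(), cc$haplotype,
    params = sim_params(
      n_fragments = 8000L, contamination = 0, delta5 = 0, delta3 = 0,
      seq_error = 0, duplication_rate = 0, seed = 32
    )
  )
  cc2 <- call_consensus(build_pileup(sim2$reads, ex_ref()), ex_ref())
  expect_same_haplotype(cc2$haplotype, cc$haplotype)
})

test_that("consensus tolerates low-level contamination, error, and damage", {
  sim <- simulate_reads(
    ex_ref(), ex_endo(), ex_contam(),
    params = sim_params(
      n_fragments = 20000L, contamination = 0.02, seq_error = 0.001,
      duplication_rate = 0, seed = 44
    )
  )
  pu <- build_pileup(sim$reads, ex_ref())
  cc <- call_consensus(pu, ex_ref())
  sites <- ex_sites()
  expect_true(all(pileup_depth(pu)[sites$position] >= 50))
  endo_alleles <- genome_vector(ex_ref(), ex_endo())[sites$position]
  expect_identical(cc$calls[sites$position], endo_alleles)
})

test_that("random planted haplotypes match a brute-force genome comparison", {
  ref <- toy_ref(600L, seed = 17, name = "rand")
  for (rep in 1:10) {
    hap <- withr::with_seed(5000 + rep, {
      pos <- sort(sample(seq(10L, 590L, by = 6L), 15L))
      toks <- vapply(seq_along(pos), function(i) {
        k <- sample(3L, 1L)
        if (k == 1L) {
          paste0(pos[i], sample(setdiff(c("A", "C", "G", "T"), ref_base(ref, pos[i])), 1L))
        } else if (k == 2L) {
          paste0(pos[i], ".1", sample(c("A", "C", "G", "T"), 1L))
        } else {
          paste0(pos[i], "DEL")
        }
      }, "")
      haplotype(toks, ref)
    })
    sim <- simulate_reads(
      ref, hap,
      params = sim_params(
        n_fragments = 2000L, contamination = 0, delta5 = 0, delta3 = 0,
        seq_error = 0, duplication_rate = 0, seed = 6000 + rep
      )
    )
    cc <- call_consensus(build_pileup(sim$reads, ref), ref, min_cov = 10L)
    expect_same_haplotype(cc$haplotype, hap)
    # brute-force oracle: applying both haplotypes gives identical genomes
    expect_identical(
      as.character(apply_variants(ref, cc$haplotype)),
      as.character(apply_variants(ref, hap))
    )
    expect_equal(diff_count(cc$haplotype, character(0)), nrow(hap))
  }
})

test_that("consensus sequence and VCF export are consistent with the calls", {
  ref <- circular_reference("ACGTACGTAC", name = "mini")
  counts <- matrix(0L, nrow = 10L, ncol = 6L)
  counts[cbind(1:10, match(strsplit("ACGTACGTAC", "")[[1]], c("A", "C", "G", "T")))] <- 20L
  counts[2, ] <- c(20L, 0L, 0L, 0L, 0L, 0L)  # substitution C->A
  counts[5, ] <- c(0L, 0L, 0L, 0L, 0L, 20L)  # deletion
  ins <- data.frame(position = 7L, ins_index = 1L, A = 0L, C = 0L, G = 18L, T = 0L, N = 0L)
  cc <- call_consensus(toy_pileup(counts, ref, ins), ref, min_cov = 5L, min_frac = 0.7)
  expect_setequal(cc$haplotype$notation, c("2A", "5DEL", "7.1G"))
  expect_equal(consensus_sequence(cc), "AAGTCGGTAC")
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(cc, ref, vcf)
  rows <- grep("^[^#]", readLines(vcf), value = TRUE)
  expect_equal(length(rows), 3L)
  f <- do.call(rbind, strsplit(rows, "\t"))
  expect_equal(f[, 2], c("2", "4", "7"))
  expect_equal(f[f[, 2] == "4", 4], "TA")  # anchored deletion
  expect_equal(f[f[, 2] == "4", 5], "T")
  expect_equal(f[f[, 2] == "7", 5], "GG")  # anchored insertion
})
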