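# Contamination estimators: pooled diagnostic rate, damage filter, mixture.

test_that("pooled diagnostic rate follows its definition", {
  ref <- toy_ref(10L, seed = 31)
  counts <- matrix(0L, nrow = 10L, ncol = 6L)
  counts[3, ] <- c(98L, 2L, 0L, 0L, 0L, 0L)   # expected A: 2 non-consensus
  counts[7, ] <- c(1L, 49L, 0L, 0L, 0L, 0L)   # expected C: 1 non-consensus
  pu <- toy_pileup(counts, ref)
  sites <- data.frame(position = c(3L, 7L), expected_allele = c("A", "C"))
  est <- estimate_diagnostic(pu, sites)
  expect_equal(est$rate, 3 / 150)
  expect_equal(est$n_bases, 150L)
  expect_equal(est$n_nonconsensus, 3L)
  expect_equal(est$n_positions, 2L)
  # deletions count as non-consensus, N-masked bases are excluded
  counts[3, ] <- c(90L, 0L, 0L, 0L, 5L, 10L)
  est2 <- estimate_diagnostic(toy_pileup(counts, ref), sites)
  expect_equal(est2$n_bases, 150L)
  expect_equal(est2$n_nonconsensus, 11L)
  # all-matching sites give rate 0 with ci_low 0
  counts[3, ] <- c(100L, 0L, 0L, 0L, 0L, 0L)
  counts[7, ] <- c(0L, 50L, 0L, 0L, 0L, 0L)
  est3 <- estimate_diagnostic(toy_pileup(counts, ref), sites)
  expect_equal(est3$rate, 0)
  expect_equal(est3$ci_low, 0)
  # errors: zero-coverage site (named), empty site set
  counts[7, ] <- 0L
  expect_error(estimate_diagnostic(toy_pileup(counts, ref), sites), "7")
  expect_error(estimate_diagnostic(pu, sites[0, ]), "empty")
})

test_that("Wilson interval matches the independent oracle", {
  for (case in list(c(3, 150), c(0, 80), c(17, 1000), c(50, 50), c(1, 10000))) {
    x <- case[1]; n <- case[2]
    got <- wilson_interval(x, n, 0.95)
    oracle <- stats::prop.test(x, n, correct = FALSE)$conf.int
    expect_equal(got[1], oracle[1], tolerance = 1e-10)
    expect_equal(got[2], oracle[2], tolerance = 1e-10)
  }
})

test_that("bootstrap CI is seeded, deterministic, and brackets the estimate", {
  ref <- toy_ref(30L, seed = 35)
  counts <- matrix(0L, nrow = 30L, ncol = 6L)
  sites <- data.frame(position = 1:20, expected_allele = ref_base(ref, 1:20))
  for (p in 1:20) {
    counts[p, match(ref_base(ref, p), c("A", "C", "G", "T"))] <- 95L
    counts[p, 5L] <- 0L
    counts[p, match(setdiff(c("A", "C", "G", "T"), ref_base(ref, p))[1], c("A", "C", "G", "T"))] <- 5L
  }
  pu <- toy_pileup(counts, ref)
  b1 <- estimate_diagnostic(pu, sites, ci = "bootstrap", boot_seed = 9L)
  b2 <- estimate_diagnostic(pu, sites, ci = "bootstrap", boot_seed = 9L)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$ci_high, b2$ci_high)
  expect_lte(b1$ci_low, b1$rate)
  expect_gte(b1$ci_high, b1$rate)
})

test_that("the damage filter excludes only damage-consistent C/G sites", {
  ref <- toy_ref(10L, seed = 33)
  counts <- matrix(0L, nrow = 10L, ncol = 6L)
  counts[1, ] <- c(0L, 100L, 0L, 2L, 0L, 0L)  # expected C with T observed -> excluded
  counts[2, ] <- c(2L, 100L, 0L, 0L, 0L, 0L)  # expected C with A mismatch -> retained
  counts[3, ] <- c(0L, 5L, 0L, 100L, 0L, 0L)  # expected T -> retained regardless
  counts[4, ] <- c(3L, 0L, 100L, 0L, 0L, 0L)  # expected G with A observed -> excluded
  pu <- toy_pileup(counts, ref)
  sites <- data.frame(
    position = 1:4, expected_allele = c("C", "C", "T", "G"),
    stringsAsFactors = FALSE
  )
  fl <- damage_filter_sites(sites, pu)
  expect_equal(fl$sites$position, c(2L, 3L))
  expect_equal(fl$excluded$position, c(1L, 4L))
  expect_match(fl$excluded$reason[1], "deamination")
  # a higher presence threshold relaxes the filter
  fl2 <- damage_filter_sites(sites, pu, min_obs = 4L)
  expect_equal(fl2$sites$position, c(1L, 2L, 3L, 4L))
})

test_that("pileup-based estimate equals a brute-force recount", {
  # 100 random toy pileups against independent arithmetic
  for (rep in 1:100) {
    dat <- withr::with_seed(rep, {
      m <- sample(3:12, 1)
      sites <- data.frame(
        position = sample(50L, m),
        expected_allele = sample(c("A", "C", "G", "T"), m, replace = TRUE),
        stringsAsFactors = FALSE
      )
      counts <- matrix(rpois(50L * 6L, 8), nrow = 50L)
      list(sites = sites, counts = counts)
    })
    ref <- toy_ref(50L, seed = 1)
    est <- estimate_diagnostic(toy_pileup(dat$counts, ref), dat$sites)
    num <- den <- 0L
    for (i in seq_len(nrow(dat$sites))) {
      row <- dat$counts[dat$sites$position[i], ]
      den <- den + sum(row[c(1:4, 6)])
      num <- num + sum(row[c(1:4, 6)]) -
        row[match(dat$sites$expected_allele[i], c("A", "C", "G", "T"))]
    }
    expect_equal(est$rate, num / den)
  }
  # and from raw simulated reads, bypassing the pileup entirely
  sim <- simulate_reads(
    ex_ref(), ex_endo(), ex_contam(),
    params = sim_params(n_fragments = 5000L, contamination = 0.05,
                        duplication_rate = 0, seed = 91)
  )
  pu <- build_pileup(sim$reads, ex_ref())
  est <- estimate_diagnostic(pu, ex_sites())
  rc <- recount_diagnostic(sim$reads, ex_sites(), ex_ref())
  expect_equal(est$n_bases, rc$n_bases)
  expect_equal(est$n_nonconsensus, rc$n_nonconsensus)
  expect_equal(est$rate, rc$rate)
})

test_that("mixture maximizer equals exhaustive evaluation on a 2-read instance", {
  L <- 40L
  endoV <- rep("A", L)
  panelV <- endoV
  panelV[10] <- "G"
  rds <- reads_df(
    make_read("e", 5L, strrep("A", 10)),           # matches endo everywhere
    make_read("c", 5L, paste0(strrep("A", 5), "G", strrep("A", 4))) # panel at 10
  )
  eps <- 0.01
  grid <- seq(0, 1, length.out = 1001L)
  est <- estimate_mixture(rds, endoV, list(panelV), eps = eps, grid = grid)
  # oracle: direct evaluation of the 2-read likelihood over the same grid
  aE <- c(10 * log(1 - eps), 9 * log(1 - eps) + log(eps / 3))
  aP <- c(9 * log(1 - eps) + log(eps / 3), 10 * log(1 - eps))
  ll <- vapply(grid, function(p) sum(log((1 - p) * exp(aE) + p * exp(aP))), 0)
  expect_equal(est$rate, grid[which.max(ll)])
  expect_equal(est$loglik, ll, tolerance = 1e-9)
  cutoff <- max(ll) - stats::qchisq(0.95, 1) / 2
  expect_equal(c(est$ci_low, est$ci_high), range(grid[ll >= cutoff]))
  expect_equal(est$n_discriminating_reads, 2L)
})

test_that("mixture boundary and uninformative cases are flagged", {
  endoV <- rep("C", 30L)
  panelV <- endoV
  panelV[5] <- "T"
  pure <- reads_df(make_read("r1", 1L, strrep("C", 20)), make_read("r2", 8L, strrep("C", 15)))
  est0 <- estimate_mixture(pure, endoV, list(panelV), eps = 0.01)
  expect_equal(est0$rate, 0)
  expect_true("boundary" %in% est0$flags)
  # panel identical to the endogenous genome: nothing discriminates
  estu <- estimate_mixture(pure, endoV, list(endoV), eps = 0.01)
  expect_true("uninformative" %in% estu$flags)
  expect_error(estimate_mixture(pure, endoV, list(), eps = 0.01), "empty")
  expect_error(estimate_mixture(pure, endoV, list(panelV), eps = 0.3), "eps")
})

test_that("mixture estimate is consistent on a scaled-down simulation", {
  # scaled down from the stated n=20,000/20-seed experiment to keep the
  # default suite fast; the full-strength behaviour is exercised through the
  # acceptance criteria
  sim <- simulate_reads(
    ex_ref(), ex_endo(), ex_contam(),
    params = sim_params(
      n_fragments = 8000L, contamination = 0.05, delta5 = 0, delta3 = 0,
      seq_error = 0.001, duplication_rate = 0, seed = 71
    )
  )
  endoV <- genome_vector(ex_ref(), ex_endo())
  panel <- list(genome_vector(ex_ref(), ex_contam()))
  est <- estimate_mixture(sim$reads, endoV, panel, eps = 0.001)
  expect_lt(abs(est$rate - 0.05), 0.015)
  expect_true(est$ci_low <= 0.05 && 0.05 <= est$ci_high)
})

test_that("filtered diagnostic and mixture estimates agree without damage", {
  sim <- noise_free_50k()
  dd <- deduplicate(sim$reads)
  pu <- build_pileup(dd$reads, ex_ref())
  fl <- damage_filter_sites(ex_sites(), pu)
  diag <- estimate_diagnostic(pu, fl$sites, method_tag = "diagnostic_filtered")
  mix <- estimate_mixture(
    dd$reads, genome_vector(ex_ref(), ex_endo()),
    list(genome_vector(ex_ref(), ex_contam())), eps = 0.001
  )
  # overlapping confidence intervals
  expect_true(diag$ci_low <= mix$ci_high && mix$ci_low <= diag$ci_high)
})
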