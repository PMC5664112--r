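# Contamination estimation: (i) pooled non-consensus base rate at
# haplogroup-diagnostic positions, with a damage-aware position filter, and
# (ii) a likelihood-mixture estimator over reads against a contaminant panel.

new_contam_estimate <- function(method, rate, ci, level, n_positions, n_bases,
                                n_nonconsensus, flags = character(0)) {
  structure(
    list(
      method = method, rate = rate, ci_low = ci[1], ci_high = ci[2],
      ci_level = level, n_positions = n_positions, n_bases = n_bases,
      n_nonconsensus = n_nonconsensus, flags = flags
    ),
    class = "contam_estimate"
  )
}

#' @export
print.contam_estimate <- function(x, ...) {
  cat(sprintf(
    "<contam_estimate> %s: %.3f%% (%d%% CI %.3f%%-%.3f%%)%s\n",
    x$method, 100 * x$rate, round(100 * x$ci_level), 100 * x$ci_low,
    100 * x$ci_high,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""
  ))
  invisible(x)
}

#' Wilson score interval for a pooled binomial count
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return `c(low, high)`.
#' @export
wilson_interval <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  # at the boundaries centre - half is exactly 0 (resp. 1) analytically;
  # pin them so floating-point jitter cannot exclude the boundary
  low <- if (x == 0) 0 else max(0, centre - half)
  high <- if (x == n) 1 else min(1, centre + half)
  c(low, high)
}

#' Contamination from non-consensus bases at diagnostic positions
#'
#' Pools the base counts at the diagnostic sites: the denominator is the sum
#' of site depths (N-masked bases excluded), the numerator the count of bases
#' differing from each site's expected endogenous allele (deletion
#' observations count as non-consensus). The CI is computed on the pooled
#' counts — Wilson score by default, or a seeded position-level nonparametric
#' bootstrap.
#'
#' @param pileup an `mt_pileup`.
#' @param sites data frame with `position` and `expected_allele` columns
#'   ([diagnostic_positions()]).
#' @param ci `"wilson"` or `"bootstrap"`.
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap resamples (default 2000).
#' @param boot_seed seed for the bootstrap resampling.
#' @param method_tag method label recorded in the estimate (default
#'   `"diagnostic"`).
#' @return a `contam_estimate`.
#' @export
estimate_diagnostic <- function(pileup, sites, ci = c("wilson", "bootstrap"),
                                level = 0.95, n_boot = 2000L, boot_seed = 1L,
                                method_tag = "diagnostic") {
  ci <- match.arg(ci)
  if (is.null(sites) || !nrow(sites)) stop("the diagnostic site set is empty")
  if (!all(sites$expected_allele %in% BASES)) {
    stop("expected alleles must be A/C/G/T")
  }
  cm <- pileup$counts[sites$position, c("A", "C", "G", "T", "del"), drop = FALSE]
  depth <- rowSums(cm)
  if (any(depth == 0)) {
    stop(
      "zero coverage at diagnostic position(s): ",
      paste(sites$position[depth == 0], collapse = ", ")
    )
  }
  expct <- cm[cbind(seq_len(nrow(sites)), match(sites$expected_allele, c("A", "C", "G", "T", "del")))]
  noncons <- depth - expct
  n_bases <- as.integer(sum(depth))
  n_non <- as.integer(sum(noncons))
  rate <- n_non / n_bases
  bounds <- if (ci == "wilson") {
    wilson_interval(n_non, n_bases, level)
  } else {
    reps <- with_local_seed(boot_seed, {
      m <- nrow(sites)
      vapply(seq_len(n_boot), function(b) {
        pick <- sample.int(m, m, replace = TRUE)
        sum(noncons[pick]) / sum(depth[pick])
      }, 0)
    })
    unname(stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  new_contam_estimate(
    method_tag, rate, bounds, level,
    n_positions = nrow(sites), n_bases = n_bases, n_nonconsensus = n_non
  )
}

#' Damage-aware filtering of diagnostic positions
#'
#' A site is excluded iff its expected allele is C or G and the pileup there
#' contains at least `min_obs` observations of the deamination product (T
#' when C is expected, A when G is expected). This removes positions where
#' apparent contamination could instead be post-mortem damage; all other
#' sites are retained.
#'
#' @param sites diagnostic sites ([diagnostic_positions()]).
#' @param pileup an `mt_pileup`.
#' @param profile optional `damage_profile`; when given, its terminal rates
#'   are recorded in the exclusion reasons for context.
#' @param min_obs minimum damage-product count triggering exclusion
#'   (default 1, i.e. presence).
#' @return list with `sites` (retained) and `excluded` (data frame
#'   `position`, `expected_allele`, `reason`).
#' @export
damage_filter_sites <- function(sites, pileup, profile = NULL, min_obs = 1L) {
  prod_base <- c(C = "T", G = "A")[sites$expected_allele]
  n_prod <- integer(nrow(sites))
  has <- !is.na(prod_base)
  if (any(has)) {
    n_prod[has] <- pileup$counts[cbind(sites$position[has], match(prod_base[has], PILEUP_CLASSES))]
  }
  excl <- has & n_prod >= min_obs
  ctx <- if (!is.null(profile)) {
    sprintf(
      " (library terminal C>T %.2f%%, G>A %.2f%%)",
      100 * profile$terminal_ct_rate, 100 * profile$terminal_ga_rate
    )
  } else {
    ""
  }
  list(
    sites = sites[!excl, , drop = FALSE],
    excluded = data.frame(
      position = sites$position[excl],
      expected_allele = sites$expected_allele[excl],
      reason = if (any(excl)) {
        sprintf(
          "%d %s observation(s) consistent with deamination of expected %s%s",
          n_prod[excl], prod_base[excl], sites$expected_allele[excl], ctx
        )
      } else {
        character(0)
      },
      stringsAsFactors = FALSE
    )
  )
}

# Per-read match/mismatch counts against a reference-coordinate genome
# vector. Reads are compared in substitution space: N read bases and
# deleted/N genome positions are skipped.
read_genome_mismatches <- function(positions, chars, read_of, genomes, n_reads) {
  lapply(genomes, function(g) {
    gb <- g[positions]
    valid <- chars %in% BASES & gb != "-" & gb != "N"
    mism <- valid & chars != gb
    gather <- function(v) {
      out <- integer(n_reads)
      tmp <- rowsum(as.integer(v), read_of)
      out[as.integer(rownames(tmp))] <- as.integer(tmp)
      out
    }
    list(n = gather(valid), m = gather(mism))
  })
}

aligned_elements <- function(reads, include_del = FALSE) {
  pure <- is_pure_match_cigar(reads$cigar)
  pos <- integer(0); ch <- character(0); rd <- integer(0)
  if (any(pure)) {
    plen <- nchar(reads$seq[pure])
    pos <- sequence(plen, from = reads$start[pure])
    ch <- unlist(strsplit(reads$seq[pure], NULL), use.names = FALSE)
    rd <- rep.int(which(pure), plen)
  }
  for (i in which(!pure)) {
    ops <- parse_cigar(reads$cigar[i])
    sq <- strsplit(reads$seq[i], "")[[1]]
    rc <- reads$start[i]; qc <- 1L
    for (j in seq_along(ops$op)) {
      w <- ops$len[j]; op <- ops$op[j]
      if (op %in% c("M", "=", "X")) {
        pos <- c(pos, rc:(rc + w - 1L))
        ch <- c(ch, sq[qc:(qc + w - 1L)])
        rd <- c(rd, rep.int(i, w))
        rc <- rc + w; qc <- qc + w
      } else if (op == "I" || op == "S") {
        qc <- qc + w
      } else if (op == "D") {
        if (include_del) {
          pos <- c(pos, rc:(rc + w - 1L))
          ch <- c(ch, rep.int("-", w))
          rd <- c(rd, rep.int(i, w))
        }
        rc <- rc + w
      }
    }
  }
  list(pos = pos, chars = ch, read_of = rd)
}

#' Likelihood-mixture contamination estimate over reads
#'
#' Each read's likelihood under a genome is the product over its aligned
#' non-N positions of `1 - eps` for matches and `eps/3` for mismatches. The
#' mixture likelihood at contaminant proportion `p` is, per read,
#' `(1-p) L(endogenous) + p mean(L(panel))`, maximized over a grid on
#' `[0, 1]`; the interval is the profile-likelihood set within
#' `qchisq(level, 1)/2` log-units of the maximum. Reads overlapping no
#' discriminating position contribute a constant and do not bias the
#' estimate.
#'
#' @param reads an `mt_reads` data frame.
#' @param endo_genome endogenous genome as a reference-coordinate base
#'   vector; build one from a haplotype with [genome_vector()].
#' @param panel non-empty list of contaminant genome vectors (same form).
#' @param eps per-base error rate in `(0, 0.25)`.
#' @param grid grid of candidate proportions (default 1001 points on
#'   `[0, 1]`).
#' @param level confidence level for the profile-likelihood interval.
#' @return a `contam_estimate` (method `"mixture"`), with flags `"boundary"`
#'   when the maximizer sits on the grid edge and `"uninformative"` when no
#'   read discriminates.
#' @export
estimate_mixture <- function(reads, endo_genome, panel, eps = 0.01,
                             grid = seq(0, 1, length.out = 1001L), level = 0.95) {
  if (!length(panel)) stop("the contaminant panel is empty")
  if (!(eps > 0 && eps < 0.25)) stop("eps must lie in (0, 0.25)")
  if (!nrow(reads)) stop("no reads supplied")
  el <- aligned_elements(reads)
  # collapse segment rows to fragments for counting purposes
  frag_id <- match(reads$id, unique(reads$id))
  el$read_of <- frag_id[el$read_of]
  counts <- read_genome_mismatches(
    el$pos, el$chars, el$read_of, c(list(endo_genome), panel),
    n_reads = length(unique(reads$id))
  )
  a_endo <- counts[[1]]$m * log(eps / 3) + (counts[[1]]$n - counts[[1]]$m) * log(1 - eps)
  a_panel_mat <- vapply(counts[-1], function(ct) {
    ct$m * log(eps / 3) + (ct$n - ct$m) * log(1 - eps)
  }, numeric(length(a_endo)))
  if (is.null(dim(a_panel_mat))) a_panel_mat <- matrix(a_panel_mat, nrow = 1L)
  mx <- apply(a_panel_mat, 1L, max)
  a_panel <- mx + log(rowMeans(exp(a_panel_mat - mx)))
  discr <- abs(a_endo - a_panel) > 1e-12
  flags <- character(0)
  if (!any(discr)) flags <- c(flags, "uninformative")
  m0 <- pmax(a_endo, a_panel)
  eE <- exp(a_endo - m0)
  eP <- exp(a_panel - m0)
  ll <- vapply(grid, function(p) sum(m0 + log((1 - p) * eE + p * eP)), 0)
  best <- which.max(ll)
  if (best == 1L || best == length(grid)) flags <- c(flags, "boundary")
  cutoff <- max(ll) - stats::qchisq(level, df = 1) / 2
  inside <- grid[ll >= cutoff]
  est <- new_contam_estimate(
    "mixture", grid[best], range(inside), level,
    n_positions = NA_integer_, n_bases = length(el$pos),
    n_nonconsensus = NA_integer_, flags = flags
  )
  est$loglik <- ll
  est$grid <- grid
  est$n_discriminating_reads <- sum(discr)
  est
}

#' Brute-force recount of the diagnostic estimator from raw reads
#'
#' Independent of the pileup path: walks every read's aligned bases and
#' counts matches/mismatches at the diagnostic sites directly. Used to
#' cross-check [estimate_diagnostic()].
#'
#' @inheritParams estimate_mixture
#' @param sites diagnostic sites.
#' @return list with `n_bases`, `n_nonconsensus`, `rate`.
#' @export
recount_diagnostic <- function(reads, sites, ref) {
  el <- aligned_elements(reads, include_del = TRUE)
  keep <- el$pos %in% sites$position & el$chars != "N"
  pos <- el$pos[keep]
  ch <- el$chars[keep]
  expct <- sites$expected_allele[match(pos, sites$position)]
  n_bases <- length(pos)
  n_non <- sum(ch != expct)
  list(n_bases = n_bases, n_nonconsensus = n_non,
       rate = if (n_bases) n_non / n_bases else NA_real_)
}
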