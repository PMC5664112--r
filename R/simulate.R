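# Ancient-read simulator: fragments from an endogenous genome with a
# contaminant lineage admixed at a set fraction, a truncated log-normal
# fragment-length model, strand-specific terminal deamination with geometric
# decay into the fragment (optionally attenuated by UDG treatment),
# independent sequencing error, and Poisson PCR duplication.

#' Simulation parameters
#'
#' @param n_fragments number of unique fragments to simulate (before PCR
#'   duplication).
#' @param frag_len_mean,frag_len_sd mean and sd (bp) of the log-normal
#'   fragment-length model, truncated to `[frag_len_min, frag_len_max]`.
#'   Defaults 68 and 15 bp, matching typical well-preserved ancient material.
#' @param contamination fraction `c` in `[0, 1]` of fragments drawn from the
#'   contaminant genome.
#' @param delta5 probability of C->T at the 5' terminal read position.
#' @param delta3 probability of G->A at the 3' terminal read position.
#' @param rho per-base geometric decay in `(0, 1)` of the deamination
#'   probability with distance from the fragment end.
#' @param udg_residual multiplier `u` in `[0, 1]` applied to `delta5`/`delta3`
#'   for UDG-treated libraries (1 = untreated).
#' @param seq_error per-base miscall probability (uniform over the three other
#'   bases), applied after damage.
#' @param duplication_rate expected number of PCR duplicate copies per unique
#'   fragment (Poisson); duplicates are exact copies. Default 4, giving the
#'   roughly 80% duplicate fraction seen in heavily amplified capture
#'   libraries.
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   output.
#' @param frag_len_min,frag_len_max truncation bounds in bp.
#' @param library library tag written to reads; by default `"UDG"` when
#'   `udg_residual < 1`, else `"non-UDG"`.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n_fragments = 50000L, frag_len_mean = 68, frag_len_sd = 15,
                       contamination = 0, delta5 = 0.25, delta3 = 0.25, rho = 0.6,
                       udg_residual = 1, seq_error = 0.001, duplication_rate = 4,
                       seed = 1L, frag_len_min = 25L, frag_len_max = 150L,
                       library = NULL) {
  p <- list(
    n_fragments = as.integer(n_fragments), frag_len_mean = frag_len_mean,
    frag_len_sd = frag_len_sd, contamination = contamination, delta5 = delta5,
    delta3 = delta3, rho = rho, udg_residual = udg_residual,
    seq_error = seq_error, duplication_rate = duplication_rate,
    seed = as.integer(seed), frag_len_min = as.integer(frag_len_min),
    frag_len_max = as.integer(frag_len_max)
  )
  if (p$n_fragments < 1L) stop("n_fragments must be >= 1")
  if (p$frag_len_mean <= 0 || p$frag_len_sd <= 0) stop("fragment length mean/sd must be positive")
  probs <- c(contamination = p$contamination, delta5 = p$delta5, delta3 = p$delta3,
             udg_residual = p$udg_residual, seq_error = p$seq_error)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop("probabilities outside [0,1]: ", paste(names(probs)[bad], collapse = ", "))
  if (p$rho <= 0 || p$rho >= 1) stop("rho must lie in (0, 1)")
  if (p$duplication_rate < 0) stop("duplication_rate must be >= 0")
  if (p$frag_len_min < 1L || p$frag_len_max <= p$frag_len_min) stop("invalid fragment length bounds")
  p$library <- library %||% (if (p$udg_residual < 1) "UDG" else "non-UDG")
  class(p) <- "sim_params"
  p
}

lognormal_pars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Exact mean of the rounded, truncated log-normal length model
#'
#' The simulator draws log-normal lengths, rounds to the nearest bp, and
#' resamples values falling outside the truncation bounds, so the realized
#' distribution is the discretized log-normal renormalized on
#' `[frag_len_min, frag_len_max]`. This computes its mean exactly, for use as
#' an independent oracle.
#'
#' @param params a [sim_params()].
#' @return list with `mean` and `sd` of the length distribution.
#' @export
truncated_length_mean <- function(params) {
  lp <- lognormal_pars(params$frag_len_mean, params$frag_len_sd)
  k <- params$frag_len_min:params$frag_len_max
  w <- stats::plnorm(k + 0.5, lp$mu, lp$sigma) - stats::plnorm(k - 0.5, lp$mu, lp$sigma)
  w <- w / sum(w)
  m <- sum(k * w)
  list(mean = m, sd = sqrt(sum((k - m)^2 * w)))
}

sample_lengths <- function(n, params) {
  lp <- lognormal_pars(params$frag_len_mean, params$frag_len_sd)
  out <- integer(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- as.integer(round(stats::rlnorm(length(need), lp$mu, lp$sigma)))
    ok <- x >= params$frag_len_min & x <= params$frag_len_max
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# Genome augmented with plainness bookkeeping: an element transition is
# "irregular" when it involves an insertion slot or a reference-position jump,
# so pure-match fragments can be identified with two cumulative sums.
build_sim_genome <- function(ref, hap) {
  g <- apply_variants(ref, hap)
  g$string <- paste(g$bases, collapse = "")
  trans_irr <- c(
    FALSE,
    g$insidx[-1] != 0L | g$insidx[-g$length] != 0L | diff(g$refpos) != 1L
  )
  g$irr_cum <- cumsum(trans_irr)
  g
}

# CIGAR for one contiguous (non-wrapping) run of aligned elements.
cigar_of_run <- function(rp, ii) {
  ops <- character(0)
  lens <- integer(0)
  push <- function(op, n) {
    if (length(ops) && ops[length(ops)] == op) {
      lens[length(lens)] <<- lens[length(lens)] + n
    } else {
      ops <<- c(ops, op)
      lens <<- c(lens, n)
    }
  }
  prev <- NA_integer_
  for (j in seq_along(rp)) {
    if (ii[j] > 0L) {
      push("I", 1L)
    } else {
      if (!is.na(prev) && rp[j] - prev > 1L) push("D", rp[j] - prev - 1L)
      push("M", 1L)
      prev <- rp[j]
    }
  }
  paste0(lens, ops, collapse = "")
}

#' Simulate aligned ancient-DNA reads with known truth
#'
#' Each fragment's origin genome is contaminant with probability
#' `params$contamination`; its start is uniform on the circle and its strand
#' uniform. Damage is applied in read orientation: a C at 5'-offset `k`
#' becomes T with probability `u * delta5 * rho^k`, and symmetrically a G at
#' 3'-offset `k` becomes A with probability `u * delta3 * rho^k`; sequencing
#' errors follow independently at rate `seq_error`; PCR duplicates are exact
#' copies. Fragments spanning the circular origin are emitted as two SAM
#' segments sharing the read id, linked by the `XC` tag (`XC:i:1` for the
#' high-coordinate part, `XC:i:2` for the wrapped part).
#'
#' @param ref a [circular_reference()].
#' @param endo endogenous [haplotype()].
#' @param contam contaminant [haplotype()] (required when
#'   `params$contamination > 0`).
#' @param params a [sim_params()].
#' @return list with `reads` (an `mt_reads` data frame, one row per SAM
#'   segment, reference-oriented sequences) and `truth` (list: per-fragment
#'   data frame `reads` with origin/coordinates/strand/duplicate-of, damage
#'   event table `damage` for unique fragments in read-orientation offsets,
#'   `contaminant_fraction`, `mean_length`, and the `params` used).
#' @export
simulate_reads <- function(ref, endo, contam = NULL, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (params$contamination > 0 && is.null(contam)) {
    stop("contamination > 0 requires a contaminant haplotype")
  }
  if (ref$length <= params$frag_len_max) {
    stop("degenerate reference: shorter than the maximum fragment length")
  }
  gE <- build_sim_genome(ref, endo)
  gC <- if (!is.null(contam)) build_sim_genome(ref, contam)

  with_local_seed(params$seed, {
    n <- params$n_fragments
    oc <- stats::runif(n) < params$contamination
    len <- sample_lengths(n, params)
    start <- integer(n)
    if (any(!oc)) start[!oc] <- sample.int(gE$length, sum(!oc), replace = TRUE)
    if (any(oc)) start[oc] <- sample.int(gC$length, sum(oc), replace = TRUE)
    rev <- stats::runif(n) < 0.5

    # classify fragments: plain = pure-match, non-wrapping
    plain <- logical(n)
    for (which_o in list(FALSE, TRUE)) {
      sel <- oc == which_o
      if (!any(sel)) next
      g <- if (which_o) gC else gE
      s <- start[sel]
      e <- s + len[sel] - 1L
      ok <- e <= g$length
      ok[ok] <- g$insidx[s[ok]] == 0L & (g$irr_cum[e[ok]] - g$irr_cum[s[ok]]) == 0L
      plain[sel] <- ok
    }

    # element index into the origin genome, fragment by fragment
    lens <- len
    slow <- which(!plain)
    slow_idx <- vector("list", length(slow))
    for (j in seq_along(slow)) {
      i <- slow[j]
      g <- if (oc[i]) gC else gE
      idx <- ((start[i] - 1L + 0:(len[i] - 1L)) %% g$length) + 1L
      while (length(idx) && g$insidx[idx[1]] != 0L) idx <- idx[-1]
      while (length(idx) && g$insidx[idx[length(idx)]] != 0L) idx <- idx[-length(idx)]
      if (length(idx) < 2L) stop("degenerate fragment after insertion trimming")
      slow_idx[[j]] <- idx
      lens[i] <- length(idx)
    }
    ends_big <- cumsum(lens)
    starts_big <- ends_big - lens + 1L
    total <- ends_big[n]
    pl <- which(plain)
    u <- params$udg_residual
    # no noise -> fragment sequences are plain genome substrings and the
    # per-base element machinery can be skipped entirely
    noise <- u * max(params$delta5, params$delta3) > 0 || params$seq_error > 0

    # genome index of each fragment's first/last retained element
    first_idx <- integer(n)
    last_idx <- integer(n)
    first_idx[pl] <- start[pl]
    last_idx[pl] <- start[pl] + lens[pl] - 1L
    for (j in seq_along(slow)) {
      i <- slow[j]
      first_idx[i] <- slow_idx[[j]][1]
      last_idx[i] <- slow_idx[[j]][lens[i]]
    }
    frag_start_ref <- integer(n)
    frag_end_ref <- integer(n)
    if (any(!oc)) {
      frag_start_ref[!oc] <- gE$refpos[first_idx[!oc]]
      frag_end_ref[!oc] <- gE$refpos[last_idx[!oc]]
    }
    if (any(oc)) {
      frag_start_ref[oc] <- gC$refpos[first_idx[oc]]
      frag_end_ref[oc] <- gC$refpos[last_idx[oc]]
    }

    damage <- data.frame(
      fragment = integer(0), offset = integer(0), type = character(0),
      stringsAsFactors = FALSE
    )
    if (noise) {
      elem_idx <- integer(total)
      if (length(pl)) {
        elem_idx[sequence(lens[pl], from = starts_big[pl])] <- sequence(lens[pl], from = start[pl])
      }
      for (j in seq_along(slow)) {
        i <- slow[j]
        elem_idx[starts_big[i]:ends_big[i]] <- slow_idx[[j]]
      }
      frag_of <- rep.int(seq_len(n), lens)
      oc_e <- oc[frag_of]
      if (!any(oc_e)) {
        chars <- gE$bases[elem_idx]
      } else if (all(oc_e)) {
        chars <- gC$bases[elem_idx]
      } else {
        chars <- character(total)
        chars[!oc_e] <- gE$bases[elem_idx[!oc_e]]
        chars[oc_e] <- gC$bases[elem_idx[oc_e]]
      }
      dist_start <- sequence(lens) - 1L
      dist_end <- rep.int(lens, lens) - 1L - dist_start
      rev_e <- rev[frag_of]

      # deamination, in fragment (reference) orientation: forward reads read
      # the fragment as-is, reverse reads read its reverse complement, so the
      # read-orientation 5' C->T channel maps to fragment C->T (forward) or
      # fragment G->A at the far end (reverse).
      if (u * max(params$delta5, params$delta3) > 0) {
        pdam <- numeric(total)
        isC <- chars == "C"
        isG <- chars == "G"
        f <- isC & !rev_e
        pdam[f] <- u * params$delta5 * params$rho^dist_start[f]
        f <- isC & rev_e
        pdam[f] <- u * params$delta3 * params$rho^dist_start[f]
        f <- isG & !rev_e
        pdam[f] <- u * params$delta3 * params$rho^dist_end[f]
        f <- isG & rev_e
        pdam[f] <- u * params$delta5 * params$rho^dist_end[f]
        hit <- stats::runif(total) < pdam
        hitC <- hit & isC
        hitG <- hit & isG
        chars[hitC] <- "T"
        chars[hitG] <- "A"
        dmg <- which(hit)
        damage <- data.frame(
          fragment = frag_of[dmg],
          offset = ifelse(rev_e[dmg], dist_end[dmg], dist_start[dmg]),
          type = ifelse(
            (isC[dmg] & !rev_e[dmg]) | (isG[dmg] & rev_e[dmg]),
            "C>T", "G>A"
          ),
          stringsAsFactors = FALSE
        )
      }

      # sequencing error after damage
      if (params$seq_error > 0) {
        err <- stats::runif(total) < params$seq_error & chars %in% BASES
        ne <- sum(err)
        if (ne) {
          shift <- sample.int(3L, ne, replace = TRUE)
          code <- match(chars[err], BASES)
          chars[err] <- BASES[((code - 1L + shift) %% 4L) + 1L]
        }
      }
      big <- paste(chars, collapse = "")
      plain_seq <- substring(big, starts_big[pl], ends_big[pl])
      slow_chars <- function(j) chars[starts_big[slow[j]]:ends_big[slow[j]]]
    } else {
      sel_c <- oc[pl]
      plain_seq <- character(length(pl))
      if (any(!sel_c)) {
        plain_seq[!sel_c] <- substring(
          gE$string, start[pl[!sel_c]], start[pl[!sel_c]] + lens[pl[!sel_c]] - 1L
        )
      }
      if (any(sel_c)) {
        plain_seq[sel_c] <- substring(
          gC$string, start[pl[sel_c]], start[pl[sel_c]] + lens[pl[sel_c]] - 1L
        )
      }
      slow_chars <- function(j) {
        g <- if (oc[slow[j]]) gC else gE
        g$bases[slow_idx[[j]]]
      }
    }

    # per-fragment SAM segments: plain fragments first, then the slow ones
    ids <- sprintf("frag%07d", seq_len(n))
    sl_pos <- vector("list", length(slow))
    sl_cigar <- vector("list", length(slow))
    sl_seq <- vector("list", length(slow))
    sl_tag <- vector("list", length(slow))
    sl_nseg <- integer(length(slow))
    for (j in seq_along(slow)) {
      i <- slow[j]
      g <- if (oc[i]) gC else gE
      idx <- slow_idx[[j]]
      rps <- g$refpos[idx]
      iis <- g$insidx[idx]
      chs <- slow_chars(j)
      anchors <- which(iis == 0L)
      wrap_at <- anchors[which(diff(rps[anchors]) < 0L)]
      cuts <- if (length(wrap_at)) c(0L, wrap_at, length(idx)) else c(0L, length(idx))
      nseg <- length(cuts) - 1L
      sl_nseg[j] <- nseg
      pos_k <- integer(nseg); cig_k <- character(nseg); seq_k <- character(nseg)
      for (k in seq_len(nseg)) {
        part <- (cuts[k] + 1L):cuts[k + 1L]
        pos_k[k] <- rps[part][iis[part] == 0L][1]
        cig_k[k] <- cigar_of_run(rps[part], iis[part])
        seq_k[k] <- paste(chs[part], collapse = "")
      }
      sl_pos[[j]] <- pos_k
      sl_cigar[[j]] <- cig_k
      sl_seq[[j]] <- seq_k
      sl_tag[[j]] <- if (nseg > 1L) seq_len(nseg) else 0L
    }
    seg_frag <- c(pl, rep.int(slow, sl_nseg))
    seg_id <- ids[seg_frag]
    seg_pos <- c(frag_start_ref[pl], unlist(sl_pos, use.names = FALSE))
    seg_cigar <- c(paste0(lens[pl], "M"), unlist(sl_cigar, use.names = FALSE))
    seg_seq <- c(plain_seq, unlist(sl_seq, use.names = FALSE))
    seg_strand <- ifelse(rev[seg_frag], "-", "+")
    seg_tag <- c(integer(length(pl)), unlist(sl_tag, use.names = FALSE))

    # PCR duplication: exact copies of every segment, new ids
    ndup <- if (params$duplication_rate > 0) {
      stats::rpois(n, params$duplication_rate)
    } else {
      integer(n)
    }
    seg_qual <- strrep("?", nchar(seg_seq))
    copies_row <- 1L + ndup[seg_frag]
    rep_rows <- rep.int(seq_along(seg_id), copies_row)
    cpy <- sequence(copies_row) - 1L
    out_id <- seg_id[rep_rows]
    dupd <- cpy > 0L
    if (any(dupd)) out_id[dupd] <- paste0(out_id[dupd], ".d", cpy[dupd])
    reads <- new_reads(data.frame(
      id = out_id,
      start = seg_pos[rep_rows],
      strand = seg_strand[rep_rows],
      mapq = 60L,
      cigar = seg_cigar[rep_rows],
      seq = seg_seq[rep_rows],
      qual = seg_qual[rep_rows],
      library = params$library,
      segment = seg_tag[rep_rows],
      stringsAsFactors = FALSE
    ))

    fcopies <- 1L + ndup
    frep <- rep.int(seq_len(n), fcopies)
    fcpy <- sequence(fcopies) - 1L
    truth_id <- ids[frep]
    fdup <- fcpy > 0L
    if (any(fdup)) truth_id[fdup] <- paste0(truth_id[fdup], ".d", fcpy[fdup])
    truth_reads <- data.frame(
      id = truth_id,
      origin = ifelse(oc[frep], "contaminant", "endogenous"),
      frag_start = frag_start_ref[frep],
      frag_end = frag_end_ref[frep],
      strand = ifelse(rev[frep], "-", "+"),
      length = lens[frep],
      duplicate_of = ifelse(fcpy == 0L, NA_character_, ids[frep]),
      stringsAsFactors = FALSE
    )
    damage$id <- ids[damage$fragment]
    truth <- list(
      reads = truth_reads,
      damage = damage[, c("id", "offset", "type")],
      contaminant_fraction = mean(oc),
      mean_length = mean(lens),
      params = unclass(params)
    )
    list(reads = reads, truth = truth)
  })
}
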