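# Misincorporation-by-offset tables and fragment-length statistics: the two
# empirical authenticity diagnostics for ancient DNA.

#' Terminal misincorporation profile
#'
#' Tabulates, in read orientation, C->T mismatches by offset from the 5' end
#' and G->A mismatches by offset from the 3' end — the two substitution
#' classes diagnostic of post-mortem cytosine deamination. For each read and
#' offset `0..K-1`, a position whose strand-adjusted reference base is C (5'
#' table) or G (3' table) counts one opportunity, and one observation when the
#' read base is the damage product. N bases are skipped. Reads shorter than
#' `2K` contribute to both ends independently; no position is double-counted
#' within one end's table.
#'
#' @param reads an `mt_reads` data frame (reference-oriented sequences;
#'   origin-wrapping fragments re-joined via their `XC` tags).
#' @param ref a [circular_reference()].
#' @param K window size in bp from each end (default 25).
#' @return a `damage_profile`: `K`, data frames `five_prime` / `three_prime`
#'   (`offset`, `opportunities`, `observations`, `rate`), and the offset-0
#'   `terminal_ct_rate` / `terminal_ga_rate`.
#' @export
misincorporation_profile <- function(reads, ref, K = 25L) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  opp5 <- obs5 <- opp3 <- obs3 <- integer(K)
  L <- ref$length

  tally <- function(adjref, adjread, off5, off3) {
    s5 <- adjref == "C" & adjread != "N" & off5 < K
    if (any(s5)) {
      opp5 <<- opp5 + tabulate(off5[s5] + 1L, K)
      h5 <- s5 & adjread == "T"
      if (any(h5)) obs5 <<- obs5 + tabulate(off5[h5] + 1L, K)
    }
    s3 <- adjref == "G" & adjread != "N" & off3 < K
    if (any(s3)) {
      opp3 <<- opp3 + tabulate(off3[s3] + 1L, K)
      h3 <- s3 & adjread == "A"
      if (any(h3)) obs3 <<- obs3 + tabulate(off3[h3] + 1L, K)
    }
  }

  if (nrow(reads)) {
    pure <- is_pure_match_cigar(reads$cigar) & reads$segment == 0L
    if (any(pure)) {
      plen <- nchar(reads$seq[pure])
      pos_all <- sequence(plen, from = reads$start[pure])
      if (max(pos_all) > L) stop("read positions beyond the reference length")
      chars <- unlist(strsplit(reads$seq[pure], NULL), use.names = FALSE)
      refc <- ref$bases[pos_all]
      d5 <- sequence(plen) - 1L
      d3 <- rep.int(plen, plen) - 1L - d5
      rev_e <- rep.int(reads$strand[pure] == "-", plen)
      adjref <- refc
      adjref[rev_e] <- comp_bases(refc[rev_e])
      adjread <- chars
      adjread[rev_e] <- comp_bases(chars[rev_e])
      off5 <- d5
      off5[rev_e] <- d3[rev_e]
      off3 <- d3
      off3[rev_e] <- d5[rev_e]
      tally(adjref, adjread, off5, off3)
    }
    rest <- reads[!(is_pure_match_cigar(reads$cigar) & reads$segment == 0L), , drop = FALSE]
    if (nrow(rest)) {
      for (d in split(rest, rest$id)) {
        d <- d[order(d$segment), , drop = FALSE]
        rp <- integer(0); rb <- character(0); qp <- integer(0)
        read_cursor <- 0L
        for (s in seq_len(nrow(d))) {
          ops <- parse_cigar(d$cigar[s])
          sq <- strsplit(d$seq[s], "")[[1]]
          rc <- d$start[s]
          qc <- 1L
          for (j in seq_along(ops$op)) {
            w <- ops$len[j]
            op <- ops$op[j]
            if (op %in% c("M", "=", "X")) {
              rp <- c(rp, rc:(rc + w - 1L))
              rb <- c(rb, sq[qc:(qc + w - 1L)])
              qp <- c(qp, read_cursor + qc:(qc + w - 1L))
              rc <- rc + w; qc <- qc + w
            } else if (op == "I" || op == "S") {
              qc <- qc + w
            } else if (op == "D") {
              rc <- rc + w
            }
          }
          read_cursor <- read_cursor + length(sq)
        }
        if (!length(rp)) next
        if (max(rp) > L) stop("read ", d$id[1], " walks off the reference")
        total_len <- read_cursor
        refc <- ref$bases[rp]
        if (d$strand[1] == "-") {
          adjref <- comp_bases(refc)
          adjread <- comp_bases(rb)
          off5 <- total_len - qp
          off3 <- qp - 1L
        } else {
          adjref <- refc
          adjread <- rb
          off5 <- qp - 1L
          off3 <- total_len - qp
        }
        tally(adjref, adjread, off5, off3)
      }
    }
  }

  rate <- function(obs, opp) ifelse(opp > 0L, obs / opp, 0)
  five <- data.frame(
    offset = 0:(K - 1L), opportunities = opp5, observations = obs5,
    rate = rate(obs5, opp5)
  )
  three <- data.frame(
    offset = 0:(K - 1L), opportunities = opp3, observations = obs3,
    rate = rate(obs3, opp3)
  )
  structure(
    list(
      K = K, five_prime = five, three_prime = three,
      terminal_ct_rate = five$rate[1], terminal_ga_rate = three$rate[1]
    ),
    class = "damage_profile"
  )
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf(
    "<damage_profile> K=%d; 5' terminal C>T %.2f%%, 3' terminal G>A %.2f%%\n",
    x$K, 100 * x$terminal_ct_rate, 100 * x$terminal_ga_rate
  ))
  invisible(x)
}

#' @describeIn misincorporation_profile plot rate against offset for both
#'   ends (base graphics).
#' @param x a `damage_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.damage_profile <- function(x, ...) {
  ylim <- c(0, max(x$five_prime$rate, x$three_prime$rate, 0.01))
  graphics::plot(
    x$five_prime$offset, x$five_prime$rate, type = "b", pch = 16, col = "firebrick",
    xlab = "offset from read end (bp)", ylab = "misincorporation rate",
    ylim = ylim, ...
  )
  graphics::lines(x$three_prime$offset, x$three_prime$rate, type = "b",
                  pch = 17, col = "steelblue")
  graphics::legend("topright", legend = c("5' C>T", "3' G>A"),
                   col = c("firebrick", "steelblue"), pch = c(16, 17), lty = 1)
  invisible(x)
}

#' Fit a geometric decay to a damage profile
#'
#' Least squares on log-rates over the given offsets: the model
#' `rate(k) = amplitude * rho^k` gives `log rate` linear in `k`. Offsets with
#' zero observed rate are dropped.
#'
#' @param profile a `damage_profile`.
#' @param offsets offsets to use (default 0:5).
#' @param end `"five_prime"` (C->T) or `"three_prime"` (G->A).
#' @return list with `rho` (decay per base) and `amplitude` (offset-0 rate).
#' @export
fit_damage_decay <- function(profile, offsets = 0:5, end = c("five_prime", "three_prime")) {
  end <- match.arg(end)
  tab <- profile[[end]]
  tab <- tab[tab$offset %in% offsets & tab$rate > 0, , drop = FALSE]
  if (nrow(tab) < 2L) stop("not enough nonzero rates to fit a decay")
  fit <- stats::lm(log(rate) ~ offset, data = tab)
  co <- stats::coef(fit)
  list(rho = exp(unname(co[2])), amplitude = exp(unname(co[1])))
}

#' Fragment length statistics
#'
#' Lengths are reference spans of the original merged fragments (split
#' origin-wrapping fragments re-joined; deletions included in the span,
#' insertions not).
#'
#' @param reads an `mt_reads` data frame.
#' @return a `fragment_stats` list: `n`, `mean_length`, `median_length`,
#'   `histogram` (named counts). Empty input gives `n = 0` and `NA` moments.
#' @export
fragment_length_stats <- function(reads) {
  if (!nrow(reads)) {
    return(structure(
      list(n = 0L, mean_length = NA_real_, median_length = NA_real_,
           histogram = integer(0)),
      class = "fragment_stats"
    ))
  }
  frg <- fragment_table(reads)
  h <- table(frg$span)
  structure(
    list(
      n = nrow(frg),
      mean_length = mean(frg$span),
      median_length = stats::median(frg$span),
      histogram = stats::setNames(as.integer(h), names(h))
    ),
    class = "fragment_stats"
  )
}

#' @export
print.fragment_stats <- function(x, ...) {
  cat(sprintf(
    "<fragment_stats> n=%d, mean %.2f bp, median %.1f bp\n",
    x$n, x$mean_length, x$median_length
  ))
  invisible(x)
}

#' Write a damage profile as TSV
#'
#' Columns `end, offset, opportunities, observations, rate`.
#'
#' @param profile a `damage_profile`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_damage_tsv <- function(profile, path) {
  tab <- rbind(
    cbind(end = "5p_CT", profile$five_prime),
    cbind(end = "3p_GA", profile$three_prime)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
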