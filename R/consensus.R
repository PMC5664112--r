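# Majority-rule consensus calling from a pileup, expressed as a variant table
# against the reference.

#' Call a consensus genome from a pileup
#'
#' At each position the majority allele over {A, C, G, T, deletion} is called
#' iff depth >= `min_cov` and the majority fraction >= `min_frac`, else N.
#' N-masked bases are excluded from the vote. A fraction exactly at
#' `min_frac` calls the allele; an exact count tie between two alleles calls
#' N. An insertion slot `(position, k)` is called iff its majority inserted
#' base has support >= `min_frac` of the anchor-position depth and
#' >= `min_cov`, with slots called in ascending `k` and the chain stopping at
#' the first failure. Variants are emitted wherever the call differs from the
#' reference base; N calls emit no variant, and a base called against a
#' reference N (e.g. the rCRS placeholder 3107) emits a substitution.
#'
#' @param pileup an `mt_pileup`.
#' @param ref a [circular_reference()].
#' @param min_cov minimum depth for a non-N call (default 10).
#' @param min_frac majority fraction in `(0.5, 1]` required for a call
#'   (default 0.7).
#' @return a `consensus_call`: `calls` (per-position A/C/G/T/-/N), `support`,
#'   `depth` (non-N depth used as the vote denominator), `insertions`
#'   (called slots), and `haplotype` (an [haplotype()] of all emitted
#'   variants).
#' @export
call_consensus <- function(pileup, ref, min_cov = 10L, min_frac = 0.7) {
  if (min_frac <= 0.5 || min_frac > 1) {
    stop("min_frac must lie in (0.5, 1]: the majority is otherwise undefined")
  }
  if (min_cov < 1L) stop("min_cov must be >= 1")
  if (pileup$length != ref$length) stop("pileup and reference lengths differ")
  cm <- pileup$counts[, c("A", "C", "G", "T", "del"), drop = FALSE]
  denom <- rowSums(cm)
  top_col <- max.col(cm, ties.method = "first")
  top_cnt <- cm[cbind(seq_len(nrow(cm)), top_col)]
  n_at_max <- rowSums(cm == top_cnt & top_cnt > 0L)
  tie <- n_at_max > 1L
  callable <- denom >= min_cov & denom > 0 & (top_cnt / pmax(denom, 1)) >= min_frac & !tie
  alleles <- c("A", "C", "G", "T", "-")[top_col]
  calls <- ifelse(callable, alleles, "N")
  support <- ifelse(denom > 0, top_cnt / denom, NA_real_)

  ins_calls <- data.frame(
    position = integer(0), ins_index = integer(0), base = character(0),
    count = integer(0), stringsAsFactors = FALSE
  )
  if (nrow(pileup$ins)) {
    for (anchor in unique(pileup$ins$position)) {
      slots <- pileup$ins[pileup$ins$position == anchor, , drop = FALSE]
      slots <- slots[order(slots$ins_index), , drop = FALSE]
      anchor_depth <- denom[anchor]
      expect_k <- 1L
      for (r in seq_len(nrow(slots))) {
        if (slots$ins_index[r] != expect_k) break
        cnts <- as.integer(slots[r, c("A", "C", "G", "T")])
        b <- which.max(cnts)
        if (sum(cnts == cnts[b]) > 1L) break
        if (cnts[b] >= min_cov && anchor_depth > 0 && cnts[b] / anchor_depth >= min_frac) {
          ins_calls <- rbind(ins_calls, data.frame(
            position = anchor, ins_index = slots$ins_index[r],
            base = c("A", "C", "G", "T")[b], count = cnts[b],
            stringsAsFactors = FALSE
          ))
          expect_k <- expect_k + 1L
        } else {
          break
        }
      }
    }
  }

  tokens <- character(0)
  sub_sel <- calls %in% BASES & calls != ref$bases
  if (any(sub_sel)) tokens <- c(tokens, paste0(which(sub_sel), calls[sub_sel]))
  del_sel <- calls == "-"
  if (any(del_sel)) tokens <- c(tokens, paste0(which(del_sel), "DEL"))
  if (nrow(ins_calls)) {
    tokens <- c(tokens, paste0(ins_calls$position, ".", ins_calls$ins_index, ins_calls$base))
  }
  hap <- haplotype(tokens, ref = ref)
  structure(
    list(
      calls = calls, support = support, depth = denom,
      insertions = ins_calls, haplotype = hap,
      min_cov = min_cov, min_frac = min_frac, ref_name = ref$name
    ),
    class = "consensus_call"
  )
}

#' @export
print.consensus_call <- function(x, ...) {
  cat(sprintf(
    "<consensus_call> %d bp, %d N call(s), %d variant(s) vs %s\n",
    length(x$calls), sum(x$calls == "N"), nrow(x$haplotype), x$ref_name
  ))
  invisible(x)
}

#' Variant table and difference count from a consensus call
#'
#' @param call a [call_consensus()] result.
#' @param ignore ignore set for the difference count (default
#'   [mt_default_ignore()]).
#' @return list with `haplotype`, `n_diff` (differences excluding the ignore
#'   set) and `n_total` (all variants).
#' @export
variant_table <- function(call, ignore = mt_default_ignore()) {
  list(
    haplotype = call$haplotype,
    n_diff = diff_count(call$haplotype, ignore),
    n_total = diff_count(call$haplotype, character(0))
  )
}

#' Consensus sequence as a character string
#'
#' Built directly from the per-position calls: N calls stay N, deletion calls
#' are removed, called insertions are inserted after their anchors.
#'
#' @param call a `consensus_call`.
#' @return a single string.
#' @export
consensus_sequence <- function(call) {
  out <- as.list(call$calls)
  out[call$calls == "-"] <- list(character(0))
  if (nrow(call$insertions)) {
    by_anchor <- split(call$insertions, call$insertions$position)
    for (a in names(by_anchor)) {
      slot <- by_anchor[[a]]
      slot <- slot[order(slot$ins_index), , drop = FALSE]
      ai <- as.integer(a)
      out[[ai]] <- c(out[[ai]], slot$base)
    }
  }
  paste(unlist(out, use.names = FALSE), collapse = "")
}

#' Write a minimal VCF 4.2 of the consensus variants
#'
#' Substitutions are plain SNV rows; deletions and insertions are
#' left-anchored on the preceding reference base, per VCF convention.
#'
#' @param call a `consensus_call`.
#' @param ref the [circular_reference()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(call, ref, path) {
  hap <- call$haplotype
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref$name, ref$length),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(hap)) {
    hap <- hap[order(hap$position, hap$insertion_index), , drop = FALSE]
    rows <- character(nrow(hap))
    for (i in seq_len(nrow(hap))) {
      p <- hap$position[i]
      if (hap$kind[i] == "substitution") {
        rows[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", ref$name, p, ref_base(ref, p), hap$alt[i])
      } else if (hap$kind[i] == "deletion") {
        a <- wrap_pos(ref, p - 1L)
        rows[i] <- sprintf(
          "%s\t%d\t.\t%s%s\t%s\t.\tPASS\t.",
          ref$name, a, ref_base(ref, a), ref_base(ref, p), ref_base(ref, a)
        )
      } else {
        rows[i] <- sprintf(
          "%s\t%d\t.\t%s\t%s%s\t.\tPASS\t.",
          ref$name, p, ref_base(ref, p), ref_base(ref, p), hap$alt[i]
        )
      }
    }
    writeLines(rows, con)
  }
  invisible(path)
}
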