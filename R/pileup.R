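# Duplicate removal and circular pileup construction.

#' Remove PCR/optical duplicate fragments
#'
#' Fragments are grouped by (start, end, strand) — both endpoints, since
#' merged single fragments make both ends informative. One representative is
#' kept per group: the highest total base quality, ties broken by the
#' lexicographically smallest read id. Origin-wrapping split fragments are
#' re-joined (via the `XC` tag) before grouping, so both segments of the
#' representative are retained.
#'
#' @param reads an `mt_reads` data frame.
#' @return list with `reads` (deduplicated, same class) and
#'   `duplicate_fraction` = 1 - unique/input fragments (0 for empty input).
#' @export
deduplicate <- function(reads) {
  if (!nrow(reads)) {
    return(list(reads = reads, duplicate_fraction = 0))
  }
  frg <- fragment_table(reads)
  uq <- unique(reads$qual)
  qs <- vapply(uq, function(q) sum(qual_ints(q)), 0)
  qual_by_row <- qs[match(reads$qual, uq)]
  qsum <- rowsum(qual_by_row, reads$id)
  frg$qsum <- qsum[match(frg$id, rownames(qsum)), 1L]
  key <- paste(frg$frag_start, frg$frag_end, frg$strand)
  ord <- order(key, -frg$qsum, frg$id)
  keep_ids <- frg$id[ord][!duplicated(key[ord])]
  out <- reads[reads$id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  list(
    reads = new_reads(out),
    duplicate_fraction = 1 - length(keep_ids) / nrow(frg)
  )
}

new_pileup <- function(counts, ins, ref_name, length) {
  colnames(counts) <- PILEUP_CLASSES
  structure(
    list(counts = counts, ins = ins, ref_name = ref_name, length = length),
    class = "mt_pileup"
  )
}

empty_ins_table <- function() {
  data.frame(
    position = integer(0), ins_index = integer(0),
    A = integer(0), C = integer(0), G = integer(0), T = integer(0), N = integer(0),
    stringsAsFactors = FALSE
  )
}

#' @export
print.mt_pileup <- function(x, ...) {
  d <- pileup_depth(x)
  cat(sprintf(
    "<mt_pileup> %s (%d bp): mean depth %.1f, %d insertion slot(s)\n",
    x$ref_name, x$length, mean(d), nrow(x$ins)
  ))
  invisible(x)
}

#' Total depth per reference position
#'
#' Depth is the sum of base (including N) and deletion observations.
#'
#' @param pileup an `mt_pileup`.
#' @return integer vector of length `pileup$length`.
#' @export
pileup_depth <- function(pileup) as.integer(rowSums(pileup$counts))

#' Build a per-position pileup from aligned reads
#'
#' Every non-masked aligned base increments exactly one counter; CIGAR
#' insertions increment `(position, k)` insertion-slot counters anchored after
#' the preceding reference position; deletions increment the deletion counter
#' of each deleted position. Origin-wrapping fragments arrive as two in-bounds
#' SAM segments and are counted per segment; a read walking off the reference
#' end without the circular split tag is an error.
#'
#' @param reads an `mt_reads` data frame.
#' @param ref a [circular_reference()].
#' @return an `mt_pileup`: `counts` (length x A,C,G,T,N,del matrix), `ins`
#'   (per-slot inserted-base counts), `ref_name`, `length`.
#' @export
build_pileup <- function(reads, ref) {
  L <- ref$length
  counts <- matrix(0L, nrow = L, ncol = 6L)
  ins <- empty_ins_table()
  if (!nrow(reads)) {
    return(new_pileup(counts, ins, ref$name, L))
  }
  pure <- is_pure_match_cigar(reads$cigar)
  plen <- nchar(reads$seq)
  over <- pure & (reads$start + plen - 1L > L)
  if (any(over & reads$segment == 0L)) {
    stop(
      "read(s) walk off the reference without a circular split tag: ",
      paste(utils::head(reads$id[over & reads$segment == 0L], 5L), collapse = ", ")
    )
  }
  pure <- pure & !over
  if (any(pure)) {
    pos_all <- sequence(plen[pure], from = reads$start[pure])
    chars <- unlist(strsplit(reads$seq[pure], NULL), use.names = FALSE)
    code <- match(chars, BASES_N)
    if (anyNA(code)) stop("invalid base character in read sequences")
    counts <- counts + matrix(tabulate((code - 1L) * L + pos_all, nbins = 6L * L), nrow = L)
  }
  slow <- which(!pure)
  if (length(slow)) {
    ins_pos <- integer(0); ins_k <- integer(0); ins_b <- character(0)
    for (i in slow) {
      ops <- parse_cigar(reads$cigar[i])
      rc <- reads$start[i]
      qc <- 1L
      sq <- strsplit(reads$seq[i], "")[[1]]
      for (j in seq_along(ops$op)) {
        w <- ops$len[j]
        op <- ops$op[j]
        if (op %in% c("M", "=", "X")) {
          if (rc + w - 1L > L) {
            stop("read ", reads$id[i], " walks off the reference without a circular split tag")
          }
          cd <- match(sq[qc:(qc + w - 1L)], BASES_N)
          counts[cbind(rc:(rc + w - 1L), cd)] <-
            counts[cbind(rc:(rc + w - 1L), cd)] + 1L
          rc <- rc + w
          qc <- qc + w
        } else if (op == "I") {
          ins_pos <- c(ins_pos, rep.int(rc - 1L, w))
          ins_k <- c(ins_k, seq_len(w))
          ins_b <- c(ins_b, sq[qc:(qc + w - 1L)])
          qc <- qc + w
        } else if (op == "D") {
          if (rc + w - 1L > L) stop("deletion walks off the reference in read ", reads$id[i])
          counts[rc:(rc + w - 1L), 6L] <- counts[rc:(rc + w - 1L), 6L] + 1L
          rc <- rc + w
        } else if (op == "S") {
          qc <- qc + w
        } else {
          stop("unsupported CIGAR operation '", op, "' in read ", reads$id[i])
        }
      }
    }
    if (length(ins_pos)) {
      keydf <- data.frame(position = ins_pos, ins_index = ins_k, base = ins_b)
      agg <- stats::aggregate(list(n = rep(1L, nrow(keydf))), keydf, sum)
      ins <- empty_ins_table()
      for (slot in split(agg, paste(agg$position, agg$ins_index))) {
        row <- data.frame(
          position = slot$position[1], ins_index = slot$ins_index[1],
          A = 0L, C = 0L, G = 0L, T = 0L, N = 0L
        )
        row[1, slot$base] <- slot$n
        ins <- rbind(ins, row)
      }
      ins <- ins[order(ins$position, ins$ins_index), , drop = FALSE]
      rownames(ins) <- NULL
    }
  }
  new_pileup(counts, ins, ref$name, L)
}

#' Read/write pileup tables
#'
#' TSV dialect `pos, ins_index, A, C, G, T, N, del, depth`, one row per
#' reference position plus one per insertion slot, preceded by a comment line
#' recording the reference name and length.
#'
#' @param pileup an `mt_pileup`.
#' @param path TSV path.
#' @return [read_pileup_tsv()] returns an `mt_pileup`; the writer returns
#'   `path` invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# reference: %s %d", pileup$ref_name, pileup$length), con)
  main <- data.frame(
    pos = seq_len(pileup$length), ins_index = 0L, pileup$counts,
    depth = pileup_depth(pileup), check.names = FALSE
  )
  names(main) <- c("pos", "ins_index", PILEUP_CLASSES, "depth")
  if (nrow(pileup$ins)) {
    extra <- data.frame(
      pos = pileup$ins$position, ins_index = pileup$ins$ins_index,
      A = pileup$ins$A, C = pileup$ins$C, G = pileup$ins$G, T = pileup$ins$T,
      N = pileup$ins$N, del = 0L,
      depth = rowSums(pileup$ins[, c("A", "C", "G", "T", "N")])
    )
    main <- rbind(main, extra)
    main <- main[order(main$pos, main$ins_index), , drop = FALSE]
  }
  utils::write.table(main, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("^# reference: (\\S+) ([0-9]+)$", hdr))[[1]]
  if (!length(m)) stop("pileup TSV lacks the reference comment line: ", path)
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  L <- as.integer(m[3])
  base <- tab[tab$ins_index == 0L, , drop = FALSE]
  counts <- matrix(0L, nrow = L, ncol = 6L)
  counts[base$pos, ] <- as.matrix(base[, PILEUP_CLASSES])
  insrows <- tab[tab$ins_index > 0L, , drop = FALSE]
  ins <- if (nrow(insrows)) {
    data.frame(
      position = insrows$pos, ins_index = insrows$ins_index,
      A = insrows$A, C = insrows$C, G = insrows$G, T = insrows$T, N = insrows$N
    )
  } else {
    empty_ins_table()
  }
  new_pileup(counts, ins, m[2], L)
}
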