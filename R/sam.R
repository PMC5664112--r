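# SAM input/output for aligned, merged fragments.

new_reads <- function(df) {
  needed <- c("id", "start", "strand", "mapq", "cigar", "seq", "qual", "library", "segment")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("reads table lacks columns: ", paste(miss, collapse = ", "))
  if (any(nchar(df$seq) != nchar(df$qual))) stop("sequence and quality lengths differ")
  structure(df[, needed, drop = FALSE], class = c("mt_reads", "data.frame"))
}

#' @export
print.mt_reads <- function(x, ...) {
  cat(sprintf("<mt_reads> %d segment(s), %d fragment(s)\n", nrow(x), length(unique(x$id))))
  invisible(x)
}

#' Write reads to a SAM file
#'
#' Emits a minimal spec-conformant SAM: `@HD`/`@SQ` header, FLAG 0/16 for
#' strand, reference-oriented SEQ/QUAL, a `LB:Z:` library tag, and for
#' fragments split at the circular origin an `XC:i:` tag (1 = high-coordinate
#' part, 2 = wrapped part) on each segment sharing the read id.
#'
#' @param reads an `mt_reads` data frame ([simulate_reads()],
#'   [read_alignments()]).
#' @param ref the [circular_reference()] the reads are aligned to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, ref, path) {
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open SAM output path: ", path, " (", conditionMessage(e), ")")
  })
  on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length)
  ), con)
  if (nrow(reads)) {
    flag <- ifelse(reads$strand == "-", 16L, 0L)
    lines <- paste(
      reads$id, flag, ref$name, reads$start, reads$mapq, reads$cigar,
      "*", 0L, 0L, reads$seq, reads$qual,
      paste0("LB:Z:", reads$library),
      sep = "\t"
    )
    split_seg <- reads$segment > 0L
    lines[split_seg] <- paste0(lines[split_seg], "\tXC:i:", reads$segment[split_seg])
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read filtered alignments from a SAM (or BAM) file
#'
#' Parses via Rsamtools, drops unmapped/secondary/supplementary records and
#' records below the mapping-quality threshold, and masks bases below the
#' base-quality threshold to N. Defaults `min_mapq = 30`, `min_baseq = 20`.
#'
#' @param path SAM (or BAM) file.
#' @param min_mapq minimum mapping quality to keep a record.
#' @param min_baseq bases with quality below this are masked to N.
#' @return an `mt_reads` data frame: columns `id`, `start`, `strand`, `mapq`,
#'   `cigar`, `seq`, `qual`, `library` (`"unknown"` when no LB tag),
#'   `segment` (from the `XC` tag, 0 when absent).
#' @export
read_alignments <- function(path, min_mapq = 30L, min_baseq = 20L) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE),
      error = function(e) stop("SAM parse error in ", path, ": ", conditionMessage(e))
    )
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("LB", "XC")
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    # htslib downgrades unparseable SAM records to a warning and drops them;
    # surface that as the parse error it is
    n_lines <- sum(!startsWith(readLines(path), "@"))
    if (n_lines != length(x$flag)) {
      stop(
        "SAM parse error in ", path, ": ", n_lines - length(x$flag),
        " record(s) could not be parsed"
      )
    }
  }
  flag <- x$flag
  keep <- !bitwAnd(flag, 4L) & !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
  mapq <- x$mapq
  mapq[is.na(mapq)] <- 0L
  keep <- keep & mapq >= min_mapq
  lb <- x$tag$LB %||% rep(NA_character_, length(flag))
  xc <- x$tag$XC %||% rep(NA_integer_, length(flag))
  df <- data.frame(
    id = x$qname[keep],
    start = x$pos[keep],
    strand = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+"),
    mapq = mapq[keep],
    cigar = x$cigar[keep],
    seq = as.character(x$seq)[keep],
    qual = as.character(x$qual)[keep],
    library = ifelse(is.na(lb[keep]), "unknown", lb[keep]),
    segment = ifelse(is.na(xc[keep]), 0L, xc[keep]),
    stringsAsFactors = FALSE
  )
  if (min_baseq > 0L && nrow(df)) {
    low <- vapply(df$qual, function(q) any(qual_ints(q) < min_baseq), NA)
    for (i in which(low)) {
      s <- strsplit(df$seq[i], "")[[1]]
      s[qual_ints(df$qual[i]) < min_baseq] <- "N"
      df$seq[i] <- paste(s, collapse = "")
    }
  }
  new_reads(df)
}

# Fragment-level view of a segment table: one row per read id, with joined
# endpoints for origin-wrapping split fragments (start from the XC:1 part,
# end from the XC:2 part).
fragment_table <- function(reads) {
  span <- cigar_ref_spans(reads$cigar)
  endp <- reads$start + span - 1L
  plain <- reads$segment == 0L
  out <- data.frame(
    id = reads$id[plain],
    frag_start = reads$start[plain],
    frag_end = endp[plain],
    strand = reads$strand[plain],
    span = span[plain],
    stringsAsFactors = FALSE
  )
  if (any(!plain)) {
    sp <- reads[!plain, , drop = FALSE]
    sp$span <- span[!plain]
    sp$endp <- endp[!plain]
    by_id <- split(sp, sp$id)
    joined <- do.call(rbind, lapply(by_id, function(d) {
      d <- d[order(d$segment), , drop = FALSE]
      data.frame(
        id = d$id[1],
        frag_start = d$start[1],
        frag_end = d$endp[nrow(d)],
        strand = d$strand[1],
        span = sum(d$span),
        stringsAsFactors = FALSE
      )
    }))
    out <- rbind(out, joined)
  }
  rownames(out) <- NULL
  out
}
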