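# Variants and haplotypes in forensic mtDNA notation.
#
# Tokens follow forensic convention relative to a 1-based reference:
#   "16129A"  substitution to A at position 16129
#   "3158.1T" first inserted base (T) after position 3158
#   "5DEL"    deletion of the base at position 5
# Deletions are stored with the DELETED marker "-" in the `alt` column.

#' Parse forensic mtDNA variant notation
#'
#' @param tokens character vector of tokens, case-insensitive
#'   (`<pos><BASE>`, `<pos>.<k><BASE>`, `<pos>DEL`).
#' @param ref optional [circular_reference()]; when supplied, positions are
#'   range-checked and reference alleles are filled in.
#' @return a data frame with columns `notation`, `position`,
#'   `insertion_index`, `ref`, `alt`, `kind` (one row per token; canonical
#'   upper-case notation round-trips through [format_variants()]).
#' @examples
#' parse_variants(c("16129A", "3158.1T", "5DEL"))
#' @export
parse_variants <- function(tokens, ref = NULL) {
  t0 <- toupper(trimws(as.character(tokens)))
  m <- regmatches(t0, regexec("^([0-9]+)(?:\\.([0-9]+))?(DEL|[ACGT])$", t0))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) {
    stop("malformed variant token(s): ", paste(tokens[bad], collapse = ", "))
  }
  pos <- vapply(m, function(x) as.integer(x[2]), 0L)
  k <- vapply(m, function(x) if (x[3] == "") 0L else as.integer(x[3]), 0L)
  allele <- vapply(m, function(x) x[4], "")
  if (any(pos < 1L)) {
    stop("variant position must be >= 1: ", paste(t0[pos < 1L], collapse = ", "))
  }
  dotted <- vapply(m, function(x) x[3] != "", NA)
  if (any(dotted & k < 1L)) {
    stop("insertion index must be >= 1: ", paste(t0[dotted & k < 1L], collapse = ", "))
  }
  if (any(k >= 1L & allele == "DEL")) {
    stop("an inserted base cannot be DEL: ", paste(t0[k >= 1L & allele == "DEL"], collapse = ", "))
  }
  kind <- ifelse(allele == "DEL", "deletion", ifelse(k >= 1L, "insertion", "substitution"))
  refa <- rep("", length(t0))
  if (!is.null(ref)) {
    if (any(pos > ref$length)) {
      stop(
        "variant position beyond reference length ", ref$length, ": ",
        paste(t0[pos > ref$length], collapse = ", ")
      )
    }
    refa[kind != "insertion"] <- ref_base(ref, pos[kind != "insertion"])
  }
  alt <- ifelse(kind == "deletion", "-", allele)
  out <- data.frame(
    notation = t0, position = pos, insertion_index = k,
    ref = refa, alt = alt, kind = kind, stringsAsFactors = FALSE
  )
  out$notation <- format_variants(out)
  out
}

#' Format variants back to canonical notation
#' @param v a variant data frame as returned by [parse_variants()].
#' @return character vector of canonical upper-case tokens.
#' @export
format_variants <- function(v) {
  slot <- ifelse(v$insertion_index > 0L, paste0(v$position, ".", v$insertion_index), as.character(v$position))
  paste0(slot, ifelse(v$kind == "deletion", "DEL", v$alt))
}

#' Build a haplotype from variant tokens or a variant table
#'
#' A haplotype is an ordered collection of variants relative to a named
#' reference: sorted by (position, insertion index), with no two variants
#' sharing a slot.
#'
#' @param variants character vector of notation tokens, or a data frame from
#'   [parse_variants()].
#' @param ref optional [circular_reference()] for range/allele checking.
#' @param reference_name recorded reference name (defaults to `ref$name` or
#'   `"chrM"`).
#' @return an object of classes `mt_haplotype`/`data.frame`.
#' @export
haplotype <- function(variants, ref = NULL, reference_name = NULL) {
  v <- if (is.character(variants)) parse_variants(variants, ref = ref) else as.data.frame(variants)
  if (!nrow(v)) {
    v <- data.frame(
      notation = character(0), position = integer(0), insertion_index = integer(0),
      ref = character(0), alt = character(0), kind = character(0), stringsAsFactors = FALSE
    )
  }
  v <- v[order(v$position, v$insertion_index), , drop = FALSE]
  key <- paste(v$position, v$insertion_index)
  if (anyDuplicated(key)) {
    stop(
      "conflicting variants share a slot: ",
      paste(unique(v$notation[duplicated(key) | duplicated(key, fromLast = TRUE)]), collapse = ", ")
    )
  }
  rownames(v) <- NULL
  attr(v, "reference_name") <- reference_name %||% (if (!is.null(ref)) ref$name else "chrM")
  class(v) <- c("mt_haplotype", "data.frame")
  v
}

#' @export
print.mt_haplotype <- function(x, ...) {
  cat(sprintf(
    "<mt_haplotype> %d variant(s) vs %s\n",
    nrow(x), attr(x, "reference_name") %||% "?"
  ))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Default ignore set for difference counting
#'
#' The conventional exclusions when reporting mitochondrial differences:
#' the placeholder position 3107 (an N in rCRS-like references) and the
#' C-stretch insertion slots 309.1 and 309.2. Entries without an allele match
#' any variant at that slot.
#'
#' @return character vector `c("3107", "309.1", "309.2")`.
#' @export
mt_default_ignore <- function() c("3107", "309.1", "309.2")

ignore_matches <- function(hap, ignore) {
  if (!nrow(hap) || !length(ignore)) return(rep(FALSE, nrow(hap)))
  ig <- toupper(ignore)
  slot <- ifelse(
    hap$insertion_index > 0L,
    paste0(hap$position, ".", hap$insertion_index),
    as.character(hap$position)
  )
  hap$notation %in% ig | slot %in% ig
}

#' Count differences from the reference
#'
#' Counts the haplotype's variants whose notation (or position slot) is not in
#' the ignore set. Each notation token counts as one difference.
#'
#' @param hap an [haplotype()].
#' @param ignore character vector of tokens or position slots to exclude
#'   (default [mt_default_ignore()]); use `character(0)` to count everything.
#' @return non-negative integer.
#' @export
diff_count <- function(hap, ignore = mt_default_ignore()) {
  sum(!ignore_matches(hap, ignore))
}

#' Apply a haplotype to the reference to build a sample genome
#'
#' Substitutions replace the reference base, insertions are inserted after
#' their anchor position in insertion-index order, deletions are removed.
#' Substitution/deletion reference alleles, when recorded, must match the
#' reference.
#'
#' @param ref a [circular_reference()].
#' @param hap an [haplotype()].
#' @return an object of class `mt_genome`: fields `bases` (character vector),
#'   `refpos` (reference position of each sample base), `insidx` (0 for
#'   reference-anchored bases, k for the k-th inserted base after `refpos`),
#'   `name`, `length`.
#' @examples
#' ref <- circular_reference("ACGT")
#' as.character(apply_variants(ref, haplotype("2.1A", ref))) # "ACAGT"
#' @export
apply_variants <- function(ref, hap) {
  if (nrow(hap)) {
    if (any(hap$position > ref$length)) {
      stop("variant position beyond reference length: ",
           paste(hap$notation[hap$position > ref$length], collapse = ", "))
    }
    chk <- hap$kind != "insertion" & hap$ref != ""
    mism <- chk & hap$ref != ref_base(ref, hap$position)
    if (any(mism)) {
      stop("reference allele mismatch at: ", paste(hap$notation[mism], collapse = ", "))
    }
  }
  base_chr <- ref$bases
  keep <- rep(TRUE, ref$length)
  subs <- hap[hap$kind == "substitution", , drop = FALSE]
  base_chr[subs$position] <- subs$alt
  dels <- hap[hap$kind == "deletion", , drop = FALSE]
  keep[dels$position] <- FALSE

  ins <- hap[hap$kind == "insertion", , drop = FALSE]
  if (nrow(ins)) {
    # append inserted bases after their anchors, in insertion-index order
    ins <- ins[order(ins$position, ins$insertion_index), , drop = FALSE]
    out_b <- vector("list", ref$length)
    out_p <- vector("list", ref$length)
    out_k <- vector("list", ref$length)
    ins_by_pos <- split(ins, ins$position)
    for (i in seq_len(ref$length)) {
      b <- if (keep[i]) base_chr[i] else character(0)
      p <- if (keep[i]) i else integer(0)
      k <- if (keep[i]) 0L else integer(0)
      ii <- ins_by_pos[[as.character(i)]]
      if (!is.null(ii)) {
        b <- c(b, ii$alt)
        p <- c(p, ii$position)
        k <- c(k, ii$insertion_index)
      }
      out_b[[i]] <- b; out_p[[i]] <- p; out_k[[i]] <- k
    }
    bases <- unlist(out_b, use.names = FALSE)
    refpos <- as.integer(unlist(out_p, use.names = FALSE))
    insidx <- as.integer(unlist(out_k, use.names = FALSE))
  } else {
    bases <- base_chr[keep]
    refpos <- which(keep)
    insidx <- integer(length(bases))
  }
  structure(
    list(bases = bases, refpos = refpos, insidx = insidx, name = ref$name, length = length(bases)),
    class = "mt_genome"
  )
}

#' @export
as.character.mt_genome <- function(x, ...) paste(x$bases, collapse = "")

#' @export
print.mt_genome <- function(x, ...) {
  cat(sprintf("<mt_genome> %d bp derived from %s\n", x$length, x$name))
  invisible(x)
}

#' Reference-coordinate base vector of a sample genome
#'
#' Projects a haplotype onto reference coordinates: substitutions applied,
#' deleted positions marked `"-"`, insertions ignored. Used by the mixture
#' contamination estimator, which works in substitution space.
#'
#' @inheritParams apply_variants
#' @return character vector of length `ref$length`.
#' @export
genome_vector <- function(ref, hap) {
  g <- ref$bases
  subs <- hap[hap$kind == "substitution", , drop = FALSE]
  g[subs$position] <- subs$alt
  g[hap$position[hap$kind == "deletion"]] <- "-"
  g
}

#' Read/write haplotype tables
#'
#' TSV dialect with columns `notation, position, insertion_index, ref, alt,
#' kind`. Reading re-parses the notation column (optionally against a
#' reference) so files remain the single source of truth.
#'
#' @param path TSV file path.
#' @param ref optional [circular_reference()] used for validation on read.
#' @return [read_haplotype_tsv()] returns an [haplotype()];
#'   [write_haplotype_tsv()] returns `path` invisibly.
#' @export
read_haplotype_tsv <- function(path, ref = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"notation" %in% names(tab)) stop("haplotype TSV lacks a 'notation' column: ", path)
  haplotype(as.character(tab$notation), ref = ref)
}

#' @rdname read_haplotype_tsv
#' @param hap an [haplotype()] to write.
#' @export
write_haplotype_tsv <- function(hap, path) {
  utils::write.table(
    as.data.frame(hap)[, c("notation", "position", "insertion_index", "ref", "alt", "kind")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
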