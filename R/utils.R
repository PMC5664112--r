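# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
BASES_N <- c("A", "C", "G", "T", "N")
PILEUP_CLASSES <- c("A", "C", "G", "T", "N", "del")
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

COMP_FROM <- c("A", "C", "G", "T", "N", "-")
COMP_TO <- c("T", "G", "C", "A", "N", "-")
comp_bases <- function(x) COMP_TO[match(x, COMP_FROM)]

revcomp_string <- function(s) {
  x <- rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]])
  paste(x, collapse = "")
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the given seed, evaluates `code`, and restores the caller's RNG state,
#' so that seeded package operations do not disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# CIGAR helpers. Only M/I/D (and =/X treated as M) are produced or consumed.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(list(len = integer(0), op = character(0)))
  }
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(len) != length(op) || !length(op)) {
    stop("malformed CIGAR string: ", cigar)
  }
  list(len = len, op = op)
}

cigar_ref_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

# vectorized reference span, with a fast path for pure-match CIGARs
cigar_ref_spans <- function(cigars) {
  out <- integer(length(cigars))
  pure <- grepl("^[0-9]+M$", cigars)
  out[pure] <- as.integer(sub("M", "", cigars[pure], fixed = TRUE))
  for (i in which(!pure)) out[i] <- cigar_ref_span(cigars[i])
  out
}

cigar_read_len <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

is_pure_match_cigar <- function(cigar) grepl("^[0-9]+M$", cigar)

qual_ints <- function(qual) utf8ToInt(qual) - 33L

`%||%` <- function(a, b) if (is.null(a)) b else a
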