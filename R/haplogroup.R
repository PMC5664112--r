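# Haplogroup classification against a defining-variant tree, and derivation
# of the diagnostic position set used for contamination estimation.
#
# The tree is a TSV of nodes with comma-separated defining-variant tokens.
# Expected alleles may equal the reference base: variants above the
# reference's own branch point are shared between the reference and the query
# lineage, which is how a haplogroup can have more defining positions than
# the query has reference differences. A trailing "!" marks a back-mutation:
# the token's allele is the (ancestral) allele expected in the query.

#' Load a haplogroup defining-variant tree
#'
#' @param path TSV with columns `node`, `parent` (empty for the root) and
#'   `variants` (comma-separated notation tokens, optionally with a trailing
#'   `!` for back-mutations; may be empty).
#' @return a `haplo_tree`: data frame plus per-node parsed variants.
#' @export
read_haplogroup_tree <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  need <- c("node", "parent", "variants")
  if (!all(need %in% names(tab))) {
    stop("tree TSV must have columns node, parent, variants: ", path)
  }
  tab$parent[is.na(tab$parent)] <- ""
  tab$variants[is.na(tab$variants)] <- ""
  haplogroup_tree(tab)
}

#' Construct a haplogroup tree from a node table
#'
#' @param tab data frame with `node`, `parent`, `variants` columns (see
#'   [read_haplogroup_tree()]).
#' @return a `haplo_tree` object.
#' @export
haplogroup_tree <- function(tab) {
  if (!nrow(tab)) stop("empty haplogroup tree")
  if (anyDuplicated(tab$node)) stop("duplicated node names in tree")
  roots <- tab$node[tab$parent == ""]
  if (length(roots) != 1L) stop("tree must have exactly one root, found ", length(roots))
  known <- c("", tab$node)
  if (!all(tab$parent %in% known)) {
    stop("unknown parent(s): ", paste(setdiff(tab$parent, known), collapse = ", "))
  }
  # reachability / acyclicity from the root
  seen <- roots
  repeat {
    nxt <- tab$node[tab$parent %in% seen & !(tab$node %in% seen)]
    if (!length(nxt)) break
    seen <- c(seen, nxt)
  }
  if (length(seen) != nrow(tab)) {
    stop("unreachable or cyclic node(s): ", paste(setdiff(tab$node, seen), collapse = ", "))
  }
  vars <- lapply(tab$variants, function(s) {
    toks <- trimws(strsplit(s, ",")[[1]])
    toks <- toks[toks != ""]
    if (!length(toks)) {
      return(data.frame(
        token = character(0), backmut = logical(0), position = integer(0),
        insertion_index = integer(0), alt = character(0), kind = character(0)
      ))
    }
    backmut <- grepl("!$", toks)
    parsed <- parse_variants(sub("!$", "", toks))
    data.frame(
      token = paste0(parsed$notation, ifelse(backmut, "!", "")),
      backmut = backmut, position = parsed$position,
      insertion_index = parsed$insertion_index, alt = parsed$alt,
      kind = parsed$kind, stringsAsFactors = FALSE
    )
  })
  names(vars) <- tab$node
  structure(
    list(nodes = tab[, c("node", "parent")], variants = vars, root = roots),
    class = "haplo_tree"
  )
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat(sprintf(
    "<haplo_tree> %d node(s), root %s\n", nrow(x$nodes), x$root
  ))
  invisible(x)
}

tree_path_nodes <- function(tree, node) {
  if (!node %in% tree$nodes$node) stop("unknown haplogroup node: ", node)
  path <- node
  while (TRUE) {
    par <- tree$nodes$parent[tree$nodes$node == path[1]]
    if (par == "") break
    path <- c(par, path)
  }
  path
}

#' Cumulative defining variants on the root-to-node path
#'
#' @param tree a `haplo_tree`.
#' @param node node name.
#' @return data frame of the path's defining variants (columns as in the
#'   per-node tables).
#' @export
path_variants <- function(tree, node) {
  out <- do.call(rbind, tree$variants[tree_path_nodes(tree, node)])
  rownames(out) <- NULL
  out
}

# Is each defining variant conferred by the query haplotype? A substitution
# with expected allele equal to the reference base is matched when the query
# has no substitution at that position; otherwise the query must carry the
# expected allele/indel at the slot.
variant_conferred <- function(defs, hap, ref) {
  vapply(seq_len(nrow(defs)), function(i) {
    p <- defs$position[i]
    k <- defs$insertion_index[i]
    at_slot <- hap$position == p & hap$insertion_index == k
    if (defs$kind[i] == "substitution") {
      if (defs$alt[i] == ref_base(ref, p)) {
        !any(at_slot & hap$kind == "substitution")
      } else {
        any(at_slot & hap$kind == "substitution" & hap$alt == defs$alt[i])
      }
    } else if (defs$kind[i] == "insertion") {
      any(at_slot & hap$kind == "insertion" & hap$alt == defs$alt[i])
    } else {
      any(at_slot & hap$kind == "deletion")
    }
  }, NA)
}

#' Score a haplotype against every node of a haplogroup tree
#'
#' Each node is scored by matched/expected over the cumulative defining
#' variants of its root-to-node path. Ranking is by matched count (so a
#' deeper node explaining more of the haplotype outranks a fully-matched but
#' shallow ancestor), ties broken by score fraction and then by name; a leaf
#' matched in full therefore beats both its ancestors and any deeper node
#' missing a variant. A back-mutation in a defining list expects the recorded
#' ancestral allele; an unmet expectation of either polarity counts as
#' missing.
#'
#' @param hap query [haplotype()] (relative to `ref`).
#' @param tree a `haplo_tree`.
#' @param ref the [circular_reference()] the haplotype is expressed against
#'   (needed to evaluate defining variants whose expected allele equals the
#'   reference base).
#' @return a data frame of class `haplogroup_scores`, ranked, with columns
#'   `node`, `expected`, `matched`, `score`, and list columns `missing`
#'   (unmet defining tokens) and `extra_private` (query variants on no scored
#'   path).
#' @export
score_haplogroups <- function(hap, tree, ref) {
  if (!inherits(tree, "haplo_tree")) stop("tree must be a haplo_tree")
  nodes <- tree$nodes$node
  res <- lapply(nodes, function(nd) {
    defs <- path_variants(tree, nd)
    if (!nrow(defs)) {
      return(list(node = nd, expected = 0L, matched = 0L, score = 0,
                  missing = character(0)))
    }
    ok <- variant_conferred(defs, hap, ref)
    list(
      node = nd, expected = nrow(defs), matched = sum(ok),
      score = sum(ok) / nrow(defs), missing = defs$token[!ok]
    )
  })
  out <- data.frame(
    node = vapply(res, `[[`, "", "node"),
    expected = vapply(res, `[[`, 0L, "expected"),
    matched = vapply(res, `[[`, 0L, "matched"),
    score = vapply(res, `[[`, 0, "score"),
    stringsAsFactors = FALSE
  )
  out$missing <- lapply(res, `[[`, "missing")
  all_path_tokens <- unique(unlist(lapply(
    nodes, function(nd) path_variants(tree, nd)$token
  ), use.names = FALSE))
  out$extra_private <- rep(
    list(setdiff(hap$notation, sub("!$", "", all_path_tokens))),
    nrow(out)
  )
  out <- out[order(-out$matched, -out$score, out$node), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("haplogroup_scores", "data.frame")
  out
}

#' @export
print.haplogroup_scores <- function(x, ...) {
  cat("<haplogroup_scores> top nodes:\n")
  top <- utils::head(x, 5L)
  for (i in seq_len(nrow(top))) {
    cat(sprintf(
      "  %-10s %d/%d (%.3f)%s\n", top$node[i], top$matched[i], top$expected[i],
      top$score[i],
      if (length(top$missing[[i]])) paste0(" missing: ", paste(top$missing[[i]], collapse = ", ")) else ""
    ))
  }
  invisible(x)
}

#' Private mutations of a haplotype relative to its best haplogroup
#'
#' Query variants not among the best node's path-defining variants, with
#' ignore-set tokens (conventional placeholder/C-stretch slots) excluded.
#'
#' @param hap query [haplotype()].
#' @param best node name, or a `haplogroup_scores` row/table (its top node is
#'   used).
#' @param tree a `haplo_tree`.
#' @param ignore tokens/slots to exclude (default [mt_default_ignore()]).
#' @return the subset of `hap` that is private (an [haplotype()] data frame).
#' @export
private_mutations <- function(hap, best, tree, ignore = mt_default_ignore()) {
  node <- if (inherits(best, "data.frame")) best$node[1] else best
  defs <- path_variants(tree, node)
  on_path <- hap$notation %in% defs$token
  ignored <- ignore_matches(hap, ignore)
  out <- hap[!on_path & !ignored, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Diagnostic positions for contamination estimation
#'
#' The positions of all substitution-type defining variants on the
#' root-to-node path, each with the derived allele expected in the endogenous
#' consensus. Insertion-type defining variants are excluded with a warning
#' (their slots cannot be scored as pooled base counts).
#'
#' @param tree a `haplo_tree`.
#' @param node node name.
#' @param ref a [circular_reference()] (positions are range-checked).
#' @return data frame with columns `position` and `expected_allele`.
#' @export
diagnostic_positions <- function(tree, node, ref) {
  defs <- path_variants(tree, node)
  drop <- defs$kind != "substitution"
  if (any(drop)) {
    warning(
      "excluding non-substitution defining variant(s) from the diagnostic set: ",
      paste(defs$token[drop], collapse = ", ")
    )
    defs <- defs[!drop, , drop = FALSE]
  }
  if (any(defs$position > ref$length)) {
    stop("defining variant position beyond reference length")
  }
  out <- data.frame(position = defs$position, expected_allele = defs$alt,
                    stringsAsFactors = FALSE)
  # a back-mutation deeper on the path supersedes the earlier expectation
  out <- out[!duplicated(out$position, fromLast = TRUE), , drop = FALSE]
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
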