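#' Parse a newick tree
#'
#' Wraps [ape::read.tree] with the validation the downstream operations
#' need: unique tip labels and non-negative branch lengths. Trees without
#' branch lengths are accepted (parsimony counting does not need them).
#'
#' @param x newick text or a file path.
#' @return An [ape::phylo] tree.
#' @export
parse_newick <- function(x) {
  tr <- tryCatch(
    if (length(x) == 1L && file.exists(x) && !grepl("\\(", x)) ape::read.tree(x)
    else ape::read.tree(text = x),
    error = function(e) stop_petfloc("parse", paste("newick parse error:",
                                                    conditionMessage(e))))
  if (is.null(tr)) stop_petfloc("parse", "newick parse error: no tree found")
  if (anyDuplicated(tr$tip.label))
    stop_petfloc("parse", sprintf("duplicate tip label: %s",
                                  tr$tip.label[duplicated(tr$tip.label)][1]))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop_petfloc("parse", "negative branch length")
  tr
}

#' Write a tree as newick text
#'
#' @param tree an [ape::phylo] tree.
#' @param canonical sort children at every node by their smallest
#'   descendant tip label before writing, so topologically identical trees
#'   serialize identically.
#' @return Newick string.
#' @export
write_newick <- function(tree, canonical = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!canonical) return(ape::write.tree(tree))
  has_len <- !is.null(tree$edge.length)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node) {
    if (node <= ntip)
      return(list(label = tree$tip.label[node], text = tree$tip.label[node]))
    eidx <- kids[[as.character(node)]]
    parts <- lapply(tree$edge[eidx, 2], rec)
    lens <- if (has_len) tree$edge.length[eidx] else NULL
    ord <- order(vapply(parts, `[[`, "", "label"))
    txt <- vapply(seq_along(parts), function(k) {
      p <- parts[[ord[k]]]
      if (has_len) sprintf("%s:%s", p$text,
                           format(lens[ord[k]], digits = 15, trim = TRUE))
      else p$text
    }, "")
    list(label = min(vapply(parts, `[[`, "", "label")),
         text = paste0("(", paste(txt, collapse = ","), ")"))
  }
  paste0(rec(root)$text, ";")
}

resolve_node <- function(tree, sel) {
  ntip <- length(tree$tip.label)
  if (is.numeric(sel)) {
    if (sel < 1 || sel > ntip + tree$Nnode)
      stop_petfloc("input", "node number out of range")
    return(as.integer(sel))
  }
  sel <- as.character(sel)
  if (length(sel) == 1L) {
    if (identical(sel, "root")) return(ntip + 1L)
    i <- match(sel, tree$tip.label)
    if (is.na(i)) stop_petfloc("input", sprintf("unknown tip: %s", sel))
    return(i)
  }
  i <- match(sel, tree$tip.label)
  if (anyNA(i))
    stop_petfloc("input", sprintf("unknown tip: %s", sel[is.na(i)][1]))
  ape::getMRCA(tree, sel)
}

#' Is a tip set monophyletic?
#'
#' Rooted definition: true iff some node's descendant tip set equals
#' `tips` exactly.
#'
#' @param tree an [ape::phylo] tree (rooted).
#' @param tips character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop_petfloc("input", sprintf("unknown tip: %s", unknown[1]))
  if (length(tips) == length(tree$tip.label)) return(TRUE)
  ape::is.monophyletic(tree, tips)
}

#' Path length between two tree nodes
#'
#' Sum of branch lengths along the unique path between two nodes, in the
#' units of the tree (substitutions per site for the trees this package
#' targets). Node selectors are a tip label, the string `"root"`, a node
#' number, or a character vector of several tip labels meaning their most
#' recent common ancestor.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param a,b node selectors.
#' @return Numeric path length.
#' @export
path_length <- function(tree, a, b) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop_petfloc("input", "tree has no branch lengths")
  na <- resolve_node(tree, a)
  nb <- resolve_node(tree, b)
  if (na == nb) return(0)
  ape::dist.nodes(tree)[na, nb]
}

#' Remove leading alignment columns
#'
#' Drops the first `k` columns of an alignment (e.g. the N-terminal block
#' covering putative transit peptides). Rows that become all-gap are
#' flagged in the `"all_gap"` attribute, not dropped.
#'
#' @param aln named character vector of equal-length aligned sequences
#'   (gap `-`), or an `XStringSet` coerced to one.
#' @param k number of leading columns to remove (default 48).
#' @return The trimmed alignment (named character vector) with attribute
#'   `all_gap`.
#' @export
remove_leading_columns <- function(aln, k = 48L) {
  aln <- stats::setNames(as.character(aln), names(aln))
  L <- unique(nchar(aln))
  if (length(L) != 1L)
    stop_petfloc("input", "alignment rows have unequal lengths")
  if (k < 0L || k > L)
    stop_petfloc("parameter", sprintf("k must be in [0, %d]", L))
  out <- substr(aln, k + 1L, L)
  attr(out, "all_gap") <- !grepl("[^-]", out)
  out
}

#' Flag N-terminal target (transit) peptides in an alignment
#'
#' Given the alignment column where the mature (plastid-encoded reference)
#' protein starts, counts each sequence's residues strictly before that
#' column. A sequence with at least `min_leading` leading residues that
#' start with methionine is flagged PRESENT (a plausible plastid-targeting
#' presequence); one with no leading residues is ABSENT; anything else
#' (short or Met-less N-terminus, e.g. a truncated transcript) is
#' INCONCLUSIVE.
#'
#' @param aln named character vector of aligned protein sequences.
#' @param mature_start_column 1-based alignment column of the first mature
#'   residue.
#' @param min_leading minimum leading residues for PRESENT (default 10).
#' @return A data.frame with `id`, `state`, `n_leading_residues`,
#'   `starts_with_met`.
#' @export
flag_target_peptide <- function(aln, mature_start_column, min_leading = 10L) {
  aln <- stats::setNames(as.character(aln), names(aln))
  L <- unique(nchar(aln))
  if (length(L) != 1L)
    stop_petfloc("input", "alignment rows have unequal lengths")
  if (mature_start_column < 1L || mature_start_column > L)
    stop_petfloc("parameter", sprintf("mature_start_column must be in [1, %d]", L))
  rows <- lapply(seq_along(aln), function(i) {
    lead <- gsub("-", "", substr(aln[[i]], 1L, mature_start_column - 1L), fixed = TRUE)
    n <- nchar(lead)
    met <- n > 0L && substr(lead, 1, 1) == "M"
    state <- if (n == 0L) "ABSENT"
             else if (n >= min_leading && met) "PRESENT"
             else "INCONCLUSIVE"
    data.frame(id = names(aln)[i], state = state, n_leading_residues = n,
               starts_with_met = met, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
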