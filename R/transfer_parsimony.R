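#' Minimum number of independent plastid-to-nucleus transfer events
#'
#' Dollo-style counting on a rooted tree: the gene is plastid-encoded
#' (PRESENT) in the ancestor above the root, a lineage can lose the
#' plastid-encoded state (transfer it to the nucleus) but never regain it.
#' The minimum number of PRESENT-to-ABSENT transitions consistent with the
#' tip states equals the number of maximal subtrees whose tips are all
#' ABSENT; the whole tree being ABSENT counts as a single event on the
#' root's stem.
#'
#' @param tree a rooted [ape::phylo] tree (branch lengths optional).
#' @param states named character vector, one entry per tip, values
#'   `"present"`/`"absent"` (case-insensitive; `"PRESENT"`/`"ABSENT"`
#'   also accepted).
#' @return A list of class `transfer_scenario` with `min_events`,
#'   `event_clades` (a list of tip-label sets, one per inferred event,
#'   each the maximal all-absent clade under the event edge), `states`
#'   and `tree`.
#' @export
min_transfer_events <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  states <- normalize_states(tree, states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  absent_tip <- unname(states == "absent")
  desc_tips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], desc_tips),
           use.names = FALSE)
  }
  # node is all-absent iff every descendant tip is absent
  all_absent <- vapply(seq_len(nnode), function(nd)
    all(absent_tip[match(desc_tips(nd), tree$tip.label)]), logical(1))
  # events: edges whose child clade is all-absent but whose parent clade is
  # not, plus the root stem when everything is absent
  event_nodes <- integer(0)
  if (all_absent[root]) {
    event_nodes <- root
  } else {
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
      if (all_absent[chd] && !all_absent[par]) event_nodes <- c(event_nodes, chd)
    }
  }
  structure(list(min_events = length(event_nodes),
                 event_clades = lapply(event_nodes, desc_tips),
                 states = states, tree = tree),
            class = "transfer_scenario")
}

normalize_states <- function(tree, states) {
  if (is.null(names(states)))
    stop_petfloc("input", "states must be a named vector (names = tip labels)")
  states <- stats::setNames(tolower(as.character(states)), names(states))
  bad <- setdiff(unique(states), c("present", "absent"))
  if (length(bad))
    stop_petfloc("input", sprintf("invalid state '%s' (use present/absent)", bad[1]))
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stop_petfloc("input", sprintf("tip without a state: %s", missing[1]))
  states[tree$tip.label]
}

#' Brute-force oracle for the minimum transfer count
#'
#' Enumerates every PRESENT/ABSENT labeling of the internal nodes
#' (including the root, which hangs below a virtual PRESENT ancestor),
#' discards labelings with an ABSENT-to-PRESENT transition on any edge
#' (including edges to tips), and returns the minimum number of
#' PRESENT-to-ABSENT transitions. Exponential in the number of internal
#' nodes; refuses trees with more than 14.
#'
#' @inheritParams min_transfer_events
#' @return Integer minimum event count.
#' @export
brute_force_min_events <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  states <- normalize_states(tree, states)
  ntip <- length(tree$tip.label)
  m <- tree$Nnode
  if (m > 14L) stop_petfloc("size", "too many internal nodes for brute force")
  root <- ntip + 1L
  tip_absent <- unname(states == "absent")
  best <- Inf
  for (mask in 0:(2^m - 1L)) {
    lab_absent <- c(tip_absent, as.logical(bitwAnd(bitwShiftR(mask, 0:(m - 1L)), 1L)))
    # virtual PRESENT ancestor above the root
    events <- if (lab_absent[root]) 1L else 0L
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      pa <- lab_absent[tree$edge[e, 1]]; ca <- lab_absent[tree$edge[e, 2]]
      if (pa && !ca) { ok <- FALSE; break }
      if (!pa && ca) events <- events + 1L
    }
    if (ok && events < best) best <- events
  }
  as.integer(best)
}

#' Read a presence/absence state table
#'
#' TSV with two columns, `taxon` and `state` (`present`/`absent`), as
#' produced by screening plastid genome annotations for the gene.
#'
#' @param path TSV file path.
#' @return Named character vector of states.
#' @export
read_states_tsv <- function(path) {
  if (!file.exists(path))
    stop_petfloc("file_not_found", sprintf("state file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "state") %in% names(df)))
    stop_petfloc("format", "state TSV needs columns taxon, state")
  stats::setNames(df$state, df$taxon)
}
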