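# Internal helpers for directed graphs over named nodes.
# Edges are represented throughout as a character matrix with columns
# "from" and "to" (zero rows allowed).

empty_edges <- function() {
  matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
}

as_edge_matrix <- function(x) {
  if (is.matrix(x) && ncol(x) == 2) {
    m <- matrix(as.character(x), ncol = 2)
  } else if (is.list(x)) {
    if (length(x) == 0) return(empty_edges())
    m <- do.call(rbind, lapply(x, function(e) as.character(e[1:2])))
  } else if (length(x) == 0) {
    return(empty_edges())
  } else {
    stop("edges must be a 2-column matrix or a list of (parent, child) pairs")
  }
  dimnames(m) <- list(NULL, c("from", "to"))
  m
}

edge_key <- function(edges) paste(edges[, 1], edges[, 2], sep = "->")

parents_of <- function(edges, node) unname(edges[edges[, 2] == node, 1])

children_of <- function(edges, node) unname(edges[edges[, 1] == node, 2])

has_edge <- function(edges, from, to) any(edges[, 1] == from & edges[, 2] == to)

add_edge <- function(edges, from, to) rbind(edges, c(from, to))

drop_edge <- function(edges, from, to) {
  edges[!(edges[, 1] == from & edges[, 2] == to), , drop = FALSE]
}

#' Topological order of a directed acyclic graph
#'
#' Kahn's algorithm, always choosing the lexicographically smallest
#' available node, so the returned order (and everything seeded from it,
#' such as ancestral sampling) is platform-deterministic.
#'
#' @param nodes character vector of node names.
#' @param edges 2-column character matrix of directed edges (from, to).
#' @return character vector: `nodes` in topological order.
#' @keywords internal
topological_order <- function(nodes, edges) {
  edges <- as_edge_matrix(edges)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (to in edges[, 2]) indeg[[to]] <- indeg[[to]] + 1L
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  while (length(avail)) {
    nd <- avail[1]
    avail <- avail[-1]
    out <- c(out, nd)
    for (ch in children_of(edges, nd)) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) avail <- sort(c(avail, ch))
    }
  }
  if (length(out) != length(nodes)) {
    stop("graph contains a directed cycle")
  }
  out
}

is_acyclic <- function(nodes, edges) {
  !inherits(try(topological_order(nodes, edges), silent = TRUE), "try-error")
}

# all subsets of x of size 0..max_size, smallest first; deterministic order
subsets_up_to <- function(x, max_size) {
  out <- list(character(0))
  for (k in seq_len(min(max_size, length(x)))) {
    cmb <- utils::combn(x, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# descendants of `node` (not including itself)
descendants_of <- function(edges, node) {
  edges <- as_edge_matrix(edges)
  seen <- character(0)
  frontier <- children_of(edges, node)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, children_of, edges = edges))), seen)
  }
  seen
}
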