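#' Discrete Bayesian-network specification
#'
#' A `bn_spec` bundles the three ingredients of a discrete Bayesian
#' network: the variables with their finite state spaces, the directed
#' acyclic graph, and one conditional probability table (CPT) per node.
#' Optional continuous auxiliary variables (e.g. handgrip strength) are
#' carried alongside the categorical network; they are sampled from
#' per-outcome-stratum Gaussians and never take part in inference.
#'
#' @section CPT layout:
#' A CPT is stored as a matrix with one column per child state and one
#' row per configuration of the parents, the **first** parent varying
#' fastest (mixed-radix row order).  Root nodes have a single row — the
#' prior.  [cpt_row_index()] maps a named parent configuration to its row.
#'
#' @param variables named list; each element a list with `name`,
#'   `states` (character, length >= 2) and `role` (`"root"`,
#'   `"internal"` or `"outcome"`).
#' @param edges 2-column character matrix (or list of pairs) of directed
#'   edges `(parent, child)`.
#' @param cpts named list of CPTs created by [new_cpt()], one per node.
#' @param aux optional named list of continuous auxiliaries; each a list
#'   with `name`, `by` (the stratifying categorical variable) and
#'   `strata` (named list state -> `c(mean, sd)`).
#' @return an object of class `bn_spec`.
#' @seealso [build_reference_network()], [validate_network()],
#'   [write_network_json()], [sample_cohort()]
#' @export
new_network_spec <- function(variables, edges, cpts, aux = list()) {
  spec <- structure(
    list(
      variables = variables,
      edges = as_edge_matrix(edges),
      cpts = cpts,
      aux = aux
    ),
    class = "bn_spec"
  )
  validate_network(spec)
  spec
}

#' Construct a conditional probability table
#'
#' @param node child variable name.
#' @param states child state labels.
#' @param parents ordered character vector of parent names (may be empty).
#' @param parent_states named list mapping each parent to its state labels.
#' @param prob numeric matrix, `prod(cards) x length(states)`; rows are
#'   parent configurations with the first parent varying fastest, and each
#'   row must sum to 1 within 1e-9.
#' @param counts optional raw count matrix of the same shape.
#' @return an object of class `bn_cpt`.
#' @export
new_cpt <- function(node, states, parents = character(0),
                    parent_states = list(), prob, counts = NULL) {
  prob <- as.matrix(prob)
  dimnames(prob) <- list(NULL, states)
  cards <- vapply(parent_states[parents], length, integer(1))
  n_rows <- if (length(parents)) prod(cards) else 1L
  if (nrow(prob) != n_rows || ncol(prob) != length(states)) {
    stop(sprintf("CPT for '%s': expected %d x %d probability matrix", node,
                 n_rows, length(states)))
  }
  if (any(prob < -1e-12 | prob > 1 + 1e-12)) {
    stop(sprintf("CPT for '%s': probabilities outside [0, 1]", node))
  }
  if (any(abs(rowSums(prob) - 1) > 1e-9)) {
    stop(sprintf("CPT for '%s': rows must sum to 1 within 1e-9", node))
  }
  structure(
    list(node = node, states = states, parents = parents,
         parent_states = parent_states[parents], prob = prob, counts = counts),
    class = "bn_cpt"
  )
}

#' Row index of a parent configuration in a CPT
#'
#' @param cpt a `bn_cpt`.
#' @param config named character vector / list: parent name -> state label.
#' @return integer row index into `cpt$prob`.
#' @export
cpt_row_index <- function(cpt, config) {
  if (!length(cpt$parents)) return(1L)
  idx <- 1L
  mult <- 1L
  for (p in cpt$parents) {
    st <- cpt$parent_states[[p]]
    k <- match(as.character(config[[p]]), st)
    if (is.na(k)) stop(sprintf("'%s' is not a state of parent '%s'",
                               as.character(config[[p]]), p))
    idx <- idx + (k - 1L) * mult
    mult <- mult * length(st)
  }
  idx
}

# enumerate parent configurations in CPT row order (first parent fastest)
cpt_parent_grid <- function(cpt) {
  if (!length(cpt$parents)) return(data.frame())
  g <- expand.grid(cpt$parent_states, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  names(g) <- cpt$parents
  g
}

#' Validate a network specification
#'
#' Checks that edge endpoints exist, the graph is acyclic, state labels
#' are unique, every node has a CPT whose parent axes match its incoming
#' edges, and that every CPT row sums to 1 within 1e-9.
#'
#' @param spec a `bn_spec`.
#' @return `spec`, invisibly; stops with an informative error otherwise.
#' @export
validate_network <- function(spec) {
  nodes <- names(spec$variables)
  for (v in spec$variables) {
    if (length(v$states) < 2) stop(sprintf("variable '%s' needs >= 2 states", v$name))
    if (anyDuplicated(v$states)) stop(sprintf("variable '%s': duplicate state labels", v$name))
  }
  ed <- spec$edges
  if (nrow(ed) && !all(c(ed) %in% nodes)) {
    stop("edge endpoint not among declared variables")
  }
  topological_order(nodes, ed)  # errors on a cycle
  for (nd in nodes) {
    cpt <- spec$cpts[[nd]]
    if (is.null(cpt)) stop(sprintf("node '%s' has no CPT", nd))
    pa <- sort(parents_of(ed, nd))
    if (!identical(sort(cpt$parents), pa)) {
      stop(sprintf("CPT parents for '%s' do not match incoming edges", nd))
    }
    if (!identical(cpt$states, spec$variables[[nd]]$states)) {
      stop(sprintf("CPT states for '%s' do not match the variable's states", nd))
    }
    if (any(abs(rowSums(cpt$prob) - 1) > 1e-9)) {
      stop(sprintf("CPT for '%s': rows must sum to 1 within 1e-9", nd))
    }
  }
  invisible(spec)
}

#' @export
print.bn_spec <- function(x, ...) {
  cat(sprintf("Discrete Bayesian network: %d nodes, %d directed edges\n",
              length(x$variables), nrow(x$edges)))
  cat("nodes:", paste(names(x$variables), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read the JSON network interchange format
#'
#' The format has three keys: `variables` (name, states, role), `edges`
#' (2-element arrays) and `cpts` (node -> `parent_order` plus `rows`, a
#' map from `"|"`-joined parent-state tuples to probability vectors).
#' Continuous auxiliaries round-trip under an `aux` key.
#'
#' @param spec a `bn_spec`.
#' @param path file path.
#' @return `write_network_json()` returns `path` invisibly;
#'   `read_network_json()` returns a `bn_spec`.
#' @export
write_network_json <- function(spec, path) {
  vars <- lapply(spec$variables, function(v) {
    list(name = v$name, states = v$states, role = v$role)
  })
  edges <- apply(spec$edges, 1, function(e) as.list(unname(e)), simplify = FALSE)
  cpts <- lapply(spec$cpts, function(cpt) {
    grid <- cpt_parent_grid(cpt)
    keys <- if (nrow(grid)) apply(grid, 1, paste, collapse = "|") else "()"
    rows <- stats::setNames(lapply(seq_len(nrow(cpt$prob)),
                                   function(i) unname(cpt$prob[i, ])), keys)
    list(parent_order = cpt$parents, states = cpt$states, rows = rows)
  })
  obj <- list(variables = unname(vars), edges = edges, cpts = cpts)
  if (length(spec$aux)) obj$aux <- spec$aux
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  variables <- list()
  for (v in obj$variables) {
    variables[[v$name]] <- list(name = v$name,
                                states = unlist(v$states),
                                role = v$role)
  }
  edges <- as_edge_matrix(lapply(obj$edges, unlist))
  state_map <- lapply(variables, `[[`, "states")
  cpts <- list()
  for (nd in names(obj$cpts)) {
    c0 <- obj$cpts[[nd]]
    parents <- as.character(unlist(c0$parent_order))
    prob <- do.call(rbind, lapply(c0$rows, unlist))
    # rows arrive keyed by parent tuple; restore canonical row order
    if (length(parents)) {
      grid <- expand.grid(state_map[parents], KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      keys <- apply(grid, 1, paste, collapse = "|")
      prob <- prob[match(keys, rownames(prob)), , drop = FALSE]
    }
    rownames(prob) <- NULL
    cpts[[nd]] <- new_cpt(nd, state_map[[nd]], parents, state_map, prob)
  }
  aux <- list()
  if (!is.null(obj$aux)) {
    aux <- lapply(obj$aux, function(a) {
      list(name = a$name, by = a$by,
           strata = lapply(a$strata, function(s) unlist(s)))
    })
  }
  new_network_spec(variables, edges, cpts, aux)
}

#' Export a directed graph as Graphviz DOT
#'
#' @param spec a `bn_spec`, or any list with `variables` and `edges`.
#' @param path optional file path; if `NULL` the DOT source is returned.
#' @return the DOT source as a character scalar (invisibly when written).
#' @export
write_dot <- function(spec, path = NULL) {
  lines <- c("digraph bn {", "  node [shape=ellipse];")
  for (nd in names(spec$variables)) lines <- c(lines, sprintf("  \"%s\";", nd))
  if (nrow(spec$edges)) {
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                              spec$edges[, 1], spec$edges[, 2]))
  }
  lines <- c(lines, "}")
  src <- paste(lines, collapse = "\n")
  if (is.null(path)) return(src)
  writeLines(src, path)
  invisible(src)
}
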