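# Maximum-likelihood CPT estimation and exact posterior inference by
# variable elimination over discrete factors.
#
# A factor is a list(vars, states, val): `states` a named list of state
# labels, `val` a numeric vector over the state product in column-major
# order with vars[1] varying fastest.

new_factor <- function(vars, states, val) {
  list(vars = vars, states = states[vars], val = as.numeric(val))
}

factor_cards <- function(f) vapply(f$states, length, integer(1))

# index vectors (1-based state codes) for every variable across all cells
factor_assignments <- function(cards) {
  total <- prod(cards)
  out <- vector("list", length(cards))
  before <- 1L
  for (j in seq_along(cards)) {
    out[[j]] <- rep(rep(seq_len(cards[j]), each = before),
                    length.out = total)
    before <- before * cards[j]
  }
  out
}

factor_product <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  states <- c(f1$states, f2$states)[vars]
  cards <- vapply(states, length, integer(1))
  asg <- factor_assignments(cards)
  names(asg) <- vars
  locate <- function(f) {
    idx <- rep(1L, prod(cards))
    mult <- 1L
    for (v in f$vars) {
      idx <- idx + (asg[[v]] - 1L) * mult
      mult <- mult * length(f$states[[v]])
    }
    idx
  }
  new_factor(vars, states, f1$val[locate(f1)] * f2$val[locate(f2)])
}

factor_marginalize <- function(f, var) {
  keep <- setdiff(f$vars, var)
  if (!length(keep)) {
    return(new_factor(character(0), list(), sum(f$val)))
  }
  cards <- factor_cards(f)
  arr <- array(f$val, dim = cards)
  pos <- match(var, f$vars)
  val <- apply(arr, seq_along(f$vars)[-pos], sum)
  new_factor(keep, f$states, as.numeric(val))
}

# slice a factor on observed states (drops the evidence variables)
factor_reduce <- function(f, evidence) {
  ev <- evidence[names(evidence) %in% f$vars]
  if (!length(ev)) return(f)
  cards <- factor_cards(f)
  asg <- factor_assignments(cards)
  names(asg) <- f$vars
  sel <- rep(TRUE, prod(cards))
  for (v in names(ev)) {
    k <- match(ev[[v]], f$states[[v]])
    if (is.na(k)) stop(sprintf("'%s' is not a state of '%s'", ev[[v]], v))
    sel <- sel & (asg[[v]] == k)
  }
  keep <- setdiff(f$vars, names(ev))
  new_factor(keep, f$states, f$val[sel])
}

# min-fill elimination order over the interaction graph of the factor
# scopes; lexicographic tie-break
min_fill_order <- function(scopes, vars) {
  adj <- stats::setNames(vector("list", length(vars)), vars)
  for (sc in scopes) {
    for (v in intersect(sc, vars)) {
      adj[[v]] <- union(adj[[v]], setdiff(intersect(sc, vars), v))
    }
  }
  order <- character(0)
  remaining <- sort(vars)
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      nb <- intersect(adj[[v]], remaining)
      if (length(nb) < 2) return(0L)
      cnt <- 0L
      for (i in seq_along(nb)[-length(nb)]) {
        for (j in seq((i + 1), length(nb))) {
          if (!nb[j] %in% adj[[nb[i]]]) cnt <- cnt + 1L
        }
      }
      cnt
    }, integer(1))
    v <- remaining[which.min(fill)]  # which.min takes the first = lexicographic
    nb <- intersect(adj[[v]], remaining)
    for (a in nb) adj[[a]] <- union(adj[[a]], setdiff(nb, a))
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
  }
  order
}

spec_factors <- function(spec) {
  lapply(names(spec$cpts), function(nd) {
    cpt <- spec$cpts[[nd]]
    vars <- c(cpt$parents, nd)
    states <- c(cpt$parent_states, stats::setNames(list(cpt$states), nd))
    # prob rows: first parent fastest; child index slowest after transpose
    # of the (rows x child) matrix into parent-major order
    val <- as.numeric(cpt$prob)  # column-major: parents fastest, child slowest
    new_factor(vars, states, val)
  })
}

#' Exact posterior inference by variable elimination
#'
#' Evidence is absorbed by slicing each factor; hidden variables are then
#' summed out in `order` (default: min-fill with lexicographic
#' tie-break); the remaining product is normalized.
#'
#' @param factors list of factors, or a `bn_spec` (whose CPTs become the
#'   factors).
#' @param query variable name to report.
#' @param evidence named list / character vector: variable -> observed
#'   state.  Must not include `query`.
#' @param order optional explicit elimination order.
#' @return named probability vector over the query's states (sums to 1).
#' @examples
#' net <- build_reference_network()
#' ev <- list(polypharmacy = "Yes", malnutrition = "Yes",
#'            eating_alone = "Yes", general_frailty = "Yes")
#' eliminate(net, "oral_frailty", ev)  # 92.46% "yes"
#' @export
eliminate <- function(factors, query, evidence = list(), order = NULL) {
  if (inherits(factors, "bn_spec")) factors <- spec_factors(factors)
  evidence <- as.list(evidence)
  if (query %in% names(evidence)) stop("query variable cannot carry evidence")
  factors <- lapply(factors, factor_reduce, evidence = evidence)
  hidden <- setdiff(unique(unlist(lapply(factors, `[[`, "vars"))), query)
  if (is.null(order)) {
    order <- min_fill_order(lapply(factors, `[[`, "vars"), hidden)
  } else {
    order <- intersect(order, hidden)
  }
  for (v in order) {
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touch)) next
    prod_f <- Reduce(factor_product, factors[touch])
    factors <- c(factors[!touch], list(factor_marginalize(prod_f, v)))
  }
  res <- Reduce(factor_product, factors)
  if (!identical(res$vars, query)) {
    for (v in setdiff(res$vars, query)) res <- factor_marginalize(res, v)
  }
  z <- sum(res$val)
  if (z <= 0) stop("evidence has zero probability under the model")
  stats::setNames(res$val / z, res$states[[query]])
}

#' Maximum-likelihood CPT estimation from data
#'
#' Each CPT row is `(count + pseudocount) / (total + pseudocount * r)`.
#' With `pseudocount = 0`, parent configurations never observed yield a
#' uniform row (with a warning).
#'
#' @param data categorical data frame covering all `nodes`.
#' @param edges 2-column character edge matrix (the DAG).
#' @param nodes node set; defaults to all categorical columns of `data`.
#' @param pseudocount additive smoothing constant (default 0 = plain MLE).
#' @param states optional named list fixing each node's state space
#'   (defaults to the sorted observed values).
#' @return named list of `bn_cpt` objects (with `counts` attached).
#' @export
fit_cpts <- function(data, edges, nodes = NULL, pseudocount = 0, states = NULL) {
  edges <- as_edge_matrix(edges)
  cat_cols <- names(data)[!vapply(data, is.numeric, logical(1))]
  if (is.null(nodes)) nodes <- cat_cols
  if (is.null(states)) states <- lapply(stats::setNames(nodes, nodes),
                                        function(v) sort(unique(data[[v]])))
  topological_order(nodes, edges)
  cpts <- list()
  for (nd in nodes) {
    pa <- parents_of(edges, nd)
    r <- length(states[[nd]])
    q <- if (length(pa)) prod(vapply(states[pa], length, integer(1))) else 1L
    idx <- rep(1L, nrow(data))
    mult <- 1L
    for (p in pa) {
      idx <- idx + (match(data[[p]], states[[p]]) - 1L) * mult
      mult <- mult * length(states[[p]])
    }
    code <- match(data[[nd]], states[[nd]])
    counts <- matrix(tabulate(idx + (code - 1L) * q, r * q),
                     nrow = q)  # rows = parent configs, cols = child states
    tot <- rowSums(counts)
    if (pseudocount == 0 && any(tot == 0)) {
      warning(sprintf("node '%s': %d unobserved parent configuration(s) set to uniform",
                      nd, sum(tot == 0)))
    }
    prob <- (counts + pseudocount) / (tot + pseudocount * r)
    prob[tot + pseudocount * r == 0, ] <- 1 / r
    cpts[[nd]] <- new_cpt(nd, states[[nd]], pa, states, prob, counts = counts)
  }
  cpts
}

#' Conditional probability of a node under every configuration of a
#' conditioning set
#'
#' One row per configuration of `given` (default: the node's parents, in
#' which case the result equals the node's CPT), computed by exact
#' inference with the configuration as evidence.  Rows are ordered with
#' the **last** conditioning variable varying fastest, mirroring the
#' published table layout.
#'
#' @param spec a `bn_spec`.
#' @param node target variable.
#' @param given character vector of conditioning variables.
#' @return data frame: one column per conditioning variable, then one
#'   probability column per state of `node`.
#' @export
conditional_table <- function(spec, node, given = NULL) {
  if (is.null(given)) given <- spec$cpts[[node]]$parents
  states <- lapply(spec$variables, `[[`, "states")
  if (!length(given)) {
    post <- eliminate(spec, node)
    return(as.data.frame(as.list(post), check.names = FALSE))
  }
  grid <- expand.grid(rev(states[given]), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, rev(seq_along(given)), drop = FALSE]
  names(grid) <- given
  probs <- t(apply(grid, 1, function(row) {
    eliminate(spec, node, as.list(row))
  }))
  colnames(probs) <- states[[node]]
  cbind(grid, as.data.frame(probs, check.names = FALSE), row.names = NULL)
}

#' Per-record posterior risk prediction
#'
#' For each cohort record, `P(target | all other categorical network
#' variables)` by variable elimination.  Identical evidence patterns are
#' computed once and reused.
#'
#' @param spec a `bn_spec`.
#' @param cohort data frame covering the network variables minus
#'   (optionally) the target.
#' @param target target variable name.
#' @param state which target state's probability to return (default the
#'   last, i.e. "yes" for the reference outcome).
#' @return numeric vector of posterior probabilities, one per record.
#' @export
predict_proba <- function(spec, cohort, target,
                          state = NULL) {
  if (!nrow(cohort)) return(numeric(0))
  vars <- setdiff(names(spec$variables), target)
  missing_cols <- setdiff(vars, names(cohort))
  if (length(missing_cols)) {
    stop(sprintf("cohort lacks network variable(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.null(state)) {
    st <- spec$variables[[target]]$states
    state <- st[length(st)]
  }
  for (v in vars) {
    bad <- !cohort[[v]] %in% spec$variables[[v]]$states
    if (any(bad)) {
      stop(sprintf("record %d: '%s' is not a state of '%s'",
                   which(bad)[1], cohort[[v]][which(bad)[1]], v))
    }
  }
  key <- do.call(paste, c(cohort[vars], sep = "\r"))
  uniq <- !duplicated(key)
  facs <- spec_factors(spec)
  post <- vapply(which(uniq), function(i) {
    ev <- as.list(cohort[i, vars, drop = FALSE])
    unname(eliminate(facs, target, ev)[state])
  }, numeric(1))
  post[match(key, key[uniq])]
}
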