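# Max-Min Hill-Climbing structure learning for discrete data:
# G^2 conditional-independence tests, the MMPC skeleton phase, and a
# BIC-scored greedy search restricted to the skeleton, honouring expert
# whitelist/blacklist constraints.

# integer-code a categorical data frame once; all counting below runs on
# joint indices via tabulate()
encode_data <- function(data, columns = names(data)) {
  columns <- columns[!vapply(data[columns], is.numeric, logical(1))]
  states <- lapply(columns, function(v) sort(unique(data[[v]])))
  names(states) <- columns
  codes <- vapply(columns, function(v) match(data[[v]], states[[v]]), integer(nrow(data)))
  list(codes = codes, states = states,
       cards = vapply(states, length, integer(1)), n = nrow(data))
}

joint_index <- function(enc, vars) {
  if (!length(vars)) return(rep(1L, enc$n))
  idx <- rep(1L, enc$n)
  mult <- 1L
  for (v in vars) {
    idx <- idx + (enc$codes[, v] - 1L) * mult
    mult <- mult * enc$cards[[v]]
  }
  idx
}

# G^2 statistic on encoded data; df adjusted for strata/levels without data
g2_stat <- function(enc, x, y, z = character(0)) {
  rx <- enc$cards[[x]]; ry <- enc$cards[[y]]
  nz <- if (length(z)) prod(enc$cards[z]) else 1L
  idx <- joint_index(enc, c(x, y, z))
  counts <- array(tabulate(idx, rx * ry * nz), dim = c(rx, ry, nz))
  g2 <- 0
  df <- 0L
  for (s in seq_len(nz)) {
    tab <- counts[, , s, drop = FALSE]
    dim(tab) <- c(rx, ry)
    n <- sum(tab)
    if (n == 0) next
    rs <- rowSums(tab); cs <- colSums(tab)
    r_eff <- sum(rs > 0); c_eff <- sum(cs > 0)
    if (r_eff < 2 || c_eff < 2) next
    e <- outer(rs, cs) / n
    nz_cells <- tab > 0
    g2 <- g2 + 2 * sum(tab[nz_cells] * log(tab[nz_cells] / e[nz_cells]))
    df <- df + (r_eff - 1L) * (c_eff - 1L)
  }
  list(statistic = g2, df = df)
}

#' G-squared conditional-independence test
#'
#' Likelihood-ratio test of `x` independent of `y` given the variables in
#' `z`: within every configuration (stratum) of `z`, `2 sum O log(O / E)`
#' over the x-by-y table, summed across strata.  Degrees of freedom sum
#' `(r - 1)(c - 1)` over strata with data, using the observed (non-empty)
#' row and column counts; strata with fewer than two observed levels on
#' either axis contribute nothing.
#'
#' @param data categorical data frame.
#' @param x,y variable names.
#' @param z character vector of conditioning variables (may be empty).
#' @return list with `statistic`, `df`, `p`.
#' @export
g2_ci_test <- function(data, x, y, z = character(0)) {
  if (x %in% z || y %in% z) stop("conditioning set must exclude x and y")
  enc <- encode_data(data, unique(c(x, y, z)))
  res <- g2_stat(enc, x, y, z)
  res$p <- if (res$df > 0) {
    stats::pchisq(res$statistic, res$df, lower.tail = FALSE)
  } else 1
  res
}

# memoised test on encoded data; returns c(p, df, statistic)
make_tester <- function(enc) {
  memo <- new.env(parent = emptyenv())
  function(x, y, z) {
    key <- paste(x, y, paste(sort(z), collapse = ","), sep = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- g2_stat(enc, x, y, z)
    p <- if (res$df > 0) stats::pchisq(res$statistic, res$df, lower.tail = FALSE) else 1
    out <- c(p = p, df = res$df, statistic = res$statistic)
    memo[[key]] <- out
    memo[[paste(y, x, paste(sort(z), collapse = ","), sep = "|")]] <- out
    out
  }
}

# worst-case (maximum) p-value of assoc(x, t | S) over subsets S of cpc,
# |S| <= max_sx; ties in the forward choice are broken by smaller df then
# lexicographic variable order
max_p_over_subsets <- function(test, x, t, cpc, max_sx) {
  worst <- c(p = -1, df = Inf, statistic = 0)
  for (S in subsets_up_to(cpc, max_sx)) {
    r <- test(x, t, S)
    if (r[["p"]] > worst[["p"]] ||
        (r[["p"]] == worst[["p"]] && r[["df"]] < worst[["df"]])) {
      worst <- r
    }
    if (worst[["p"]] >= 1) break
  }
  worst
}

#' MMPC: max-min parents-and-children skeleton discovery
#'
#' For every target the forward phase repeatedly admits the candidate
#' with the largest minimum association (1 - p of the G-squared test) over
#' all conditioning subsets of the current candidate set (up to
#' `max_sx`); candidates independent of the target given some subset are
#' dropped permanently.  The backward phase removes members that a subset
#' of the remainder renders conditionally independent.  Symmetry is then
#' enforced by intersection: the undirected edge x - y survives only if
#' each endpoint is in the other's neighbour set.
#'
#' @param data categorical data frame.
#' @param alpha CI-test level (default 0.05).
#' @param max_sx maximum conditioning-set size (default 3).
#' @return list with `neighbours` (named list node -> character vector)
#'   and `pairs` (2-column matrix of undirected edges, lexicographic).
#' @export
mmpc <- function(data, alpha = 0.05, max_sx = 3) {
  enc <- encode_data(data)
  vars <- colnames(enc$codes)
  if (length(vars) < 2) stop("need at least 2 categorical variables")
  test <- make_tester(enc)
  pc <- list()
  for (t in vars) {
    cpc <- character(0)
    candidates <- setdiff(vars, t)
    repeat {
      best <- NULL
      keep <- character(0)
      for (x in sort(candidates)) {
        worst <- max_p_over_subsets(test, x, t, cpc, max_sx)
        if (worst[["p"]] >= alpha) next  # independent given some subset: drop
        keep <- c(keep, x)
        # max-min: candidate with the smallest worst-case p wins
        if (is.null(best) || worst[["p"]] < best$p ||
            (worst[["p"]] == best$p && worst[["df"]] < best$df)) {
          best <- list(x = x, p = worst[["p"]], df = worst[["df"]])
        }
      }
      if (is.null(best)) break
      cpc <- c(cpc, best$x)
      candidates <- setdiff(keep, best$x)
      if (!length(candidates)) break
    }
    # backward: prune members now shielded by the rest of the CPC
    for (x in cpc) {
      others <- setdiff(cpc, x)
      worst <- max_p_over_subsets(test, x, t, others, max_sx)
      if (worst[["p"]] >= alpha) cpc <- setdiff(cpc, x)
    }
    pc[[t]] <- sort(cpc)
  }
  for (t in vars) pc[[t]] <- sort(intersect(pc[[t]], names(which(vapply(pc, function(s) t %in% s, logical(1))))))
  pairs <- do.call(rbind, lapply(vars, function(t) {
    nb <- pc[[t]][pc[[t]] > t]
    if (length(nb)) cbind(t, nb) else NULL
  }))
  if (is.null(pairs)) pairs <- matrix(character(0), ncol = 2)
  dimnames(pairs) <- list(NULL, c("a", "b"))
  list(neighbours = pc, pairs = pairs)
}

# decomposable family score: multinomial log-likelihood at the MLE minus
# (k / 2) log N, k = (r - 1) * prod(parent cards); higher is better
family_score <- function(enc, node, parents) {
  r <- enc$cards[[node]]
  q <- if (length(parents)) prod(enc$cards[parents]) else 1L
  idx <- joint_index(enc, c(node, parents))
  counts <- matrix(tabulate(idx, r * q), nrow = r)
  tot <- colSums(counts)
  nz <- counts > 0
  ll <- sum(counts[nz] * log(counts[nz] / rep(tot, each = r)[nz]))
  ll - (r - 1) * q / 2 * log(enc$n)
}

#' BIC score of a DAG on categorical data
#'
#' Sum over nodes of the multinomial log-likelihood at the MLE minus
#' `(k / 2) log N` free-parameter penalty (higher is better).
#'
#' @param data categorical data frame.
#' @param edges 2-column character edge matrix (the DAG).
#' @param nodes optional node set (default: all categorical columns).
#' @return numeric scalar.
#' @export
bic_score <- function(data, edges, nodes = NULL) {
  enc <- encode_data(data)
  if (is.null(nodes)) nodes <- colnames(enc$codes)
  edges <- as_edge_matrix(edges)
  topological_order(nodes, edges)  # acyclicity guard
  sum(vapply(nodes, function(nd) family_score(enc, nd, parents_of(edges, nd)),
             numeric(1)))
}

#' Edge constraints for structure learning
#'
#' @param whitelist,blacklist 2-column character matrices (or lists of
#'   pairs) of directed edges that must / must not appear.
#' @return list of class `of_constraints`.
#' @export
edge_constraints <- function(whitelist = NULL, blacklist = NULL) {
  wl <- if (is.null(whitelist)) empty_edges() else as_edge_matrix(whitelist)
  bl <- if (is.null(blacklist)) empty_edges() else as_edge_matrix(blacklist)
  if (length(intersect(edge_key(wl), edge_key(bl)))) {
    stop("whitelist and blacklist overlap")
  }
  if (nrow(wl) && !is_acyclic(unique(c(wl)), wl)) {
    stop("whitelist is cyclic")
  }
  structure(list(whitelist = wl, blacklist = bl), class = "of_constraints")
}

#' Greedy hill-climbing over DAGs restricted to a skeleton
#'
#' Score-based phase of MMHC: starting from the whitelist, repeatedly
#' applies the first BIC-improving move in a fixed enumeration (adds,
#' then deletes, then reversals, each in lexicographic edge order).
#' Additions are restricted to pairs present in the skeleton or the
#' whitelist; the blacklist and acyclicity are never violated, whitelist
#' edges are never removed or reversed, and in-degree is capped at
#' `max_parents`.  Terminates at a local optimum, deterministically.
#'
#' @param data categorical data frame.
#' @param skeleton result of [mmpc()] (or a list with a `pairs` matrix);
#'   `NULL` means run [mmpc()] first with `alpha`.
#' @param constraints an [edge_constraints()] object.
#' @param max_parents in-degree cap (default 5).
#' @param alpha forwarded to [mmpc()] when `skeleton` is `NULL`.
#' @param max_sx forwarded to [mmpc()] when `skeleton` is `NULL`.
#' @return list of class `of_structure`: `edges`, `score`, `nodes`,
#'   `skeleton`.
#' @export
hill_climb <- function(data, skeleton = NULL, constraints = edge_constraints(),
                       max_parents = 5, alpha = 0.05, max_sx = 3) {
  enc <- encode_data(data)
  nodes <- colnames(enc$codes)
  if (is.null(skeleton)) skeleton <- mmpc(data, alpha = alpha, max_sx = max_sx)
  allowed <- skeleton$pairs
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
  allowed_pairs <- unique(c(
    if (nrow(allowed)) pair_key(allowed[, 1], allowed[, 2]),
    if (nrow(constraints$whitelist)) {
      pair_key(constraints$whitelist[, 1], constraints$whitelist[, 2])
    }
  ))
  bl_keys <- edge_key(constraints$blacklist)
  wl_keys <- edge_key(constraints$whitelist)
  if (nrow(constraints$whitelist) &&
      !all(c(constraints$whitelist) %in% nodes)) {
    stop("whitelist references unknown variables")
  }
  score_memo <- new.env(parent = emptyenv())
  fscore <- function(nd, parents) {
    key <- paste(nd, paste(sort(parents), collapse = ","), sep = "|")
    hit <- score_memo[[key]]
    if (is.null(hit)) {
      hit <- family_score(enc, nd, sort(parents))
      score_memo[[key]] <- hit
    }
    hit
  }
  edges <- constraints$whitelist
  # candidate directed arcs: both orientations of every allowed pair,
  # minus blacklisted, in lexicographic order
  cand <- NULL
  for (pk in sort(allowed_pairs)) {
    ab <- strsplit(pk, "~", fixed = TRUE)[[1]]
    cand <- rbind(cand, c(ab[1], ab[2]), c(ab[2], ab[1]))
  }
  if (is.null(cand)) cand <- empty_edges()
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  cand <- cand[!(paste(cand[, 1], cand[, 2], sep = "->") %in% bl_keys), , drop = FALSE]
  delta_add <- function(edges, from, to) {
    pa <- parents_of(edges, to)
    if (length(pa) >= max_parents) return(-Inf)
    fscore(to, c(pa, from)) - fscore(to, pa)
  }
  repeat {
    improved <- FALSE
    # adds
    for (i in seq_len(nrow(cand))) {
      from <- cand[i, 1]; to <- cand[i, 2]
      if (has_edge(edges, from, to) || has_edge(edges, to, from)) next
      if (!is_acyclic(nodes, add_edge(edges, from, to))) next
      if (delta_add(edges, from, to) > 1e-10) {
        edges <- add_edge(edges, from, to)
        improved <- TRUE
        break
      }
    }
    if (improved) next
    # deletes (never a whitelist edge)
    if (nrow(edges)) {
      ord <- order(edges[, 1], edges[, 2])
      for (i in ord) {
        from <- edges[i, 1]; to <- edges[i, 2]
        if (paste(from, to, sep = "->") %in% wl_keys) next
        pa <- parents_of(edges, to)
        if (fscore(to, setdiff(pa, from)) - fscore(to, pa) > 1e-10) {
          edges <- drop_edge(edges, from, to)
          improved <- TRUE
          break
        }
      }
    }
    if (improved) next
    # reversals (never a whitelist edge; reversed arc must not be blacklisted)
    if (nrow(edges)) {
      ord <- order(edges[, 1], edges[, 2])
      for (i in ord) {
        from <- edges[i, 1]; to <- edges[i, 2]
        if (paste(from, to, sep = "->") %in% wl_keys) next
        if (paste(to, from, sep = "->") %in% bl_keys) next
        e2 <- add_edge(drop_edge(edges, from, to), to, from)
        if (!is_acyclic(nodes, e2)) next
        if (length(parents_of(edges, from)) >= max_parents) next
        d <- (fscore(to, setdiff(parents_of(edges, to), from)) -
                fscore(to, parents_of(edges, to))) +
             (fscore(from, c(parents_of(edges, from), to)) -
                fscore(from, parents_of(edges, from)))
        if (d > 1e-10) {
          edges <- e2
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  total <- sum(vapply(nodes, function(nd) fscore(nd, parents_of(edges, nd)),
                      numeric(1)))
  structure(list(edges = edges, score = total, nodes = nodes,
                 skeleton = skeleton),
            class = "of_structure")
}

#' Structural Hamming distance between two DAGs
#'
#' With `skeleton = TRUE` (default) compares undirected skeletons: the
#' number of adjacencies present in exactly one graph.  With
#' `skeleton = FALSE` additionally counts shared adjacencies whose
#' orientation differs.
#'
#' @param edges1,edges2 2-column character edge matrices.
#' @param skeleton compare skeletons only?
#' @return integer distance.
#' @export
shd <- function(edges1, edges2, skeleton = TRUE) {
  e1 <- as_edge_matrix(edges1); e2 <- as_edge_matrix(edges2)
  und <- function(e) unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "~"))
  u1 <- und(e1); u2 <- und(e2)
  d <- length(setdiff(u1, u2)) + length(setdiff(u2, u1))
  if (!skeleton) {
    shared <- intersect(u1, u2)
    k1 <- edge_key(e1)
    k2 <- edge_key(e2)
    for (pk in shared) {
      ab <- strsplit(pk, "~", fixed = TRUE)[[1]]
      same <- (paste(ab[1], ab[2], sep = "->") %in% k1) ==
              (paste(ab[1], ab[2], sep = "->") %in% k2)
      if (!same) d <- d + 1L
    }
  }
  d
}
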