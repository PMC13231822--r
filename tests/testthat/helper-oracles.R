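# Independent oracles used across the suite.  These deliberately avoid
# the package's factor machinery: the joint is enumerated row by row.

# exhaustive-enumeration posterior P(query | evidence) for small networks
enumerate_posterior <- function(spec, query, evidence = list()) {
  states <- lapply(spec$variables, `[[`, "states")
  grid <- expand.grid(states, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- rep(1, nrow(grid))
  for (nd in names(states)) {
    cpt <- spec$cpts[[nd]]
    ri <- rep(1L, nrow(grid))
    mult <- 1L
    for (pa in cpt$parents) {
      ri <- ri + (match(grid[[pa]], cpt$parent_states[[pa]]) - 1L) * mult
      mult <- mult * length(cpt$parent_states[[pa]])
    }
    p <- p * cpt$prob[cbind(ri, match(grid[[nd]], cpt$states))]
  }
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  p <- p[keep]
  g <- grid[[query]][keep]
  out <- vapply(states[[query]], function(s) sum(p[g == s]), numeric(1))
  out / sum(out)
}

# brute-force Mann-Whitney U by pair counting
brute_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# brute-force AUC by concordant-pair counting
brute_auc <- function(predicted, observed) {
  pos <- predicted[observed == 1]
  neg <- predicted[observed == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# random small discrete network: random DAG (<= max_parents parents from
# earlier nodes), random state counts, Dirichlet(1) CPT rows
random_network <- function(n_nodes, max_states = 3, max_parents = 2,
                           p_edge = 0.5) {
  nodes <- sprintf("V%02d", seq_len(n_nodes))
  states <- lapply(nodes, function(nd) {
    paste0("s", seq_len(sample(2:max_states, 1)))
  })
  names(states) <- nodes
  edges <- ofbn:::empty_edges()
  for (i in seq_len(n_nodes)[-1]) {
    avail <- nodes[seq_len(i - 1)]
    k <- min(length(avail), stats::rbinom(1, max_parents, p_edge))
    if (k > 0) {
      for (pa in sample(avail, k)) edges <- rbind(edges, c(pa, nodes[i]))
    }
  }
  variables <- lapply(nodes, function(nd) {
    list(name = nd, states = states[[nd]],
         role = if (nd %in% edges[, 2]) "internal" else "root")
  })
  names(variables) <- nodes
  rdirichlet_row <- function(k) {
    g <- stats::rgamma(k, 1)
    g / sum(g)
  }
  cpts <- lapply(nodes, function(nd) {
    pa <- ofbn:::parents_of(edges, nd)
    q <- if (length(pa)) prod(lengths(states[pa])) else 1L
    prob <- t(vapply(seq_len(q), function(i) rdirichlet_row(length(states[[nd]])),
                     numeric(length(states[[nd]]))))
    new_cpt(nd, states[[nd]], pa, states, prob)
  })
  names(cpts) <- nodes
  new_network_spec(variables, edges, cpts)
}

# tiny deterministic chain A -> B (binary) used in several places
toy_chain <- function(p_b_given_a1 = 0.9, p_b_given_a0 = 0.1, p_a = 0.5) {
  st <- list(A = c("a0", "a1"), B = c("b0", "b1"))
  new_network_spec(
    variables = list(A = list(name = "A", states = st$A, role = "root"),
                     B = list(name = "B", states = st$B, role = "internal")),
    edges = rbind(c("A", "B")),
    cpts = list(
      A = new_cpt("A", st$A, prob = rbind(c(1 - p_a, p_a))),
      B = new_cpt("B", st$B, "A", st,
                  rbind(c(1 - p_b_given_a0, p_b_given_a0),
                        c(1 - p_b_given_a1, p_b_given_a1)))
    )
  )
}
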