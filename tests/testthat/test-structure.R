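sample_chain <- function(n, seed) {
  # A -> B -> C with strong links
  set.seed(seed)
  a <- rbinom(n, 1, 0.5)
  b <- rbinom(n, 1, plogis(-1 + 2 * a))
  c <- rbinom(n, 1, plogis(-1 + 2 * b))
  data.frame(A = c("n", "y")[a + 1], B = c("n", "y")[b + 1],
             C = c("n", "y")[c + 1], stringsAsFactors = FALSE)
}

test_that("G2 test matches direct summation and detects dependence", {
  set.seed(5)
  d <- data.frame(x = sample(c("a", "b"), 500, TRUE),
                  y = sample(c("u", "v"), 500, TRUE), stringsAsFactors = FALSE)
  r <- g2_ci_test(d, "x", "y")
  # independent re-summation oracle on the 2x2 table
  tab <- table(d$x, d$y)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  g2_direct <- 2 * sum(ifelse(tab > 0, tab * log(tab / e), 0))
  expect_equal(r$statistic, g2_direct, tolerance = 1e-10)
  expect_identical(r$df, 1L)

  # y a deterministic copy of x
  d2 <- data.frame(x = d$x, y = d$x, stringsAsFactors = FALSE)
  expect_lt(g2_ci_test(d2, "x", "y")$p, 1e-10)

  # conditional: x and y dependent marginally, independent given z
  set.seed(6)
  z <- sample(c("p", "q"), 4000, TRUE)
  x <- ifelse(runif(4000) < ifelse(z == "p", 0.8, 0.2), "a", "b")
  y <- ifelse(runif(4000) < ifelse(z == "p", 0.8, 0.2), "u", "v")
  d3 <- data.frame(x, y, z, stringsAsFactors = FALSE)
  expect_lt(g2_ci_test(d3, "x", "y")$p, 1e-6)
  expect_gt(g2_ci_test(d3, "x", "y", "z")$p, 0.001)
  expect_identical(g2_ci_test(d3, "x", "y", "z")$df, 2L)
  expect_error(g2_ci_test(d3, "x", "y", "x"), "exclude")
})

test_that("mmpc recovers chain and collider skeletons and rejects noise", {
  d <- sample_chain(20000, seed = 301)
  sk <- mmpc(d)
  expect_setequal(apply(sk$pairs, 1, paste, collapse = "-"), c("A-B", "B-C"))
  expect_false("C" %in% sk$neighbours$A)

  # collider A -> C <- B
  set.seed(302)
  a <- rbinom(20000, 1, 0.5); b <- rbinom(20000, 1, 0.5)
  cc <- rbinom(20000, 1, plogis(-1 + 1.5 * a + 1.5 * b))
  dc <- data.frame(A = c("n", "y")[a + 1], B = c("n", "y")[b + 1],
                   C = c("n", "y")[cc + 1], stringsAsFactors = FALSE)
  skc <- mmpc(dc)
  keys <- apply(skc$pairs, 1, paste, collapse = "-")
  expect_setequal(keys, c("A-C", "B-C"))

  # mutually independent noise: empty skeleton at strict alpha
  set.seed(303)
  dn <- as.data.frame(lapply(1:4, function(i) sample(c("a", "b"), 5000, TRUE)),
                      col.names = paste0("N", 1:4), stringsAsFactors = FALSE)
  expect_equal(nrow(mmpc(dn, alpha = 0.001)$pairs), 0)

  # symmetry by construction
  net <- build_reference_network(include_aux = FALSE)
  sk2 <- mmpc(sample_cohort(net, 5000, seed = 304))
  for (v in names(sk2$neighbours)) {
    for (w in sk2$neighbours[[v]]) expect_true(v %in% sk2$neighbours[[w]])
  }
})

test_that("bic_score matches hand evaluation and decomposes", {
  d <- data.frame(x = c(rep("a", 6), rep("b", 4)), stringsAsFactors = FALSE)
  s <- bic_score(d, NULL, nodes = "x")
  expect_equal(s, 6 * log(0.6) + 4 * log(0.4) - 0.5 * log(10), tolerance = 1e-3)

  net <- build_reference_network(include_aux = FALSE)
  coh <- sample_cohort(net, 2000, seed = 401)
  empty <- bic_score(coh, NULL)
  parts <- vapply(names(coh), function(v) bic_score(coh[v], NULL), numeric(1))
  expect_equal(empty, sum(parts), tolerance = 1e-8)

  # an edge from independent noise lowers the penalized score at n = 10,000
  set.seed(402)
  dn <- data.frame(u = sample(c("a", "b"), 10000, TRUE),
                   v = sample(c("c", "d"), 10000, TRUE), stringsAsFactors = FALSE)
  expect_lt(bic_score(dn, rbind(c("u", "v"))), bic_score(dn, NULL))
  expect_error(bic_score(dn, rbind(c("u", "v"), c("v", "u"))), "cycle")
})

test_that("hill climbing honours constraints and never lowers the score", {
  net <- build_reference_network(include_aux = FALSE)
  coh <- sample_cohort(net, 5000, seed = 501)

  # whitelisting every reference edge forces the reference DAG
  forced <- hill_climb(coh, constraints = edge_constraints(whitelist = net$edges))
  expect_true(all(ofbn:::edge_key(net$edges) %in% ofbn:::edge_key(forced$edges)))
  expect_true(ofbn:::is_acyclic(forced$nodes, forced$edges))
  expect_gte(forced$score, bic_score(coh, net$edges))

  # blacklist is never violated; result stays acyclic
  bl <- rbind(c("polypharmacy", "oral_frailty"), c("oral_frailty", "polypharmacy"))
  fit <- hill_climb(coh, constraints = edge_constraints(blacklist = bl))
  expect_false(any(ofbn:::edge_key(bl) %in% ofbn:::edge_key(fit$edges)))
  expect_true(ofbn:::is_acyclic(fit$nodes, fit$edges))
  # local optimum at least as good as the empty graph it started from
  expect_gte(fit$score, bic_score(coh, NULL))

  # pure noise yields the empty graph
  set.seed(502)
  dn <- as.data.frame(lapply(1:4, function(i) sample(c("a", "b"), 3000, TRUE)),
                      col.names = paste0("N", 1:4), stringsAsFactors = FALSE)
  expect_equal(nrow(hill_climb(dn, alpha = 0.001)$edges), 0)

  expect_error(edge_constraints(whitelist = rbind(c("a", "b")),
                                blacklist = rbind(c("a", "b"))), "overlap")
  expect_error(edge_constraints(whitelist = rbind(c("a", "b"), c("b", "a"))),
               "cyclic")
})

test_that("structure recovery improves with sample size", {
  net <- build_reference_network(include_aux = FALSE)
  mean_shd <- vapply(c(500, 5000, 50000), function(n) {
    mean(vapply(1:3, function(s) {
      coh <- sample_cohort(net, n, seed = 600 + s)
      fit <- hill_climb(coh)
      shd(fit$edges, net$edges)
    }, numeric(1)))
  }, numeric(1))
  expect_gte(mean_shd[1], mean_shd[3])
  expect_lte(mean_shd[3], 4)
})

test_that("shd counts skeleton and orientation differences", {
  e1 <- rbind(c("a", "b"), c("b", "c"))
  e2 <- rbind(c("b", "a"), c("b", "c"), c("c", "d"))
  expect_identical(shd(e1, e2), 1L)              # c-d missing
  expect_identical(shd(e1, e2, skeleton = FALSE), 2L)  # + a-b flipped
  expect_identical(shd(e1, e1, skeleton = FALSE), 0L)
})
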