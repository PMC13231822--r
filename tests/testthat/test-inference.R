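test_that("fit_cpts estimates frequencies with optional smoothing", {
  d <- data.frame(p = c("yes", "yes", "yes", "yes", "no"),
                  x = c("no", "yes", "yes", "yes", "no"),
                  stringsAsFactors = FALSE)
  cpts <- fit_cpts(d, rbind(c("p", "x")))
  row_yes <- cpt_row_index(cpts$x, list(p = "yes"))
  expect_equal(unname(cpts$x$prob[row_yes, ]), c(0.25, 0.75))

  # Laplace smoothing fills an unseen configuration with a uniform row
  d2 <- data.frame(p = c("yes", "yes"), x = c("no", "yes"), stringsAsFactors = FALSE)
  sm <- fit_cpts(d2, rbind(c("p", "x")),
                 states = list(p = c("no", "yes"), x = c("no", "yes")),
                 pseudocount = 1)
  row_no <- cpt_row_index(sm$x, list(p = "no"))
  expect_equal(unname(sm$x$prob[row_no, ]), c(0.5, 0.5))
  # and with pseudocount 0 the unseen row is uniform with a warning
  expect_warning(
    mle <- fit_cpts(d2, rbind(c("p", "x")),
                    states = list(p = c("no", "yes"), x = c("no", "yes"))),
    "unobserved")
  expect_equal(unname(mle$x$prob[row_no, ]), c(0.5, 0.5))
})

test_that("variable elimination equals exhaustive enumeration", {
  net <- build_reference_network(include_aux = FALSE)
  cases <- list(
    list(q = "oral_frailty", ev = list()),
    list(q = "oral_frailty",
         ev = list(polypharmacy = "Yes", malnutrition = "Yes",
                   eating_alone = "Yes", general_frailty = "Yes")),
    list(q = "oral_frailty", ev = list(age = ">=60", depression = "Yes")),
    list(q = "malnutrition", ev = list(oral_frailty = "yes")),  # diagnostic
    list(q = "age", ev = list())                                # root prior
  )
  for (cs in cases) {
    expect_equal(unname(eliminate(net, cs$q, cs$ev)),
                 unname(enumerate_posterior(net, cs$q, cs$ev)),
                 tolerance = 1e-9)
  }
  expect_equal(unname(eliminate(net, "age")), c(322, 358) / 680, tolerance = 1e-12)

  # posteriors are probability vectors
  post <- eliminate(net, "oral_frailty", list(malnutrition = "Yes"))
  expect_equal(sum(post), 1, tolerance = 1e-9)

  # impossible evidence raises, never returns NaN
  z <- toy_chain(p_b_given_a1 = 1, p_b_given_a0 = 1)
  expect_error(eliminate(z, "A", list(B = "b0")), "zero probability")
  expect_error(eliminate(net, "age", list(age = "<60")), "cannot carry evidence")
})

test_that("the published full-evidence risk query returns 92.46%", {
  net <- build_reference_network()
  post <- eliminate(net, "oral_frailty",
                    list(polypharmacy = "Yes", malnutrition = "Yes",
                         eating_alone = "Yes", general_frailty = "Yes"))
  expect_equal(unname(post["yes"]), 0.9246, tolerance = 1e-9)
})

test_that("conditional_table reproduces the published 16-row table", {
  net <- build_reference_network()
  ct <- conditional_table(net, "oral_frailty")
  expect_identical(nrow(ct), 16L)
  t3 <- load_fixtures()$table3
  # rows are emitted with the last parent fastest, the published layout
  for (i in seq_len(nrow(t3))) {
    expect_identical(unlist(ct[i, 1:4], use.names = FALSE),
                     unlist(t3[i, 1:4], use.names = FALSE))
    expect_lt(abs(ct$yes[i] - t3$p_yes[i]), 5e-5)
  }
  # node with no parents: single row equal to the prior
  pr <- conditional_table(net, "age")
  expect_equal(unname(unlist(pr)), c(322, 358) / 680, tolerance = 1e-9)
  # conditioning on a non-parent ancestor set agrees with enumeration
  small <- build_reference_network(include_aux = FALSE)
  ct2 <- conditional_table(small, "oral_frailty", given = c("age", "depression"))
  for (i in seq_len(nrow(ct2))) {
    oracle <- enumerate_posterior(small, "oral_frailty",
                                  as.list(ct2[i, c("age", "depression")]))
    expect_equal(unname(unlist(ct2[i, c("no", "yes")])), unname(oracle),
                 tolerance = 1e-9)
  }
})

test_that("predict_proba respects the Markov property and validates input", {
  net <- build_reference_network(include_aux = FALSE)
  coh <- sample_cohort(net, 200, seed = 61)
  pred <- predict_proba(net, coh, "oral_frailty")
  expect_length(pred, 200)
  # given its parents, the outcome ignores non-descendant evidence
  cpt <- net$cpts$oral_frailty
  for (i in c(1, 50, 137)) {
    ri <- cpt_row_index(cpt, coh[i, cpt$parents])
    expect_equal(pred[i], unname(cpt$prob[ri, "yes"]), tolerance = 1e-9)
  }
  expect_identical(predict_proba(net, coh[0, ], "oral_frailty"), numeric(0))
  bad <- coh
  bad$age[3] <- "ninety"
  expect_error(predict_proba(net, bad, "oral_frailty"), "record 3")
})

test_that("eliminate equals enumeration on random networks (property)", {
  set.seed(777)
  for (rep in 1:25) {
    spec <- random_network(sample(4:8, 1))
    nodes <- names(spec$variables)
    q <- sample(nodes, 1)
    n_ev <- sample(0:2, 1)
    ev_nodes <- sample(setdiff(nodes, q), n_ev)
    ev <- lapply(ev_nodes, function(v) sample(spec$variables[[v]]$states, 1))
    names(ev) <- ev_nodes
    oracle <- try(enumerate_posterior(spec, q, ev), silent = TRUE)
    if (inherits(oracle, "try-error") || any(!is.finite(oracle))) next
    expect_equal(unname(eliminate(spec, q, ev)), unname(oracle), tolerance = 1e-9)
  }
})

test_that("sampling then refitting round-trips the CPTs", {
  net <- build_reference_network(include_aux = FALSE)
  coh <- sample_cohort(net, 50000, seed = 71)
  cpts <- suppressWarnings(
    fit_cpts(coh, net$edges, states = lapply(net$variables, `[[`, "states")))
  for (nd in c("age", "polypharmacy", "eating_alone", "general_frailty")) {
    tot <- rowSums(cpts[[nd]]$counts)
    rows <- tot >= 1000
    expect_lt(max(abs(cpts[[nd]]$prob[rows, ] - net$cpts[[nd]]$prob[rows, ])), 0.02)
  }
})
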