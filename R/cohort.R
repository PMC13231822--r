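#' Sample a synthetic patient cohort from a Bayesian network
#'
#' Ancestral sampling: nodes are visited in the lexicographically
#' smallest topological order and each record's state is drawn from the
#' node's CPT row selected by its already-sampled parents.  Continuous
#' auxiliary covariates, if the spec carries any, are then drawn from
#' their per-stratum Gaussians given the sampled stratifying variable.
#' A single `set.seed(seed)` call drives all randomness, so a given
#' `(spec, n, seed)` always reproduces the identical cohort.
#'
#' @param spec a validated `bn_spec`.
#' @param n number of records (>= 1).
#' @param seed integer random seed.
#' @param missing_rate optional MCAR missingness rate in `[0, 1)` applied
#'   to the categorical columns (default 0: no missing values).
#' @return a `data.frame` of class `of_cohort` with one column per
#'   variable; attributes `n` and `seed` record the draw.
#' @examples
#' net <- build_reference_network()
#' coh <- sample_cohort(net, n = 100, seed = 1)
#' mean(coh$oral_frailty == "yes")
#' @export
sample_cohort <- function(spec, n, seed, missing_rate = 0) {
  validate_network(spec)
  if (n < 1) stop("n must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  set.seed(as.integer(seed))
  nodes <- names(spec$variables)
  order <- topological_order(nodes, spec$edges)
  codes <- list()  # integer state codes per node
  for (nd in order) {
    cpt <- spec$cpts[[nd]]
    if (!length(cpt$parents)) {
      row_idx <- rep(1L, n)
    } else {
      row_idx <- rep(1L, n)
      mult <- 1L
      for (p in cpt$parents) {
        row_idx <- row_idx + (codes[[p]] - 1L) * mult
        mult <- mult * length(cpt$parent_states[[p]])
      }
    }
    k <- ncol(cpt$prob)
    cum <- t(apply(cpt$prob, 1, cumsum))
    u <- stats::runif(n)
    if (k == 2) {
      codes[[nd]] <- 1L + (u > cum[row_idx, 1])
    } else {
      codes[[nd]] <- 1L + as.integer(rowSums(u > cum[row_idx, -k, drop = FALSE]))
    }
  }
  out <- as.data.frame(lapply(nodes, function(nd) {
    spec$variables[[nd]]$states[codes[[nd]]]
  }), stringsAsFactors = FALSE)
  names(out) <- nodes
  for (a in spec$aux) {
    by <- out[[a$by]]
    x <- numeric(n)
    for (s in names(a$strata)) {
      sel <- by == s
      x[sel] <- stats::rnorm(sum(sel), a$strata[[s]][["mean"]],
                             a$strata[[s]][["sd"]])
    }
    out[[a$name]] <- x
  }
  if (missing_rate > 0) {
    for (nd in nodes) {
      out[[nd]][stats::runif(n) < missing_rate] <- NA
    }
  }
  structure(out, n = n, seed = as.integer(seed),
            class = c("of_cohort", "data.frame"))
}

#' Empirical state frequencies of a cohort
#'
#' @param cohort a data frame of categorical columns (continuous columns
#'   are skipped).
#' @return named list: variable -> named relative-frequency vector
#'   (sums to 1 within 1e-12).
#' @export
empirical_marginals <- function(cohort) {
  if (!nrow(cohort)) stop("cohort is empty")
  cols <- names(cohort)[!vapply(cohort, is.numeric, logical(1))]
  out <- lapply(cols, function(nd) {
    tab <- table(cohort[[nd]], useNA = "no")
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  stats::setNames(out, cols)
}

#' Read / write a cohort CSV
#'
#' Plain UTF-8 CSV with a header row of variable names; categorical cells
#' hold state labels verbatim.
#'
#' @param cohort a data frame.
#' @param path file path.
#' @return `read_cohort_csv()` returns a data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
}
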