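# Multivariable binary logistic regression from first principles: dummy
# coding with the first listed state as reference, IRLS maximum
# likelihood, Wald inference with OR confidence intervals, tolerance/VIF
# collinearity diagnostics, and the Hosmer-Lemeshow calibration test.

CI_Z <- 1.959964  # fixed 95% multiplier

#' Build a treatment-coded design matrix
#'
#' Each categorical variable with k states contributes k - 1 indicator
#' columns (`var=state`), the first observed-or-declared state being the
#' reference; numeric columns enter as-is; an intercept column of ones is
#' first.
#'
#' @param cohort data frame.
#' @param terms character vector of column names to include.
#' @param levels optional named list variable -> state order (defaults to
#'   sorted unique values); the first level is the reference.
#' @return list with `X` (numeric matrix), `reference_levels` (named
#'   character vector), `terms`.
#' @export
design_matrix <- function(cohort, terms, levels = NULL) {
  cols <- list("(Intercept)" = rep(1, nrow(cohort)))
  refs <- character(0)
  for (v in terms) {
    col <- cohort[[v]]
    if (is.null(col)) stop(sprintf("unknown column '%s'", v))
    if (is.numeric(col)) {
      cols[[v]] <- col
    } else {
      lv <- if (!is.null(levels[[v]])) levels[[v]] else sort(unique(col))
      bad <- setdiff(unique(col), lv)
      if (length(bad)) stop(sprintf("column '%s': unexpected state '%s'", v, bad[1]))
      refs[[v]] <- lv[1]
      for (s in lv[-1]) cols[[paste0(v, "=", s)]] <- as.numeric(col == s)
    }
  }
  list(X = do.call(cbind, cols), reference_levels = refs, terms = terms)
}

#' Fit a binary logistic regression by IRLS
#'
#' Maximum likelihood via iteratively reweighted least squares;
#' convergence when `max |delta beta| < 1e-8` (at most 100 iterations).
#' Standard errors come from the inverse observed information.  A
#' coefficient exceeding 15 in absolute value triggers a separation
#' warning.
#'
#' @param X numeric design matrix including an intercept column (see
#'   [design_matrix()]), or the list that function returns.
#' @param y binary 0/1 outcome vector (or logical).
#' @param weights optional case weights (grouped-data fitting).
#' @return object of class `of_logit`: list with `coefficients` (data
#'   frame: term, B, SE, Wald, OR, ci_lo, ci_hi, p), `vcov`, `deviance`,
#'   `fitted`, `converged`, `iterations`, `reference_levels`.
#' @export
fit_logistic <- function(X, y, weights = NULL) {
  refs <- character(0)
  if (is.list(X) && !is.null(X$X)) {
    refs <- X$reference_levels
    X <- X$X
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (is.null(weights)) weights <- rep(1, length(y))
  n_par <- ncol(X)
  if (sum(weights) <= n_par) stop("more parameters than observations")
  # constant non-intercept columns make the information singular
  const <- apply(X, 2, function(cl) all(cl == cl[1]))
  if (any(const & colnames(X) != "(Intercept)")) {
    stop(sprintf("constant non-intercept column: %s",
                 colnames(X)[const & colnames(X) != "(Intercept)"][1]))
  }
  beta <- rep(0, n_par)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(100L)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- weights * p * (1 - p)
    info <- crossprod(X, X * w)
    score <- crossprod(X, weights * (y - p))
    step <- tryCatch(solve(info, score),
                     error = function(e) stop("singular information matrix: rank-deficient design"))
    beta <- beta + drop(step)
    if (any(abs(beta) > 15)) {
      warning("possible complete separation: |coefficient| > 15")
      break
    }
    if (max(abs(step)) < 1e-8) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  info <- crossprod(X, X * (weights * p * (1 - p)))
  vcov <- tryCatch(solve(info),
                   error = function(e) matrix(NA_real_, n_par, n_par))
  se <- sqrt(diag(vcov))
  dev <- -2 * sum(weights * (y * log(pmax(p, 1e-300)) +
                               (1 - y) * log(pmax(1 - p, 1e-300))))
  wald <- (beta / se)^2
  coefs <- data.frame(
    term = colnames(X), B = beta, SE = se, Wald = wald,
    OR = exp(beta), ci_lo = exp(beta - CI_Z * se), ci_hi = exp(beta + CI_Z * se),
    p = stats::pchisq(wald, 1, lower.tail = FALSE),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(coefficients = coefs, vcov = vcov, deviance = dev,
                 fitted = p, converged = converged, iterations = iter,
                 reference_levels = refs),
            class = "of_logit")
}

#' @export
print.of_logit <- function(x, ...) {
  cat(sprintf("Binary logistic regression (IRLS, %d iterations%s)\n",
              x$iterations, if (x$converged) "" else ", NOT converged"))
  print(x$coefficients, digits = 4)
  cat(sprintf("deviance: %.3f\n", x$deviance))
  invisible(x)
}

#' Tolerance / VIF collinearity diagnostics
#'
#' For each non-intercept column j, `R2_j` is the coefficient of
#' determination of an OLS regression of column j on all other columns;
#' tolerance is `1 - R2_j` and VIF its reciprocal.  Exactly collinear
#' columns report `VIF = Inf`.
#'
#' @param X numeric design matrix with an intercept column (or the list
#'   from [design_matrix()]).
#' @return data frame: `term`, `tolerance`, `vif`.
#' @export
collinearity <- function(X) {
  if (is.list(X) && !is.null(X$X)) X <- X$X
  keep <- colnames(X) != "(Intercept)"
  if (sum(keep) < 2) stop("need at least 2 non-intercept columns")
  terms <- colnames(X)[keep]
  out <- lapply(terms, function(tm) {
    yj <- X[, tm]
    Xo <- X[, colnames(X) != tm, drop = FALSE]
    fit <- stats::lm.fit(Xo, yj)
    ssr <- sum(fit$residuals^2)
    sst <- sum((yj - mean(yj))^2)
    r2 <- if (sst == 0) 1 else 1 - ssr / sst
    tol <- max(1 - r2, 0)
    data.frame(term = tm, tolerance = tol,
               vif = if (tol <= .Machine$double.eps^0.75) Inf else 1 / tol,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hosmer-Lemeshow calibration test
#'
#' Records are ranked by predicted risk and split into `groups`
#' near-equal bins; the statistic is
#' `sum over bins of (O - E)^2 / (E (1 - E / n_g))` on the event counts,
#' with `df = groups - 2`.  A bin whose expected event count is zero is
#' merged with its neighbour (with a message).
#'
#' @param predicted probabilities in (0, 1).
#' @param observed binary 0/1 vector.
#' @param groups number of bins (default 10, giving df = 8).
#' @return list with `chi2`, `df`, `p`, `bins` (per-bin n, observed,
#'   expected, mean predicted).
#' @export
hosmer_lemeshow <- function(predicted, observed, groups = 10) {
  if (groups < 3) stop("groups must be >= 3")
  if (any(predicted <= 0 | predicted >= 1)) stop("predicted must lie in (0, 1)")
  observed <- as.numeric(observed)
  n <- length(predicted)
  ord <- order(predicted)
  bin <- ceiling(seq_along(ord) / (n / groups))
  bin[bin > groups] <- groups
  idx <- split(ord, bin)
  stats_of <- function(ii) c(n = length(ii), o = sum(observed[ii]),
                             e = sum(predicted[ii]), m = mean(predicted[ii]))
  tab <- do.call(rbind, lapply(idx, stats_of))
  # merge zero-expected bins upward
  while (nrow(tab) > 2 && any(tab[, "e"] == 0 | tab[, "e"] == tab[, "n"])) {
    i <- which(tab[, "e"] == 0 | tab[, "e"] == tab[, "n"])[1]
    j <- if (i == 1) 2 else i - 1
    message("Hosmer-Lemeshow: merging a degenerate bin with its neighbour")
    tab[j, c("n", "o", "e")] <- tab[j, c("n", "o", "e")] + tab[i, c("n", "o", "e")]
    tab[j, "m"] <- tab[j, "e"] / tab[j, "n"]
    tab <- tab[-i, , drop = FALSE]
  }
  chi2 <- sum((tab[, "o"] - tab[, "e"])^2 /
                (tab[, "e"] * (1 - tab[, "e"] / tab[, "n"])))
  df <- nrow(tab) - 2
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       bins = as.data.frame(tab))
}
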