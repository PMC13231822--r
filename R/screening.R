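# Univariate screening: Pearson chi-square on contingency tables, pooled /
# Welch t tests, tie-corrected Mann-Whitney U, and the observational
# sample-size formula.  All p-values are two-sided; no continuity
# correction anywhere (the published 2x2 statistics match the uncorrected
# formula).

#' Pearson chi-square test on an r x c contingency table
#'
#' Expected counts are `row_i * col_j / N`; the statistic is
#' `sum((O - E)^2 / E)` with no continuity correction and
#' `df = (r - 1)(c - 1)`.
#'
#' @param counts non-negative integer matrix with at least 2 rows and
#'   2 columns.
#' @param variable optional variable name carried into the result.
#' @return an object of class `of_contingency`: list with `variable`,
#'   `counts`, `expected`, `chi2`, `df`, `p`.
#' @examples
#' pearson_chi2(rbind(c(224, 61), c(164, 231)))$chi2  # 92.887
#' @export
pearson_chi2 <- function(counts, variable = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (nrow(counts) < 2 || ncol(counts) < 2) stop("need at least a 2 x 2 table")
  n <- sum(counts)
  if (n <= 0) stop("empty table")
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: a row or column total is zero")
  }
  expected <- outer(rs, cs) / n
  chi2 <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  structure(list(variable = variable, counts = counts, expected = expected,
                 chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "of_contingency")
}

#' Two-sample t test (pooled or Welch), raw or summary form
#'
#' @param x,y numeric vectors (ignored when summary statistics are given).
#' @param variant `"pooled"` (default, the convention behind the published
#'   table) or `"welch"`.
#' @param summary_x,summary_y optional `c(mean, sd, n)` summaries replacing
#'   the raw vectors.
#' @return list with `statistic`, `df`, `p`, `method`.
#' @export
two_sample_t <- function(x = NULL, y = NULL, variant = c("pooled", "welch"),
                         summary_x = NULL, summary_y = NULL) {
  variant <- match.arg(variant)
  stat_of <- function(s) list(m = s[1], sd = s[2], n = s[3])
  if (is.null(summary_x)) {
    if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 observations")
    summary_x <- c(mean(x), stats::sd(x), length(x))
    summary_y <- c(mean(y), stats::sd(y), length(y))
  }
  a <- stat_of(summary_x); b <- stat_of(summary_y)
  if (variant == "pooled") {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    if (sp2 <= 0) stop("zero pooled variance")
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    v <- a$sd^2 / a$n + b$sd^2 / b$n
    if (v <= 0) stop("zero variance")
    se <- sqrt(v)
    df <- v^2 / ((a$sd^2 / a$n)^2 / (a$n - 1) + (b$sd^2 / b$n)^2 / (b$n - 1))
  }
  t <- (a$m - b$m) / se
  list(statistic = t, df = df,
       p = 2 * stats::pt(-abs(t), df),
       method = paste0(variant, "-t"))
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' `U` is computed from midranks; the z statistic uses the tie-corrected
#' variance `n1 n2 / 12 * (N + 1 - sum(t^3 - t) / (N (N - 1)))` and a
#' two-sided normal p-value.
#'
#' @param x,y numeric vectors (non-empty).
#' @return list with `statistic` (z), `U`, `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) stop("undefined variance: all observations tied")
  z <- (U - n1 * n2 / 2) / sqrt(v)
  list(statistic = z, U = U, p = 2 * stats::pnorm(-abs(z)),
       method = "mann-whitney")
}

#' Univariate screening of candidate risk variables
#'
#' Categorical columns are tested against the binary outcome by Pearson
#' chi-square; numeric columns by pooled t test when Shapiro-Wilk accepts
#' normality in both outcome groups (alpha 0.05), otherwise Mann-Whitney.
#' Columns with fewer than two observed states are skipped with a warning.
#'
#' @param cohort data frame containing `outcome`.
#' @param outcome name of the binary outcome column.
#' @param alpha selection level (default 0.05).
#' @return data frame with one row per screened variable: `variable`,
#'   `test`, `statistic`, `df`, `p`, `selected`.
#' @export
screen <- function(cohort, outcome, alpha = 0.05) {
  if (!outcome %in% names(cohort)) stop(sprintf("unknown outcome column '%s'", outcome))
  yl <- sort(unique(cohort[[outcome]]))
  if (length(yl) != 2) stop("outcome must be binary")
  rows <- list()
  for (v in setdiff(names(cohort), outcome)) {
    col <- cohort[[v]]
    if (is.numeric(col)) {
      g1 <- col[cohort[[outcome]] == yl[1]]
      g2 <- col[cohort[[outcome]] == yl[2]]
      normal <- function(g) {
        # Shapiro-Wilk accepts 3..5000 observations; larger groups use a
        # deterministic evenly-spaced subsample
        if (length(g) > 5000) g <- g[round(seq(1, length(g), length.out = 5000))]
        stats::shapiro.test(g)$p.value >= 0.05
      }
      res <- if (normal(g1) && normal(g2)) {
        two_sample_t(g1, g2, "pooled")
      } else {
        mann_whitney(g1, g2)
      }
      rows[[v]] <- data.frame(variable = v, test = res$method,
                              statistic = res$statistic,
                              df = if (is.null(res$df)) NA_real_ else res$df,
                              p = res$p, stringsAsFactors = FALSE)
    } else {
      tab <- table(col, cohort[[outcome]])
      if (nrow(tab) < 2) {
        warning(sprintf("variable '%s' has a single observed state; skipped", v))
        next
      }
      res <- pearson_chi2(unclass(tab), variable = v)
      rows[[v]] <- data.frame(variable = v, test = "chi-square",
                              statistic = res$chi2, df = res$df, p = res$p,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$selected <- out$p < alpha
  out
}

#' Required sample size for estimating a prevalence
#'
#' `n0 = ceil(u^2 pi (1 - pi) / delta^2)` with `u` the two-sided normal
#' quantile at level `alpha`, inflated for anticipated non-response:
#' `n = ceil(n0 / (1 - dropout))`.
#'
#' @param pi expected prevalence in (0, 1).
#' @param alpha two-sided level (default 0.05).
#' @param delta absolute margin of error.
#' @param dropout anticipated non-response fraction in `[0, 1)`.
#' @return integer sample size.
#' @examples
#' required_sample_size(pi = 0.412, delta = 0.05, dropout = 0.20)  # 467
#' @export
required_sample_size <- function(pi, alpha = 0.05, delta, dropout = 0) {
  if (pi <= 0 || pi >= 1) stop("pi must be in (0, 1)")
  if (delta <= 0) stop("delta must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  u <- stats::qnorm(1 - alpha / 2)
  n0 <- ceiling(u^2 * pi * (1 - pi) / delta^2)
  as.integer(ceiling(n0 / (1 - dropout)))
}
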