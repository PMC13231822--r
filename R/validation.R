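# Node-level sensitivity analysis of the outcome and model validation:
# ROC curve with trapezoidal AUC, Youden operating point, decile
# calibration, and the Hosmer-Lemeshow link into a consolidated report.

#' Sensitivity of the target to a single node
#'
#' Two indices, both computed by exact inference and both zero when the
#' node is independent of the target:
#' * `max-swing`: `max over states s, s' of |P(target = t | node = s) -
#'   P(target = t | node = s')|` for the target's last state;
#' * `mutual-information`: `I(node; target)` in nats from the exact joint.
#'
#' Neither is the (undocumented) index printed by GeNIe; the max-swing
#' index shares its 0-1 scale.
#'
#' @param spec a `bn_spec`.
#' @param target target variable.
#' @param node probed variable (distinct from `target`).
#' @param method `"max-swing"` (default) or `"mutual-information"`.
#' @return list with `node`, `index`, `method`.
#' @export
sensitivity_index <- function(spec, target, node,
                              method = c("max-swing", "mutual-information")) {
  method <- match.arg(method)
  if (node == target) stop("node must differ from target")
  node_states <- spec$variables[[node]]$states
  if (method == "max-swing") {
    tgt_states <- spec$variables[[target]]$states
    last <- tgt_states[length(tgt_states)]
    p <- vapply(node_states, function(s) {
      unname(eliminate(spec, target, stats::setNames(list(s), node))[last])
    }, numeric(1))
    idx <- max(p) - min(p)
  } else {
    # joint via elimination: P(node) * P(target | node)
    p_node <- eliminate(spec, node)
    mi <- 0
    p_t <- eliminate(spec, target)
    for (s in node_states) {
      cond <- eliminate(spec, target, stats::setNames(list(s), node))
      for (t in names(cond)) {
        pj <- p_node[[s]] * cond[[t]]
        if (pj > 0) mi <- mi + pj * log(pj / (p_node[[s]] * p_t[[t]]))
      }
    }
    idx <- max(mi, 0)
  }
  list(node = node, index = idx, method = method)
}

#' ROC curve, AUC, Youden operating point and calibration bins
#'
#' Thresholds sweep the unique predicted values; the AUC is the
#' trapezoidal area, which equals the tie-corrected rank statistic
#' `U / (n+ n-)`.  The Youden threshold maximizes TPR - FPR (ties: the
#' lower threshold).  Calibration bins are prediction deciles
#' (equal-count).
#'
#' @param predicted numeric risk scores.
#' @param observed binary 0/1 outcome.
#' @param bins number of calibration bins (default 10).
#' @return object of class `of_roc`: list with `roc_points` (data frame
#'   fpr, tpr, threshold), `auc`, `youden_threshold`, `sensitivity`,
#'   `specificity`, `calibration` (data frame mean_predicted,
#'   observed_frequency, n).
#' @export
roc_curve <- function(predicted, observed, bins = 10) {
  observed <- as.numeric(observed)
  n_pos <- sum(observed == 1)
  n_neg <- sum(observed == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: need at least one positive and one negative")
  }
  thr <- sort(unique(predicted), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    pred_pos <- predicted >= t
    c(fpr = sum(pred_pos & observed == 0) / n_neg,
      tpr = sum(pred_pos & observed == 1) / n_pos)
  }, numeric(2)))
  roc <- data.frame(fpr = c(0, pts[, "fpr"], 1),
                    tpr = c(0, pts[, "tpr"], 1),
                    threshold = c(Inf, thr, -Inf))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  youden <- roc$tpr - roc$fpr
  best <- which(youden == max(youden))
  best <- best[length(best)]  # lowest threshold among ties
  if (!is.finite(roc$threshold[best])) best <- which.max(youden)
  # decile calibration
  ord <- order(predicted)
  n <- length(predicted)
  bin <- ceiling(seq_len(n) / (n / bins))
  bin[bin > bins] <- bins
  calib <- do.call(rbind, lapply(split(ord, bin), function(ii) {
    data.frame(mean_predicted = mean(predicted[ii]),
               observed_frequency = mean(observed[ii]),
               n = length(ii))
  }))
  rownames(calib) <- NULL
  structure(list(roc_points = roc, auc = auc,
                 youden_threshold = roc$threshold[best],
                 sensitivity = roc$tpr[best],
                 specificity = 1 - roc$fpr[best],
                 calibration = calib),
            class = "of_roc")
}

#' @export
print.of_roc <- function(x, ...) {
  cat(sprintf("AUC %.3f | Youden threshold %.4f: sensitivity %.3f, specificity %.3f\n",
              x$auc, x$youden_threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Validate a network against a scored cohort
#'
#' Chains [predict_proba()] -> [roc_curve()] -> [hosmer_lemeshow()] into
#' one consolidated report of apparent (training-set) performance.
#'
#' @param spec a `bn_spec`.
#' @param cohort data frame containing the target column.
#' @param target target variable name.
#' @param positive_state state counted as an event (default the target's
#'   last state).
#' @param groups Hosmer-Lemeshow bins (default 10).
#' @return list with `predicted`, `roc` (an `of_roc`), `hl`.
#' @export
validate_model <- function(spec, cohort, target, positive_state = NULL,
                           groups = 10) {
  if (!target %in% names(cohort)) stop(sprintf("cohort lacks target '%s'", target))
  st <- spec$variables[[target]]$states
  if (is.null(positive_state)) positive_state <- st[length(st)]
  pred <- predict_proba(spec, cohort, target, state = positive_state)
  obs <- as.numeric(cohort[[target]] == positive_state)
  roc <- roc_curve(pred, obs)
  hl <- hosmer_lemeshow(pmin(pmax(pred, 1e-12), 1 - 1e-12), obs, groups = groups)
  list(predicted = pred, roc = roc, hl = hl)
}

#' Sensitivity table for every non-target node
#'
#' @param spec a `bn_spec`.
#' @param target target variable.
#' @param method forwarded to [sensitivity_index()].
#' @return data frame sorted by decreasing index.
#' @export
sensitivity_table <- function(spec, target, method = "max-swing") {
  nodes <- setdiff(names(spec$variables), target)
  out <- do.call(rbind, lapply(nodes, function(nd) {
    r <- sensitivity_index(spec, target, nd, method)
    data.frame(node = nd, index = r$index, method = r$method,
               stringsAsFactors = FALSE)
  }))
  out[order(-out$index), , drop = FALSE]
}
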