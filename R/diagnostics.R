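# DeLong placement values: for each event, the fraction of nonevents it
# outranks (ties count 1/2), and vice versa.
.placements <- function(scores, y) {
  xe <- scores[y]; xn <- scores[!y]
  v10 <- vapply(xe, function(x) mean((x > xn) + 0.5 * (x == xn)), numeric(1))
  v01 <- vapply(xn, function(x) mean((xe > x) + 0.5 * (xe == x)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC area under the curve with DeLong confidence interval
#'
#' Tie-corrected Mann-Whitney AUC (ties count one half) with the DeLong
#' variance estimate for the confidence interval.
#'
#' @param scores Numeric predictor (higher = more disease-like).
#' @param labels Binary event indicator.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble of class `cad_roc`: `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`; the ROC curve is attached as attribute `"curve"`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  y <- .as_binary(labels)
  stopifnot(length(scores) == length(y))
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  pl <- .placements(scores, y)
  m <- sum(y); n <- sum(!y)
  v <- stats::var(pl$v10) / m + stats::var(pl$v01) / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(max(v, 0))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[y] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[!y] >= t), numeric(1))
  )
  out <- tibble::tibble(
    auc = pl$auc,
    ci_low = max(0, pl$auc - half), ci_high = min(1, pl$auc + half),
    n_pos = m, n_neg = n
  )
  attr(out, "curve") <- curve
  class(out) <- c("cad_roc", class(out))
  out
}

#' Plot a ROC curve
#' @param object A `cad_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cad_roc <- function(object, ...) {
  curve <- attr(object, "curve")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step(color = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC, AUC = %.1f%% (CI %.0f-%.0f%%)",
                                  100 * object$auc, 100 * object$ci_low,
                                  100 * object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Paired DeLong test for two correlated AUCs
#'
#' Two-sided test that two predictors measured on the same subjects have
#' equal AUC, using the DeLong covariance of placement values.
#'
#' @param scores_a,scores_b Numeric predictors on the same subjects.
#' @param labels Binary event indicator.
#' @return One-row tibble: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels) {
  y <- .as_binary(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(y))
    stop("scores_a, scores_b, labels must have equal length", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  pa <- .placements(scores_a, y)
  pb <- .placements(scores_b, y)
  m <- sum(y); n <- sum(!y)
  v <- stats::var(pa$v10 - pb$v10) / m + stats::var(pa$v01 - pb$v01) / n
  d <- pa$auc - pb$auc
  z <- if (v <= 1e-18) {
    if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else d / sqrt(v)
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

#' Optimal cut-point by the sensitivity x specificity criterion
#'
#' The Liu optimal threshold: the candidate maximizing the product of
#' sensitivity and specificity, where "test positive" means score strictly
#' greater than the threshold. Candidates are midpoints between consecutive
#' sorted scores; ties are broken toward the lower threshold.
#'
#' @param scores Numeric predictor.
#' @param labels Binary event indicator.
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `product`.
#' @export
liu_cutpoint <- function(scores, labels) {
  y <- .as_binary(labels)
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  s <- sort(scores)
  cand <- unique((s[-1] + s[-length(s)]) / 2)
  prod <- vapply(cand, function(th) {
    mean(scores[y] > th) * mean(scores[!y] <= th)
  }, numeric(1))
  best <- which(prod >= max(prod) - 1e-12)[1]
  th <- cand[best]
  tibble::tibble(threshold = th,
                 sensitivity = mean(scores[y] > th),
                 specificity = mean(scores[!y] <= th),
                 product = prod[best])
}

#' Binary diagnostic accuracy metrics
#'
#' Sensitivity, specificity, predictive values, and likelihood ratios from a
#' 2x2 confusion table, computed as exact rationals before any rounding.
#' Metrics whose margin is empty are returned `NA` with a warning.
#'
#' @param tp,fp,tn,fn Confusion-table counts (non-negative).
#' @return One-row tibble: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `plr`, `nlr`, and the four counts.
#' @export
binary_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0 || tn + fp == 0)
    stop("need at least one subject in each disease class", call. = FALSE)
  safe <- function(num, den, name) {
    if (den == 0) {
      warning(name, " undefined: empty margin", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    ppv = safe(tp, tp + fp, "ppv"), npv = safe(tn, tn + fn, "npv"),
    plr = if (spec == 1) Inf else sens / (1 - spec),
    nlr = if (spec == 0) Inf else (1 - sens) / spec,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

.nri_from_moves <- function(up_e, down_e, n_e, up_ne, down_ne, n_ne,
                            conf_level) {
  ev <- (up_e - down_e) / n_e
  ne <- (down_ne - up_ne) / n_ne
  nri <- ev + ne
  se <- sqrt((up_e + down_e) / n_e^2 - (up_e - down_e)^2 / n_e^3 +
               (up_ne + down_ne) / n_ne^2 - (down_ne - up_ne)^2 / n_ne^3)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    nri = nri, event_component = ev, nonevent_component = ne,
    up_events = up_e, down_events = down_e,
    up_nonevents = up_ne, down_nonevents = down_ne,
    n_events = n_e, n_nonevents = n_ne,
    ci_low = nri - z * se, ci_high = nri + z * se
  )
}

#' Categorical net reclassification index
#'
#' Net proportion of subjects moved to a more appropriate risk category by a
#' new model relative to an old one, over a shared ordinal category scale:
#' upward moves count in favour for events, downward moves in favour for
#' nonevents. The confidence interval uses the asymptotic normal variance of
#' the two components.
#'
#' @param old_categories,new_categories Ordinal risk categories (factors on
#'   the same level set, or integer codes).
#' @param events Binary event indicator.
#' @param conf_level Confidence level.
#' @return One-row tibble: `nri`, the event/nonevent components, the four
#'   move counts, group sizes, and `ci_low`/`ci_high`.
#' @export
categorical_nri <- function(old_categories, new_categories, events,
                            conf_level = 0.95) {
  y <- .as_binary(events)
  if (is.factor(old_categories) || is.factor(new_categories)) {
    if (!is.factor(old_categories) || !is.factor(new_categories) ||
        !identical(levels(old_categories), levels(new_categories)))
      stop("old and new categories must share the same level scale",
           call. = FALSE)
    old_categories <- as.integer(old_categories)
    new_categories <- as.integer(new_categories)
  }
  stopifnot(length(old_categories) == length(new_categories),
            length(old_categories) == length(y))
  up <- new_categories > old_categories
  down <- new_categories < old_categories
  .nri_from_moves(sum(up & y), sum(down & y), sum(y),
                  sum(up & !y), sum(down & !y), sum(!y), conf_level)
}

#' Continuous (category-free) net reclassification index
#'
#' Any increase in predicted probability counts as an upward move, any
#' decrease as downward; the component formulas are as in
#' [categorical_nri()].
#'
#' @param p_old,p_new Predicted probabilities in \[0, 1\] on the same
#'   subjects.
#' @param events Binary event indicator.
#' @param conf_level Confidence level.
#' @return One-row tibble as in [categorical_nri()].
#' @export
continuous_nri <- function(p_old, p_new, events, conf_level = 0.95) {
  y <- .as_binary(events)
  if (length(p_old) != length(p_new) || length(p_old) != length(y))
    stop("p_old, p_new, events must have equal length", call. = FALSE)
  up <- p_new > p_old
  down <- p_new < p_old
  .nri_from_moves(sum(up & y), sum(down & y), sum(y),
                  sum(up & !y), sum(down & !y), sum(!y), conf_level)
}

#' Integrated discrimination improvement
#'
#' Difference in mean predicted-probability separation between events and
#' nonevents for the new versus the old model:
#' `(mean dp | events) - (mean dp | nonevents)` with `dp = p_new - p_old`.
#' Asymptotic confidence interval.
#'
#' @inheritParams continuous_nri
#' @return One-row tibble: `idi`, `ci_low`, `ci_high`.
#' @export
idi <- function(p_old, p_new, events, conf_level = 0.95) {
  y <- .as_binary(events)
  if (length(p_old) != length(p_new) || length(p_old) != length(y))
    stop("p_old, p_new, events must have equal length", call. = FALSE)
  d <- p_new - p_old
  est <- mean(d[y]) - mean(d[!y])
  se <- sqrt(stats::var(d[y]) / sum(y) + stats::var(d[!y]) / sum(!y))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(idi = est, ci_low = est - z * se, ci_high = est + z * se)
}
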