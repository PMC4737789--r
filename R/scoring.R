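#' Train the linear discriminant acoustic score
#'
#' Fits a Fisher linear discriminant (pooled within-class covariance) of the
#' binary obstructive-disease label on the four acoustic measures, and a
#' reduced discriminant on AMI + S4Amp alone for recordings with short
#' diastasis (where the spectral measures are unavailable). Each branch
#' carries an affine calibration mapping its raw discriminant value to the
#' 0-100 point scale such that the training scores have mean 25 and SD 12
#' before clipping — the orientation and spread of the deployed score scale.
#'
#' @param features Tibble with columns `fpr`, `pcaspec`, `ami`, `s4amp`
#'   (NA allowed where `short_diastasis` is `TRUE`).
#' @param labels Binary vector (logical, 0/1, or two-level factor); `TRUE`/1
#'   marks obstructive disease.
#' @param calibration Length-2 numeric `c(mean, sd)` of the calibrated
#'   training scores.
#' @param min_full,min_reduced Minimum per-class training sizes for the full
#'   and reduced branches.
#' @param ridge Ridge added to a singular pooled covariance (with a warning).
#' @return A `cad_discriminant` object.
#' @export
train_discriminant <- function(features, labels, calibration = c(25, 12),
                               min_full = 20, min_reduced = 10,
                               ridge = 1e-6) {
  y <- .as_binary(labels)
  stopifnot(nrow(features) == length(y))
  full_vars <- c("fpr", "pcaspec", "ami", "s4amp")
  red_vars <- c("ami", "s4amp")

  fit_branch <- function(vars, min_n) {
    X <- as.matrix(features[, vars])
    ok <- stats::complete.cases(X)
    X <- X[ok, , drop = FALSE]; yb <- y[ok]
    if (min(table(yb)) < min_n)
      stop("need at least ", min_n, " subjects per class with features ",
           paste(vars, collapse = ", "), call. = FALSE)
    mu0 <- colMeans(X[!yb, , drop = FALSE])
    mu1 <- colMeans(X[yb, , drop = FALSE])
    S0 <- stats::cov(X[!yb, , drop = FALSE])
    S1 <- stats::cov(X[yb, , drop = FALSE])
    n0 <- sum(!yb); n1 <- sum(yb)
    Sp <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
    w <- tryCatch(solve(Sp, mu1 - mu0), error = function(e) {
      warning("singular pooled covariance: ridge-regularized fit",
              call. = FALSE)
      solve(Sp + diag(ridge, ncol(Sp)), mu1 - mu0)
    })
    intercept <- -sum(w * (mu0 + mu1) / 2)
    raw <- drop(X %*% w) + intercept
    sd_raw <- stats::sd(raw)
    slope <- if (sd_raw > 1e-12) calibration[2] / sd_raw else 1
    offset <- calibration[1] - slope * mean(raw)
    list(weights = stats::setNames(as.numeric(w), vars),
         intercept = intercept,
         calibration = c(slope = slope, offset = offset),
         n = c(healthy = n0, diseased = n1))
  }

  full <- fit_branch(full_vars, min_full)
  reduced <- fit_branch(red_vars, min_reduced)
  structure(
    list(weights_full = full$weights, intercept_full = full$intercept,
         calibration_full = full$calibration,
         weights_reduced = reduced$weights,
         intercept_reduced = reduced$intercept,
         calibration_reduced = reduced$calibration,
         n_train = full$n, feature_order = full_vars),
    class = "cad_discriminant"
  )
}

.as_binary <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) return(labels == levels(labels)[2])
  if (is.numeric(labels)) return(labels != 0)
  stop("labels must be logical, 0/1, or a two-level factor", call. = FALSE)
}

#' @export
print.cad_discriminant <- function(x, ...) {
  cat("<cad_discriminant>\n  full:   ",
      paste(sprintf("%s=%.3g", names(x$weights_full), x$weights_full),
            collapse = ", "),
      sprintf("(intercept %.3g)\n", x$intercept_full),
      " reduced:",
      paste(sprintf("%s=%.3g", names(x$weights_reduced), x$weights_reduced),
            collapse = ", "),
      sprintf("(intercept %.3g)\n", x$intercept_reduced))
  invisible(x)
}

#' @export
tidy.cad_discriminant <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(model = "full", term = names(x$weights_full),
                   estimate = as.numeric(x$weights_full)),
    tibble::tibble(model = "full", term = "(intercept)",
                   estimate = x$intercept_full),
    tibble::tibble(model = "reduced", term = names(x$weights_reduced),
                   estimate = as.numeric(x$weights_reduced)),
    tibble::tibble(model = "reduced", term = "(intercept)",
                   estimate = x$intercept_reduced)
  )
}

#' @export
glance.cad_discriminant <- function(x, ...) {
  tibble::tibble(n_healthy = x$n_train[["healthy"]],
                 n_diseased = x$n_train[["diseased"]],
                 slope_full = x$calibration_full[["slope"]],
                 slope_reduced = x$calibration_reduced[["slope"]])
}

#' Assign the score category
#'
#' Three deployment categories of the acoustic score: low (<= 20 points),
#' intermediate (20, 30\], high (> 30). Boundaries belong to the lower
#' category, consistent with the negative-predictive-value usage of
#' "score <= 20".
#'
#' @param value Numeric score(s) in \[0, 100\].
#' @return Ordered factor with levels `low < intermediate < high`.
#' @export
score_category <- function(value) {
  cut(value, breaks = c(-Inf, 20, 30, Inf),
      labels = c("low", "intermediate", "high"),
      right = TRUE, ordered_result = TRUE)
}

#' Compute acoustic scores from feature vectors
#'
#' Applies the trained discriminant to each feature row: the full
#' four-feature branch normally, the reduced AMI + S4Amp branch when
#' `short_diastasis` is `TRUE` (or the spectral features are missing). The
#' calibrated value is clipped to \[0, 100\] and categorized.
#'
#' @param features Tibble with the feature columns (and optionally
#'   `short_diastasis`).
#' @param model A `cad_discriminant` from [train_discriminant()].
#' @return Tibble with `value` (points), `category` (ordered factor), and
#'   `short_diastasis_used`.
#' @export
cad_score <- function(features, model) {
  short <- if ("short_diastasis" %in% names(features)) {
    features$short_diastasis
  } else rep(FALSE, nrow(features))
  short <- short | !stats::complete.cases(
    features[, names(model$weights_full), drop = FALSE])
  value <- numeric(nrow(features))
  for (i in seq_len(nrow(features))) {
    if (short[i]) {
      vars <- names(model$weights_reduced)
      x <- as.numeric(features[i, vars])
      if (anyNA(x))
        stop("missing feature(s) ",
             paste(vars[is.na(x)], collapse = ", "),
             " required by the reduced model", call. = FALSE)
      raw <- sum(model$weights_reduced * x) + model$intercept_reduced
      cal <- model$calibration_reduced
    } else {
      x <- as.numeric(features[i, names(model$weights_full)])
      raw <- sum(model$weights_full * x) + model$intercept_full
      cal <- model$calibration_full
    }
    value[i] <- min(max(cal[["slope"]] * raw + cal[["offset"]], 0), 100)
  }
  tibble::tibble(value = value, category = score_category(value),
                 short_diastasis_used = short)
}

#' Repeated stratified cross-validation of the discriminant
#'
#' Validates the discriminant with the repeated ten-fold scheme used for the
#' deployed algorithm: per repeat, subjects are assigned to stratified folds
#' (each class spread evenly), the model is trained on nine folds and scores
#' the held-out fold, held-out scores are pooled within the repeat, and one
#' AUC is computed per repeat.
#'
#' @inheritParams train_discriminant
#' @param repeats,folds Cross-validation scheme (default 20 x 10-fold).
#' @param seed RNG seed for the fold assignments.
#' @return A `cad_cv` object; see [tidy.cad_cv()] and [glance.cad_cv()].
#' @export
cross_validate <- function(features, labels, repeats = 20, folds = 10,
                           seed = 1) {
  y <- .as_binary(labels)
  n <- length(y)
  if (n < folds) stop("need at least as many subjects as folds", call. = FALSE)
  if (min(table(y)) < folds)
    stop("cannot stratify: a class has fewer subjects than folds",
         call. = FALSE)
  aucs <- .with_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      fold <- integer(n)
      for (cl in c(TRUE, FALSE)) {
        idx <- which(y == cl)
        fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
      }
      pred <- numeric(n)
      for (f in seq_len(folds)) {
        tr <- fold != f
        m <- train_discriminant(features[tr, ], y[tr],
                                min_full = 2, min_reduced = 2)
        pred[!tr] <- cad_score(features[!tr, ], m)$value
      }
      roc_auc(pred, y)$auc
    }, numeric(1))
  })
  structure(list(mean_auc = mean(aucs), aucs = aucs,
                 repeats = repeats, folds = folds, seed = seed),
            class = "cad_cv")
}

#' @export
print.cad_cv <- function(x, ...) {
  cat(sprintf("<cad_cv> %d x %d-fold: mean AUC %.3f (range %.3f-%.3f)\n",
              x$repeats, x$folds, x$mean_auc, min(x$aucs), max(x$aucs)))
  invisible(x)
}

#' Per-repeat cross-validation AUCs
#' @param x A `cad_cv` object.
#' @param ... Unused.
#' @return Tibble with `repeat_id` and `auc`.
#' @export
tidy.cad_cv <- function(x, ...) {
  tibble::tibble(repeat_id = seq_along(x$aucs), auc = x$aucs)
}

#' Cross-validation summary
#' @param x A `cad_cv` object.
#' @param ... Unused.
#' @return One-row tibble with `mean_auc`, `sd_auc`, `repeats`, `folds`.
#' @export
glance.cad_cv <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc, sd_auc = stats::sd(x$aucs),
                 repeats = x$repeats, folds = x$folds)
}

#' Save / load a discriminant model as JSON
#'
#' @param model A `cad_discriminant`.
#' @param path File path.
#' @return `path` invisibly (`save_model`); a `cad_discriminant`
#'   (`load_model`).
#' @export
save_model <- function(model, path) {
  ser <- unclass(model)
  for (fld in c("weights_full", "weights_reduced", "calibration_full",
                "calibration_reduced", "n_train"))
    ser[[fld]] <- as.list(ser[[fld]])  # keep names in the JSON object
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$weights_full <- unlist(m$weights_full)
  m$weights_reduced <- unlist(m$weights_reduced)
  m$calibration_full <- unlist(m$calibration_full)
  m$calibration_reduced <- unlist(m$calibration_reduced)
  m$n_train <- unlist(m$n_train)
  structure(m, class = "cad_discriminant")
}

.cadsound_env <- new.env(parent = emptyenv())

#' Packaged default discriminant
#'
#' A deterministic out-of-the-box model trained on a fixed feature-level
#' reference cohort (165 healthy / 63 diseased, internal seed), so that
#' single-recording scoring works without a user-supplied training cohort.
#' For any real application the discriminant should be retrained on the
#' target population.
#'
#' @return A `cad_discriminant`.
#' @export
default_discriminant <- function() {
  if (is.null(.cadsound_env$default_model)) {
    cohort <- simulate_feature_cohort(165, 63, delta = 0.4, seed = 20150903)
    .cadsound_env$default_model <- train_discriminant(
      cohort, cohort$event)
  }
  .cadsound_env$default_model
}
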