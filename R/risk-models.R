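#' Default pre-test probability coefficient table
#'
#' Logistic coefficients for the clinical pre-test probability of obstructive
#' coronary disease from age, sex, and chest-pain type, in the tradition of
#' the updated Diamond-Forrester models (logit linear in age, with additive
#' male-sex and symptom-type terms; non-anginal pain is the reference).
#' The shipped values are a documented package default of that functional
#' form; analyses that depend on an exactly published table should pass
#' their own via the `coeffs` argument of [diamond_forrester()].
#'
#' @return List: `intercept`, `age` (per year), `male`, and named vector
#'   `chest_pain` (`non_anginal`, `atypical`, `typical`).
#' @export
df_coefficients <- function() {
  list(
    intercept = -6.917,
    age = 0.0635,
    male = 1.332,
    chest_pain = c(non_anginal = 0, atypical = 0.633, typical = 1.998)
  )
}

#' Clinical pre-test probability of obstructive disease
#'
#' Logistic pre-test model on age, sex, and chest-pain type. Vectorized.
#'
#' @param age Age in years (18-110).
#' @param sex `"male"` or `"female"`.
#' @param chest_pain `"typical"`, `"atypical"`, or `"non_anginal"`.
#' @param coeffs Coefficient table, see [df_coefficients()].
#' @return Pre-test probability in percent (0-100).
#' @export
diamond_forrester <- function(age, sex, chest_pain,
                              coeffs = df_coefficients()) {
  stopifnot(all(age >= 18 & age <= 110))
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  bad <- setdiff(unique(chest_pain), names(coeffs$chest_pain))
  if (length(bad) > 0)
    stop("unknown chest_pain level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  lin <- coeffs$intercept + coeffs$age * age +
    coeffs$male * (sex == "male") + coeffs$chest_pain[chest_pain]
  as.numeric(100 * stats::plogis(lin))
}

#' Four-level risk category
#'
#' Pre-defined probability categories: very low (< 10 %), low (10-30 %),
#' moderate (30-60 %), high (>= 60 %); each boundary belongs to the upper
#' category (right-continuous at 10/30/60).
#'
#' @param p Probability in percent (0-100).
#' @return Ordered factor `very_low < low < moderate < high`.
#' @export
risk_category <- function(p) {
  stopifnot(all(p >= 0 & p <= 100, na.rm = TRUE))
  cut(p, breaks = c(-Inf, 10, 30, 60, Inf),
      labels = c("very_low", "low", "moderate", "high"),
      right = FALSE, ordered_result = TRUE)
}

#' Coronary calcium score grouping
#'
#' Standard Agatston-score strata: `zero` (= 0), `low` (> 0 and < 400),
#' `high` (>= 400).
#'
#' @param cacs Agatston units (>= 0).
#' @return Ordered factor `zero < low < high`.
#' @export
cacs_group <- function(cacs) {
  if (any(cacs < 0, na.rm = TRUE))
    stop("cacs must be non-negative", call. = FALSE)
  factor(ifelse(cacs == 0, "zero", ifelse(cacs < 400, "low", "high")),
         levels = c("zero", "low", "high"), ordered = TRUE)
}

# Ridge-regularized logistic IRLS, used only when glm reports separation.
.ridge_logit <- function(X, y, lambda = 1e-3, maxit = 100) {
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p) + 1e-10
    z <- eta + (y - p) / W
    A <- crossprod(X, X * W) + diag(lambda, ncol(X))
    beta_new <- solve(A, crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < 1e-10) break
    beta <- drop(beta_new)
  }
  beta
}

#' Combine the pre-test probability and the acoustic score
#'
#' Logistic regression of the obstructive-disease label on the logit of the
#' pre-test probability and the raw acoustic score — the simplest fusion
#' consistent with reporting a combined AUC and reclassification statistics.
#' Under complete separation a lightly ridge-penalized fit is used with a
#' warning.
#'
#' @param data Data frame with columns `df_probability` (%) and `cad_score`
#'   (points).
#' @param labels Binary obstructive-disease indicator.
#' @param cad_weight Optional fixed coefficient for `cad_score` (e.g. `0`
#'   to constrain the score out of the model); `NULL` (default) estimates it.
#' @return A `cad_combined` object: coefficients, fitted per-patient
#'   `combined_probability` (%), and the training data reference.
#' @export
combine_df_cad <- function(data, labels, cad_weight = NULL) {
  y <- .as_binary(labels)
  stopifnot(all(c("df_probability", "cad_score") %in% names(data)),
            nrow(data) == length(y))
  ldf <- stats::qlogis(pmin(pmax(data$df_probability / 100, 1e-4), 1 - 1e-4))
  offs <- if (is.null(cad_weight)) NULL else cad_weight * data$cad_score
  fit_df <- data.frame(y = y, ldf = ldf, score = data$cad_score)
  sep <- FALSE
  fit <- withCallingHandlers(
    if (is.null(cad_weight)) {
      stats::glm(y ~ ldf + score, family = stats::binomial(), data = fit_df)
    } else {
      stats::glm(y ~ ldf, family = stats::binomial(), data = fit_df,
                 offset = offs)
    },
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!sep) {
    cf_chk <- stats::coef(fit)
    # diverged fits: dropped terms or fitted log-odds pinned at +/- infinity
    if (anyNA(cf_chk) || max(abs(stats::predict(fit))) > 20) sep <- TRUE
  }
  if (sep) {
    warning("separation detected: ridge-penalized logistic fit used",
            call. = FALSE)
    X <- cbind(1, ldf, if (is.null(cad_weight)) fit_df$score)
    b <- .ridge_logit(X, y)
    coefs <- c("(Intercept)" = b[1], ldf = b[2],
               score = if (is.null(cad_weight)) b[3] else cad_weight)
    eta <- drop(X %*% b) + if (is.null(cad_weight)) 0 else offs
  } else {
    cf <- stats::coef(fit)
    coefs <- c(cf, score = if (is.null(cad_weight)) unname(cf["score"])
               else cad_weight)
    coefs <- coefs[!duplicated(names(coefs))]
    eta <- stats::predict(fit)
  }
  structure(
    list(coefficients = coefs, cad_weight_fixed = cad_weight,
         combined_probability = as.numeric(100 * stats::plogis(eta)),
         n = length(y)),
    class = "cad_combined"
  )
}

#' @export
print.cad_combined <- function(x, ...) {
  cat("<cad_combined> logistic fusion of pre-test probability and acoustic score\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
tidy.cad_combined <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients))
}

#' @export
glance.cad_combined <- function(x, ...) {
  tibble::tibble(n = x$n,
                 score_coefficient = unname(x$coefficients["score"]))
}

#' Predict combined probabilities for new patients
#'
#' @param object A `cad_combined` model.
#' @param newdata Data frame with `df_probability` and `cad_score`.
#' @param ... Unused.
#' @return Combined probability in percent.
#' @export
predict.cad_combined <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$combined_probability)
  ldf <- stats::qlogis(pmin(pmax(newdata$df_probability / 100, 1e-4),
                            1 - 1e-4))
  b <- object$coefficients
  eta <- b[["(Intercept)"]] + b[["ldf"]] * ldf +
    b[["score"]] * newdata$cad_score
  as.numeric(100 * stats::plogis(eta))
}
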