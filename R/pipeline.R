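#' Packaged reference reclassification counts
#'
#' The reference validation cohort's reclassification cross-tabulation
#' (n = 228: 63 obstructive, 165 non- or non-obstructive disease) between
#' the four-level risk categories of the clinical pre-test model alone and
#' of the combined pre-test + acoustic-score model. Shipped as a plain-text
#' fixture so the reclassification arithmetic can be reproduced without any
#' external data.
#'
#' @return Tibble: `disease`, `old_category`, `new_category`, `n`.
#' @export
table3_counts <- function() {
  path <- system.file("extdata", "reference_reclassification.csv",
                      package = "cadsound", mustWork = TRUE)
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  lv <- c("very_low", "low", "moderate", "high")
  out$old_category <- factor(out$old_category, levels = lv, ordered = TRUE)
  out$new_category <- factor(out$new_category, levels = lv, ordered = TRUE)
  out
}

#' Packaged reference acoustic-score category counts
#'
#' Counts of reference-cohort patients per acoustic-score category
#' (low <= 20, intermediate 20-30, high > 30) and disease group.
#'
#' @return Tibble: `group`, `category`, `n`.
#' @export
score_category_counts <- function() {
  path <- system.file("extdata", "reference_score_categories.csv",
                      package = "cadsound", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

.expand_reclassification <- function(counts = table3_counts()) {
  idx <- rep(seq_len(nrow(counts)), counts$n)
  ex <- counts[idx, ]
  tibble::tibble(old = ex$old_category, new = ex$new_category,
                 event = ex$disease == "obstructive")
}

#' Reproduce the reference reclassification arithmetic
#'
#' Recomputes, from the packaged reference counts, every quantity of the
#' published reclassification analysis: the categorical net reclassification
#' index and its components, the upward/downward move counts, the negative
#' predictive value of a low acoustic score and positive predictive value of
#' a high one, and the very-low-category totals of the combined model. Each
#' computed value is compared against the published reference value.
#'
#' The reference table prints its nonevent net move as "55 - 36 = 20 (12 %)",
#' which is internally inconsistent: 55 - 36 = 19 and 19/165 = 11.5 %. The
#' computed (formula) values are reported and the discrepancy is flagged in
#' the `note` column rather than silently matched.
#'
#' @return Tibble: `quantity`, `computed`, `reference`, `matches`, `note`.
#' @export
reproduce_table3 <- function() {
  ex <- .expand_reclassification()
  nri <- categorical_nri(ex$old, ex$new, ex$event)
  sc <- score_category_counts()
  n_of <- function(g, cat) sc$n[sc$group == g & sc$category == cat]
  # healthy = non-CAD + non-obstructive; test negative = score <= 20
  tn <- n_of("non_cad", "low") + n_of("non_obstructive", "low")
  fn <- n_of("obstructive", "low")
  tp <- n_of("obstructive", "high")
  fp <- n_of("non_cad", "high") + n_of("non_obstructive", "high")
  very_low_total <- sum(ex$new == "very_low")
  very_low_events <- sum(ex$new == "very_low" & ex$event)

  row <- function(quantity, computed, reference, note = "") {
    tibble::tibble(quantity = quantity, computed = computed,
                   reference = reference,
                   matches = abs(computed - reference) < 5e-3 + 1e-12,
                   note = note)
  }
  dplyr::bind_rows(
    row("categorical_nri", round(nri$nri, 2), 0.31),
    row("up_events", nri$up_events, 18),
    row("down_events", nri$down_events, 6),
    row("event_component_pct", round(100 * nri$event_component), 19),
    row("up_nonevents", nri$up_nonevents, 36),
    row("down_nonevents", nri$down_nonevents, 55),
    row("net_nonevent_moves", nri$down_nonevents - nri$up_nonevents, 20,
        "reference prints 55 - 36 = 20; the arithmetic gives 19"),
    row("nonevent_component_pct", round(100 * nri$nonevent_component, 1), 12,
        "reference prints 12 %; 19/165 = 11.5 %"),
    row("npv_low_score", tn / (tn + fn), 0.925),
    row("ppv_high_score", round(tp / (tp + fp), 3), 0.435),
    row("very_low_total", very_low_total, 70),
    row("very_low_prevalence_pct", round(100 * very_low_events / very_low_total),
        3)
  )
}

#' Score a single recording end to end
#'
#' Full single-recording pipeline: read the WAV, band-limit, detect cycles,
#' gate on recording quality, extract features, and score with the supplied
#' (or packaged default) discriminant. When quality gating fails, no score
#' is produced and the quality status is reported instead.
#'
#' @param wav Path to a WAV file, or a [pcg_recording].
#' @param model A `cad_discriminant`; default [default_discriminant()].
#' @param pca Optional `pca_spec_model` for the spectral projection.
#' @param metadata Optional sidecar path for [read_recording()].
#' @param out Optional path: result written as JSON.
#' @param config Overrides merged over segmentation/feature defaults.
#' @return List with `status` (`ok` or the exclusion label), `quality`
#'   (tibble), and `score` (tibble from [cad_score()], or `NULL` when
#'   excluded).
#' @export
run_score <- function(wav, model = NULL, pca = NULL, metadata = NULL,
                      out = NULL, config = list()) {
  rec <- if (inherits(wav, "pcg_recording")) wav else {
    read_recording(wav, metadata)
  }
  rec8 <- resample_recording(rec, 8000)
  recf <- bandlimit(rec8, 20, 1000)
  cycles <- detect_cycles(recf, config)
  quality <- assess_quality(recf, cycles, config)
  result <- if (quality$status != "ok") {
    list(status = quality$status, quality = quality, score = NULL)
  } else {
    if (is.null(model)) model <- default_discriminant()
    features <- extract_features(rec, pca = pca, config = config)
    list(status = "ok", quality = quality,
         score = cad_score(features, model), features = features)
  }
  if (!is.null(out)) {
    ser <- result
    ser$features <- if (!is.null(result$features))
      as.list(result$features) else NULL
    jsonlite::write_json(ser, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  result
}

#' Evaluate diagnostic accuracy on a cohort table
#'
#' Runs the full diagnostic-evaluation suite on a patient table: ROC/AUC for
#' the acoustic score, the pre-test probability, and their logistic
#' combination (with paired DeLong comparisons); the optimal cut-point and
#' binary metrics at it; the four-level categorical net reclassification
#' index of combined vs pre-test model; continuous NRI and IDI; and the
#' reclassification cross-tabulation.
#'
#' @param cohort Data frame (or CSV path) with columns `disease`
#'   (`non_cad`/`non_obstructive`/`obstructive`) and `cad_score`, plus either
#'   `df_probability` or the covariates `age`, `sex`, `chest_pain` from which
#'   it is computed.
#' @param out Optional path prefix: `<out>.json` and `<out>.md` are written.
#' @return A `cad_report` list: `roc` (per-model tibble), `comparisons`,
#'   `cutpoint`, `metrics_at_cutpoint`, `categorical_nri`, `continuous_nri`,
#'   `idi`, `reclassification` (cross-tab tibble), `n`.
#' @export
run_evaluate <- function(cohort, out = NULL) {
  if (is.character(cohort))
    cohort <- utils::read.csv(cohort, stringsAsFactors = FALSE)
  cohort <- tibble::as_tibble(cohort)
  need <- c("disease", "cad_score")
  if (!"df_probability" %in% names(cohort))
    need <- c(need, "age", "sex", "chest_pain")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"df_probability" %in% names(cohort))
    cohort$df_probability <- diamond_forrester(cohort$age, cohort$sex,
                                               cohort$chest_pain)
  y <- cohort$disease == "obstructive"

  roc_cad <- roc_auc(cohort$cad_score, y)
  roc_df <- roc_auc(cohort$df_probability, y)
  comb <- combine_df_cad(cohort, y)
  roc_comb <- roc_auc(comb$combined_probability, y)
  roc_tbl <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(roc_cad), model = "cad_score", .before = 1),
    dplyr::mutate(tibble::as_tibble(roc_df), model = "df", .before = 1),
    dplyr::mutate(tibble::as_tibble(roc_comb), model = "combined", .before = 1)
  )
  comparisons <- dplyr::bind_rows(
    dplyr::mutate(
      compare_auc_paired(comb$combined_probability, cohort$cad_score, y),
      contrast = "combined_vs_cad_score", .before = 1),
    dplyr::mutate(
      compare_auc_paired(comb$combined_probability, cohort$df_probability, y),
      contrast = "combined_vs_df", .before = 1),
    dplyr::mutate(
      compare_auc_paired(cohort$cad_score, cohort$df_probability, y),
      contrast = "cad_score_vs_df", .before = 1)
  )

  cut <- liu_cutpoint(cohort$cad_score, y)
  pos <- cohort$cad_score > cut$threshold
  metrics <- binary_metrics(tp = sum(pos & y), fp = sum(pos & !y),
                            tn = sum(!pos & !y), fn = sum(!pos & y))

  old_cat <- risk_category(cohort$df_probability)
  new_cat <- risk_category(comb$combined_probability)
  cnri <- categorical_nri(old_cat, new_cat, y)
  cont <- continuous_nri(cohort$df_probability / 100,
                         comb$combined_probability / 100, y)
  idi_res <- idi(cohort$df_probability / 100,
                 comb$combined_probability / 100, y)
  xtab <- dplyr::count(
    tibble::tibble(disease = ifelse(y, "obstructive",
                                    "non_obstructive_or_non_cad"),
                   old_category = old_cat, new_category = new_cat),
    .data$disease, .data$old_category, .data$new_category, .drop = FALSE)

  report <- structure(
    list(n = nrow(cohort), roc = roc_tbl, comparisons = comparisons,
         cutpoint = cut, metrics_at_cutpoint = metrics,
         categorical_nri = cnri, continuous_nri = cont, idi = idi_res,
         reclassification = xtab, combined_model = comb),
    class = "cad_report"
  )
  if (!is.null(out)) {
    ser <- unclass(report)
    ser$combined_model <- list(coefficients = as.list(comb$coefficients))
    jsonlite::write_json(ser, paste0(out, ".json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", pretty = TRUE,
                         factor = "string")
    .write_report_md(report, paste0(out, ".md"))
  }
  report
}

#' @export
print.cad_report <- function(x, ...) {
  cat(sprintf("<cad_report> n = %d\n", x$n))
  cat("AUCs:\n")
  for (i in seq_len(nrow(x$roc)))
    cat(sprintf("  %-10s %.1f%% (CI %.0f-%.0f%%)\n", x$roc$model[i],
                100 * x$roc$auc[i], 100 * x$roc$ci_low[i],
                100 * x$roc$ci_high[i]))
  cat(sprintf("Optimal cut-point: %.1f (sens %.0f%%, spec %.0f%%)\n",
              x$cutpoint$threshold, 100 * x$cutpoint$sensitivity,
              100 * x$cutpoint$specificity))
  cat(sprintf("Categorical NRI: %.2f (CI %.2f-%.2f)\n",
              x$categorical_nri$nri, x$categorical_nri$ci_low,
              x$categorical_nri$ci_high))
  cat(sprintf("Continuous NRI: %.2f; IDI: %.3f\n",
              x$continuous_nri$nri, x$idi$idi))
  invisible(x)
}

.write_report_md <- function(x, path) {
  lines <- c(
    "# Diagnostic evaluation report", "",
    sprintf("Patients: %d", x$n), "",
    "## ROC",
    sprintf("- %s: AUC %.1f%% (CI %.0f-%.0f%%)", x$roc$model,
            100 * x$roc$auc, 100 * x$roc$ci_low, 100 * x$roc$ci_high),
    "",
    sprintf("## Cut-point %.2f", x$cutpoint$threshold),
    sprintf("- sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%%",
            100 * x$metrics_at_cutpoint$sensitivity,
            100 * x$metrics_at_cutpoint$specificity,
            100 * x$metrics_at_cutpoint$ppv,
            100 * x$metrics_at_cutpoint$npv),
    "",
    "## Reclassification",
    sprintf("- categorical NRI %.3f (CI %.3f to %.3f)", x$categorical_nri$nri,
            x$categorical_nri$ci_low, x$categorical_nri$ci_high),
    sprintf("- continuous NRI %.3f (CI %.3f to %.3f)", x$continuous_nri$nri,
            x$continuous_nri$ci_low, x$continuous_nri$ci_high),
    sprintf("- IDI %.4f (CI %.4f to %.4f)", x$idi$idi, x$idi$ci_low,
            x$idi$ci_high),
    "",
    "| disease | old | new | n |", "|---|---|---|---|",
    sprintf("| %s | %s | %s | %d |", x$reclassification$disease,
            x$reclassification$old_category, x$reclassification$new_category,
            x$reclassification$n)
  )
  writeLines(lines, path)
  invisible(path)
}
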