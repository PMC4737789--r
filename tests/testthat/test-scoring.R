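test_that("well-separated classes give near-perfect held-out discrimination", {
  co <- simulate_feature_cohort(60, 60, delta = 3, seed = 11)
  cv <- cross_validate(co, co$event, repeats = 3, folds = 10, seed = 12)
  expect_gte(cv$mean_auc, 0.95)
})

test_that("shuffled labels give chance-level cross-validated AUC", {
  co <- simulate_feature_cohort(100, 100, delta = 0.8, seed = 13)
  null_aucs <- vapply(1:4, function(k) {
    shuffled <- withr::with_seed(14 + k, sample(co$event))
    cross_validate(co, shuffled, repeats = 3, folds = 10,
                   seed = 15 + k)$mean_auc
  }, numeric(1))
  expect_gt(mean(null_aucs), 0.44)
  expect_lt(mean(null_aucs), 0.56)
})

test_that("identical class means carry no signal", {
  co <- simulate_feature_cohort(100, 100, delta = 0, seed = 16)
  m <- train_discriminant(co, co$event)
  sc <- cad_score(co, m)
  auc <- roc_auc(sc$value, co$event)$auc
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.62)
})

test_that("training scores are calibrated to mean 25, SD 12", {
  co <- simulate_feature_cohort(165, 63, delta = 0.4, seed = 17)
  m <- train_discriminant(co, co$event)
  sc <- cad_score(co, m)
  expect_equal(mean(sc$value), 25, tolerance = 0.5)
  expect_equal(stats::sd(sc$value), 12, tolerance = 0.5)
})

test_that("score categories own their boundaries", {
  expect_equal(as.character(score_category(c(20, 24.2, 30, 30.01, 5))),
               c("low", "intermediate", "intermediate", "high", "low"))
})

test_that("short-diastasis subjects are scored by the reduced model", {
  co <- simulate_feature_cohort(80, 80, delta = 0.8, seed = 18)
  m <- train_discriminant(co, co$event)
  fv <- tibble::tibble(fpr = NA_real_, pcaspec = NA_real_,
                       ami = 0.7, s4amp = 0.2, short_diastasis = TRUE)
  sc <- cad_score(fv, m)
  expect_true(sc$short_diastasis_used)
  expect_true(sc$value >= 0 && sc$value <= 100)
  # reduced score must ignore the spectral features entirely
  fv2 <- dplyr::mutate(fv, fpr = 99, pcaspec = -99)
  expect_equal(cad_score(fv2, m)$value, sc$value)
  expect_error(cad_score(dplyr::mutate(fv, ami = NA_real_), m), "missing")
})

test_that("scores are monotone in positively weighted features and clipped", {
  co <- simulate_feature_cohort(80, 80, delta = 1, seed = 19)
  m <- train_discriminant(co, co$event)
  base <- co[1, ]
  for (v in names(m$weights_full)) {
    if (m$weights_full[[v]] <= 0) next
    stepped <- dplyr::bind_rows(base, base, base, base)
    stepped[[v]] <- base[[v]] + c(0, 1, 2, 5)
    vals <- cad_score(stepped, m)$value
    expect_true(all(diff(vals) >= 0))
  }
  extreme <- dplyr::mutate(base, fpr = 1e6, pcaspec = 1e6, ami = 1e6,
                           s4amp = 1e6)
  expect_lte(cad_score(extreme, m)$value, 100)
  extreme_lo <- dplyr::mutate(base, fpr = -1e6, pcaspec = -1e6, ami = -1e6,
                              s4amp = -1e6)
  expect_gte(cad_score(extreme_lo, m)$value, 0)
})

test_that("cross-validated AUC does not exceed resubstitution AUC", {
  co <- simulate_feature_cohort(120, 60, delta = 0.5, seed = 20)
  m <- train_discriminant(co, co$event)
  resub <- roc_auc(cad_score(co, m)$value, co$event)$auc
  cv <- cross_validate(co, co$event, repeats = 10, folds = 10, seed = 21)
  expect_lte(cv$mean_auc, resub)
})

test_that("the Fisher direction agrees with an independent LDA fit", {
  co <- simulate_feature_cohort(100, 80, delta = 0.8, seed = 22)
  m <- train_discriminant(co, co$event)
  ld <- MASS::lda(as.matrix(co[, c("fpr", "pcaspec", "ami", "s4amp")]),
                  grouping = co$event)
  w_ref <- as.numeric(ld$scaling[, 1])
  w <- as.numeric(m$weights_full)
  cosine <- abs(sum(w * w_ref)) / sqrt(sum(w^2) * sum(w_ref^2))
  expect_gt(cosine, 0.999)
})

test_that("model persistence round-trips through JSON", {
  co <- simulate_feature_cohort(60, 60, delta = 1, seed = 23)
  m <- train_discriminant(co, co$event)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$weights_full, m$weights_full)
  expect_equal(m2$calibration_reduced, m$calibration_reduced)
  expect_equal(cad_score(co[1:5, ], m2)$value, cad_score(co[1:5, ], m)$value)
})

test_that("tidy and glance expose coefficients and CV summaries", {
  co <- simulate_feature_cohort(60, 60, delta = 1, seed = 24)
  m <- train_discriminant(co, co$event)
  td <- tidy(m)
  expect_setequal(unique(td$model), c("full", "reduced"))
  expect_true("(intercept)" %in% td$term)
  cv <- cross_validate(co, co$event, repeats = 3, folds = 5, seed = 25)
  expect_equal(nrow(tidy(cv)), 3)
  expect_named(glance(cv), c("mean_auc", "sd_auc", "repeats", "folds"))
})

test_that("the packaged default model is deterministic and usable", {
  m1 <- default_discriminant()
  m2 <- default_discriminant()
  expect_identical(m1, m2)
  fv <- tibble::tibble(fpr = -0.5, pcaspec = 1, ami = 0.6, s4amp = 0.15,
                       short_diastasis = FALSE)
  sc <- cad_score(fv, m1)
  expect_true(sc$value >= 0 && sc$value <= 100)
})
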