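test_that("AUC matches hand-counted concordant pairs and handles ties", {
  r <- roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(rep(2, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC equals the exhaustive pair-count oracle on small inputs", {
  set.seed(51)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    scores <- sample(1:6, n, replace = TRUE)  # ties likely
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels)$auc, auc_pair_oracle(scores, labels))
  }
})

test_that("AUC, DeLong CI, and paired test agree with pROC", {
  set.seed(52)
  y <- rep(c(0, 1), each = 60)
  a <- stats::rnorm(120) + y
  b <- stats::rnorm(120) + 0.5 * y
  r <- roc_auc(a, y)
  pr <- pROC::roc(y, a, quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(c(r$ci_low, r$ci_high), ci[c(1, 3)], tolerance = 1e-9)
  cmp <- compare_auc_paired(a, b, y)
  ref <- pROC::roc.test(pr, pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("paired comparison is antisymmetric and null for identical scores", {
  set.seed(53)
  y <- rep(c(0, 1), each = 40)
  a <- stats::rnorm(80) + y
  b <- stats::rnorm(80)
  ab <- compare_auc_paired(a, b, y)
  ba <- compare_auc_paired(b, a, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(compare_auc_paired(a, a, y)$p_value, 1)
  expect_error(compare_auc_paired(a, b[-1], y), "equal length")
})

test_that("an informative score beats noise in most replicates (power)", {
  set.seed(54)
  hits <- 0
  for (i in 1:20) {
    y <- rep(c(0, 1), each = 200)
    good <- stats::rnorm(400) + y
    noise <- stats::rnorm(400)
    if (compare_auc_paired(good, noise, y)$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("the optimal cut-point separates separable classes at the gap", {
  cut <- liu_cutpoint(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(cut$threshold, 2.5)
  expect_equal(cut$product, 1)
})

test_that("the cut-point equals the exhaustive threshold oracle", {
  got <- liu_cutpoint(c(1, 2, 2, 3), c(0, 1, 0, 1))
  ref <- liu_oracle(c(1, 2, 2, 3), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(got$threshold, ref$threshold)
  expect_equal(got$product, ref$product)
  set.seed(55)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    scores <- sample(1:8, n, replace = TRUE)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    got <- liu_cutpoint(scores, labels)
    ref <- liu_oracle(scores, labels)
    expect_equal(got$threshold, ref$threshold)
    expect_equal(got$product, ref$product)
  }
})

test_that("score negation with label inversion leaves the optimum invariant", {
  set.seed(56)
  scores <- stats::rnorm(30)
  labels <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
  a <- liu_cutpoint(scores, labels)
  b <- liu_cutpoint(-scores, !labels)
  expect_equal(b$product, a$product)
  expect_equal(b$sensitivity, a$specificity)
})

test_that("binary metrics reproduce the printed predictive values exactly", {
  npv <- binary_metrics(tp = 37, fp = 48, tn = 74, fn = 6)
  expect_identical(npv$npv, 74 / 80)     # 92.5 %
  expect_identical(npv$ppv, 37 / 85)     # 43.5 %
  perfect <- binary_metrics(tp = 10, fp = 0, tn = 10, fn = 0)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  expect_equal(perfect$plr, Inf)
})

test_that("binary-metric identities hold as exact rationals", {
  set.seed(57)
  for (i in 1:50) {
    k <- sample(0:30, 4, replace = TRUE)
    tp <- k[1] + 1; fp <- k[2]; tn <- k[3] + 1; fn <- k[4]
    m <- suppressWarnings(binary_metrics(tp, fp, tn, fn))
    expect_identical(m$sensitivity, tp / (tp + fn))
    expect_identical(m$specificity, tn / (tn + fp))
    if (m$specificity < 1)
      expect_identical(m$plr, m$sensitivity / (1 - m$specificity))
    expect_identical(m$nlr, (1 - m$sensitivity) / m$specificity)
  }
  expect_warning(m <- binary_metrics(tp = 0, fp = 0, tn = 5, fn = 5), "ppv")
  expect_true(is.na(m$ppv))
  expect_error(binary_metrics(0, 5, 5, 0), "each disease class")
})

test_that("categorical NRI is zero under identity and 2 at the extreme", {
  lv <- c("very_low", "low", "moderate", "high")
  old <- factor(rep(lv, each = 5), levels = lv, ordered = TRUE)
  ev <- rep(c(TRUE, FALSE), 10)
  expect_equal(categorical_nri(old, old, ev)$nri, 0)
  up1 <- factor(lv[pmin(as.integer(old) + 1, 4)], levels = lv, ordered = TRUE)
  dn1 <- factor(lv[pmax(as.integer(old) - 1, 1)], levels = lv, ordered = TRUE)
  old_mid <- factor(rep(c("low", "moderate"), 10), levels = lv, ordered = TRUE)
  new_all <- factor(ifelse(ev, "high", "very_low"), levels = lv,
                    ordered = TRUE)
  expect_equal(categorical_nri(old_mid, new_all, ev)$nri, 2)
  expect_error(categorical_nri(old, factor(rep("a", 20)), ev), "level scale")
})

test_that("continuous NRI handles identity, extremes, and real signal", {
  p <- stats::runif(40)
  ev <- rep(c(TRUE, FALSE), 20)
  expect_equal(continuous_nri(p, p, ev)$nri, 0)
  eps <- 0.01
  p_new <- ifelse(ev, pmin(p + eps, 1), pmax(p - eps, 0))
  expect_equal(continuous_nri(p, p_new, ev)$nri, 2)
  # an added informative predictor is detected in almost every replicate
  set.seed(58)
  wins <- 0
  for (i in 1:20) {
    n <- 150
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
    y <- stats::runif(n) < stats::plogis(-0.5 + x1 + 1.2 * x2)
    if (length(unique(y)) < 2) next
    p_old <- stats::fitted(stats::glm(y ~ x1, family = stats::binomial()))
    p_new <- stats::fitted(stats::glm(y ~ x1 + x2, family = stats::binomial()))
    if (continuous_nri(p_old, p_new, y)$nri > 0) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("IDI reproduces two-point arithmetic and shift invariance", {
  ev <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(idi(c(0.2, 0.2, 0.3, 0.3), c(0.4, 0.4, 0.2, 0.2), ev)$idi, 0.3)
  expect_equal(idi(c(0.1, 0.4, 0.2, 0.6), c(0.1, 0.4, 0.2, 0.6), ev)$idi, 0)
  set.seed(59)
  p_old <- stats::runif(40, 0.2, 0.6)
  p_new <- p_old + stats::rnorm(40, sd = 0.05)
  evr <- rep(c(TRUE, FALSE), 20)
  base <- idi(p_old, p_new, evr)$idi
  expect_equal(idi(p_old + 0.1, p_new + 0.1, evr)$idi, base)
  expect_error(idi(p_old, p_new[-1], evr), "equal length")
})

test_that("NRI component bookkeeping satisfies its defining identities", {
  set.seed(60)
  lv <- c("very_low", "low", "moderate", "high")
  old <- factor(sample(lv, 120, replace = TRUE), levels = lv, ordered = TRUE)
  new <- factor(sample(lv, 120, replace = TRUE), levels = lv, ordered = TRUE)
  ev <- sample(c(TRUE, FALSE), 120, replace = TRUE)
  r <- categorical_nri(old, new, ev)
  expect_equal(r$nri, r$event_component + r$nonevent_component)
  expect_equal(r$event_component,
               (r$up_events - r$down_events) / r$n_events)
  expect_equal(r$nonevent_component,
               (r$down_nonevents - r$up_nonevents) / r$n_nonevents)
  expect_lte(r$ci_low, r$nri)
  expect_gte(r$ci_high, r$nri)
})
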