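test_that("waveform synthesis is bit-identical under a fixed seed", {
  p <- subject_params(seed = 71)
  a <- simulate_pcg(p, duration_s = 12)
  b <- simulate_pcg(p, duration_s = 12)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$cycles, b$cycles)
  c <- simulate_pcg(subject_params(seed = 72), duration_s = 12)
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("ground-truth landmarks satisfy the cycle invariants", {
  sim <- simulate_pcg(subject_params(heart_rate_bpm = 70, seed = 73),
                      duration_s = 20)
  cyc <- sim$cycles
  expect_true(all(cyc$s1_onset < cyc$s2_onset))
  expect_true(all(cyc$s2_onset < cyc$s3_onset))
  expect_true(all(cyc$s3_onset < cyc$s4_onset))
  expect_true(all(cyc$s4_onset < cyc$next_s1_onset))
  expect_equal(cyc$rr_interval, cyc$next_s1_onset - cyc$s1_onset)
})

test_that("with murmur and S3/S4 off the diastasis spectrum is flat at the
           floor", {
  p <- subject_params(s3_amp = 0, s4_amp = 0,
                      murmur_low_gain_db = -Inf, murmur_high_gain_db = -Inf,
                      seed = 74)
  sim <- simulate_pcg(p, duration_s = 25)
  recf <- bandlimit(sim$recording, 20, 1000)
  wins <- suppressMessages(diastasis_windows(recf, detect_cycles(recf)))
  spec <- mean_spectrum(wins, recf$sample_rate)
  expect_lte(max(spec$power_db) - min(spec$power_db), 6)
})

test_that("a +10 dB murmur gain raises the low-band diastasis power by
           10 dB", {
  band_low_db <- function(gain) {
    p <- subject_params(s3_amp = 0, s4_amp = 0, murmur_low_gain_db = gain,
                        seed = 75)
    sim <- simulate_pcg(p, duration_s = 25)
    recf <- bandlimit(sim$recording, 20, 1000)
    wins <- suppressMessages(diastasis_windows(recf, detect_cycles(recf)))
    spec <- mean_spectrum(wins, recf$sample_rate)
    sel <- spec$freq < 150
    10 * log10(mean(10^(spec$power_db[sel] / 10)))
  }
  expect_equal(band_low_db(10) - band_low_db(0), 10, tolerance = 1)
})

test_that("cohort group moments match their configured targets at large n", {
  pars <- cohort_params(n = c(4000, 3000, 3000), seed = 76)
  co <- simulate_cohort(pars, truncate = FALSE)
  for (g in 1:3) {
    grp <- c("non_cad", "non_obstructive", "obstructive")[g]
    sel <- co$disease == grp
    se <- pars$score_sds[g] / sqrt(sum(sel))
    expect_lt(abs(mean(co$cad_score[sel]) - pars$score_means[g]), 3 * se)
    expect_lt(abs(stats::sd(co$cad_score[sel]) - pars$score_sds[g]),
              0.05 * pars$score_sds[g])
  }
})

test_that("zero spread pins scores exactly to the group means", {
  pars <- cohort_params(score_sds = rep(0, 3), score_df_correlation = NULL,
                        seed = 77)
  co <- simulate_cohort(pars, truncate = FALSE)
  m <- tapply(co$cad_score, co$disease, unique)
  expect_equal(as.numeric(m[c("non_cad", "non_obstructive", "obstructive")]),
               c(21.3, 29.7, 32.8))
})

test_that("truncation keeps scores inside the instrument range", {
  co <- simulate_cohort(cohort_params(seed = 78))
  expect_true(all(co$cad_score >= 0 & co$cad_score <= 100))
  expect_true(all(co$df_probability >= 0 & co$df_probability <= 100))
  expect_equal(nrow(co), 228)
  expect_equal(unname(table(co$disease)[c("non_cad", "non_obstructive",
                                          "obstructive")]),
               c(124L, 41L, 63L), ignore_attr = TRUE)
})

test_that("the copula hits the target score-to-pre-test correlation on
           average", {
  rs <- vapply(1:120, function(i) {
    co <- simulate_cohort(cohort_params(seed = 1000 + i))
    stats::cor(co$cad_score, co$df_probability)
  }, numeric(1))
  expect_gt(mean(rs), 0.33)
  expect_lt(mean(rs), 0.39)
})

test_that("an infeasible correlation target is refused", {
  expect_error(simulate_cohort(cohort_params(score_df_correlation = 0.995,
                                             seed = 79)),
               "infeasible")
})

test_that("audio cohort generation is deterministic and carries truth", {
  a <- simulate_pcg_cohort(n_healthy = 2, n_diseased = 2, duration_s = 12,
                           seed = 80)
  b <- simulate_pcg_cohort(n_healthy = 2, n_diseased = 2, duration_s = 12,
                           seed = 80)
  expect_identical(a$truth, b$truth)
  expect_identical(a$recordings[[1]]$samples, b$recordings[[1]]$samples)
  expect_equal(a$truth$diseased, c(FALSE, FALSE, TRUE, TRUE))
})
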