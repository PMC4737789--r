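make_windows <- function(segments, fs = 8000) {
  tibble::tibble(
    cycle = seq_along(segments),
    start = 0, end = vapply(segments, length, integer(1)) / fs,
    duration = vapply(segments, length, integer(1)) / fs,
    short_diastasis = FALSE,
    samples = segments
  )
}

test_that("a pure tone peaks at its frequency; silence sits at the floor", {
  fs <- 8000
  t <- (0:2047) / fs
  tone <- lapply(1:10, function(i) sin(2 * pi * 100 * t))
  spec <- mean_spectrum(make_windows(tone), fs)
  expect_lt(abs(spec$freq[which.max(spec$power_db)] - 100), attr(spec, "df"))

  silent <- mean_spectrum(make_windows(lapply(1:5, function(i) numeric(2048))),
                          fs)
  expect_true(all(silent$power_db == -120))
})

test_that("white-noise spectra are flat and match a direct FFT oracle", {
  fs <- 8000
  set.seed(41)
  segs <- lapply(1:60, function(i) stats::rnorm(2048))
  spec <- mean_spectrum(make_windows(segs), fs)
  expect_lte(max(spec$power_db) - min(spec$power_db), 6)
  # oracle: one-sided rectangular-window periodogram average, same data
  nseg <- 1024
  oracle <- Reduce(`+`, lapply(segs, function(x) {
    p <- Mod(stats::fft(x[1:nseg])[1:(nseg / 2 + 1)])^2 / (fs * nseg)
    p[c(-1, -length(p))] <- 2 * p[c(-1, -length(p))]
    p
  })) / length(segs)
  f <- (0:(nseg / 2)) * fs / nseg
  keep <- f >= 20 & f <= 1000
  # mean dB level agrees within 1 dB (window functions differ slightly)
  expect_lt(abs(mean(spec$power_db) - mean(10 * log10(oracle[keep]))), 1)
})

test_that("short windows alone raise the short-diastasis error", {
  fs <- 8000
  segs <- lapply(1:5, function(i) stats::rnorm(500))  # 62.5 ms
  expect_error(mean_spectrum(make_windows(segs), fs), "short diastasis")
})

test_that("FPR of a flat spectrum equals the bandwidth ratio", {
  expect_lt(abs(feature_fpr(flat_spectrum()) - log10(130 / 850)), 0.02)
})

test_that("FPR saturates when all power sits in one low-frequency tone", {
  spec <- flat_spectrum(level_db = -120)
  spec$power_db[which.min(abs(spec$freq - 100))] <- 0
  expect_gte(feature_fpr(spec), 2)
})

test_that("a +10 dB low-band gain raises FPR by one log10 unit", {
  base <- flat_spectrum(-40)
  up <- base
  up$power_db[up$freq < 150] <- up$power_db[up$freq < 150] + 10
  expect_equal(feature_fpr(up) - feature_fpr(base), 1.0, tolerance = 1e-6)
})

test_that("PCA recovers a single variation mode and its variance share", {
  fs <- 8000; nseg <- 1024
  freq <- (0:(nseg / 2)) * fs / nseg
  keep <- freq >= 20 & freq <= 1000
  p <- sum(keep)
  as_spec <- function(v) {
    out <- tibble::tibble(freq = freq[keep], power_db = v)
    structure(out, n_windows = 1L, sample_rate = fs, df = fs / nseg,
              class = c("pcg_spectrum", class(out)))
  }
  base <- -40 + 5 * exp(-((freq[keep] - 80) / 60)^2)
  shape <- exp(-((freq[keep] - 100) / 80)^2)
  set.seed(42)
  s_i <- stats::rnorm(30, sd = 3)
  specs <- lapply(s_i, function(s) as_spec(base + s * shape))
  m <- fit_pca_spec(specs)
  v_unit <- shape / sqrt(sum(shape^2))
  expect_lt(max(abs(abs(m$loading) - v_unit)), 1e-6)
  expect_gt(m$explained_variance_fraction, 0.999)

  # two orthogonal modes with variances 9 and 1
  u1 <- rep(0, p); u1[1:50] <- 1 / sqrt(50)
  u2 <- rep(0, p); u2[51:100] <- 1 / sqrt(50)
  set.seed(43)
  specs2 <- lapply(1:400, function(i) {
    as_spec(base + stats::rnorm(1, sd = 3) * u1 + stats::rnorm(1, sd = 1) * u2)
  })
  m2 <- fit_pca_spec(specs2)
  expect_equal(m2$explained_variance_fraction, 0.9, tolerance = 0.02)

  expect_error(fit_pca_spec(lapply(1:10, function(i) as_spec(base))),
               "degenerate")
})

test_that("the spectral projection is a centred unit-norm dot product", {
  fs <- 8000; nseg <- 1024
  freq <- (0:(nseg / 2)) * fs / nseg
  keep <- freq >= 20 & freq <= 1000
  as_spec <- function(v) {
    out <- tibble::tibble(freq = freq[keep], power_db = v)
    structure(out, n_windows = 1L, sample_rate = fs, df = fs / nseg,
              class = c("pcg_spectrum", class(out)))
  }
  set.seed(44)
  specs <- lapply(1:12, function(i) as_spec(stats::rnorm(sum(keep), -40, 3)))
  m <- fit_pca_spec(specs)
  expect_equal(feature_pcaspec(as_spec(m$mean_spectrum), m), 0)
  expect_equal(feature_pcaspec(as_spec(m$mean_spectrum + 2 * m$loading), m), 2)
  bad <- as_spec(m$mean_spectrum)
  bad$freq <- bad$freq + 1
  expect_error(feature_pcaspec(bad, m), "grid")
})

test_that("AMI matches a brute-force joint-histogram oracle to 1e-9", {
  set.seed(45)
  x <- stats::rnorm(1500)
  lags <- 1:5
  got <- feature_ami(x, 2000, config = list(ami_lags = lags))
  nb <- 16L
  n <- length(x)
  b <- ceiling(rank(x, ties.method = "first") * nb / n)
  oracle <- mean(vapply(lags, function(tau) {
    bx <- b[1:(n - tau)]; by <- b[(tau + 1):n]
    acc <- 0
    for (i in 1:nb) for (j in 1:nb) {
      pij <- sum(bx == i & by == j) / (n - tau)
      if (pij > 0) {
        pi_ <- sum(bx == i) / (n - tau)
        p_j <- sum(by == j) / (n - tau)
        acc <- acc + pij * log2(pij / (pi_ * p_j))
      }
    }
    acc
  }, numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("AMI separates structure from noise and is small for i.i.d. data", {
  set.seed(46)
  t <- (0:4095) / 2000
  sine <- sin(2 * pi * 30 * t)
  noise <- stats::rnorm(4096)
  expect_gt(feature_ami(sine, 2000), feature_ami(noise, 2000))
  expect_lt(feature_ami(noise, 2000), 0.2)
  expect_warning(z <- feature_ami(numeric(2000), 2000), "constant")
  expect_equal(z, 0)
  expect_error(feature_ami(stats::rnorm(50), 2000), "too short")
})

test_that("S4 amplitude is the envelope ratio to S1 and scales linearly", {
  fs <- 8000
  dur <- 12
  t <- (0:(dur * fs - 1)) / fs
  burst <- function(center, amp) {
    amp * exp(-0.5 * ((t - center) / 0.01)^2) * sin(2 * pi * 40 * (t - center))
  }
  build <- function(s4_amp) {
    x <- numeric(length(t))
    s1_times <- seq(0.5, dur - 0.6, by = 1)
    for (s1 in s1_times) x <- x + burst(s1, 1.0)
    for (s1 in s1_times[-1]) x <- x + burst(s1 - 0.12, s4_amp)
    rec <- pcg_recording(x, fs)
    cyc <- tibble::tibble(
      cycle = seq_len(length(s1_times) - 1),
      s1_onset = s1_times[-length(s1_times)],
      s2_onset = s1_times[-length(s1_times)] + 0.31,
      s3_onset = NA_real_, s4_onset = NA_real_,
      next_s1_onset = s1_times[-1], rr_interval = 1.0)
    list(rec = rec, cyc = cyc)
  }
  b1 <- build(0.4)
  got1 <- feature_s4amp(b1$cyc[3, ], b1$rec, cycles = b1$cyc)
  expect_equal(got1, 0.4, tolerance = 0.04)
  b2 <- build(0.8)
  got2 <- feature_s4amp(b2$cyc[3, ], b2$rec, cycles = b2$cyc)
  expect_equal(got2 / got1, 2, tolerance = 0.1)
  b0 <- build(0)
  expect_lt(feature_s4amp(b0$cyc[3, ], b0$rec, cycles = b0$cyc), 0.05)
})

test_that("feature extraction is deterministic and complete at 60 bpm", {
  sim <- fixture_sim60()
  f1 <- quiet_features(sim$recording)
  f2 <- quiet_features(sim$recording)
  expect_identical(f1, f2)
  expect_false(f1$short_diastasis)
  expect_false(anyNA(f1[c("fpr", "ami", "s4amp")]))
  expect_equal(f1$s4amp, 0.25, tolerance = 0.1)
})

test_that("a tachycardic subject falls back to the reduced feature set", {
  sim <- simulate_pcg(subject_params(heart_rate_bpm = 115, seed = 107),
                      duration_s = 20)
  f <- quiet_features(sim$recording)
  expect_true(f$short_diastasis)
  expect_true(is.na(f$fpr))
  expect_true(is.na(f$pcaspec))
  expect_false(is.na(f$ami))
  expect_false(is.na(f$s4amp))
})

test_that("raising the simulated murmur gain raises mean FPR", {
  f_at_gain <- function(g, seeds) {
    vapply(seeds, function(s) {
      p <- subject_params(murmur_low_gain_db = g, seed = s)
      quiet_features(simulate_pcg(p, duration_s = 12)$recording)$fpr
    }, numeric(1))
  }
  lo <- f_at_gain(0, 501:504)
  hi <- f_at_gain(8, 501:504)
  expect_gt(mean(hi), mean(lo))
  expect_true(all(hi > lo))  # paired seeds: effect holds subject by subject
})
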