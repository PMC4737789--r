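#' Subject-level phonocardiogram simulation parameters
#'
#' Defaults describe a healthy resting adult recorded with a chest-wall
#' sensor: 60 bpm, S1 the loudest sound, S2 somewhat softer, soft S3/S4, a
#' white sensor/ambient noise floor 50 dB below S1, and diastolic murmur
#' components at a reference level 20 dB above that floor. The two murmur
#' gains mirror the two spectral disease signatures of coronary stenosis:
#' elevated low-frequency (< 150 Hz) diastolic power and faint
#' high-frequency (200-500 Hz) microbruits from post-stenotic turbulence.
#' Gains are in dB relative to the murmur reference level; `-Inf` switches a
#' component off.
#'
#' @param heart_rate_bpm Heart rate, 40-130 bpm.
#' @param s1_amp,s2_amp,s3_amp,s4_amp Relative tone-burst amplitudes.
#' @param murmur_low_gain_db Low-frequency (20-150 Hz) diastolic murmur gain.
#' @param murmur_high_gain_db Microbruit (200-500 Hz) diastolic gain.
#' @param noise_floor_db White-noise floor in dB relative to S1 amplitude.
#' @param seed RNG seed for the noise processes.
#' @return Named list of parameters.
#' @export
subject_params <- function(heart_rate_bpm = 60, s1_amp = 1, s2_amp = 0.7,
                           s3_amp = 0.2, s4_amp = 0.25,
                           murmur_low_gain_db = 0, murmur_high_gain_db = 0,
                           noise_floor_db = -50, seed = 1) {
  stopifnot(heart_rate_bpm >= 40, heart_rate_bpm <= 130,
            s1_amp >= 0, s2_amp >= 0, s3_amp >= 0, s4_amp >= 0)
  list(heart_rate_bpm = heart_rate_bpm, s1_amp = s1_amp, s2_amp = s2_amp,
       s3_amp = s3_amp, s4_amp = s4_amp,
       murmur_low_gain_db = murmur_low_gain_db,
       murmur_high_gain_db = murmur_high_gain_db,
       noise_floor_db = noise_floor_db, seed = seed)
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.tone_burst <- function(t, center, dur, freq, amp) {
  # Gaussian-enveloped tone; `dur` is roughly the full width at ~6 sigma
  sigma <- dur / 6
  amp * exp(-0.5 * ((t - center) / sigma)^2) * sin(2 * pi * freq * (t - center))
}

#' Simulate a phonocardiogram with exact ground truth
#'
#' Generates a single-channel heart-sound waveform as a per-beat sum of
#' Gaussian-enveloped tone bursts (S1 ~55 Hz / 70 ms; S2 ~90 Hz / 60 ms;
#' S3 ~32 Hz and S4 ~36 Hz, 50 ms each, S4 centred 120 ms before the next
#' S1), plus diastasis-gated coloured murmur noise shaped by the two gain
#' knobs, plus a white noise floor. Systole duration follows
#' `0.31 * sqrt(RR)`. Landmark times (burst centres) are returned exactly,
#' so detector accuracy is testable against ground truth.
#'
#' @param params A [subject_params()] list.
#' @param duration_s Recording length in seconds.
#' @param sample_rate Sampling rate in Hz (>= 2000).
#' @param subject_id Identifier stored in the recording.
#' @return List with `recording` (a [pcg_recording] with four nominal
#'   breath-hold annotations) and `cycles` (ground-truth tibble in the
#'   [detect_cycles()] layout).
#' @export
simulate_pcg <- function(params = subject_params(), duration_s = 30,
                         sample_rate = 8000, subject_id = "sim") {
  if (sample_rate < 2000) stop("sample_rate must be >= 2000 Hz", call. = FALSE)
  rr <- 60 / params$heart_rate_bpm
  systole <- 0.31 * sqrt(rr)
  s1_times <- seq(0.5, duration_s - 0.6, by = rr)
  if (length(s1_times) < 3) stop("duration too short", call. = FALSE)
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate

  .with_seed(params$seed, {
    x <- numeric(n)
    k_last <- length(s1_times)
    for (k in seq_len(k_last)) {
      s1 <- s1_times[k]
      x <- x + .tone_burst(t, s1, 0.07, 55, params$s1_amp)
      x <- x + .tone_burst(t, s1 + systole, 0.06, 90, params$s2_amp)
      if (params$s3_amp > 0)
        x <- x + .tone_burst(t, s1 + systole + 0.13, 0.05, 32, params$s3_amp)
      if (k < k_last && params$s4_amp > 0)
        x <- x + .tone_burst(t, s1_times[k + 1] - 0.12, 0.05, 36, params$s4_amp)
    }

    sigma_n <- params$s1_amp * 10^(params$noise_floor_db / 20)
    sigma_ref <- sigma_n * 10  # murmur reference: 20 dB above the floor
    murmur <- numeric(n)
    for (band_gain in list(c(20, 150, params$murmur_low_gain_db),
                           c(200, 500, params$murmur_high_gain_db))) {
      g <- band_gain[3]
      if (!is.finite(g)) next
      bf <- signal::butter(4, band_gain[1:2] / (sample_rate / 2), type = "pass")
      # two zero-phase passes: steep skirts keep murmur energy inside its band
      col_noise <- as.numeric(signal::filtfilt(bf, signal::filtfilt(bf, stats::rnorm(n))))
      col_noise <- col_noise / stats::sd(col_noise)
      murmur <- murmur + col_noise * sigma_ref * 10^(g / 20)
    }
    gate <- numeric(n)
    for (k in seq_len(k_last - 1)) {
      g0 <- s1_times[k] + systole + 0.13 + 0.05
      g1 <- s1_times[k + 1] - 0.12 - 0.05
      if (g1 > g0) gate[t >= g0 & t < g1] <- 1
    }
    x <- x + murmur * gate + stats::rnorm(n, sd = sigma_n)
  })

  bh_len <- 7.5
  bh_starts <- seq(2, by = max(bh_len + 2, (duration_s - 4) / 4),
                   length.out = 4)
  bh <- lapply(bh_starts[bh_starts + bh_len < duration_s],
               function(s) c(s, s + bh_len))

  cycles <- tibble::tibble(
    cycle = seq_len(length(s1_times) - 1L),
    s1_onset = s1_times[-length(s1_times)],
    s2_onset = s1_times[-length(s1_times)] + systole,
    s3_onset = if (params$s3_amp > 0)
      s1_times[-length(s1_times)] + systole + 0.13 else NA_real_,
    s4_onset = if (params$s4_amp > 0)
      s1_times[-1] - 0.12 else NA_real_,
    next_s1_onset = s1_times[-1],
    rr_interval = diff(s1_times)
  )
  list(
    recording = pcg_recording(x, sample_rate, subject_id = subject_id,
                              breath_hold_intervals = bh),
    cycles = cycles
  )
}

#' Simulate an audio cohort with disease-dependent murmur energy
#'
#' Draws per-subject heart rates uniformly from `rate_range`, assigns the
#' diseased subjects elevated murmur gains, and synthesizes one recording per
#' subject. Defaults plant a +6 dB low-frequency and +3 dB high-frequency
#' diastolic murmur excess in disease, the direction (not magnitude) of the
#' spectral contrast observed clinically.
#'
#' @param n_healthy,n_diseased Group sizes.
#' @param diseased_low_gain_db,diseased_high_gain_db Murmur gains in disease;
#'   healthy subjects sit at the 0 dB reference.
#' @param duration_s,sample_rate Passed to [simulate_pcg()].
#' @param rate_range Heart-rate range (bpm) sampled uniformly.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return List: `recordings` (named list of [pcg_recording]), `truth`
#'   (tibble with `subject_id`, `diseased`, `heart_rate_bpm`, gains).
#' @export
simulate_pcg_cohort <- function(n_healthy = 40, n_diseased = 40,
                                diseased_low_gain_db = 6,
                                diseased_high_gain_db = 3,
                                duration_s = 20, sample_rate = 8000,
                                rate_range = c(55, 80), seed = 1) {
  n <- n_healthy + n_diseased
  diseased <- rep(c(FALSE, TRUE), c(n_healthy, n_diseased))
  rates <- .with_seed(seed, stats::runif(n, rate_range[1], rate_range[2]))
  recs <- vector("list", n)
  ids <- sprintf("sub%03d", seq_len(n))
  for (i in seq_len(n)) {
    p <- subject_params(
      heart_rate_bpm = rates[i],
      murmur_low_gain_db = if (diseased[i]) diseased_low_gain_db else 0,
      murmur_high_gain_db = if (diseased[i]) diseased_high_gain_db else 0,
      seed = (seed * 1000L + i) %% .Machine$integer.max
    )
    recs[[i]] <- simulate_pcg(p, duration_s, sample_rate,
                              subject_id = ids[i])$recording
  }
  names(recs) <- ids
  list(recordings = recs,
       truth = tibble::tibble(subject_id = ids, diseased = diseased,
                              heart_rate_bpm = rates))
}

#' Cohort score-distribution parameters
#'
#' Defaults reproduce the validation cohort's printed group distributions:
#' acoustic scores 21.3 +/- 12.7 (no CAD, n = 124), 29.7 +/- 11.8
#' (non-obstructive CAD, n = 41), 32.8 +/- 10.8 (obstructive CAD, n = 63);
#' pre-test probabilities 25 +/- 17, 34 +/- 21, 51 +/- 22 %; and a
#' whole-cohort score-to-pre-test-probability Pearson correlation of 0.36.
#'
#' @param n Integer vector of group sizes (non-CAD, non-obstructive,
#'   obstructive).
#' @param score_means,score_sds Per-group acoustic score moments (points).
#' @param df_means,df_sds Per-group pre-test probability moments (%).
#' @param score_df_correlation Target whole-cohort Pearson correlation, or
#'   `NULL` for no within-group coupling (the group-mean structure alone then
#'   sets the correlation).
#' @param seed RNG seed.
#' @return Named list of parameters.
#' @export
cohort_params <- function(n = c(124, 41, 63),
                          score_means = c(21.3, 29.7, 32.8),
                          score_sds = c(12.7, 11.8, 10.8),
                          df_means = c(25, 34, 51),
                          df_sds = c(17, 21, 22),
                          score_df_correlation = 0.36,
                          seed = 1) {
  stopifnot(length(n) == 3, all(n > 0), all(score_sds >= 0), all(df_sds > 0),
            is.null(score_df_correlation) || abs(score_df_correlation) < 1)
  list(n = as.integer(n), score_means = score_means, score_sds = score_sds,
       df_means = df_means, df_sds = df_sds,
       score_df_correlation = score_df_correlation, seed = seed)
}

# Solve the within-group latent correlation such that the whole-cohort
# Pearson correlation between score and pre-test probability matches the
# target: total covariance = weighted within-group covariance + covariance
# of the group means. Truncation effects are ignored (small).
.solve_within_r <- function(p) {
  if (is.null(p$score_df_correlation)) return(0)
  w <- p$n / sum(p$n)
  ms <- sum(w * p$score_means); md <- sum(w * p$df_means)
  var_s <- sum(w * p$score_sds^2) + sum(w * (p$score_means - ms)^2)
  var_d <- sum(w * p$df_sds^2) + sum(w * (p$df_means - md)^2)
  cov_between <- sum(w * (p$score_means - ms) * (p$df_means - md))
  need <- p$score_df_correlation * sqrt(var_s * var_d) - cov_between
  r <- need / sum(w * p$score_sds * p$df_sds)
  if (abs(r) >= 1)
    stop("infeasible correlation target for the given group margins",
         call. = FALSE)
  r
}

.rtruncnorm <- function(u, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, length(u)))
  a <- stats::pnorm((lo - mean) / sd); b <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(a + u * (b - a))
}

# Chest-pain and sex frequencies per disease group (validation cohort,
# Table-1-style): rows non_cad / non_obstructive / obstructive.
.covariate_freqs <- function() {
  list(
    chest_pain = rbind(
      non_cad         = c(non_anginal = 20, atypical = 70, typical = 34),
      non_obstructive = c(non_anginal = 8, atypical = 19, typical = 14),
      obstructive     = c(non_anginal = 8, atypical = 12, typical = 43)
    ),
    male = c(non_cad = 0.41, non_obstructive = 0.54, obstructive = 0.76),
    cacs_group = rbind(
      non_cad         = c(zero = 70, low = 47, high = 6),
      non_obstructive = c(zero = 2, low = 22, high = 17),
      obstructive     = c(zero = 2, low = 23, high = 36)
    )
  )
}

#' Simulate a patient cohort calibrated to the printed group distributions
#'
#' Per disease group, draws acoustic scores and pre-test probabilities from
#' a Gaussian copula whose latent correlation is moment-matched so the
#' whole-cohort Pearson correlation hits the target (the group-mean structure
#' already contributes part of it). Scores and probabilities are truncated to
#' their natural ranges by inverse-CDF sampling. Age, sex, and chest-pain
#' covariates are back-filled consistently with the drawn pre-test
#' probability (age solved from the logistic pre-test model given drawn sex
#' and symptom type), and a calcium-score group and value are attached.
#'
#' @param params A [cohort_params()] list.
#' @param truncate Truncate scores to \[0, 100\] (and probabilities to
#'   \[0.5, 99.5\]); `FALSE` draws plain normals.
#' @param coeffs Pre-test model coefficient table for the age back-fill, see
#'   [df_coefficients()].
#' @return Tibble with `subject_id`, `age`, `sex`, `chest_pain`, `cacs`,
#'   `cacs_group`, `df_probability` (%), `cad_score` (points), `disease`
#'   (`non_cad` / `non_obstructive` / `obstructive`); the seed is kept in
#'   attribute `"seed"`.
#' @export
simulate_cohort <- function(params = cohort_params(), truncate = TRUE,
                            coeffs = df_coefficients()) {
  r_within <- .solve_within_r(params)
  groups <- c("non_cad", "non_obstructive", "obstructive")
  fr <- .covariate_freqs()
  .with_seed(params$seed, {
    rows <- lapply(1:3, function(g) {
      ng <- params$n[g]
      z1 <- stats::rnorm(ng)
      z2 <- r_within * z1 + sqrt(1 - r_within^2) * stats::rnorm(ng)
      if (truncate) {
        score <- .rtruncnorm(stats::pnorm(z1), params$score_means[g],
                             params$score_sds[g], 0, 100)
        df <- .rtruncnorm(stats::pnorm(z2), params$df_means[g],
                          params$df_sds[g], 0.5, 99.5)
      } else {
        score <- params$score_means[g] + params$score_sds[g] * z1
        df <- params$df_means[g] + params$df_sds[g] * z2
      }
      cp_lv <- colnames(fr$chest_pain)
      cp <- sample(cp_lv, ng, replace = TRUE, prob = fr$chest_pain[g, ])
      male <- stats::runif(ng) < fr$male[g]
      cg_lv <- colnames(fr$cacs_group)
      cg <- sample(cg_lv, ng, replace = TRUE, prob = fr$cacs_group[g, ])
      cacs <- ifelse(cg == "zero", 0,
                     ifelse(cg == "low", stats::runif(ng, 1, 399),
                            400 * exp(stats::rexp(ng, rate = 1))))
      # back-fill age from the pre-test logistic given sex and symptoms
      lin <- stats::qlogis(pmin(pmax(df / 100, 0.002), 0.998))
      b_pain <- coeffs$chest_pain[cp]
      age <- (lin - coeffs$intercept - ifelse(male, coeffs$male, 0) - b_pain) /
        coeffs$age
      tibble::tibble(
        age = pmin(pmax(round(age), 18), 110),
        sex = ifelse(male, "male", "female"),
        chest_pain = cp, cacs = round(cacs, 1), cacs_group = cg,
        df_probability = df, cad_score = score, disease = groups[g]
      )
    })
    out <- dplyr::bind_rows(rows)
  })
  out <- dplyr::mutate(out,
                       subject_id = sprintf("pt%03d", dplyr::row_number()),
                       .before = 1)
  attr(out, "seed") <- params$seed
  out
}

#' Draw group acoustic scores from the printed distributions only
#'
#' Convenience generator for distribution-level experiments: plain normal
#' draws of the acoustic score for the three disease groups, no covariates,
#' no truncation.
#'
#' @param params A [cohort_params()] list (only `n`, `score_means`,
#'   `score_sds`, `seed` are used).
#' @return Tibble with `cad_score`, `disease`, and logical `event`
#'   (obstructive vs all others).
#' @export
simulate_score_groups <- function(params = cohort_params()) {
  groups <- c("non_cad", "non_obstructive", "obstructive")
  .with_seed(params$seed, {
    score <- unlist(lapply(1:3, function(g) {
      stats::rnorm(params$n[g], params$score_means[g], params$score_sds[g])
    }))
  })
  disease <- rep(groups, params$n)
  tibble::tibble(cad_score = score, disease = disease,
                 event = disease == "obstructive")
}

#' Simulate a feature-level cohort for discriminant experiments
#'
#' Draws the four acoustic features from class-conditional Gaussians with a
#' standardized mean shift per feature in the diseased class. Used to
#' exercise training, scoring, and cross-validation without audio synthesis.
#' The default shift of 0.4 SD per feature yields a class separation
#' comparable to the clinically observed score distributions (AUC ~ 0.72).
#'
#' @param n_healthy,n_diseased Group sizes.
#' @param delta Standardized mean shift per feature (length 1 or 4, order
#'   fpr, pcaspec, ami, s4amp).
#' @param seed RNG seed.
#' @return Tibble with `fpr`, `pcaspec`, `ami`, `s4amp`,
#'   `short_diastasis = FALSE`, and logical `event`.
#' @export
simulate_feature_cohort <- function(n_healthy = 165, n_diseased = 63,
                                    delta = 0.4, seed = 1) {
  delta <- rep(delta, length.out = 4)
  mu0 <- c(fpr = -0.8, pcaspec = 0, ami = 0.6, s4amp = 0.12)
  sd0 <- c(fpr = 0.3, pcaspec = 4, ami = 0.2, s4amp = 0.06)
  n <- n_healthy + n_diseased
  event <- rep(c(FALSE, TRUE), c(n_healthy, n_diseased))
  .with_seed(seed, {
    X <- sapply(1:4, function(j) {
      stats::rnorm(n, mu0[j] + event * delta[j] * sd0[j], sd0[j])
    })
  })
  colnames(X) <- names(mu0)
  out <- tibble::as_tibble(X)
  out$short_diastasis <- FALSE
  out$event <- event
  out
}
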