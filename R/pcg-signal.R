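#' Phonocardiogram recording object
#'
#' Container for a single-channel heart-sound recording: the sampled waveform,
#' its acquisition metadata, and optional breath-hold annotations. The nominal
#' acquisition protocol is a 3-minute recording from the 4th left intercostal
#' space with four 7.5 s breath holds; shorter recordings are accepted.
#'
#' @param samples Numeric waveform in arbitrary linear units.
#' @param sample_rate Sampling rate in Hz; must be at least 2000 Hz so that
#'   spectral content up to 1000 Hz is resolved.
#' @param subject_id Opaque subject identifier.
#' @param breath_hold_intervals Optional two-column matrix or list of
#'   `c(start_s, end_s)` pairs, within the recording and non-overlapping.
#' @return An object of class `pcg_recording` with fields `samples`,
#'   `sample_rate`, `duration`, `subject_id`, `breath_hold_intervals`.
#' @export
pcg_recording <- function(samples, sample_rate, subject_id = "anon",
                          breath_hold_intervals = NULL) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  if (sample_rate < 2000)
    stop("sample_rate must be >= 2000 Hz to resolve 1000 Hz content",
         call. = FALSE)
  duration <- length(samples) / sample_rate
  if (!is.null(breath_hold_intervals)) {
    bh <- do.call(rbind, lapply(breath_hold_intervals, function(x) x[1:2]))
    if (any(bh < 0) || any(bh > duration) || any(bh[, 2] <= bh[, 1]))
      stop("breath-hold intervals must lie within [0, duration]", call. = FALSE)
    o <- order(bh[, 1])
    if (nrow(bh) > 1 && any(bh[o, 1][-1] < bh[o, 2][-nrow(bh)]))
      stop("breath-hold intervals must not overlap", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         duration = duration, subject_id = subject_id,
         breath_hold_intervals = breath_hold_intervals),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> subject '%s': %.1f s @ %d Hz (%d samples)\n",
              x$subject_id, x$duration, as.integer(x$sample_rate),
              length(x$samples)))
  invisible(x)
}

#' Read a phonocardiogram from a WAV file
#'
#' Loads a PCM (16/24-bit) or float WAV file, keeps the first channel,
#' normalizes the amplitude scale to \[-1, 1\], and optionally attaches subject
#' metadata from a YAML/JSON sidecar with fields `subject_id` and
#' `breath_hold_intervals`.
#'
#' @param path Path to the WAV file.
#' @param metadata Optional path to a YAML (`.yml`/`.yaml`) or JSON sidecar.
#' @return A [pcg_recording].
#' @export
read_recording <- function(path, metadata = NULL) {
  wav <- read_wav(path)
  if (wav$sample_rate < 2000)
    stop("unsupported sample rate ", wav$sample_rate,
         " Hz (need >= 2000 Hz)", call. = FALSE)
  subject_id <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  bh <- NULL
  if (!is.null(metadata)) {
    meta <- if (grepl("\\.ya?ml$", metadata, ignore.case = TRUE)) {
      yaml::read_yaml(metadata)
    } else {
      jsonlite::read_json(metadata, simplifyVector = TRUE)
    }
    if (!is.null(meta$subject_id)) subject_id <- meta$subject_id
    if (!is.null(meta$breath_hold_intervals)) {
      bhm <- meta$breath_hold_intervals
      if (is.matrix(bhm) || is.data.frame(bhm)) {
        bh <- lapply(seq_len(nrow(bhm)), function(i) as.numeric(bhm[i, 1:2]))
      } else {
        bh <- lapply(bhm, as.numeric)
      }
    }
  }
  pcg_recording(wav$samples, wav$sample_rate, subject_id = subject_id,
                breath_hold_intervals = bh)
}

#' Zero-phase band-pass filtering
#'
#' Band-limits the waveform to the analysis band (20-1000 Hz by default, the
#' standard range for diastolic heart-sound analysis) with a zero-phase FFT
#' mask whose edges are raised-cosine ramps: the lower ramp spans the half
#' octave below `low_hz`, the upper ramp 10 % above `high_hz`. The smooth,
#' reasonably wide ramps keep the filter's impulse response short, so the
#' loud valve sounds do not ring into the quiet diastolic floor; the mask is
#' exactly phase-free (envelope timing, on which the landmark detector
#' depends, is untouched), re-applying the filter is idempotent up to the
#' ramps, and attenuation one octave outside the band is total.
#'
#' @param rec A [pcg_recording].
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @return A filtered [pcg_recording].
#' @export
bandlimit <- function(rec, low_hz = 20, high_hz = 1000) {
  fs <- rec$sample_rate
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("band must satisfy 0 < low < high < Nyquist (", fs / 2, " Hz)",
         call. = FALSE)
  n <- length(rec$samples)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided spectrum folded to [0, fs/2]
  lo0 <- low_hz / 2
  hi1 <- min(high_hz * 1.1, (high_hz + fs / 2) / 2)
  mask <- numeric(n)
  mask[f >= low_hz & f <= high_hz] <- 1
  ramp_lo <- f > lo0 & f < low_hz
  mask[ramp_lo] <- 0.5 - 0.5 * cos(pi * (f[ramp_lo] - lo0) / (low_hz - lo0))
  ramp_hi <- f > high_hz & f < hi1
  mask[ramp_hi] <- 0.5 + 0.5 * cos(pi * (f[ramp_hi] - high_hz) /
                                     (hi1 - high_hz))
  out <- rec
  out$samples <- Re(stats::fft(stats::fft(rec$samples) * mask,
                               inverse = TRUE) / n)
  out
}

#' Resample a recording to the internal analysis rate
#'
#' All spectral analysis runs on a single 8000 Hz grid; recordings at other
#' rates are resampled here (polyphase when the ratio is rational with small
#' terms, linear interpolation otherwise).
#'
#' @param rec A [pcg_recording].
#' @param target_rate Target rate in Hz.
#' @return A [pcg_recording] at `target_rate`.
#' @export
resample_recording <- function(rec, target_rate = 8000) {
  if (rec$sample_rate == target_rate) return(rec)
  r <- target_rate / rec$sample_rate
  fr <- .rational_approx(r)
  out <- rec
  if (!is.null(fr)) {
    out$samples <- as.numeric(signal::resample(rec$samples, fr[1], fr[2]))
  } else {
    t_old <- seq(0, rec$duration, length.out = length(rec$samples))
    n_new <- round(rec$duration * target_rate)
    out$samples <- stats::approx(t_old, rec$samples,
                                 xout = seq(0, rec$duration, length.out = n_new))$y
  }
  out$sample_rate <- target_rate
  out$duration <- length(out$samples) / target_rate
  out
}

.rational_approx <- function(r, max_den = 64L) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  NULL
}

#' Amplitude envelope via the analytic signal
#'
#' Band-passes the waveform, takes the Hilbert (analytic-signal) magnitude,
#' and smooths with a moving average.
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate (Hz).
#' @param band Length-2 band in Hz, or NULL for no filtering.
#' @param smooth_s Moving-average length in seconds.
#' @return Numeric envelope, same length as `x`.
#' @keywords internal
envelope <- function(x, fs, band = NULL, smooth_s = 0.02) {
  if (!is.null(band)) {
    bf <- signal::butter(4, band / (fs / 2), type = "pass")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  if (smooth_s > 0) {
    w <- max(1L, round(smooth_s * fs))
    env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
    env[is.na(env)] <- 0
  }
  env
}

#' Recording-level quality assessment
#'
#' Reproduces the three recording-exclusion labels used in clinical deployment
#' of acoustic CAD scoring: arrhythmia/tachycardia, excess noise, and
#' too-weak heart signal. The named gates are quantified as:
#' \itemize{
#'   \item `arrhythmia`: RR coefficient of variation above `rr_cv_max`
#'     (default 0.12) or heart rate above `max_bpm` (default 85 bpm);
#'   \item `excess_noise`: more than `noisy_fraction_max` (default 0.5) of
#'     candidate diastasis windows have mean broadband envelope power above
#'     4x the median envelope power of the whole recording;
#'   \item `weak_signal`: median S1 envelope peak less than `s1_snr_min_db`
#'     (default 6 dB) above the recording's median envelope level.
#' }
#'
#' @param rec A [pcg_recording] (band-limited).
#' @param cycles Cycle table from [detect_cycles()] on the same recording.
#' @param config Named list overriding `max_bpm`, `rr_cv_max`,
#'   `noisy_fraction_max`, `noise_power_factor`, `s1_snr_min_db`.
#' @return One-row tibble: `status` (`ok`, `arrhythmia`, `excess_noise`,
#'   `weak_signal`), `heart_rate_bpm`, `rr_cv`, `noisy_window_fraction`,
#'   `s1_snr_db`.
#' @export
assess_quality <- function(rec, cycles, config = list()) {
  cfg <- utils::modifyList(list(
    max_bpm = 85, rr_cv_max = 0.12, noisy_fraction_max = 0.5,
    noise_power_factor = 4, s1_snr_min_db = 6
  ), config)
  if (nrow(cycles) < 10)
    stop("insufficient data: need at least 10 cardiac cycles, got ",
         nrow(cycles), call. = FALSE)

  rr <- cycles$rr_interval
  heart_rate_bpm <- 60 / stats::median(rr)
  rr_cv <- stats::sd(rr) / mean(rr)

  fs <- rec$sample_rate
  env <- envelope(rec$samples, fs, band = c(20, 1000), smooth_s = 0.02)
  env_pow <- env^2
  med_pow <- stats::median(env_pow)

  wins <- diastasis_windows(rec, cycles)
  noisy_frac <- if (nrow(wins) == 0) 0 else {
    wpow <- vapply(seq_len(nrow(wins)), function(i) {
      i0 <- max(1L, round(wins$start[i] * fs)); i1 <- min(length(env_pow), round(wins$end[i] * fs))
      if (i1 <= i0) return(med_pow)
      mean(env_pow[i0:i1])
    }, numeric(1))
    mean(wpow > cfg$noise_power_factor * med_pow)
  }

  s1_peaks <- vapply(seq_len(nrow(cycles)), function(i) {
    i0 <- max(1L, round((cycles$s1_onset[i] - 0.05) * fs))
    i1 <- min(length(env), round((cycles$s1_onset[i] + 0.05) * fs))
    max(env[i0:i1])
  }, numeric(1))
  s1_snr_db <- 20 * log10(stats::median(s1_peaks) / max(stats::median(env), 1e-12))

  status <- if (heart_rate_bpm > cfg$max_bpm || rr_cv > cfg$rr_cv_max) {
    "arrhythmia"
  } else if (noisy_frac > cfg$noisy_fraction_max) {
    "excess_noise"
  } else if (s1_snr_db < cfg$s1_snr_min_db) {
    "weak_signal"
  } else "ok"

  tibble::tibble(status = status, heart_rate_bpm = heart_rate_bpm,
                 rr_cv = rr_cv, noisy_window_fraction = noisy_frac,
                 s1_snr_db = s1_snr_db)
}
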