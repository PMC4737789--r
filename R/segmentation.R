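#' Default segmentation parameters
#'
#' Landmark-detector and window-placement constants. All times in seconds,
#' relative to recording start; windows are half-open `[start, end)`.
#'
#' @return Named list of defaults.
#' @export
segmentation_config <- function() {
  list(
    s1s2_band = c(30, 150),     # Hz, envelope band for the loud valve sounds
    s34_band = c(20, 60),       # Hz, envelope band for the soft diastolic sounds
    peak_height_frac = 0.45,    # S1/S2 peak gate vs 95th pct of candidate peaks
    s34_local_factor = 4,       # S3/S4 gate vs local diastolic envelope median
    s3_duration = 0.06,         # s, nominal S3 length appended to its onset
    no_s3_fraction = 0.15,      # diastasis start at s2 + this * RR when no S3
    pre_s1_guard = 0.05,        # s, window ends this early when no S4 found
    short_threshold = 0.128,    # s, minimum window for spectral features
    min_duration = 10           # s, minimum analyzable recording
  )
}

.find_peaks <- function(x, min_dist, min_height = -Inf) {
  d <- diff(x)
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  idx <- idx[x[idx] >= min_height]
  if (length(idx) == 0) return(integer(0))
  idx <- idx[order(x[idx], decreasing = TRUE)]
  keep <- integer(0)
  for (i in idx) {
    if (all(abs(i - keep) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Detect cardiac cycles from a phonocardiogram
#'
#' ECG-free cycle detection: a smoothed Hilbert envelope in the 30-150 Hz band
#' isolates the loud valve sounds; the dominant beat period is estimated by
#' autocorrelation of that envelope over lags corresponding to 40-120 bpm;
#' peaks are then picked with a minimum separation tied to the period, and
#' S1/S2 are disambiguated by interval ordering (the S1-to-S2 interval,
#' systole, is the shorter intra-beat interval). The soft diastolic sounds S3
#' and S4 are searched in a 20-60 Hz envelope inside physiologic sub-windows
#' of each diastole and marked present only when an interior envelope peak
#' exceeds `s34_local_factor` times the median low-band envelope of that
#' beat's diastole (a local baseline, so murmur energy does not mask them).
#'
#' @param rec A band-limited [pcg_recording].
#' @param config Overrides of [segmentation_config()] entries.
#' @return A tibble with one row per cycle: `cycle`, `s1_onset`, `s2_onset`,
#'   `s3_onset`, `s4_onset` (NA when not detected), `next_s1_onset`,
#'   `rr_interval`. Times are envelope-peak times in seconds.
#' @export
detect_cycles <- function(rec, config = list()) {
  cfg <- utils::modifyList(segmentation_config(), config)
  if (rec$duration < cfg$min_duration)
    stop("recording too short for cycle detection (need >= ",
         cfg$min_duration, " s)", call. = FALSE)
  fs <- rec$sample_rate
  env <- envelope(rec$samples, fs, band = cfg$s1s2_band, smooth_s = 0.02)

  # beat period by autocorrelation of the envelope decimated to 200 Hz
  # (5 ms resolution is ample for a rate estimate), 40-120 bpm
  fs_ds <- 200
  env_ds <- env[seq(1L, length(env), by = max(1L, round(fs / fs_ds)))]
  lag_min <- round(0.5 * fs_ds); lag_max <- round(1.5 * fs_ds)
  ac <- stats::acf(env_ds, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  seg <- ac[(lag_min + 1):(lag_max + 1)]
  if (all(!is.finite(seg)) || max(seg, na.rm = TRUE) <= 0)
    stop("segmentation failure: no periodicity found in 40-120 bpm",
         call. = FALSE)
  rr_est <- (lag_min + which.max(seg) - 1) / fs_ds

  cand <- .find_peaks(env, min_dist = round(0.18 * fs))
  if (length(cand) < 4)
    stop("segmentation failure: too few envelope peaks", call. = FALSE)
  thr <- cfg$peak_height_frac * stats::quantile(env[cand], 0.95)
  pk <- cand[env[cand] >= thr]
  if (length(pk) < 4)
    stop("segmentation failure: too few heart-sound peaks", call. = FALSE)

  # S1/S2 alternation: the shorter of the two alternating gaps is systole
  tpk <- pk / fs
  gaps <- diff(tpk)
  odd <- mean(gaps[seq(1, length(gaps), by = 2)])
  even <- mean(gaps[seq_len(length(gaps)) %% 2 == 0])
  first_is_s1 <- odd < even
  s1_idx <- if (first_is_s1) seq(1, length(pk), by = 2) else seq(2, length(pk), by = 2)
  s1_t <- tpk[s1_idx]
  if (length(s1_t) < 2)
    stop("segmentation failure: fewer than two S1 candidates", call. = FALSE)
  rr_med <- stats::median(diff(s1_t))
  if (rr_med < 0.5 || rr_med > 1.5)
    stop("segmentation failure: no periodicity found in 40-120 bpm",
         call. = FALSE)

  env34 <- envelope(rec$samples, fs, band = cfg$s34_band, smooth_s = 0.01)

  # candidate peak inside [t0, t1], gated against the local diastolic
  # background [b0, b1] so diastolic murmur energy does not mask S3/S4;
  # only interior local maxima that dominate the region's right edge count
  # (the narrowband envelope of the upcoming S1 rises monotonically there)
  peak_in <- function(t0, t1, b0, b1) {
    i0 <- max(1L, round(t0 * fs)); i1 <- min(length(env34), round(t1 * fs))
    if (i1 - i0 < 3) return(c(NA_real_, -Inf))
    j0 <- max(1L, round(b0 * fs)); j1 <- min(length(env34), round(b1 * fs))
    local_med <- stats::median(env34[j0:j1])
    loc <- .find_peaks(env34[i0:i1], min_dist = round(0.03 * fs))
    if (length(loc) == 0) return(c(NA_real_, -Inf))
    j <- loc[which.max(env34[i0 + loc - 1])]
    pk <- env34[i0 + j - 1]
    if (pk > cfg$s34_local_factor * local_med && pk > env34[i1]) {
      c((i0 + j - 1) / fs, pk)
    } else c(NA_real_, pk)
  }

  rows <- lapply(seq_len(length(s1_t) - 1L), function(k) {
    s1 <- s1_t[k]; ns1 <- s1_t[k + 1L]
    s2_cand <- tpk[tpk > s1 + 0.1 & tpk < ns1 - 0.15]
    if (length(s2_cand) == 0) return(NULL)
    s2 <- s2_cand[1]
    s4p <- peak_in(ns1 - 0.20, ns1 - 0.06, s2 + 0.05, ns1 - 0.03)
    s4 <- s4p[1]
    s3_hi <- min(s2 + 0.30, if (is.na(s4)) ns1 - 0.22 else s4 - 0.03)
    s3p <- peak_in(s2 + 0.08, s3_hi, s2 + 0.05, ns1 - 0.03)
    s3 <- s3p[1]
    tibble::tibble(s1_onset = s1, s2_onset = s2, s3_onset = s3,
                   s4_onset = s4, next_s1_onset = ns1,
                   rr_interval = ns1 - s1)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    stop("segmentation failure: no complete cycles", call. = FALSE)
  dplyr::mutate(out, cycle = dplyr::row_number(), .before = 1)
}

#' Locate the diastasis analysis window of one cycle
#'
#' The analysis window is the quiescent mid-diastolic interval between the
#' third and fourth heart sounds. Start is the end of S3 (its onset plus the
#' nominal S3 duration) when S3 was detected, otherwise `s2 + 0.15 * RR`
#' (mid-diastole placement). End is the S4 onset when S4 was detected,
#' otherwise 50 ms before the next S1. Windows shorter than 128 ms are
#' flagged `short_diastasis`: they carry too little signal for the spectral
#' measures and route the subject to the reduced score.
#'
#' @param cycle One row of the [detect_cycles()] table.
#' @param rec The corresponding [pcg_recording].
#' @param config Overrides of [segmentation_config()] entries.
#' @return One-row tibble: `cycle`, `start`, `end`, `duration`,
#'   `short_diastasis`, and the waveform segment in list-column `samples`.
#' @export
locate_diastasis <- function(cycle, rec, config = list()) {
  cfg <- utils::modifyList(segmentation_config(), config)
  start <- if (!is.na(cycle$s3_onset)) {
    cycle$s3_onset + cfg$s3_duration
  } else {
    cycle$s2_onset + cfg$no_s3_fraction * cycle$rr_interval
  }
  end <- if (!is.na(cycle$s4_onset)) {
    cycle$s4_onset
  } else {
    cycle$next_s1_onset - cfg$pre_s1_guard
  }
  if (end <= start)
    stop("degenerate diastasis window (end <= start) in cycle ",
         cycle$cycle, call. = FALSE)
  fs <- rec$sample_rate
  i0 <- max(1L, round(start * fs) + 1L)
  i1 <- min(length(rec$samples), round(end * fs))
  tibble::tibble(
    cycle = cycle$cycle, start = start, end = end, duration = end - start,
    short_diastasis = (end - start) < cfg$short_threshold,
    samples = list(rec$samples[i0:i1])
  )
}

#' Extract all diastasis windows of a recording
#'
#' Applies [locate_diastasis()] to every detected cycle; cycles with
#' degenerate (non-positive) windows are skipped with a message.
#'
#' @inheritParams locate_diastasis
#' @param cycles Cycle table from [detect_cycles()].
#' @return Tibble of accepted windows (possibly zero rows).
#' @export
diastasis_windows <- function(rec, cycles, config = list()) {
  rows <- lapply(seq_len(nrow(cycles)), function(i) {
    tryCatch(locate_diastasis(cycles[i, ], rec, config),
             error = function(e) {
               message("skipping cycle ", cycles$cycle[i], ": ",
                       conditionMessage(e))
               NULL
             })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(cycle = integer(), start = numeric(),
                          end = numeric(), duration = numeric(),
                          short_diastasis = logical(), samples = list())
  }
  out
}

#' Export landmarks and windows as an audio-annotation label file
#'
#' Writes a three-column tab-separated file (start, end, label) readable by
#' common audio annotation viewers.
#'
#' @param cycles Cycle table from [detect_cycles()].
#' @param windows Window table from [diastasis_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(cycles, windows, path) {
  lab <- function(t, label, dur = 0.02) {
    tibble::tibble(start = t, end = t + dur, label = label)
  }
  out <- dplyr::bind_rows(
    lab(cycles$s1_onset, "S1"), lab(cycles$s2_onset, "S2"),
    lab(cycles$s3_onset[!is.na(cycles$s3_onset)], "S3"),
    lab(cycles$s4_onset[!is.na(cycles$s4_onset)], "S4"),
    tibble::tibble(start = windows$start, end = windows$end,
                   label = ifelse(windows$short_diastasis,
                                  "diastasis_short", "diastasis"))
  )
  out <- dplyr::arrange(out, .data$start)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
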