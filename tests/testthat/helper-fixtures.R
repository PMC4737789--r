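# Shared fixtures for the test suite. Everything is generated in code;
# recordings are kept short to bound runtime.

quiet_features <- function(rec, ...) {
  suppressMessages(extract_features(rec, ...))
}

# A clean 60 bpm subject reused across files.
fixture_sim60 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_pcg(subject_params(heart_rate_bpm = 60, seed = 101),
                             duration_s = 20)
    cache
  }
})

# Hand-built flat power spectrum on the analysis grid (8 kHz, 1024-point).
flat_spectrum <- function(level_db = -40, fs = 8000, nseg = 1024) {
  freq <- (0:(nseg / 2)) * fs / nseg
  keep <- freq >= 20 & freq <= 1000
  out <- tibble::tibble(freq = freq[keep],
                        power_db = rep(level_db, sum(keep)))
  structure(out, n_windows = 1L, sample_rate = fs, df = fs / nseg,
            class = c("pcg_spectrum", class(out)))
}

# Independent pair-counting AUC oracle (ties count one half).
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exhaustive cut-point oracle: every midpoint between consecutive sorted
# scores, maximize sensitivity x specificity, ties to the lowest threshold.
liu_oracle <- function(scores, labels) {
  s <- sort(scores)
  cand <- unique((s[-1] + s[-length(s)]) / 2)
  best_th <- NA_real_; best <- -Inf
  for (th in cand) {
    pr <- mean(scores[labels] > th) * mean(scores[!labels] <= th)
    if (pr > best + 1e-12) { best <- pr; best_th <- th }
  }
  list(threshold = best_th, product = best)
}

# Stereo 16-bit PCM WAV writer used to test first-channel extraction.
write_stereo_wav <- function(left, right, path, sample_rate) {
  inter <- as.integer(round(pmin(pmax(
    as.vector(rbind(left, right)), -1), 1) * 32767))
  data_size <- length(inter) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  invisible(path)
}
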