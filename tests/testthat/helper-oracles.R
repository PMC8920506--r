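# Independent oracles, written against the math rather than the package
# implementation, used to freeze expected values in the tests.

# direct convolution oracle: place `count` spikes at stimFrame (1-based)
# and convolve explicitly with a double-exponential kernel normalised to
# unit sampled peak; returns the full noiseless dF/F0 series
oracleCalciumSignal <- function(count, rise, decay, amp, dt, nFrames,
                                stimFrame) {
  tgrid <- (seq_len(nFrames) - 1) * dt
  h <- exp(-tgrid / decay) - exp(-tgrid / rise)
  h <- h / max(h)
  sig <- rep(0, nFrames)
  for (f in seq_len(nFrames)) {
    lag <- f - stimFrame
    if (lag >= 0) sig[f] <- count * amp * h[lag + 1]
  }
  sig
}

# explicit superposition oracle for a synaptic train: sum of
# difference-of-exponential responses, each normalised to unit sampled
# peak, at the given onset times and amplitudes
oracleTrain <- function(times, amps, riseS, decayS, dt, n) {
  tgrid <- (seq_len(n) - 1) * dt
  h <- exp(-tgrid / decayS) - exp(-tgrid / riseS)
  h <- h / max(h)
  y <- rep(0, n)
  for (j in seq_along(times)) {
    i0 <- round(times[j] / dt) + 1
    idx <- i0:n
    y[idx] <- y[idx] + amps[j] * h[seq_along(idx)]
  }
  y
}

# brute-force Monte-Carlo oracle for the activation false-positive rate:
# simulates pure-noise traces and pushes them through zero-phase low-pass
# filtering (applied exactly as the squared magnitude response in the
# frequency domain, the ideal forward-backward filter), baseline dF/F0,
# max-over-window and the mean + 3 SD rule written out inline
oracleNoiseFpr <- function(nReps, nFrames, baselineFrames, stimFrame,
                           cutoffHz, fs, noiseSd, seed) {
  set.seed(seed)
  bf <- signal::butter(4, cutoffHz / (fs / 2), type = "low")
  w <- 2 * pi * (0:(nFrames - 1)) / nFrames
  ejw <- exp(-1i * outer(w, 0:4))
  H <- as.numeric(Mod((ejw %*% bf$b) / (ejw %*% bf$a))^2)
  hits <- 0L
  for (r in seq_len(nReps)) {
    f <- 100 * (1 + rnorm(nFrames, 0, noiseSd))
    ff <- Re(stats::fft(stats::fft(f) * H, inverse = TRUE)) / nFrames
    f0 <- mean(ff[seq_len(baselineFrames)])
    dff <- (ff - f0) / f0
    base <- dff[seq_len(baselineFrames)]
    win <- dff[stimFrame:nFrames]
    # local maxima within the window
    w <- win[2:(length(win) - 1)]
    pk <- w[w >= win[1:(length(win) - 2)] & w > win[3:length(win)]]
    if (length(pk) && max(pk) > mean(base) + 3 * sd(base)) hits <- hits + 1L
  }
  hits / nReps
}

# closed-form paired t-test on a vector of differences
oraclePairedT <- function(diffs) {
  n <- length(diffs)
  tstat <- mean(diffs) / (sd(diffs) / sqrt(n))
  list(statistic = tstat, p = 2 * pt(abs(tstat), n - 1, lower.tail = FALSE))
}

# small helper used across tests
expect_rel <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected) / max(abs(expected),
                                                   .Machine$double.eps),
                      tol)
}
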