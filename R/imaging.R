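# Trace -> dF/F0 -> peak detection -> activation calls -> field summaries.

#' Compute dF/F0 from a raw fluorescence trace
#'
#' The mean of the first \code{baselineFrames} samples is the baseline F0;
#' the output is (F - F0) / F0, preserving length. Invariant to
#' multiplicative rescaling of the raw trace.
#'
#' @param trace numeric fluorescence vector (or matrix, cells x frames)
#' @param baselineFrames number of leading baseline frames (default 50)
#' @return dF/F0 series (same shape as input)
#' @examples
#' computeDFF(c(rep(100, 50), rep(150, 10)))[60]
#' @export
computeDFF <- function(trace, baselineFrames = 50) {
  if (baselineFrames < 2) stop("baselineFrames must be >= 2")
  if (is.matrix(trace)) {
    if (ncol(trace) < baselineFrames)
      stop("trace shorter than the baseline window")
    f0 <- rowMeans(trace[, seq_len(baselineFrames), drop = FALSE])
    if (any(f0 <= 0)) stop("degenerate baseline: nonpositive baseline mean")
    return(sweep(sweep(trace, 1, f0, "-"), 1, f0, "/"))
  }
  if (length(trace) < baselineFrames)
    stop("trace shorter than the baseline window")
  f0 <- mean(trace[seq_len(baselineFrames)])
  if (f0 <= 0) stop("degenerate baseline: nonpositive baseline mean")
  (trace - f0) / f0
}

#' Zero-phase low-pass filter
#'
#' 4-pole Butterworth applied forward and backward
#' (\code{signal::filtfilt}), so the result is zero-phase with unit DC gain.
#'
#' @param series numeric vector
#' @param cutoffHz cutoff frequency; must lie strictly below Nyquist
#' @param sampleHz sampling rate of the series
#' @param order filter order (default 4)
#' @return filtered series, same length
#' @export
lowpass <- function(series, cutoffHz, sampleHz, order = 4) {
  n <- length(series)
  if (n == 0) stop("empty series")
  nyq <- sampleHz / 2
  if (cutoffHz <= 0 || cutoffHz >= nyq)
    stop("cutoffHz must lie in (0, Nyquist)")
  bf <- signal::butter(order, cutoffHz / nyq, type = "low")
  if (n < 5) return(as.numeric(signal::filtfilt(bf, series)))
  # mirror-pad so the forward/backward passes start from settled state
  pad <- min(n - 1, max(3 * order, ceiling(10 * sampleHz / cutoffHz)))
  x <- c(2 * series[1] - series[(pad + 1):2],
         series,
         2 * series[n] - series[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, x))
  y[(pad + 1):(pad + n)]
}

#' Detect local maxima of a dF/F0 series within a window
#'
#' @param dff numeric dF/F0 series
#' @param searchWindow integer vector of frame indices to search (must lie
#'   within the trace)
#' @return data.frame with columns \code{frame} and \code{amplitude},
#'   ordered by frame; zero rows if the window contains no local maximum
#' @export
detectPeaks <- function(dff, searchWindow = seq_along(dff)) {
  if (length(searchWindow) == 0) stop("empty search window")
  if (min(searchWindow) < 1 || max(searchWindow) > length(dff))
    stop("search window outside trace")
  n <- length(dff)
  idx <- searchWindow[searchWindow >= 2 & searchWindow <= n - 1]
  isMax <- dff[idx] > dff[idx - 1] & dff[idx] >= dff[idx + 1]
  pk <- idx[isMax]
  # window endpoints count if they dominate their single neighbour
  if (1 %in% searchWindow && n >= 2 && dff[1] > dff[2]) pk <- c(1, pk)
  if (n %in% searchWindow && n >= 2 && dff[n] > dff[n - 1]) pk <- c(pk, n)
  pk <- sort(unique(pk))
  data.frame(frame = pk, amplitude = dff[pk])
}

#' Classify a cell as activated by the mean + 3 SD peak rule
#'
#' A cell is active if its largest detected peak exceeds
#' \code{noiseMean + 3 * noiseSd}.
#'
#' @param peaks data.frame from \code{\link{detectPeaks}}
#' @param noiseMean,noiseSd noise statistics of the dF/F0 series (SD > 0)
#' @param nSd number of SDs above the mean defining significance (default 3)
#' @return list with \code{active} (logical) and \code{peak_dff}
#'   (largest peak amplitude; 0 if no peaks)
#' @export
classifyActive <- function(peaks, noiseMean, noiseSd, nSd = 3) {
  if (!is.finite(noiseSd) || noiseSd <= 0) stop("noiseSd must be positive")
  peakDff <- if (nrow(peaks)) max(peaks$amplitude) else 0
  list(active = nrow(peaks) > 0 && peakDff > noiseMean + nSd * noiseSd,
       peak_dff = peakDff)
}

#' Per-cell activation analysis of a TraceSet
#'
#' The imaging pipeline for one condition: raw traces are low-pass
#' filtered, converted to dF/F0 against the first-\code{baselineFrames}
#' baseline, peaks are searched from the stimulation frame to the end of
#' the trace, and cells are called active if the maximal peak exceeds the
#' mean + 3 SD of the noise. Noise statistics are estimated from the
#' pre-stimulus baseline of each cell's filtered dF/F0 by default, or from
#' all baselines pooled (\code{noiseScope = "field"}).
#'
#' @param ts a \linkS4class{TraceSet}
#' @param baselineFrames baseline window length (default 50)
#' @param cutoffHz low-pass cutoff (default 5 Hz); \code{NULL} disables
#'   filtering
#' @param noiseScope "cell" (default) or "field"
#' @param nSd significance multiple (default 3)
#' @param searchWindow frame indices to search; default stim frame to end
#' @return data.frame (one row per cell): hierarchy keys, \code{peak_dff},
#'   \code{active}, \code{noise_mean}, \code{noise_sd}, plus any ground
#'   truth columns present in the TraceSet
#' @export
analyzeTraces <- function(ts, baselineFrames = 50, cutoffHz = 5,
                          noiseScope = c("cell", "field"), nSd = 3,
                          searchWindow = NULL) {
  noiseScope <- match.arg(noiseScope)
  stopifnot(is(ts, "TraceSet"))
  f <- traces(ts)
  fs <- 1 / framePeriod(ts)
  sf <- stimFrame(ts)
  if (is.null(searchWindow)) searchWindow <- sf:ncol(f)
  filt <- if (is.null(cutoffHz)) t(f) else
    apply(f, 1, lowpass, cutoffHz = cutoffHz, sampleHz = fs)
  dff <- computeDFF(t(filt), baselineFrames)
  base <- dff[, seq_len(min(baselineFrames, sf - 1)), drop = FALSE]
  if (noiseScope == "cell") {
    nm <- rowMeans(base)
    nsd <- apply(base, 1, sd)
  } else {
    nm <- rep(mean(base), nrow(dff))
    nsd <- rep(sd(as.numeric(base)), nrow(dff))
  }
  res <- lapply(seq_len(nrow(dff)), function(i) {
    pk <- detectPeaks(dff[i, ], searchWindow)
    cl <- classifyActive(pk, nm[i], nsd[i], nSd)
    data.frame(peak_dff = cl$peak_dff, active = cl$active,
               noise_mean = nm[i], noise_sd = nsd[i])
  })
  out <- cbind(hierarchyKeys(ts), do.call(rbind, res))
  rd <- as.data.frame(SummarizedExperiment::rowData(ts))
  extra <- setdiff(colnames(rd), colnames(out))
  if (length(extra)) out <- cbind(out, rd[, extra, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Summarise activation over one imaging field
#'
#' Computes the proportion of activated cells under one of three
#' denominator rules: all cells, cells responding in the presence of
#' picrotoxin, or cells responding to the maximal stimulus delivered. The
#' two restricted modes require the matched reference responses.
#'
#' @param responses data.frame of per-cell responses (needs \code{cell},
#'   \code{active}, \code{peak_dff})
#' @param denominatorMode "all_cells", "responds_to_ptx" or
#'   "responds_to_max_stim"
#' @param referenceResponses per-cell responses under the reference
#'   condition (PTX or maximal stimulus); required for restricted modes and
#'   must cover the same cells
#' @return one-row data.frame: \code{n_denominator}, \code{n_active},
#'   \code{proportion}, \code{mean_amplitude} (active cells only),
#'   \code{denominator_mode}
#' @export
summarizeField <- function(responses,
                           denominatorMode = c("all_cells",
                                               "responds_to_ptx",
                                               "responds_to_max_stim"),
                           referenceResponses = NULL) {
  denominatorMode <- match.arg(denominatorMode)
  keep <- responses
  if (denominatorMode != "all_cells") {
    if (is.null(referenceResponses))
      stop("reference responses required for restricted denominator modes")
    if (!all(responses$cell %in% referenceResponses$cell))
      stop("cell keys of responses and reference do not match")
    refActive <- referenceResponses$cell[referenceResponses$active]
    keep <- responses[responses$cell %in% refActive, , drop = FALSE]
  }
  nDen <- nrow(keep)
  nAct <- sum(keep$active)
  data.frame(n_denominator = nDen, n_active = nAct,
             proportion = if (nDen > 0) nAct / nDen else NA_real_,
             mean_amplitude = if (nAct > 0)
               mean(keep$peak_dff[keep$active]) else NA_real_,
             denominator_mode = denominatorMode)
}

#' Extract ROI traces from a movie by labelled-mask averaging
#'
#' Each ROI trace is the plain mean over its mask pixels, frame by frame.
#'
#' @param movie numeric array, height x width x frames
#' @param mask integer matrix (height x width); 0 = background, k > 0 = ROI k
#' @param framePeriod_s frame period
#' @param stimFrame stimulation frame
#' @return a \linkS4class{TraceSet} with one row per ROI label
#' @export
roiTraces <- function(movie, mask, framePeriod_s, stimFrame) {
  stopifnot(length(dim(movie)) == 3,
            all(dim(movie)[1:2] == dim(mask)))
  labs <- sort(setdiff(unique(as.integer(mask)), 0L))
  if (length(labs) == 0) stop("mask contains no ROI labels")
  nf <- dim(movie)[3]
  flat <- matrix(movie, ncol = nf)
  tr <- t(vapply(labs, function(l)
    colMeans(flat[as.integer(mask) == l, , drop = FALSE]),
    numeric(nf)))
  traceSet(tr, framePeriod_s, stimFrame,
           hierarchy = data.frame(mouse = "m1", slice = "s1", field = "f1",
                                  cell = sprintf("roi%03d", labs)))
}
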