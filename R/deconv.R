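# Spike inference by non-negative sparse deconvolution with the calibrated
# difference-of-exponentials kernel. The per-trace inverse problem
#   min_{s >= 0}  0.5 * || y - K s ||^2  +  lambda * sum(s)
# (K the causal convolution matrix of the sampled kernel) is solved by
# accelerated proximal gradient descent (FISTA) with a non-negative
# soft-threshold, which is deterministic and converges monotonically after
# restart.

# Lipschitz constant of the quadratic term: largest eigenvalue of K'K via
# deterministic power iteration.
.lipschitz <- function(G) {
  v <- rep(1 / sqrt(nrow(G)), nrow(G))
  lam <- 0
  for (i in 1:100) {
    w <- G %*% v
    lamNew <- sqrt(sum(w^2))
    if (lamNew == 0) return(1)
    v <- as.numeric(w / lamNew)
    if (abs(lamNew - lam) < 1e-10 * lamNew) break
    lam <- lamNew
  }
  lam
}

.convMatrix <- function(k, n) {
  K <- matrix(0, n, n)
  lk <- length(k)
  for (j in seq_len(n)) {
    i <- j:min(n, j + lk - 1)
    K[i, j] <- k[seq_along(i)]
  }
  K
}

#' Robust noise-SD estimate of a dF/F0 trace
#'
#' Median absolute deviation of the first differences, scaled by
#' \code{sqrt(2)}, which is insensitive to sparse transients.
#'
#' @param dff numeric dF/F0 series
#' @return estimated noise SD
#' @export
estimateNoiseSd <- function(dff) {
  if (length(dff) < 3) stop("series too short")
  mad(diff(dff)) / sqrt(2)
}

#' Deconvolve a dF/F0 trace into non-negative spiking activity
#'
#' Solves the non-negative LASSO above. The deconvolved activity is
#' expressed in spike units (the solution amplitudes divided by the
#' kernel's single-spike amplitude); contiguous runs of positive activity
#' are grouped into events and events with magnitude below half a spike are
#' discarded, giving integer-consistent counts on noiseless input.
#'
#' @param dff numeric dF/F0 series
#' @param kernel a \linkS4class{KernelParams} (calibrated rise/decay and
#'   single-spike amplitude)
#' @param framePeriod_s frame period of the series, seconds
#' @param sparsityWeight LASSO weight; default 2 x the robust noise-SD
#'   estimate of the trace
#' @param eventThreshold minimal event magnitude in spikes (default 0.5)
#' @param maxIter,tol solver controls
#' @return a \linkS4class{SpikeEstimate}
#' @examples
#' kp <- kernelParams()
#' ts <- genCalciumTraces(3, kp, noiseSd = 0, seed = 1)
#' dff <- computeDFF(traces(ts)[1, ])
#' deconvolve(dff, kp, framePeriod(ts))
#' @export
deconvolve <- function(dff, kernel, framePeriod_s,
                       sparsityWeight = NULL, eventThreshold = 0.5,
                       maxIter = 500, tol = 1e-9) {
  validObject(kernel)
  n <- length(dff)
  if (n < 3) stop("series too short to deconvolve")
  if (framePeriod_s <= 0) stop("framePeriod_s must be positive")
  if (kernel@rise_s < framePeriod_s / 50)
    stop("kernel rise time incompatible with the frame period")
  k <- kernel@unitAmplitude * sampleKernel(kernel, framePeriod_s,
                                           nSamples = min(n,
                                             ceiling(10 * kernel@decay_s /
                                                       framePeriod_s)))
  if (is.null(sparsityWeight)) sparsityWeight <- 2 * estimateNoiseSd(dff)
  K <- .convMatrix(k, n)
  G <- crossprod(K)
  Kty <- as.numeric(crossprod(K, dff))
  L <- .lipschitz(G)
  s <- rep(0, n); z <- s; tAcc <- 1
  objPrev <- Inf
  for (it in seq_len(maxIter)) {
    grad <- as.numeric(G %*% z) - Kty
    sNew <- pmax(0, z - (grad + sparsityWeight) / L)
    tNew <- (1 + sqrt(1 + 4 * tAcc^2)) / 2
    z <- sNew + ((tAcc - 1) / tNew) * (sNew - s)
    s <- sNew; tAcc <- tNew
    if (it %% 10 == 0) {
      r <- dff - as.numeric(K %*% s)
      obj <- 0.5 * sum(r^2) + sparsityWeight * sum(s)
      if (is.finite(objPrev) &&
          abs(objPrev - obj) < tol * max(1, abs(obj))) break
      if (obj > objPrev) { z <- s; tAcc <- 1 }   # restart on overshoot
      objPrev <- obj
    }
  }
  act <- s                # spike units: K already carries unitAmplitude
  act[act < 1e-8] <- 0
  ev <- .groupEvents(act, eventThreshold)
  new("SpikeEstimate", activity = act, events = ev,
      spikeCount = sum(ev$magnitude), framePeriod_s = framePeriod_s)
}

# contiguous positive runs -> events (frame = magnitude-weighted centre,
# rounded); drop events below the threshold magnitude
.groupEvents <- function(act, eventThreshold) {
  pos <- act > 0
  if (!any(pos))
    return(data.frame(frame = integer(0), magnitude = numeric(0)))
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  frames <- integer(0); mags <- numeric(0)
  for (i in keep) {
    idx <- starts[i]:ends[i]
    mag <- sum(act[idx])
    if (mag >= eventThreshold) {
      frames <- c(frames, as.integer(round(sum(idx * act[idx]) / mag)))
      mags <- c(mags, mag)
    }
  }
  data.frame(frame = frames, magnitude = mags)
}

#' Activity call and total deconvolved spikes within a stimulation window
#'
#' A cell is active if at least one detected event (>= half a spike) falls
#' in the window; the total is the summed event magnitude over the window.
#'
#' @param estimate a \linkS4class{SpikeEstimate}
#' @param stimWindow integer frame range of the stimulation epoch
#' @return list: \code{active} (logical), \code{total_spikes}
#' @export
callActiveAndTotal <- function(estimate, stimWindow) {
  if (length(stimWindow) == 0 || min(stimWindow) < 1 ||
      max(stimWindow) > length(estimate@activity))
    stop("invalid stimulation window")
  inWin <- estimate@events$frame %in% stimWindow
  list(active = any(inWin),
       total_spikes = sum(estimate@events$magnitude[inWin]))
}

#' Calibrate kernel time constants from ground-truth paired data
#'
#' Finds the rise/decay time constants (and the single-spike amplitude)
#' minimising the squared reconstruction error of count-scaled kernels
#' against the observed dF/F0 transients, with all spikes at the known
#' stimulation frame. The amplitude solves in closed form given the time
#' constants; the time constants are optimised on the log scale.
#'
#' @param dffMatrix cells x frames dF/F0 matrix
#' @param counts known spike counts per trace (>= 10 traces)
#' @param framePeriod_s frame period
#' @param stimFrame stimulation frame (spikes assumed there)
#' @param init a \linkS4class{KernelParams} used as the starting point and
#'   as the fallback when no spiking traces are available
#' @return a \linkS4class{KernelParams}; if no trace has a positive count a
#'   warning is raised and \code{init} is returned
#' @export
kernelFromGroundTruth <- function(dffMatrix, counts, framePeriod_s,
                                  stimFrame, init = kernelParams()) {
  dffMatrix <- as.matrix(dffMatrix)
  if (nrow(dffMatrix) < 10) stop("need >= 10 paired traces")
  if (length(counts) != nrow(dffMatrix))
    stop("counts must match traces")
  if (all(counts == 0)) {
    warning("no spiking traces: falling back to configured kernel defaults")
    return(init)
  }
  if (all(dffMatrix == 0)) stop("all-zero traces: no events to fit")
  n <- ncol(dffMatrix)
  post <- stimFrame:n
  yl <- dffMatrix[, post, drop = FALSE]
  obj <- function(par) {
    rise <- exp(par[1]); decay <- exp(par[2])
    if (decay <= rise) return(1e12)
    kv <- sampleKernel(kernelParams(rise, decay, 1), framePeriod_s,
                       nSamples = length(post))
    denom <- sum(counts^2) * sum(kv^2)
    if (denom == 0) return(1e12)
    amp <- sum(counts * (yl %*% kv)) / denom
    pred <- outer(counts * amp, kv)
    sum((yl - pred)^2)
  }
  fit <- optim(log(c(init@rise_s, init@decay_s)), obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12))
  rise <- exp(fit$par[1]); decay <- exp(fit$par[2])
  kv <- sampleKernel(kernelParams(rise, decay, 1), framePeriod_s,
                     nSamples = length(post))
  amp <- sum(counts * (yl %*% kv)) / (sum(counts^2) * sum(kv^2))
  kernelParams(rise, decay, amp)
}

#' Validate deconvolved counts against ground truth
#'
#' @param estimates numeric vector of estimated spike counts
#' @param trueCounts matched true counts (variance must be positive)
#' @return list: \code{r_squared} of the least-squares regression of
#'   estimates on truth, \code{slope}, \code{intercept}, \code{p}, \code{n}
#' @export
validateDeconvolution <- function(estimates, trueCounts) {
  if (length(estimates) != length(trueCounts)) stop("length mismatch")
  if (length(estimates) < 3) stop("need at least 3 pairs")
  if (var(trueCounts) == 0) stop("degenerate truth: zero variance")
  m <- lm(estimates ~ trueCounts)
  sm <- summary(m)
  list(r_squared = sm$r.squared,
       slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
       p = unname(coef(sm)[2, 4]), n = length(estimates))
}

#' @importFrom stats optim
NULL
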