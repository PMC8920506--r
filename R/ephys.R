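# Intrinsic and synaptic feature extraction from sweep data, using the
# operational definitions of the slice-physiology analysis: dV/dt spike
# criteria, Rm = dV/I, single-exponential tau, rheobase on the step grid,
# sag percentage, AP waveform features with sub-sample interpolation,
# paired-pulse ratios with extrapolated baselines, E/I ratios and one-site
# binding fits compared by an extra sum-of-squares F test.

#' Spike validity criteria
#'
#' @param dvdtThreshold_mV_ms dV/dt threshold defining the AP threshold
#'   crossing (default 10 mV/ms)
#' @param minAmplitude_mV minimal peak-minus-threshold amplitude
#'   (default 40 mV)
#' @param overshootFloor_mV spike peak must exceed this voltage
#'   (default 0 mV)
#' @return list of criteria
#' @export
spikeCriteria <- function(dvdtThreshold_mV_ms = 10, minAmplitude_mV = 40,
                          overshootFloor_mV = 0) {
  stopifnot(dvdtThreshold_mV_ms > 0, minAmplitude_mV > 0)
  list(dvdt = dvdtThreshold_mV_ms, minAmp = minAmplitude_mV,
       overshoot = overshootFloor_mV)
}

#' Detect action potentials in a voltage sweep
#'
#' Candidate peaks are local maxima above the overshoot floor. For each
#' peak, the threshold is the first sample of the contiguous run of
#' dV/dt >= threshold (central differences) leading into the peak; spikes
#' must reach the minimal amplitude (peak minus threshold voltage).
#'
#' @param voltage_mV numeric voltage trace in mV
#' @param dt_s sampling interval, seconds (uniform sampling required)
#' @param criteria from \code{\link{spikeCriteria}}
#' @param window optional index range to search
#' @return data.frame: \code{peak_index}, \code{threshold_index},
#'   \code{peak_mV}, \code{threshold_mV}, \code{amplitude_mV}; zero rows if
#'   no valid spikes
#' @export
detectSpikes <- function(voltage_mV, dt_s, criteria = spikeCriteria(),
                         window = NULL) {
  n <- length(voltage_mV)
  if (n < 5) return(data.frame(peak_index = integer(0),
                               threshold_index = integer(0),
                               peak_mV = numeric(0),
                               threshold_mV = numeric(0),
                               amplitude_mV = numeric(0)))
  # central-difference dV/dt in mV/ms
  dvdt <- c(0, (voltage_mV[3:n] - voltage_mV[1:(n - 2)]) / (2 * dt_s * 1e3),
            0)
  v <- voltage_mV
  cand <- which(v > criteria$overshoot)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[v[cand] >= v[cand - 1] & v[cand] > v[cand + 1]]
  if (!is.null(window)) cand <- cand[cand %in% window]
  out <- list()
  lastPeak <- -Inf
  for (pk in cand) {
    # walk back through the dV/dt >= threshold run preceding the peak
    i <- pk
    while (i > 1 && dvdt[i - 1] >= criteria$dvdt) i <- i - 1
    if (dvdt[i] < criteria$dvdt) next        # no qualifying upstroke
    thrIdx <- i
    amp <- v[pk] - v[thrIdx]
    if (amp < criteria$minAmp) next
    if (pk - lastPeak < 1e-3 / dt_s) next    # 1 ms refractory de-dup
    lastPeak <- pk
    out[[length(out) + 1]] <- data.frame(
      peak_index = pk, threshold_index = thrIdx, peak_mV = v[pk],
      threshold_mV = v[thrIdx], amplitude_mV = amp)
  }
  if (length(out) == 0)
    return(data.frame(peak_index = integer(0), threshold_index = integer(0),
                      peak_mV = numeric(0), threshold_mV = numeric(0),
                      amplitude_mV = numeric(0)))
  do.call(rbind, out)
}

# linear-interpolated crossing time of `level` between samples i and i+1
.crossTime <- function(v, tt, i, level) {
  tt[i] + (level - v[i]) / (v[i + 1] - v[i]) * (tt[i + 1] - tt[i])
}

#' Measure passive membrane properties from a step family
#'
#' Resting potential is the mean of the zero-current rest sweep; input
#' resistance is the mean of \eqn{\Delta V / I} over small hyperpolarizing
#' steps (|steady-state deflection| <= \code{maxDeflection_mV}); the
#' membrane time constant comes from a single-exponential fit to the onset
#' of the smallest hyperpolarizing response; sag is measured on the largest
#' hyperpolarizing step as 100 (Vmin - Vss) / (Vmin - Vbaseline). Steady
#' state is the mean of the final 100 ms of the step.
#'
#' @param sweeps a \linkS4class{SweepSet} from a current-clamp step
#'   protocol (command table with amplitude_pA, onset_s, duration_s)
#' @param maxDeflection_mV cutoff defining a "small" step (default 10 mV)
#' @param tauFitWindow_s onset window for the exponential fit (default 0.15)
#' @return list: \code{vm_mV}, \code{rm_mohm}, \code{tau_ms},
#'   \code{sag_percent}
#' @export
measurePassive <- function(sweeps, maxDeflection_mV = 10,
                           tauFitWindow_s = 0.15) {
  stopifnot(is(sweeps, "SweepSet"), sweeps@mode == "current_clamp")
  cmd <- sweepCommand(sweeps)
  tt <- sweepTimes(sweeps)
  dt <- sweepDt(sweeps)
  dat <- sweepData(sweeps)
  rest <- which(cmd$amplitude_pA == 0)
  if (length(rest) == 0) stop("insufficient data: no rest sweep")
  if (max(tt) - min(tt) < 1 - dt)
    warning("rest sweep shorter than 1 s")
  vm <- mean(dat[, rest[1]])
  neg <- which(cmd$amplitude_pA < 0)
  if (length(neg) == 0)
    stop("insufficient data: no hyperpolarizing step")
  stepStats <- lapply(neg, function(j) {
    on <- cmd$onset_s[j]; dur <- cmd$duration_s[j]
    iBase <- tt < on
    iSS <- tt >= (on + dur - 0.1) & tt < (on + dur)
    iStep <- tt >= on & tt < (on + dur)
    vBase <- mean(dat[iBase, j])
    vSS <- mean(dat[iSS, j])
    list(j = j, I = cmd$amplitude_pA[j], vBase = vBase, vSS = vSS,
         dV = vSS - vBase, vMin = min(dat[iStep, j]))
  })
  dVs <- vapply(stepStats, `[[`, 1, "dV")
  small <- abs(dVs) <= maxDeflection_mV
  if (!any(small))
    stop("insufficient data: no small hyperpolarizing step for Rm")
  rm <- mean(vapply(stepStats[small], function(s) s$dV / (s$I * 1e-3), 1))
  # tau from the smallest-amplitude hyperpolarizing step onset
  jTau <- stepStats[[which.min(abs(dVs))]]$j
  on <- cmd$onset_s[match(jTau, cmd$sweep)]
  iFit <- tt >= on & tt < on + tauFitWindow_s
  yf <- dat[iFit, jTau]
  tf <- tt[iFit] - on
  st <- list(a = yf[length(yf)], b = yf[1] - yf[length(yf)],
             tau = 0.02)
  fit <- tryCatch(
    minpack.lm::nlsLM(yf ~ a + b * exp(-tf / tau), start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  tau <- if (is.null(fit)) NA_real_ else coef(fit)[["tau"]] * 1e3
  # sag on the largest hyperpolarizing step
  sBig <- stepStats[[which.min(vapply(stepStats, `[[`, 1, "I"))]]
  sag <- 100 * (sBig$vMin - sBig$vSS) / (sBig$vMin - sBig$vBase)
  list(vm_mV = vm, rm_mohm = rm, tau_ms = tau, sag_percent = sag)
}

#' Measure action-potential waveform features
#'
#' Features of one detected spike: threshold and peak voltage, amplitude
#' (peak minus threshold), rise time (threshold to peak), half-width at
#' half-maximal amplitude with linear sub-sample interpolation of both
#' crossings, and afterhyperpolarization amplitude (threshold minus trough)
#' and time (falling-phase threshold crossing to trough).
#'
#' @param voltage_mV voltage trace
#' @param dt_s sampling interval
#' @param spike one row of \code{\link{detectSpikes}} output
#' @param ahpWindow_s search window after the peak for the AHP trough
#'   (bounded by the next spike if any; default 0.05)
#' @param nextThresholdIndex threshold index of the following spike, if any
#' @return list: threshold_mV, peak_mV, amplitude_mV, rise_ms,
#'   half_width_ms, ahp_amplitude_mV, ahp_time_ms
#' @export
measureApFeatures <- function(voltage_mV, dt_s, spike, ahpWindow_s = 0.05,
                              nextThresholdIndex = NULL) {
  v <- voltage_mV
  n <- length(v)
  tt <- (seq_len(n) - 1) * dt_s
  pk <- spike$peak_index; thr <- spike$threshold_index
  vThr <- v[thr]; vPk <- v[pk]
  half <- (vThr + vPk) / 2
  # rising half crossing between thr and pk
  iUp <- thr
  for (i in thr:(pk - 1)) if (v[i] <= half && v[i + 1] > half) { iUp <- i; break }
  tUp <- .crossTime(v, tt, iUp, half)
  # falling half crossing after the peak
  iEnd <- if (!is.null(nextThresholdIndex)) nextThresholdIndex - 1 else
    min(n - 1, pk + round(ahpWindow_s / dt_s))
  iDown <- NA
  for (i in pk:(iEnd)) if (v[i] >= half && v[i + 1] < half) { iDown <- i; break }
  if (is.na(iDown))
    stop("feature undefined: AP truncated before the falling half-crossing")
  tDown <- .crossTime(v, tt, iDown, half)
  # falling-phase threshold crossing, then the AHP trough
  iFall <- NA
  for (i in pk:iEnd) if (v[i] >= vThr && v[i + 1] < vThr) { iFall <- i; break }
  ahpAmp <- NA_real_; ahpTime <- NA_real_
  if (!is.na(iFall)) {
    tFall <- .crossTime(v, tt, iFall, vThr)
    trWin <- (iFall + 1):iEnd
    iTr <- trWin[which.min(v[trWin])]
    ahpAmp <- vThr - v[iTr]
    ahpTime <- (tt[iTr] - tFall) * 1e3
  }
  list(threshold_mV = vThr, peak_mV = vPk, amplitude_mV = vPk - vThr,
       rise_ms = (tt[pk] - tt[thr]) * 1e3,
       half_width_ms = (tDown - tUp) * 1e3,
       ahp_amplitude_mV = ahpAmp, ahp_time_ms = ahpTime)
}

#' Firing-rate analysis of an increasing step family
#'
#' Rheobase is the lowest injected current with at least one valid spike;
#' the steady-state rate of a sweep is its spike count divided by the step
#' duration; the maximal instantaneous rate is the inverse of the smallest
#' inter-spike interval over all sweeps (sweeps with >= 2 spikes).
#'
#' @param sweeps a current-clamp \linkS4class{SweepSet}
#' @param criteria spike criteria
#' @return list: \code{fi} (data.frame current_pA, rate_hz),
#'   \code{rheobase_pA} (NA if no sweep spikes),
#'   \code{max_steady_state_hz}, \code{max_instantaneous_hz}
#' @export
computeFi <- function(sweeps, criteria = spikeCriteria()) {
  stopifnot(is(sweeps, "SweepSet"), sweeps@mode == "current_clamp")
  cmd <- sweepCommand(sweeps)
  tt <- sweepTimes(sweeps)
  dt <- sweepDt(sweeps)
  dat <- sweepData(sweeps)
  pos <- which(cmd$amplitude_pA > 0)
  rate <- numeric(0); cur <- numeric(0); minIsi <- Inf
  for (j in pos) {
    on <- cmd$onset_s[j]; dur <- cmd$duration_s[j]
    win <- which(tt >= on & tt < on + dur)
    sp <- detectSpikes(dat[, j], dt, criteria, window = win)
    cur <- c(cur, cmd$amplitude_pA[j])
    rate <- c(rate, nrow(sp) / dur)
    if (nrow(sp) >= 2)
      minIsi <- min(minIsi, min(diff(tt[sp$peak_index])))
  }
  ord <- order(cur)
  fi <- data.frame(current_pA = cur[ord], rate_hz = rate[ord])
  spiking <- fi$current_pA[fi$rate_hz > 0]
  list(fi = fi,
       rheobase_pA = if (length(spiking)) min(spiking) else NA_real_,
       max_steady_state_hz = if (nrow(fi)) max(fi$rate_hz) else NA_real_,
       max_instantaneous_hz = if (is.finite(minIsi)) 1 / minIsi else
         NA_real_)
}

#' Full intrinsic profile from a current-clamp step family
#'
#' Combines \code{\link{measurePassive}}, \code{\link{computeFi}} and
#' \code{\link{measureApFeatures}} (single-spike features measured at the
#' first spike of the sweep closest to twice rheobase) into one row.
#'
#' @param sweeps a current-clamp \linkS4class{SweepSet}
#' @param criteria spike criteria
#' @return one-row data.frame with the intrinsic feature set (mV, MOhm, ms,
#'   pA, Hz, percent)
#' @export
intrinsicProfile <- function(sweeps, criteria = spikeCriteria()) {
  pas <- measurePassive(sweeps)
  fi <- computeFi(sweeps, criteria)
  ap <- list(threshold_mV = NA_real_, peak_mV = NA_real_,
             amplitude_mV = NA_real_, rise_ms = NA_real_,
             half_width_ms = NA_real_, ahp_amplitude_mV = NA_real_,
             ahp_time_ms = NA_real_)
  if (!is.na(fi$rheobase_pA)) {
    cmd <- sweepCommand(sweeps)
    tt <- sweepTimes(sweeps)
    dt <- sweepDt(sweeps)
    target <- 2 * fi$rheobase_pA
    js <- which(cmd$amplitude_pA > 0)
    j <- js[which.min(abs(cmd$amplitude_pA[js] - target))]
    on <- cmd$onset_s[j]; dur <- cmd$duration_s[j]
    win <- which(tt >= on & tt < on + dur)
    sp <- detectSpikes(sweepData(sweeps)[, j], dt, criteria, window = win)
    if (nrow(sp) >= 1) {
      nxt <- if (nrow(sp) >= 2) sp$threshold_index[2] else NULL
      ap <- measureApFeatures(sweepData(sweeps)[, j], dt, sp[1, ],
                              nextThresholdIndex = nxt)
    }
  }
  cbind(data.frame(vm_mV = pas$vm_mV, rm_mohm = pas$rm_mohm,
                   tau_ms = pas$tau_ms, sag_percent = pas$sag_percent,
                   rheobase_pA = fi$rheobase_pA,
                   max_steady_state_hz = fi$max_steady_state_hz,
                   max_instantaneous_hz = fi$max_instantaneous_hz),
        as.data.frame(ap))
}

#' Measure evoked postsynaptic currents in a stimulus train
#'
#' The first-pulse amplitude is measured from the pre-stimulus baseline;
#' its decay is fit with a single exponential, which is extrapolated under
#' each later response and subtracted before that response's peak is
#' measured (the extrapolated-baseline paired-pulse rule). Amplitudes are
#' reported as positive magnitudes.
#'
#' @param current_pA current trace
#' @param dt_s sampling interval
#' @param stimTimes_s stimulus times (within the sweep)
#' @param polarity "inward" (negative-going) or "outward"
#' @param peakWindow_s window after each stimulus searched for the peak
#'   (default: up to the next stimulus or 45 ms)
#' @param decayFitDelay_s dead time after the peak before the exponential
#'   decay fit starts, excluding the rise-phase contamination
#'   (default 5 ms)
#' @param rebaseline "exponential" (default) or "linear" extrapolation
#' @return list: \code{amplitudes_pA} (per pulse), \code{decay_tau_ms}
#'   (first response), \code{ppr_2_1}, \code{ppr_4_1} (NA when fewer
#'   pulses), \code{fit_ok}
#' @export
measurePsc <- function(current_pA, dt_s, stimTimes_s,
                       polarity = c("inward", "outward"),
                       peakWindow_s = NULL, decayFitDelay_s = 0.005,
                       rebaseline = c("exponential", "linear")) {
  polarity <- match.arg(polarity)
  rebaseline <- match.arg(rebaseline)
  n <- length(current_pA)
  tt <- (seq_len(n) - 1) * dt_s
  if (min(stimTimes_s) < 0 || max(stimTimes_s) > max(tt))
    stop("stimulus times outside the sweep")
  y <- if (polarity == "inward") -current_pA else current_pA
  base <- mean(y[tt < stimTimes_s[1]])
  y <- y - base
  nP <- length(stimTimes_s)
  gaps <- diff(c(stimTimes_s, max(tt)))
  if (is.null(peakWindow_s)) peakWindow_s <- pmin(gaps, 0.045)
  peakWindow_s <- rep_len(peakWindow_s, nP)
  extrap <- rep(0, n)           # running tail of earlier responses
  amps <- numeric(nP)
  tauMs <- NA_real_; fitOk <- TRUE
  for (p in seq_len(nP)) {
    i0 <- which.min(abs(tt - stimTimes_s[p]))
    iw <- i0:min(n, i0 + round(peakWindow_s[p] / dt_s))
    resid <- y - extrap
    iPk <- iw[which.max(resid[iw])]
    amps[p] <- resid[iPk]
    # fit the decay of this response on the re-baselined trace
    iDecEnd <- if (p < nP) which.min(abs(tt - stimTimes_s[p + 1])) - 1 else
      min(n, iPk + round(0.045 / dt_s))
    iDecStart <- min(iPk + round(decayFitDelay_s / dt_s), iDecEnd - 4)
    iDec <- max(iPk, iDecStart):iDecEnd
    if (length(iDec) >= 8) {
      td <- tt[iDec] - tt[iPk]
      yd <- resid[iDec]
      fit <- tryCatch(
        minpack.lm::nlsLM(yd ~ a * exp(-td / tau),
                          start = list(a = amps[p],
                                       tau = max(td[length(td)] / 3, dt_s)),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) {
        fitOk <- FALSE
        if (p == 1) tauMs <- NA_real_
      } else {
        cf <- coef(fit)
        if (p == 1) tauMs <- cf[["tau"]] * 1e3
        tailIdx <- iPk:n
        contrib <- rep(0, n)
        if (rebaseline == "exponential") {
          contrib[tailIdx] <- cf[["a"]] *
            exp(-(tt[tailIdx] - tt[iPk]) / cf[["tau"]])
        } else {
          slope <- -cf[["a"]] / cf[["tau"]]
          lin <- cf[["a"]] + slope * (tt[tailIdx] - tt[iPk])
          contrib[tailIdx] <- pmax(0, lin)
        }
        extrap <- extrap + contrib
      }
    }
  }
  list(amplitudes_pA = amps, decay_tau_ms = tauMs,
       ppr_2_1 = if (nP >= 2) amps[2] / amps[1] else NA_real_,
       ppr_4_1 = if (nP >= 4) amps[4] / amps[1] else NA_real_,
       fit_ok = fitOk)
}

#' Excitation/inhibition ratio per stimulation intensity
#'
#' @param epsc data.frame with columns intensity_uA, amplitude_pA
#' @param ipsc data.frame with the same columns and the same intensities
#' @return data.frame: intensity_uA, ei_ratio (NA where the IPSC is not
#'   positive)
#' @export
eiRatio <- function(epsc, ipsc) {
  if (!setequal(epsc$intensity_uA, ipsc$intensity_uA) ||
      nrow(epsc) != nrow(ipsc))
    stop("intensity sets of EPSC and IPSC tables do not match")
  e <- epsc[order(epsc$intensity_uA), ]
  i <- ipsc[order(ipsc$intensity_uA), ]
  ratio <- ifelse(i$amplitude_pA > 0, e$amplitude_pA / i$amplitude_pA,
                  NA_real_)
  data.frame(intensity_uA = e$intensity_uA, ei_ratio = ratio)
}

.fitBindingOne <- function(df) {
  starts <- list(
    list(bmax = max(df$amplitude) * 1.2, kd = max(median(df$intensity), 1)),
    list(bmax = max(df$amplitude) * 2, kd = max(df$intensity)),
    list(bmax = max(df$amplitude), kd = min(df$intensity)))
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(amplitude ~ bmax * intensity / (kd + intensity),
                        data = df, start = st,
                        lower = c(1e-9, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- coef(fit)
      return(new("BindingFit", bmax = cf[["bmax"]], k = cf[["kd"]],
                 rss = sum(resid(fit)^2), df = nrow(df) - 2,
                 converged = TRUE, model = fit))
    }
  }
  # derivative-free fallback on log-scale parameters
  obj <- function(par) {
    b <- exp(par[1]); k <- exp(par[2])
    sum((df$amplitude - b * df$intensity / (k + df$intensity))^2)
  }
  op <- optim(log(c(max(df$amplitude) * 1.5, median(df$intensity))), obj,
              method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-14))
  new("BindingFit", bmax = exp(op$par[1]), k = exp(op$par[2]),
      rss = op$value, df = nrow(df) - 2,
      converged = op$convergence == 0, model = NULL)
}

#' One-site binding fits per group with an extra sum-of-squares F test
#'
#' Fits \eqn{y = B_{max} x / (K + x)} separately per group and once to the
#' pooled data, and compares the pooled (null) model against the separate
#' fits with
#' \eqn{F = \frac{(SS_{pooled} - SS_{sep}) / (df_{pooled} - df_{sep})}
#'            {SS_{sep} / df_{sep}}}.
#'
#' @param pointsByGroup named list of data.frames with columns
#'   \code{intensity} and \code{amplitude} (>= 3 intensities per group)
#' @return list: \code{fits} (named list of \linkS4class{BindingFit}),
#'   \code{pooled} fit, \code{f}, \code{df1}, \code{df2}, \code{p}
#' @export
fitBindingAndCompare <- function(pointsByGroup) {
  if (is.null(names(pointsByGroup)) || length(pointsByGroup) < 2)
    stop("pointsByGroup must be a named list of >= 2 groups")
  for (g in names(pointsByGroup))
    if (length(unique(pointsByGroup[[g]]$intensity)) < 3)
      stop("need >= 3 intensities per group: ", g)
  fits <- lapply(pointsByGroup, .fitBindingOne)
  pooledDf <- do.call(rbind, lapply(pointsByGroup, function(d)
    d[, c("intensity", "amplitude")]))
  pooled <- .fitBindingOne(pooledDf)
  ssSep <- sum(vapply(fits, function(f) f@rss, 1))
  dfSep <- sum(vapply(fits, function(f) f@df, 1))
  ssPool <- pooled@rss
  dfPool <- pooled@df
  f <- ((ssPool - ssSep) / (dfPool - dfSep)) / (ssSep / dfSep)
  list(fits = fits, pooled = pooled, f = f,
       df1 = dfPool - dfSep, df2 = dfSep,
       p = pf(f, dfPool - dfSep, dfSep, lower.tail = FALSE))
}
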