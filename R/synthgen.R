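# Synthetic-data generators. Every generated object carries its ground truth
# (in rowData for TraceSets, metadata$truth for SweepSets, attr "truth" for
# population tables) so downstream modules are testable without downloads.

#' Generate calcium traces with known spike counts
#'
#' Each trace is \code{baselineF * (1 + signal + noise)} where the signal is
#' the spike count times the unit-amplitude difference-of-exponentials
#' kernel placed at the stimulation frame(s), and the noise is i.i.d.
#' Gaussian in dF/F0 units. For train protocols (\code{nPulses > 1}) the
#' spikes are distributed across pulses (spaced at the stimulus inter-pulse
#' interval) as evenly as possible, earliest pulses first.
#'
#' @param spikeCounts non-negative integer vector, one per cell
#' @param kernel a \linkS4class{KernelParams}
#' @param noiseSd Gaussian noise SD in dF/F0 units (>= 0)
#' @param nFrames frames per trace (default 500)
#' @param framePeriod_s frame period, seconds (default 0.0338, i.e. ~30 Hz)
#' @param stimFrame 1-based stimulus frame; must leave a full baseline
#'   window before it (>= 51 with the default 50-frame baseline)
#' @param nPulses pulses in the stimulus train (default 1)
#' @param pulseHz train frequency for multi-pulse stimuli (default 20)
#' @param baselineF baseline fluorescence level (a.u.)
#' @param seed integer seed; identical seeds give identical output
#' @return a \linkS4class{TraceSet}; rowData carries \code{true_spikes} and
#'   \code{true_peak_dff} (noiseless sampled peak)
#' @examples
#' ts <- genCalciumTraces(c(0, 1, 5), kernelParams(), noiseSd = 0,
#'                        seed = 1)
#' SummarizedExperiment::rowData(ts)$true_peak_dff
#' @export
genCalciumTraces <- function(spikeCounts, kernel = kernelParams(),
                             noiseSd = 0.06, nFrames = 500,
                             framePeriod_s = 0.0338, stimFrame = 51L,
                             nPulses = 1L, pulseHz = 20,
                             baselineF = 100, seed = 1L) {
  stopifnot(all(spikeCounts >= 0), noiseSd >= 0)
  validObject(kernel)
  if (stimFrame < 51)
    stop("stimFrame must be >= 51 so the 50-frame baseline precedes it")
  if (stimFrame > nFrames) stop("stimFrame beyond end of trace")
  nCells <- length(spikeCounts)
  k <- sampleKernel(kernel, framePeriod_s, nSamples = nFrames)
  pulseFrames <- stimFrame +
    round((seq_len(nPulses) - 1) / pulseHz / framePeriod_s)
  pulseFrames <- pulseFrames[pulseFrames <= nFrames]
  sig <- matrix(0, nCells, nFrames)
  for (i in seq_len(nCells)) {
    cnt <- spikeCounts[i]
    if (cnt > 0) {
      # distribute spikes over pulses, earliest pulses get the remainder
      per <- rep(floor(cnt / length(pulseFrames)), length(pulseFrames))
      extra <- cnt - sum(per)
      if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
      for (j in seq_along(pulseFrames)) {
        if (per[j] == 0) next
        idx <- pulseFrames[j]:min(nFrames, pulseFrames[j] + length(k) - 1)
        sig[i, idx] <- sig[i, idx] +
          per[j] * kernel@unitAmplitude * k[seq_along(idx)]
      }
    }
  }
  truePeak <- apply(sig, 1, max)
  set.seed(seed)
  noise <- matrix(rnorm(nCells * nFrames, 0, noiseSd), nCells, nFrames)
  f <- baselineF * (1 + sig + noise)
  traceSet(f, framePeriod_s, stimFrame,
           condition = list(n_pulses = length(pulseFrames),
                            pulse_hz = pulseHz),
           truth = data.frame(true_spikes = spikeCounts,
                              true_peak_dff = truePeak))
}

#' Generate a hierarchical population activation dataset
#'
#' Simulates per-cell Bernoulli activation under a probit-scale linear
#' predictor: wild-type intercept at the maximal intensity, a log-intensity
#' trend, a genotype shift, and nested Gaussian random intercepts for mouse,
#' slice and field. Active cells draw a lognormal response amplitude with a
#' genotype-specific log mean. The default design is calibrated so the
#' marginal activation probabilities at the maximal stimulus are 0.16
#' (wild-type) and 0.51 (mutant).
#'
#' @param design a \linkS4class{PopulationDesign}
#' @param intensitiesSubset optional subset of the design's intensities to
#'   simulate (e.g. \code{"max"} for the maximal stimulus only)
#' @return tidy data.frame with columns mouse, slice, field, cell, genotype,
#'   intensity_uA, n_pulses, active, amplitude (NA for inactive cells), and
#'   attribute \code{"truth"}: the probit parameters and the drawn random
#'   effects
#' @examples
#' pop <- genPopulationDataset(populationDesign(nMicePerGenotype = 2))
#' head(pop)
#' @export
genPopulationDataset <- function(design = populationDesign(),
                                 intensitiesSubset = NULL) {
  validObject(design)
  ints <- design@intensities
  if (identical(intensitiesSubset, "max")) ints <- max(ints)
  else if (!is.null(intensitiesSubset)) {
    if (!all(intensitiesSubset %in% design@intensities))
      stop("intensitiesSubset must be drawn from the design intensities")
    ints <- sort(intensitiesSubset)
  }
  if (length(ints) == 0) stop("empty intensity list")
  set.seed(design@seed)
  xmax <- max(design@intensities)
  pulse <- setNames(rep_len(design@pulseCounts, length(ints)),
                    as.character(ints))

  cells <- expand.grid(
    cellNo = seq_len(design@nCellsPerField),
    fieldNo = seq_len(design@nFieldsPerSlice),
    sliceNo = seq_len(design@nSlicesPerMouse),
    mouseNo = seq_len(design@nMicePerGenotype),
    genotype = c("WT", "HET"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$mouse <- sprintf("%s_m%02d", cells$genotype, cells$mouseNo)
  cells$slice <- sprintf("%s_s%d", cells$mouse, cells$sliceNo)
  cells$field <- sprintf("%s_f%d", cells$slice, cells$fieldNo)
  cells$cell <- sprintf("%s_c%03d", cells$field, cells$cellNo)

  mice <- unique(cells$mouse)
  slices <- unique(cells$slice)
  fields <- unique(cells$field)
  reMouse <- setNames(rnorm(length(mice), 0, design@randomSdMouse), mice)
  reSlice <- setNames(rnorm(length(slices), 0, design@randomSdSlice), slices)
  reField <- setNames(rnorm(length(fields), 0, design@randomSdField), fields)

  out <- cells[rep(seq_len(nrow(cells)), each = length(ints)),
               c("mouse", "slice", "field", "cell", "genotype")]
  out$intensity_uA <- rep(ints, times = nrow(cells))
  out$n_pulses <- pulse[as.character(out$intensity_uA)]
  eta <- design@interceptProbit +
    design@intensitySlope * (log(out$intensity_uA) - log(xmax)) +
    (out$genotype == "HET") * design@genotypeEffectProbit +
    reMouse[out$mouse] + reSlice[out$slice] + reField[out$field]
  out$active <- rbinom(nrow(out), 1, pnorm(eta))
  out$amplitude <- NA_real_
  act <- out$active == 1
  mu <- design@amplitudeLogMean[out$genotype[act]]
  out$amplitude[act] <- rlnorm(sum(act), mu, design@amplitudeLogSd)
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    interceptProbit = design@interceptProbit,
    genotypeEffectProbit = design@genotypeEffectProbit,
    intensitySlope = design@intensitySlope,
    randomEffects = list(mouse = reMouse, slice = reSlice,
                         field = reField),
    amplitudeLogMean = design@amplitudeLogMean,
    amplitudeLogSd = design@amplitudeLogSd)
  out
}

# piecewise-linear AP template sampled at dt_s; all segment durations are
# rounded to whole samples so the closed-form feature values are exact on
# the grid. Returns voltage samples starting at the threshold sample, plus
# the feature ground truth.
apTemplate <- function(threshold_mV = -40, peak_mV = 40, rise_ms = 0.5,
                       fall_ms = 1.0, ahp_mV = 12, ahpTime_ms = 3,
                       recover_ms = 5, recoverTo_mV = NULL, dt_s = 2e-5) {
  dtms <- dt_s * 1e3
  nr <- max(2L, round(rise_ms / dtms))
  nf <- max(2L, round(fall_ms / dtms))
  na <- max(2L, round(ahpTime_ms / dtms))
  trough <- threshold_mV - ahp_mV
  if (is.null(recoverTo_mV)) recoverTo_mV <- threshold_mV - 5
  nrec <- max(2L, round(recover_ms / dtms))
  v <- c(seq(threshold_mV, peak_mV, length.out = nr + 1),
         seq(peak_mV, threshold_mV, length.out = nf + 1)[-1],
         seq(threshold_mV, trough, length.out = na + 1)[-1],
         seq(trough, recoverTo_mV, length.out = nrec + 1)[-1])
  amp <- peak_mV - threshold_mV
  list(v = v,
       truth = list(threshold_mV = threshold_mV, peak_mV = peak_mV,
                    amplitude_mV = amp,
                    rise_ms = nr * dtms,
                    half_width_ms = (nr + nf) * dtms / 2,
                    ahp_amplitude_mV = ahp_mV,
                    ahp_time_ms = na * dtms,
                    peak_offset = nr))
}

#' Generate a current-clamp step family with known intrinsic properties
#'
#' Subthreshold sweeps follow the RC response
#' \eqn{V(t) = V_m + I R_m (1 - e^{-t/\tau})}; large hyperpolarizing steps
#' additionally carry an additive sag bump (difference of exponentials,
#' amplitude \code{sagFraction} of the steady-state deflection), so the
#' true sag percentage is computable from the analytic waveform.
#' Suprathreshold sweeps insert a piecewise-linear action-potential
#' template (constructed dV/dt profile) at spike times from a leaky
#' integrate-and-fire rule. The LIF voltage threshold — which is also the
#' AP threshold of the template — is placed 2 pA below the steady-state
#' rheobase deflection, so the first spiking step equals
#' \code{rheobase_pA} on any step grid containing it (grid spacing > 2 pA).
#'
#' @param cellParams list overriding any of: vm_mV (-80), rm_mohm (250),
#'   tau_ms (25), rheobase_pA (120), sagFraction (0.1), sagTau_ms (100:
#'   decay of the sag bump), sagMinStep_pA (-75: steps at or below this
#'   get sag), peak_mV (40), apRise_ms (0.5), apFall_ms (1.0),
#'   ahp_mV (12), ahpTime_ms (3)
#' @param stepAmplitudes_pA injected step currents; default
#'   \code{seq(-100, 300, by = 20)}
#' @param stepDur_s step duration, default 0.6 (600 ms)
#' @param baselineDur_s pre-step baseline, default 0.1
#' @param tailDur_s post-step tail, default 0.3 (total sweep 1 s)
#' @param sampleHz sampling rate, default 50000
#' @param noiseSd_mV additive Gaussian voltage noise SD (default 0)
#' @param seed integer seed
#' @return a \linkS4class{SweepSet} (mode current_clamp, unit mV); a
#'   zero-current rest sweep is always included. \code{sweepTruth()} carries
#'   vm, rm, tau, rheobase, sag percentage, AP features, and per-sweep spike
#'   times.
#' @export
genCurrentClamp <- function(cellParams = list(),
                            stepAmplitudes_pA = seq(-100, 300, by = 20),
                            stepDur_s = 0.6, baselineDur_s = 0.1,
                            tailDur_s = 0.3, sampleHz = 5e4,
                            noiseSd_mV = 0, seed = 1L) {
  p <- modifyList(list(vm_mV = -80, rm_mohm = 250, tau_ms = 25,
                       rheobase_pA = 120, sagFraction = 0.1,
                       sagTau_ms = 100, sagMinStep_pA = -75,
                       peak_mV = 40, apRise_ms = 0.5, apFall_ms = 1.0,
                       ahp_mV = 12, ahpTime_ms = 3), cellParams)
  if (p$rm_mohm <= 0 || p$tau_ms <= 0)
    stop("rm_mohm and tau_ms must be positive")
  dt <- 1 / sampleHz
  nBase <- round(baselineDur_s / dt)
  nStep <- round(stepDur_s / dt)
  nTail <- round(tailDur_s / dt)
  n <- nBase + nStep + nTail
  tt <- (seq_len(n) - 1) * dt
  tau <- p$tau_ms * 1e-3
  # LIF voltage threshold: 2 pA below the rheobase deflection at steady
  # state; it doubles as the AP threshold of the inserted template
  vth <- p$vm_mV + (p$rheobase_pA - 2) * p$rm_mohm * 1e-3
  tmpl <- apTemplate(vth, p$peak_mV, p$apRise_ms, p$apFall_ms,
                     p$ahp_mV, p$ahpTime_ms, dt_s = dt)
  amps <- c(0, stepAmplitudes_pA)   # rest sweep first
  sweeps <- matrix(p$vm_mV, n, length(amps))
  spikeTimes <- vector("list", length(amps))
  sagTruth <- NA_real_
  stepIdx <- nBase + seq_len(nStep)
  for (j in seq_along(amps)) {
    I <- amps[j]
    if (I == 0) { spikeTimes[[j]] <- numeric(0); next }
    dv <- I * p$rm_mohm * 1e-3
    v <- rep(p$vm_mV, n)
    if (I < 0) {
      ts <- (stepIdx - nBase - 1) * dt
      sag <- if (I <= p$sagMinStep_pA) p$sagFraction else 0
      tauSag <- p$sagTau_ms * 1e-3
      # additive sag bump: unit-peak difference of exponentials with the
      # membrane tau as rise, scaled to sagFraction of the deflection
      tPkBump <- log(tauSag / tau) * tau * tauSag / (tauSag - tau)
      bumpPk <- exp(-tPkBump / tauSag) - exp(-tPkBump / tau)
      fsag <- function(ts) p$vm_mV + dv * (1 - exp(-ts / tau)) +
        sag * dv * (exp(-ts / tauSag) - exp(-ts / tau)) / bumpPk
      v[stepIdx] <- fsag(ts)
      vEnd <- v[nBase + nStep]
      tTail <- (seq_len(nTail) - 1) * dt
      v[(nBase + nStep + 1):n] <- p$vm_mV + (vEnd - p$vm_mV) * exp(-tTail / tau)
      if (I == min(amps) && sag > 0) {
        # ground-truth sag from the dense analytic waveform
        vmin <- optimize(fsag, c(0, stepDur_s))$objective
        vss <- fsag(stepDur_s)
        sagTruth <- 100 * (vmin - vss) / (vmin - p$vm_mV)
      }
    } else {
      # leaky integrate-and-fire with template insertion
      vinf <- p$vm_mV + dv
      decay <- exp(-dt / tau)
      i <- nBase + 1
      vcur <- p$vm_mV
      st <- numeric(0)
      while (i <= nBase + nStep) {
        vcur <- vinf + (vcur - vinf) * decay
        if (vcur >= vth) {
          st <- c(st, tt[i])
          tend <- min(length(tmpl$v), n - i + 1)
          v[i:(i + tend - 1)] <- tmpl$v[seq_len(tend)]
          i <- i + tend
          vcur <- tmpl$v[tend]
          next
        }
        v[i] <- vcur
        i <- i + 1
      }
      # post-step relaxation back to rest
      if (n > nBase + nStep) {
        i0 <- nBase + nStep + 1
        vcur <- v[nBase + nStep]
        for (i in i0:n) {
          vcur <- p$vm_mV + (vcur - p$vm_mV) * decay
          v[i] <- vcur
        }
      }
      spikeTimes[[j]] <- st
    }
    sweeps[, j] <- v
  }
  if (noiseSd_mV > 0) {
    set.seed(seed)
    sweeps <- sweeps + rnorm(length(sweeps), 0, noiseSd_mV)
  }
  nSpk <- vapply(spikeTimes, length, 1L)
  spiking <- amps > 0 & nSpk > 0
  rheo <- if (any(spiking)) min(amps[spiking]) else NA_real_
  isis <- unlist(lapply(spikeTimes, function(s) if (length(s) >= 2) diff(s)))
  truth <- list(vm_mV = p$vm_mV, rm_mohm = p$rm_mohm, tau_ms = p$tau_ms,
                rheobase_pA = rheo, sag_percent = sagTruth,
                ap = tmpl$truth, spike_times_s = spikeTimes,
                step_window_s = c(baselineDur_s, baselineDur_s + stepDur_s),
                fi_hz = nSpk / stepDur_s,
                max_instantaneous_hz =
                  if (length(isis)) 1 / min(isis) else NA_real_,
                max_steady_state_hz = max(nSpk / stepDur_s))
  sweepSet(sweeps, tt, "current_clamp", "mV",
           command = data.frame(sweep = seq_along(amps),
                                amplitude_pA = amps,
                                onset_s = baselineDur_s,
                                duration_s = stepDur_s),
           protocol = list(step_onset_s = baselineDur_s,
                           step_duration_s = stepDur_s),
           metadata = list(truth = truth))
}

#' Generate evoked synaptic-current sweeps with a one-site binding law
#'
#' Per-intensity first-pulse peak amplitude follows
#' \eqn{B_{max} x / (K + x)}; later pulses in a train are scaled by
#' \code{pprFactors}. Each response is a difference-of-exponentials waveform
#' normalised to unit peak on the sampling grid, and trains superpose
#' linearly. Polarity "inward" produces negative-going currents (EPSC at
#' -70 mV); amplitudes in the ground truth are magnitudes (pA).
#'
#' @param bmax_pA saturating amplitude (> 0)
#' @param k_uA half-saturation intensity (> 0)
#' @param intensities_uA stimulation intensities, one sweep each
#' @param pprFactors per-pulse scale factors (length = pulses per train)
#' @param rise_ms,decay_ms waveform kinetics (default 1 and 7.2 ms)
#' @param stimHz train frequency (default 20)
#' @param noiseSd_pA additive Gaussian current noise SD
#' @param polarity "inward" or "outward"
#' @param sweepDur_s sweep length (default 0.5 s, first stimulus at 0.1 s)
#' @param stimOnset_s time of the first stimulus
#' @param sampleHz sampling rate (default 10000)
#' @param seed integer seed
#' @return a \linkS4class{SweepSet} (voltage_clamp, pA);
#'   \code{sweepTruth()} lists per-sweep per-pulse amplitudes, the binding
#'   parameters, PPRs and the decay constant.
#' @export
genSynapticSweeps <- function(bmax_pA = 1000, k_uA = 200,
                              intensities_uA = c(100, 200, 300, 400, 500),
                              pprFactors = 1, rise_ms = 1, decay_ms = 7.2,
                              stimHz = 20, noiseSd_pA = 0,
                              polarity = c("inward", "outward"),
                              sweepDur_s = 0.5, stimOnset_s = 0.1,
                              sampleHz = 1e4, seed = 1L) {
  polarity <- match.arg(polarity)
  if (bmax_pA <= 0 || k_uA <= 0) stop("bmax_pA and k_uA must be positive")
  if (rise_ms <= 0 || decay_ms <= 0) stop("kinetics must be positive")
  dt <- 1 / sampleHz
  n <- round(sweepDur_s / dt)
  tt <- (seq_len(n) - 1) * dt
  kern <- sampleKernel(kernelParams(rise_ms * 1e-3, decay_ms * 1e-3, 1), dt,
                       nSamples = n)
  nPulse <- length(pprFactors)
  stimTimes <- stimOnset_s + (seq_len(nPulse) - 1) / stimHz
  sgn <- if (polarity == "inward") -1 else 1
  sweeps <- matrix(0, n, length(intensities_uA))
  ampTruth <- matrix(0, length(intensities_uA), nPulse)
  for (j in seq_along(intensities_uA)) {
    x <- intensities_uA[j]
    a1 <- bmax_pA * x / (k_uA + x)
    y <- rep(0, n)
    for (pp in seq_len(nPulse)) {
      amp <- a1 * pprFactors[pp]
      ampTruth[j, pp] <- amp
      i0 <- round(stimTimes[pp] / dt) + 1
      idx <- i0:min(n, i0 + length(kern) - 1)
      y[idx] <- y[idx] + amp * kern[seq_along(idx)]
    }
    sweeps[, j] <- sgn * y
  }
  if (noiseSd_pA > 0) {
    set.seed(seed)
    sweeps <- sweeps + rnorm(length(sweeps), 0, noiseSd_pA)
  }
  truth <- list(bmax_pA = bmax_pA, k_uA = k_uA,
                amplitudes_pA = ampTruth,
                first_pulse_pA = ampTruth[, 1],
                ppr = pprFactors / pprFactors[1],
                decay_ms = decay_ms, rise_ms = rise_ms,
                stim_times_s = stimTimes)
  sweepSet(sweeps, tt, "voltage_clamp", "pA",
           command = data.frame(sweep = seq_along(intensities_uA),
                                intensity_uA = intensities_uA),
           protocol = list(stim_times_s = stimTimes, stim_hz = stimHz,
                           polarity = polarity),
           metadata = list(truth = truth))
}
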