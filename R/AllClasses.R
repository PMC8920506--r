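#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment rowData assay
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats coef lm mad median nls optimize pf pnorm predict qnorm
#'   qt quantile rbinom rlnorm rnorm sd setNames t.test update var vcov
#'   anova as.formula binomial confint fitted gaussian logLik resid residuals
#' @importFrom utils read.csv read.delim write.csv head tail modifyList
NULL

#' Calcium indicator impulse-response parameters
#'
#' Difference-of-exponentials kernel describing the fluorescence transient
#' evoked by a single action potential. The kernel is normalised to unit peak
#' on the sampling grid in use, so \code{unitAmplitude} is the peak dF/F0 of
#' a single-spike transient.
#'
#' @slot rise_s rise time constant, seconds (> 0)
#' @slot decay_s decay time constant, seconds (> rise_s)
#' @slot unitAmplitude single-spike peak dF/F0 (> 0)
#' @export
setClass("KernelParams",
  representation(rise_s = "numeric", decay_s = "numeric",
                 unitAmplitude = "numeric"))

setValidity("KernelParams", function(object) {
  msg <- character()
  if (length(object@rise_s) != 1 || !is.finite(object@rise_s) ||
      object@rise_s <= 0)
    msg <- c(msg, "rise_s must be a single positive number")
  if (length(object@decay_s) != 1 || !is.finite(object@decay_s) ||
      object@decay_s <= 0)
    msg <- c(msg, "decay_s must be a single positive number")
  if (length(msg) == 0 && object@decay_s <= object@rise_s)
    msg <- c(msg, "decay_s must exceed rise_s")
  if (length(object@unitAmplitude) != 1 || !is.finite(object@unitAmplitude) ||
      object@unitAmplitude <= 0)
    msg <- c(msg, "unitAmplitude must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct kernel parameters
#'
#' @param rise_s rise time constant in seconds
#' @param decay_s decay time constant in seconds (must exceed \code{rise_s})
#' @param unitAmplitude peak dF/F0 response to a single action potential
#' @return a \linkS4class{KernelParams} object
#' @examples
#' kernelParams()
#' @export
kernelParams <- function(rise_s = 0.2, decay_s = 1.2, unitAmplitude = 0.3) {
  new("KernelParams", rise_s = as.numeric(rise_s),
      decay_s = as.numeric(decay_s),
      unitAmplitude = as.numeric(unitAmplitude))
}

#' @describeIn kernelParams accessor for the rise time constant (s)
#' @param object a \code{KernelParams}
#' @export
kernelRise <- function(object) object@rise_s

#' @describeIn kernelParams accessor for the decay time constant (s)
#' @export
kernelDecay <- function(object) object@decay_s

#' @describeIn kernelParams accessor for the single-spike peak dF/F0
#' @export
unitAmplitude <- function(object) object@unitAmplitude

setMethod("show", "KernelParams", function(object) {
  cat("KernelParams: rise", object@rise_s, "s, decay", object@decay_s,
      "s, unit amplitude", object@unitAmplitude, "dF/F0\n")
})

#' Evaluate the normalised indicator kernel on a sampling grid
#'
#' Samples the difference-of-exponentials impulse response
#' \eqn{h(t) = e^{-t/\tau_d} - e^{-t/\tau_r}} at \code{0, dt, 2 dt, ...} and
#' normalises to unit maximum on that grid, so a single spike placed on a
#' frame produces a sampled peak of exactly \code{unitAmplitude}.
#'
#' @param kernel a \linkS4class{KernelParams}
#' @param dt sampling interval, seconds
#' @param nSamples number of samples; default covers decay to < 1e-4 of peak
#' @return numeric vector of kernel samples with maximum 1
#' @export
sampleKernel <- function(kernel, dt, nSamples = NULL) {
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0)
  if (is.null(nSamples))
    nSamples <- ceiling(10 * kernel@decay_s / dt)
  tt <- (seq_len(nSamples) - 1) * dt
  h <- exp(-tt / kernel@decay_s) - exp(-tt / kernel@rise_s)
  pk <- max(h)
  if (pk <= 0) stop("degenerate kernel: nonpositive peak")
  h / pk
}

#' Per-ROI fluorescence traces with acquisition metadata
#'
#' A \code{TraceSet} is a \link[SummarizedExperiment]{SummarizedExperiment}
#' holding one fluorescence trace per cell (rows = cells, columns = frames)
#' together with the frame period, the stimulation frame, the stimulus
#' condition and the experimental hierarchy keys (mouse, slice, field, cell)
#' in \code{rowData}. Generators attach ground truth (true spike counts,
#' noiseless peak dF/F0) as additional \code{rowData} columns.
#'
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

setValidity("TraceSet", function(object) {
  msg <- character()
  md <- S4Vectors::metadata(object)
  if (is.null(md$frame_period_s) || md$frame_period_s <= 0)
    msg <- c(msg, "metadata frame_period_s must be positive")
  nf <- ncol(object)
  if (is.null(md$stim_frame) || md$stim_frame < 1 || md$stim_frame > nf)
    msg <- c(msg, "metadata stim_frame must lie within 1..n_frames")
  hk <- c("mouse", "slice", "field", "cell")
  if (!all(hk %in% colnames(SummarizedExperiment::rowData(object))))
    msg <- c(msg, "rowData must carry mouse/slice/field/cell keys")
  if (length(msg)) msg else TRUE
})

#' Construct a TraceSet
#'
#' @param traces numeric matrix, cells x frames, raw fluorescence (a.u.)
#' @param framePeriod_s frame period in seconds
#' @param stimFrame 1-based frame index of stimulus onset
#' @param hierarchy data.frame with columns mouse, slice, field, cell
#'   (one row per trace); defaults to a single-field labelling
#' @param condition list describing the stimulus (e.g. intensity_uA,
#'   n_pulses, ptx)
#' @param truth optional data.frame of ground-truth columns bound to rowData
#' @return a \linkS4class{TraceSet}
#' @export
traceSet <- function(traces, framePeriod_s, stimFrame, hierarchy = NULL,
                     condition = list(), truth = NULL) {
  traces <- as.matrix(traces)
  n <- nrow(traces)
  if (is.null(hierarchy))
    hierarchy <- data.frame(mouse = "m1", slice = "s1", field = "f1",
                            cell = sprintf("c%03d", seq_len(n)))
  rd <- S4Vectors::DataFrame(hierarchy)
  if (!is.null(truth)) rd <- cbind(rd, S4Vectors::DataFrame(truth))
  rownames(traces) <- rd$cell
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(F = traces), rowData = rd,
    metadata = list(frame_period_s = framePeriod_s,
                    stim_frame = as.integer(stimFrame),
                    condition = condition))
  new("TraceSet", se)
}

#' @describeIn traceSet fluorescence matrix (cells x frames)
#' @param object a \code{TraceSet}
#' @export
traces <- function(object) SummarizedExperiment::assay(object, "F")

#' @describeIn traceSet frame period in seconds
#' @export
framePeriod <- function(object) S4Vectors::metadata(object)$frame_period_s

#' @describeIn traceSet 1-based stimulation frame
#' @export
stimFrame <- function(object) S4Vectors::metadata(object)$stim_frame

#' @describeIn traceSet stimulus condition descriptor (list)
#' @export
condition <- function(object) S4Vectors::metadata(object)$condition

#' @describeIn traceSet hierarchy keys as a data.frame
#' @export
hierarchyKeys <- function(object) {
  rd <- SummarizedExperiment::rowData(object)
  as.data.frame(rd[, c("mouse", "slice", "field", "cell")])
}

setMethod("show", "TraceSet", function(object) {
  md <- S4Vectors::metadata(object)
  cat("TraceSet:", nrow(object), "cells x", ncol(object), "frames @",
      signif(1 / md$frame_period_s, 4), "Hz; stim at frame",
      md$stim_frame, "\n")
  if (length(md$condition))
    cat("  condition:",
        paste(names(md$condition), unlist(md$condition),
              sep = "=", collapse = ", "), "\n")
})

#' Design of a hierarchical slice-imaging population experiment
#'
#' Describes a nested mouse -> slice -> field -> cell design in which each
#' cell's activation by perforant-path stimulation is Bernoulli with a
#' probit-scale linear predictor (intensity trend + genotype shift + nested
#' random intercepts), and active-cell response amplitudes are lognormal.
#' The default calibration targets marginal activation probabilities at the
#' maximal stimulus of 0.16 (wild-type) and 0.51 (mutant).
#'
#' @slot nMicePerGenotype,nSlicesPerMouse,nFieldsPerSlice,nCellsPerField counts
#' @slot intensities stimulation intensities, microamps, strictly increasing
#' @slot pulseCounts pulses per train for each condition
#' @slot interceptProbit wild-type probit intercept at the maximal intensity
#' @slot genotypeEffectProbit probit-scale genotype shift (conditional scale)
#' @slot intensitySlope probit change per unit log intensity ratio
#' @slot randomSdMouse,randomSdSlice,randomSdField probit-scale random SDs
#' @slot amplitudeLogMean named numeric, mean log amplitude per genotype
#' @slot amplitudeLogSd SD of log amplitude
#' @slot seed integer seed
#' @export
setClass("PopulationDesign",
  representation(nMicePerGenotype = "integer", nSlicesPerMouse = "integer",
                 nFieldsPerSlice = "integer", nCellsPerField = "integer",
                 intensities = "numeric", pulseCounts = "numeric",
                 interceptProbit = "numeric", genotypeEffectProbit = "numeric",
                 intensitySlope = "numeric",
                 randomSdMouse = "numeric", randomSdSlice = "numeric",
                 randomSdField = "numeric",
                 amplitudeLogMean = "numeric", amplitudeLogSd = "numeric",
                 seed = "integer"))

setValidity("PopulationDesign", function(object) {
  msg <- character()
  cts <- c(object@nMicePerGenotype, object@nSlicesPerMouse,
           object@nFieldsPerSlice, object@nCellsPerField)
  if (any(cts < 1)) msg <- c(msg, "all counts must be >= 1")
  if (length(object@intensities) < 1)
    msg <- c(msg, "intensities must be non-empty")
  else if (any(diff(object@intensities) <= 0))
    msg <- c(msg, "intensities must be strictly increasing")
  if (any(c(object@randomSdMouse, object@randomSdSlice,
            object@randomSdField) < 0))
    msg <- c(msg, "random-effect SDs must be >= 0")
  if (object@amplitudeLogSd < 0) msg <- c(msg, "amplitudeLogSd must be >= 0")
  if (!all(c("WT", "HET") %in% names(object@amplitudeLogMean)))
    msg <- c(msg, "amplitudeLogMean must be named WT and HET")
  if (length(msg)) msg else TRUE
})

#' Construct a population design
#'
#' Unless probit-scale parameters are supplied explicitly, the wild-type
#' intercept and the genotype effect are calibrated so that the *marginal*
#' activation probability at the maximal stimulus (averaging over the nested
#' Gaussian random effects, i.e. \eqn{P = \Phi(\eta / \sqrt{1 + \sigma^2})})
#' equals \code{pMaxWt} and \code{pMaxHet}.
#'
#' @param nMicePerGenotype,nSlicesPerMouse,nFieldsPerSlice,nCellsPerField
#'   design counts
#' @param intensities stimulation intensities (microamps), increasing
#' @param pulseCounts pulses per stimulus train (recycled over conditions)
#' @param pMaxWt,pMaxHet target marginal activation at the maximal intensity
#' @param interceptProbit,genotypeEffectProbit optional explicit
#'   conditional-scale parameters overriding the calibration
#' @param intensitySlope probit slope per unit log-intensity (relative to max)
#' @param randomSdMouse,randomSdSlice,randomSdField probit random-effect SDs
#' @param amplitudeLogMean named numeric (WT, HET) mean log dF/F0 of active
#'   cells
#' @param amplitudeLogSd SD of log amplitude
#' @param seed integer seed used by the generator
#' @return a \linkS4class{PopulationDesign}
#' @examples
#' populationDesign()
#' @export
populationDesign <- function(nMicePerGenotype = 6, nSlicesPerMouse = 2,
                             nFieldsPerSlice = 2, nCellsPerField = 15,
                             intensities = c(50, 100, 200, 400),
                             pulseCounts = 4,
                             pMaxWt = 0.16, pMaxHet = 0.51,
                             interceptProbit = NULL,
                             genotypeEffectProbit = NULL,
                             intensitySlope = 0.9,
                             randomSdMouse = 0.3, randomSdSlice = 0.2,
                             randomSdField = 0.2,
                             amplitudeLogMean = c(WT = log(0.5),
                                                  HET = log(1.15)),
                             amplitudeLogSd = 0.5,
                             seed = 1L) {
  sig2 <- randomSdMouse^2 + randomSdSlice^2 + randomSdField^2
  scale <- sqrt(1 + sig2)
  if (is.null(interceptProbit)) interceptProbit <- qnorm(pMaxWt) * scale
  if (is.null(genotypeEffectProbit))
    genotypeEffectProbit <- (qnorm(pMaxHet) - qnorm(pMaxWt)) * scale
  new("PopulationDesign",
      nMicePerGenotype = as.integer(nMicePerGenotype),
      nSlicesPerMouse = as.integer(nSlicesPerMouse),
      nFieldsPerSlice = as.integer(nFieldsPerSlice),
      nCellsPerField = as.integer(nCellsPerField),
      intensities = as.numeric(intensities),
      pulseCounts = as.numeric(pulseCounts),
      interceptProbit = interceptProbit,
      genotypeEffectProbit = genotypeEffectProbit,
      intensitySlope = intensitySlope,
      randomSdMouse = randomSdMouse, randomSdSlice = randomSdSlice,
      randomSdField = randomSdField,
      amplitudeLogMean = amplitudeLogMean,
      amplitudeLogSd = amplitudeLogSd,
      seed = as.integer(seed))
}

setMethod("show", "PopulationDesign", function(object) {
  cat("PopulationDesign:", object@nMicePerGenotype, "mice/genotype x",
      object@nSlicesPerMouse, "slices x", object@nFieldsPerSlice,
      "fields x", object@nCellsPerField, "cells\n")
  cat("  intensities (uA):", paste(object@intensities, collapse = ", "),
      "\n")
  cat("  probit: intercept", signif(object@interceptProbit, 4),
      ", genotype effect", signif(object@genotypeEffectProbit, 4),
      ", slope", object@intensitySlope, "\n")
  cat("  random SDs (mouse/slice/field):", object@randomSdMouse,
      object@randomSdSlice, object@randomSdField, "\n")
})

#' Uniformly sampled voltage- or current-clamp sweep series
#'
#' Holds a samples x sweeps matrix of recorded values with a shared time
#' base, the command protocol (one row per sweep for step protocols) and a
#' free-form protocol list (e.g. synaptic stimulus times). Generators attach
#' ground truth in \code{metadata(x)$truth}.
#'
#' @slot data numeric matrix, samples x sweeps
#' @slot time_s numeric vector of sample times (uniform)
#' @slot mode "current_clamp" or "voltage_clamp"
#' @slot unit recorded unit, "mV" or "pA"
#' @slot command data.frame describing per-sweep command steps
#' @slot protocol list of protocol details (stimulus times, intensities, ...)
#' @slot metadata list; generators put ground truth here
#' @export
setClass("SweepSet",
  representation(data = "matrix", time_s = "numeric", mode = "character",
                 unit = "character", command = "data.frame",
                 protocol = "list", metadata = "list"))

setValidity("SweepSet", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@time_s))
    msg <- c(msg, "nrow(data) must equal length(time_s)")
  if (length(object@time_s) > 2) {
    dt <- diff(object@time_s)
    if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
      msg <- c(msg, "time base must be uniformly sampled")
    if (dt[1] <= 0) msg <- c(msg, "time base must be increasing")
  }
  if (!object@mode %in% c("current_clamp", "voltage_clamp"))
    msg <- c(msg, "mode must be current_clamp or voltage_clamp")
  if (length(msg)) msg else TRUE
})

#' Construct a SweepSet
#'
#' @param data samples x sweeps numeric matrix
#' @param time_s uniform sample times in seconds
#' @param mode "current_clamp" or "voltage_clamp"
#' @param unit recorded unit ("mV" for current clamp, "pA" for voltage clamp)
#' @param command per-sweep command description (data.frame)
#' @param protocol list of protocol details
#' @param metadata list of extra metadata (ground truth for generated sets)
#' @return a \linkS4class{SweepSet}
#' @export
sweepSet <- function(data, time_s, mode, unit,
                     command = data.frame(), protocol = list(),
                     metadata = list()) {
  new("SweepSet", data = as.matrix(data), time_s = as.numeric(time_s),
      mode = mode, unit = unit, command = command, protocol = protocol,
      metadata = metadata)
}

#' @describeIn sweepSet samples x sweeps matrix
#' @param object a \code{SweepSet}
#' @export
sweepData <- function(object) object@data

#' @describeIn sweepSet sample times (s)
#' @export
sweepTimes <- function(object) object@time_s

#' @describeIn sweepSet sampling interval (s)
#' @export
sweepDt <- function(object) object@time_s[2] - object@time_s[1]

#' @describeIn sweepSet per-sweep command table
#' @export
sweepCommand <- function(object) object@command

#' @describeIn sweepSet protocol list
#' @export
sweepProtocol <- function(object) object@protocol

#' @describeIn sweepSet ground truth attached by a generator (or NULL)
#' @export
sweepTruth <- function(object) object@metadata$truth

setMethod("show", "SweepSet", function(object) {
  cat("SweepSet:", ncol(object@data), "sweeps x", nrow(object@data),
      "samples (", object@mode, ",", object@unit, ") @",
      signif(1 / sweepDt(object), 5), "Hz\n")
})

#' Detection threshold from a normal fit to null dF/F0 values
#'
#' @slot noiseMean fitted mean of the null distribution (dF/F0)
#' @slot noiseSd fitted SD (maximum likelihood)
#' @slot pTail upper-tail probability defining the threshold
#' @slot threshold noiseMean + z(1 - pTail) * noiseSd
#' @export
setClass("DetectionThreshold",
  representation(noiseMean = "numeric", noiseSd = "numeric",
                 pTail = "numeric", threshold = "numeric"))

setValidity("DetectionThreshold", function(object) {
  msg <- character()
  if (object@pTail <= 0 || object@pTail > 0.5)
    msg <- c(msg, "pTail must lie in (0, 0.5]")
  expected <- object@noiseMean + qnorm(1 - object@pTail) * object@noiseSd
  if (abs(object@threshold - expected) > 1e-8 * max(1, abs(expected)))
    msg <- c(msg, "threshold inconsistent with noiseMean/noiseSd/pTail")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DetectionThreshold", function(object) {
  cat("DetectionThreshold: mean", signif(object@noiseMean, 4), "SD",
      signif(object@noiseSd, 4), "p_tail", object@pTail, "-> threshold",
      signif(object@threshold, 5), "dF/F0\n")
})

#' Non-negative deconvolution result for one trace
#'
#' @slot activity per-frame deconvolved activity in spike units (>= 0)
#' @slot events data.frame of detected events (frame, magnitude in spikes)
#' @slot spikeCount total event magnitude after the 0.5-spike event threshold
#' @slot framePeriod_s frame period used
#' @export
setClass("SpikeEstimate",
  representation(activity = "numeric", events = "data.frame",
                 spikeCount = "numeric", framePeriod_s = "numeric"))

setValidity("SpikeEstimate", function(object) {
  msg <- character()
  if (any(object@activity < -1e-9))
    msg <- c(msg, "activity must be non-negative")
  if (object@spikeCount < 0) msg <- c(msg, "spikeCount must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpikeEstimate", function(object) {
  cat("SpikeEstimate:", nrow(object@events), "events, total",
      signif(object@spikeCount, 4), "spikes over",
      length(object@activity), "frames\n")
})

#' One-site binding fit (Bmax x / (K + x))
#'
#' @slot bmax saturating amplitude, pA
#' @slot k half-saturation intensity, microamps
#' @slot rss residual sum of squares
#' @slot df residual degrees of freedom
#' @slot converged logical convergence flag
#' @slot model the underlying nls fit (or NULL)
#' @export
setClass("BindingFit",
  representation(bmax = "numeric", k = "numeric", rss = "numeric",
                 df = "numeric", converged = "logical",
                 model = "ANY"))

setValidity("BindingFit", function(object) {
  msg <- character()
  if (object@converged && (object@bmax <= 0 || object@k <= 0))
    msg <- c(msg, "converged fit must have bmax > 0 and k > 0")
  if (object@rss < 0) msg <- c(msg, "rss must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BindingFit", function(object) {
  cat("BindingFit: Bmax", signif(object@bmax, 5), "pA, K",
      signif(object@k, 5), "uA (RSS", signif(object@rss, 4), ", df",
      object@df, ")\n")
})

#' Hierarchical mixed-model fit wrapper
#'
#' Wraps an lme4/lmerTest fit of one of the population responses together
#' with its specification, so that genotype-curve comparisons can refit the
#' reduced model from the stored call.
#'
#' @slot model the fitted merMod object
#' @slot response "active", "amplitude" or "est_spikes"
#' @slot family "binomial-probit" or "normal-log"
#' @slot formula model formula used
#' @slot data the model frame source data
#' @slot converged logical
#' @slot messages character vector of convergence diagnostics
#' @export
setClass("GlmmFit",
  representation(model = "ANY", response = "character", family = "character",
                 formula = "ANY", data = "data.frame", converged = "logical",
                 messages = "character"))

setMethod("show", "GlmmFit", function(object) {
  cat("GlmmFit:", object@response, "~ [", object@family, "],",
      if (object@converged) "converged" else "NOT CONVERGED", "\n")
  print(fixedEffects(object))
})

#' Fixed-effect table of a mixed-model fit
#'
#' @param fit a \linkS4class{GlmmFit}
#' @return data.frame with estimate, SE, z/t value and p value per term
#' @export
fixedEffects <- function(fit) {
  co <- coef(summary(fit@model))
  df <- as.data.frame(co)
  names(df)[1:2] <- c("estimate", "se")
  df
}

#' Random-effect variance components of a mixed-model fit
#'
#' @param fit a \linkS4class{GlmmFit}
#' @return data.frame of grouping factor and variance
#' @export
randomVariances <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit@model))
  vc[, c("grp", "vcov", "sdcor")]
}
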