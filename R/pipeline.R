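# End-to-end orchestration: generate -> process -> fit -> report, with a
# flat dotted-namespace key/value configuration that validates against a
# schema and round-trips through text. Outputs carry no timestamps, so
# identical config + seed gives byte-identical machine-readable output.

.configSchema <- function() {
  list(
    seed = "integer",
    stages.synth = "logical", stages.imaging = "logical",
    stages.calibration = "logical", stages.deconv = "logical",
    stages.popstats = "logical", stages.ephys = "logical",
    synth.n_traces = "integer", synth.max_spikes = "integer",
    synth.noise_sd = "numeric",
    kernel.rise_s = "numeric", kernel.decay_s = "numeric",
    kernel.unit_amplitude = "numeric",
    imaging.baseline_frames = "integer", imaging.cutoff_hz = "numeric",
    imaging.n_sd = "numeric",
    calibration.p_tail = "numeric",
    deconv.event_threshold = "numeric",
    pop.n_mice = "integer", pop.n_slices = "integer",
    pop.n_fields = "integer", pop.n_cells = "integer")
}

#' Default pipeline configuration
#'
#' @param seed integer seed stamped into every stage
#' @return named list (flat, dotted namespaces) accepted by
#'   \code{\link{runPipeline}}
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(seed = as.integer(seed),
       stages.synth = TRUE, stages.imaging = TRUE,
       stages.calibration = TRUE, stages.deconv = TRUE,
       stages.popstats = TRUE, stages.ephys = TRUE,
       synth.n_traces = 60L, synth.max_spikes = 14L,
       synth.noise_sd = 0.06,
       kernel.rise_s = 0.2, kernel.decay_s = 1.2,
       kernel.unit_amplitude = 0.3,
       imaging.baseline_frames = 50L, imaging.cutoff_hz = 5,
       imaging.n_sd = 3,
       calibration.p_tail = 0.001,
       deconv.event_threshold = 0.5,
       pop.n_mice = 4L, pop.n_slices = 2L, pop.n_fields = 2L,
       pop.n_cells = 10L)
}

#' Validate a pipeline configuration against the schema
#'
#' Unknown keys and type mismatches are errors naming the offending key.
#'
#' @param config named list
#' @return the config with defaults filled in, invisibly usable
#' @export
validateRunConfig <- function(config) {
  schema <- .configSchema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  full <- modifyList(defaultRunConfig(), config)
  for (k in names(full)) {
    v <- full[[k]]
    ok <- switch(schema[[k]],
                 integer = is.numeric(v) && length(v) == 1 &&
                   v == round(v),
                 numeric = is.numeric(v) && length(v) == 1,
                 logical = is.logical(v) && length(v) == 1)
    if (!ok) stop("config key has wrong type: ", k)
    if (schema[[k]] == "integer") full[[k]] <- as.integer(v)
  }
  full
}

#' Write / read a pipeline configuration as key = value text
#'
#' @param config named list
#' @param path file path
#' @return \code{writeRunConfig}: path invisibly; \code{readRunConfig}:
#'   the validated config list
#' @export
writeRunConfig <- function(config, path) {
  writeKeyValue(config, path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- readKeyValue(path)
  for (k in names(raw))
    if (identical(raw[[k]], "TRUE")) raw[[k]] <- TRUE
    else if (identical(raw[[k]], "FALSE")) raw[[k]] <- FALSE
  validateRunConfig(raw)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order: synthetic-data generation,
#' imaging activation analysis, indicator calibration (linear AP line,
#' detection threshold), spike deconvolution with ground-truth validation,
#' hierarchical genotype comparison, and electrophysiology feature
#' extraction. Writes per-stage delimited outputs, the resolved
#' configuration, and a machine-readable key/value report to
#' \code{outDir}. A stage failure aborts with the failing stage named;
#' outputs of completed stages are preserved.
#'
#' @param config configuration list (see \code{\link{defaultRunConfig}});
#'   validated before anything runs
#' @param outDir output directory (created if needed)
#' @return the report as a named list, invisibly; also written to
#'   \code{report.txt}
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempdir()) {
  cfg <- validateRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeRunConfig(cfg, file.path(outDir, "config.resolved.txt"))
  report <- list(pipeline.seed = cfg$seed,
                 pipeline.package_version =
                   as.character(utils::packageVersion("dgexcite")))
  kp <- kernelParams(cfg$kernel.rise_s, cfg$kernel.decay_s,
                     cfg$kernel.unit_amplitude)
  stage <- function(name, enabled, fun) {
    if (!enabled) return(NULL)
    message("stage: ", name)
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  env <- new.env()
  stage("synth", cfg$stages.synth, function() {
    set.seed(cfg$seed)
    counts <- sample(0:cfg$synth.max_spikes, cfg$synth.n_traces,
                     replace = TRUE)
    env$ts <- genCalciumTraces(counts, kp, noiseSd = cfg$synth.noise_sd,
                               seed = cfg$seed + 1L)
    writeTraceSet(env$ts, file.path(outDir, "traces.csv"))
    env$design <- populationDesign(nMicePerGenotype = cfg$pop.n_mice,
                                   nSlicesPerMouse = cfg$pop.n_slices,
                                   nFieldsPerSlice = cfg$pop.n_fields,
                                   nCellsPerField = cfg$pop.n_cells,
                                   seed = cfg$seed + 2L)
    env$pop <- genPopulationDataset(env$design)
    writePopulation(env$pop, file.path(outDir, "population.tsv"))
    env$cc <- genCurrentClamp(seed = cfg$seed + 3L)
    env$syn <- genSynapticSweeps(pprFactors = c(1, 0.8, 0.7, 0.65),
                                 seed = cfg$seed + 4L)
    writeSweepSet(env$cc, file.path(outDir, "current_clamp.csv"))
    writeSweepSet(env$syn, file.path(outDir, "synaptic.csv"))
    report$synth.n_traces <<- nrow(env$ts)
    report$synth.n_population_rows <<- nrow(env$pop)
  })
  stage("imaging", cfg$stages.imaging, function() {
    env$resp <- analyzeTraces(env$ts,
                              baselineFrames = cfg$imaging.baseline_frames,
                              cutoffHz = cfg$imaging.cutoff_hz,
                              nSd = cfg$imaging.n_sd)
    write.csv(env$resp, file.path(outDir, "cell_responses.csv"),
              row.names = FALSE)
    fs <- summarizeField(env$resp, "all_cells")
    write.csv(fs, file.path(outDir, "field_summary.csv"),
              row.names = FALSE)
    report$imaging.proportion_active <<- fs$proportion
  })
  stage("calibration", cfg$stages.calibration, function() {
    pairs <- data.frame(spikes = env$resp$true_spikes,
                        peak_dff = env$resp$peak_dff)
    fit <- fitApCalciumLine(pairs)
    report$calibration.slope <<- fit$slope
    report$calibration.r_squared <<- fit$r_squared
    nullVals <- pairs$peak_dff[pairs$spikes == 0]
    if (length(nullVals) >= 5) {
      thr <- fitDetectionThreshold(nullVals, cfg$calibration.p_tail)
      report$calibration.threshold <<- thr@threshold
      writeKeyValue(list(noise_mean = thr@noiseMean,
                         noise_sd = thr@noiseSd, p_tail = thr@pTail,
                         threshold = thr@threshold),
                    file.path(outDir, "detection_threshold.txt"))
    }
  })
  stage("deconv", cfg$stages.deconv, function() {
    dff <- computeDFF(traces(env$ts), cfg$imaging.baseline_frames)
    est <- vapply(seq_len(nrow(dff)), function(i)
      deconvolve(dff[i, ], kp, framePeriod(env$ts),
                 eventThreshold = cfg$deconv.event_threshold)@spikeCount,
      1)
    truth <- SummarizedExperiment::rowData(env$ts)$true_spikes
    val <- validateDeconvolution(est, truth)
    write.csv(data.frame(cell = rownames(traces(env$ts)),
                         est_spikes = est, true_spikes = truth),
              file.path(outDir, "deconvolved.csv"), row.names = FALSE)
    report$deconv.r_squared <<- val$r_squared
  })
  stage("popstats", cfg$stages.popstats, function() {
    fit <- suppressMessages(suppressWarnings(
      fitGlmm(env$pop, response = "active")))
    lrt <- suppressMessages(suppressWarnings(compareGenotypeCurves(fit)))
    report$popstats.converged <<- fit@converged
    report$popstats.genotype_lrt_stat <<- lrt$statistic
    report$popstats.genotype_lrt_p <<- lrt$p
  })
  stage("ephys", cfg$stages.ephys, function() {
    prof <- intrinsicProfile(env$cc)
    write.csv(prof, file.path(outDir, "intrinsic_profile.csv"),
              row.names = FALSE)
    report$ephys.rheobase_pA <<- prof$rheobase_pA
    report$ephys.ap_half_width_ms <<- prof$half_width_ms
    tr <- sweepTruth(env$syn)
    psc <- measurePsc(sweepData(env$syn)[, ncol(sweepData(env$syn))],
                      sweepDt(env$syn), tr$stim_times_s)
    report$ephys.ppr_2_1 <<- psc$ppr_2_1
    report$ephys.epsc_decay_ms <<- psc$decay_tau_ms
  })
  writeKeyValue(report, file.path(outDir, "report.txt"))
  invisible(report)
}
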