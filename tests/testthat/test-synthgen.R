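# Generators: kernel convention, convolution oracle, determinism,
# population calibration, LIF rheobase, synaptic superposition, round trips.

test_that("noiseless calcium traces follow the kernel convention", {
  kp <- kernelParams(unitAmplitude = 0.3)
  ts <- genCalciumTraces(c(0, 1), kp, noiseSd = 0, seed = 1)
  dff <- computeDFF(traces(ts))
  # zero-spike trace is flat at baseline; one spike peaks at unitAmplitude
  expect_equal(max(abs(dff[1, ])), 0)
  expect_equal(max(dff[2, ]), 0.3, tolerance = 1e-12)
  expect_equal(SummarizedExperiment::rowData(ts)$true_peak_dff, c(0, 0.3))
})

test_that("generated traces match an independent convolution oracle", {
  set.seed(7)
  counts <- sample(0:14, 12, replace = TRUE)
  kp <- kernelParams(0.2, 1.2, 0.3)
  ts <- genCalciumTraces(counts, kp, noiseSd = 0, nFrames = 500,
                         framePeriod_s = 1 / 30, stimFrame = 51, seed = 7)
  dff <- computeDFF(traces(ts))
  for (i in seq_along(counts)) {
    sig <- oracleCalciumSignal(counts[i], 0.2, 1.2, 0.3, 1 / 30, 500, 51)
    expect_lt(max(abs(dff[i, ] - sig)), 1e-10)
  }
})

test_that("generators are deterministic under a fixed seed", {
  a <- genCalciumTraces(c(2, 5), kernelParams(), noiseSd = 0.05, seed = 42)
  b <- genCalciumTraces(c(2, 5), kernelParams(), noiseSd = 0.05, seed = 42)
  expect_identical(traces(a), traces(b))
  d <- populationDesign(nMicePerGenotype = 2, seed = 9L)
  expect_identical(genPopulationDataset(d), genPopulationDataset(d))
  s1 <- genSynapticSweeps(noiseSd_pA = 3, seed = 5)
  s2 <- genSynapticSweeps(noiseSd_pA = 3, seed = 5)
  expect_identical(sweepData(s1), sweepData(s2))
})

test_that("trace generation validates its preconditions", {
  expect_error(genCalciumTraces(1, kernelParams(), stimFrame = 30),
               "baseline")
  expect_error(kernelParams(rise_s = -0.1), "positive")
  expect_error(kernelParams(rise_s = 1.5, decay_s = 1.2), "exceed")
})

test_that("saturated design activates every cell", {
  d <- populationDesign(nMicePerGenotype = 2, nCellsPerField = 5,
                        interceptProbit = 8, genotypeEffectProbit = 0,
                        intensitySlope = 0,
                        randomSdMouse = 0, randomSdSlice = 0,
                        randomSdField = 0, seed = 3L)
  pop <- genPopulationDataset(d)
  expect_true(all(pop$active == 1))
  expect_true(all(is.finite(pop$amplitude)))
})

test_that("default activation probabilities are calibrated to 0.51 / 0.16", {
  # >= 1e4 cells per genotype at the maximal stimulus; compare against the
  # targets with a cluster-aware Monte-Carlo SE (per-mouse proportions)
  d <- populationDesign(nMicePerGenotype = 48, nCellsPerField = 55,
                        seed = 17L)
  pop <- genPopulationDataset(d, intensitiesSubset = "max")
  for (g in c("WT", "HET")) {
    target <- if (g == "WT") 0.16 else 0.51
    sub <- pop[pop$genotype == g, ]
    expect_gte(nrow(sub), 1e4)
    byMouse <- tapply(sub$active, sub$mouse, mean)
    se <- sd(byMouse) / sqrt(length(byMouse))
    expect_lt(abs(mean(sub$active) - target), 3 * se)
  }
})

test_that("population generator rejects invalid designs", {
  expect_error(populationDesign(intensities = numeric(0)))
  expect_error(populationDesign(intensities = c(100, 100)))
  expect_error(genPopulationDataset(populationDesign(),
                                    intensitiesSubset = 123),
               "intensities")
})

test_that("current-clamp generator obeys Ohm's law and the AP geometry", {
  cc <- genCurrentClamp(cellParams = list(rm_mohm = 100, sagFraction = 0),
                        stepAmplitudes_pA = c(-50, 200), seed = 1)
  tr <- sweepTruth(cc)
  dat <- sweepData(cc)
  tt <- sweepTimes(cc)
  # steady-state deflection of the -50 pA step is exactly -5 mV
  iSS <- tt >= 0.6 & tt < 0.7
  expect_equal(mean(dat[iSS, 2]) - tr$vm_mV, -5, tolerance = 1e-6)
  # template amplitude is peak minus threshold by construction
  expect_equal(tr$ap$amplitude_mV, tr$ap$peak_mV - tr$ap$threshold_mV)
  expect_error(genCurrentClamp(cellParams = list(rm_mohm = -5)), "positive")
})

test_that("LIF rheobase lands exactly on the step grid", {
  cc <- genCurrentClamp(cellParams = list(rheobase_pA = 120),
                        stepAmplitudes_pA = seq(0, 240, by = 10), seed = 1)
  tr <- sweepTruth(cc)
  expect_equal(tr$rheobase_pA, 120)
  # simulate-and-inspect: the 120 pA sweep spikes, the 110 pA sweep not
  cmd <- sweepCommand(cc)
  nSpk <- vapply(tr$spike_times_s, length, 1L)
  expect_gt(nSpk[cmd$amplitude_pA == 120], 0)
  expect_equal(nSpk[cmd$amplitude_pA == 110], 0L)
})

test_that("synaptic sweeps follow the one-site binding law and PPR", {
  ss <- genSynapticSweeps(bmax_pA = 1000, k_uA = 200,
                          intensities_uA = 200, pprFactors = c(1, 0.8),
                          noiseSd_pA = 0, seed = 1)
  tr <- sweepTruth(ss)
  expect_equal(tr$first_pulse_pA, 500)     # half-saturation at x = K
  expect_equal(tr$ppr, c(1, 0.8))
  expect_error(genSynapticSweeps(bmax_pA = -1), "positive")
  expect_error(genSynapticSweeps(rise_ms = -1), "positive")
})

test_that("noiseless trains match the explicit superposition oracle", {
  ss <- genSynapticSweeps(bmax_pA = 900, k_uA = 150,
                          intensities_uA = c(100, 300),
                          pprFactors = c(1, 0.8, 0.7, 0.65),
                          rise_ms = 1, decay_ms = 7.2, stimHz = 20,
                          noiseSd_pA = 0, seed = 1)
  tr <- sweepTruth(ss)
  dt <- sweepDt(ss)
  for (j in 1:2) {
    y <- oracleTrain(tr$stim_times_s, tr$amplitudes_pA[j, ],
                     1e-3, 7.2e-3, dt, nrow(sweepData(ss)))
    expect_lt(max(abs(-sweepData(ss)[, j] - y)), 1e-9)
  }
})

test_that("generated artifacts round-trip through the writers losslessly", {
  ts <- genCalciumTraces(c(0, 3, 7), kernelParams(), noiseSd = 0.05,
                         seed = 2)
  p <- tempfile(fileext = ".csv")
  writeTraceSet(ts, p)
  ts2 <- readTraceSet(p)
  expect_equal(traces(ts), traces(ts2))
  expect_identical(stimFrame(ts), stimFrame(ts2))
  expect_equal(framePeriod(ts), framePeriod(ts2))
  expect_equal(SummarizedExperiment::rowData(ts)$true_spikes,
               SummarizedExperiment::rowData(ts2)$true_spikes)

  ss <- genSynapticSweeps(noiseSd_pA = 2, seed = 3)
  p2 <- tempfile(fileext = ".csv")
  writeSweepSet(ss, p2)
  ss2 <- readSweepSet(p2)
  expect_equal(sweepData(ss), sweepData(ss2), ignore_attr = TRUE)
  expect_equal(sweepProtocol(ss)$stim_times_s,
               sweepProtocol(ss2)$stim_times_s)

  pop <- genPopulationDataset(populationDesign(nMicePerGenotype = 2))
  p3 <- tempfile(fileext = ".tsv")
  writePopulation(pop, p3)
  pop2 <- readPopulation(p3)
  expect_equal(pop$active, pop2$active)
  expect_equal(pop$amplitude, pop2$amplitude, tolerance = 1e-12)
  expect_identical(pop$field, pop2$field)
})
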