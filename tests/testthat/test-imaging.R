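# dF/F0, filtering, peak detection, activation calls, field summaries.

test_that("computeDFF matches its closed form and is scale invariant", {
  expect_equal(computeDFF(rep(100, 60)), rep(0, 60))
  tr <- c(rep(100, 50), rep(150, 20))
  expect_equal(computeDFF(tr)[60], 0.5)
  noisy <- 100 * (1 + rnorm(200, 0, 0.05))
  expect_lt(max(abs(computeDFF(noisy) - computeDFF(7.3 * noisy))), 1e-12)
  expect_error(computeDFF(rep(-1, 60)), "baseline")
  expect_error(computeDFF(rep(100, 60), baselineFrames = 1), ">= 2")
})

test_that("dF/F0 of a generated transient matches the convolution oracle", {
  kp <- kernelParams(0.2, 1.2, 0.3)
  ts <- genCalciumTraces(4, kp, noiseSd = 0, seed = 1)
  dff <- computeDFF(traces(ts)[1, ])
  sig <- oracleCalciumSignal(4, 0.2, 1.2, 0.3, 0.0338, 500, 51)
  expect_lt(max(abs(dff - sig)), 1e-10)
})

test_that("lowpass has unit DC gain and attenuates high frequencies", {
  expect_lt(max(abs(lowpass(rep(3.7, 100), 5, 30) - 3.7)), 1e-9)
  tt <- (0:999) / 1000
  hi <- sin(2 * pi * 300 * tt)          # far above a 20 Hz cutoff
  out <- lowpass(hi, 20, 1000)
  mid <- 200:800                        # avoid filter edge transients
  expect_lt(max(abs(out[mid])), max(abs(hi)) / 10)
  expect_error(lowpass(numeric(0), 5, 30), "empty")
  expect_error(lowpass(rnorm(100), 20, 30), "Nyquist")
})

test_that("detectPeaks returns ordered local maxima within the window", {
  bump <- c(0, 1, 2, 3, 2, 1, 0)
  pk <- detectPeaks(bump)
  expect_equal(pk$frame, 4)
  expect_equal(pk$amplitude, 3)
  expect_equal(nrow(detectPeaks(rep(0, 50))), 0)
  expect_error(detectPeaks(bump, integer(0)), "empty")
  expect_error(detectPeaks(bump, 1:20), "outside")
  # two separated kernel transients peak at the oracle frames
  kp <- kernelParams(0.1, 0.6, 0.3)
  sig1 <- oracleCalciumSignal(1, 0.1, 0.6, 0.3, 0.0338, 500, 60)
  sig2 <- oracleCalciumSignal(1, 0.1, 0.6, 0.3, 0.0338, 500, 300)
  pk2 <- detectPeaks(sig1 + sig2)
  o1 <- which.max(sig1); o2 <- which.max(sig2)
  expect_equal(pk2$frame, c(o1, o2))
})

test_that("classifyActive applies the mean + 3 SD rule", {
  pk <- function(a) data.frame(frame = 10, amplitude = a)
  expect_true(classifyActive(pk(0.1 + 4 * 0.02), 0.1, 0.02)$active)
  expect_false(classifyActive(pk(0.1 + 2 * 0.02), 0.1, 0.02)$active)
  expect_equal(classifyActive(pk(0.5), 0, 0.01)$peak_dff, 0.5)
  none <- data.frame(frame = integer(0), amplitude = numeric(0))
  expect_false(classifyActive(none, 0, 0.01)$active)
  expect_error(classifyActive(pk(1), 0, 0), "positive")
})

test_that("false-positive rate on pure noise matches the Monte-Carlo oracle", {
  nFrames <- 300; nTr <- 1500; noiseSd <- 0.05
  ts <- genCalciumTraces(rep(0, nTr), kernelParams(), noiseSd = noiseSd,
                         nFrames = nFrames, stimFrame = 51, seed = 11)
  resp <- analyzeTraces(ts)
  fpr <- mean(resp$active)
  oracle <- oracleNoiseFpr(4000, nFrames, 50, 51, 5, 1 / 0.0338, noiseSd,
                           seed = 12)
  # binomial 99% CI of the oracle estimate around the pipeline rate
  se <- sqrt(max(oracle * (1 - oracle), 1e-6) *
               (1 / 4000 + 1 / nTr))
  expect_lt(abs(fpr - oracle), max(2.576 * se, 0.005))
})

test_that("summarizeField handles the three denominator modes", {
  resp <- data.frame(cell = sprintf("c%02d", 1:10),
                     active = c(rep(TRUE, 4), rep(FALSE, 6)),
                     peak_dff = c(2, 3, 4, 5, rep(0.1, 6)))
  all <- summarizeField(resp, "all_cells")
  expect_equal(all$proportion, 0.4)
  expect_equal(all$mean_amplitude, 3.5)
  ref <- data.frame(cell = sprintf("c%02d", 1:10),
                    active = c(rep(TRUE, 5), rep(FALSE, 5)),
                    peak_dff = 1)
  ptx <- summarizeField(resp, "responds_to_ptx", ref)
  expect_equal(ptx$n_denominator, 5)
  expect_equal(ptx$proportion, 0.8)
  expect_error(summarizeField(resp, "responds_to_ptx"), "reference")
  bad <- ref; bad$cell <- sprintf("x%02d", 1:10)
  expect_error(summarizeField(resp, "responds_to_max_stim", bad), "match")
  # proportions always within [0, 1] and n_active <= n_denominator
  for (mode in c("all_cells", "responds_to_ptx")) {
    fs <- summarizeField(resp, mode, ref)
    expect_true(fs$proportion >= 0 && fs$proportion <= 1)
    expect_lte(fs$n_active, fs$n_denominator)
  }
})

test_that("field summaries of a synthetic population match direct aggregation", {
  d <- populationDesign(nMicePerGenotype = 2, seed = 21L)
  pop <- genPopulationDataset(d, intensitiesSubset = "max")
  one <- pop[pop$field == pop$field[1], ]
  resp <- data.frame(cell = one$cell, active = one$active == 1,
                     peak_dff = ifelse(is.na(one$amplitude), 0,
                                       one$amplitude))
  fs <- summarizeField(resp, "all_cells")
  expect_equal(fs$proportion, mean(one$active))
  expect_equal(fs$n_active, sum(one$active))
})

test_that("roiTraces averages labelled mask pixels", {
  movie <- array(0, c(4, 4, 10))
  mask <- matrix(0L, 4, 4)
  mask[1:2, 1:2] <- 1L; mask[3:4, 3:4] <- 2L
  for (f in 1:10) {
    movie[1:2, 1:2, f] <- f
    movie[3:4, 3:4, f] <- 2 * f
  }
  ts <- roiTraces(movie, mask, 0.0338, 5)
  expect_equal(unname(traces(ts)[1, ]), as.numeric(1:10))
  expect_equal(unname(traces(ts)[2, ]), as.numeric(2 * (1:10)))
  expect_error(roiTraces(movie, matrix(0L, 4, 4), 0.0338, 5), "labels")
})
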