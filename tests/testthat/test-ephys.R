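# Feature extraction against constructed waveforms and generator truth.

# build a voltage trace with triangular APs: slow ramp to threshold, linear
# rise to peak, linear fall back through threshold, optional AHP dip with
# recovery held just below threshold (as during a sustained current step)
triAp <- function(times_s, dt = 2e-5, dur = 0.8, vrest = -70, thr = -40,
                  peak = 40, rise_ms = 1, fall_ms = 1, ahp = 0) {
  n <- round(dur / dt)
  v <- rep(vrest, n)
  nr <- round(rise_ms * 1e-3 / dt); nf <- round(fall_ms * 1e-3 / dt)
  nRamp <- round(0.004 / dt)       # 7.5 mV/ms ramp, below the spike criterion
  for (t0 in sort(times_s)) {
    i <- round(t0 / dt) + 1
    v[(i - nRamp):(i - 1)] <- seq(v[i - nRamp - 1], thr,
                                  length.out = nRamp)
    shape <- c(seq(thr, peak, length.out = nr + 1),
               seq(peak, thr, length.out = nf + 1)[-1])
    if (ahp > 0) {
      na <- round(0.003 / dt)
      shape <- c(shape, seq(thr, thr - ahp, length.out = na + 1)[-1],
                 seq(thr - ahp, thr - 4, length.out = na + 1)[-1])
    }
    iEnd <- i + length(shape) - 1
    v[i:iEnd] <- shape
    # hold the final level until the next event so troughs stay troughs
    if (iEnd < n) v[(iEnd + 1):n] <- shape[length(shape)]
  }
  v
}

test_that("spike detection enforces the dV/dt, overshoot and amplitude criteria", {
  dt <- 2e-5
  expect_equal(nrow(detectSpikes(rep(-70, 1000), dt)), 0)
  # depolarization peaking below 0 mV is not a spike
  sub <- triAp(0.1, peak = -20, thr = -50)
  expect_equal(nrow(detectSpikes(sub, dt)), 0)
  # a proper AP is found with its threshold at the constructed crossing
  v <- triAp(0.1)
  sp <- detectSpikes(v, dt)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$threshold_mV, -40, tolerance = 0.5)
  expect_equal(sp$peak_mV, 40)
  expect_equal(sp$amplitude_mV, 80, tolerance = 0.5)
  # the whole trace shifted down so the peak stays subthreshold: rejected
  expect_equal(nrow(detectSpikes(v - 50, dt)), 0)
  # shifted but still overshooting: threshold-relative features unchanged
  sp2 <- detectSpikes(v - 10, dt)
  expect_equal(sp2$amplitude_mV, sp$amplitude_mV)
})

test_that("AP features match the constructed geometry", {
  dt <- 2e-5
  v <- triAp(0.1, rise_ms = 1, fall_ms = 1, ahp = 12)
  sp <- detectSpikes(v, dt)
  ft <- measureApFeatures(v, dt, sp[1, ])
  expect_equal(ft$amplitude_mV, 80, tolerance = 0.5)
  expect_equal(ft$half_width_ms, 1, tolerance = 0.02)
  expect_equal(ft$rise_ms, 1, tolerance = 0.05)
  expect_equal(ft$ahp_amplitude_mV, 12, tolerance = 0.5)
  # truncated AP: no falling crossing before the sweep ends
  cut <- v[1:(sp$peak_index + 3)]
  spCut <- detectSpikes(cut, dt)
  expect_error(measureApFeatures(cut, dt, spCut[1, ]), "truncated")
})

test_that("generator ground truth is recovered by the full profile", {
  cc <- genCurrentClamp(seed = 1)
  tr <- sweepTruth(cc)
  prof <- intrinsicProfile(cc)
  dt <- sweepDt(cc)
  expect_equal(prof$vm_mV, tr$vm_mV, tolerance = 1e-6)
  expect_lt(abs(prof$rm_mohm - tr$rm_mohm) / tr$rm_mohm, 0.02)
  expect_lt(abs(prof$tau_ms - tr$tau_ms) / tr$tau_ms, 0.02)
  expect_lt(abs(prof$sag_percent - tr$sag_percent) / tr$sag_percent, 0.02)
  expect_equal(prof$rheobase_pA, tr$rheobase_pA)   # exact on the grid
  expect_equal(prof$threshold_mV, tr$ap$threshold_mV, tolerance = 0.1)
  expect_equal(prof$peak_mV, tr$ap$peak_mV)
  expect_equal(prof$half_width_ms, tr$ap$half_width_ms,
               tolerance = dt * 1e3)
  expect_equal(prof$rise_ms, tr$ap$rise_ms, tolerance = dt * 1e3)
  expect_equal(prof$ahp_amplitude_mV, tr$ap$ahp_amplitude_mV,
               tolerance = 0.5)
  expect_equal(prof$ahp_time_ms, tr$ap$ahp_time_ms, tolerance = dt * 1e3)
  expect_equal(prof$max_steady_state_hz, tr$max_steady_state_hz)
  expect_equal(prof$max_instantaneous_hz, tr$max_instantaneous_hz,
               tolerance = 1e-6)
})

test_that("passive measurements follow their defining formulas", {
  # Ohm's law: -5 mV deflection at -50 pA means 100 MOhm
  cc <- genCurrentClamp(cellParams = list(rm_mohm = 100, sagFraction = 0),
                        stepAmplitudes_pA = c(-50, 150), seed = 1)
  pas <- measurePassive(cc)
  expect_equal(pas$rm_mohm, 100, tolerance = 0.5)
  # sag formula on a constructed step: baseline -70, min -90, steady -85
  dt <- 1e-4; n <- 10000
  tt <- (seq_len(n) - 1) * dt
  rest <- rep(-70, n)
  stepV <- rep(-70, n)
  on <- tt >= 0.1 & tt < 0.7
  td <- tt[on] - 0.1
  # 20 ms linear drop to the -90 mV minimum, then relaxation to -85 mV
  stepV[on] <- ifelse(td <= 0.02, -70 - 20 * td / 0.02,
                      -85 - 5 * exp(-(td - 0.02) / 0.05))
  ss <- sweepSet(cbind(rest, stepV), tt, "current_clamp", "mV",
                 command = data.frame(sweep = 1:2, amplitude_pA = c(0, -100),
                                      onset_s = 0.1, duration_s = 0.6))
  pas2 <- measurePassive(ss, maxDeflection_mV = 20)
  expect_equal(pas2$sag_percent, 25, tolerance = 0.5)
  expect_error(measurePassive(sweepSet(cbind(rest), tt, "current_clamp",
                                       "mV",
                                       command = data.frame(sweep = 1,
                                                            amplitude_pA = 0,
                                                            onset_s = 0.1,
                                                            duration_s = 0.6))),
               "hyperpolarizing")
})

test_that("firing rates follow their definitions", {
  dt <- 2e-5
  v <- triAp(c(0.2, 0.21, 0.23), dt = dt, ahp = 10)
  ss <- sweepSet(cbind(rep(-70, length(v)), v),
                 (seq_along(v) - 1) * dt, "current_clamp", "mV",
                 command = data.frame(sweep = 1:2, amplitude_pA = c(0, 100),
                                      onset_s = 0.1, duration_s = 0.6))
  fi <- computeFi(ss)
  expect_equal(fi$max_instantaneous_hz, 100, tolerance = 0.5)  # 10 ms ISI
  expect_equal(fi$max_steady_state_hz, 3 / 0.6)
  expect_equal(fi$rheobase_pA, 100)
  # no spiking sweep: explicit NA sentinel, not zero
  quiet <- sweepSet(cbind(rep(-70, length(v)), rep(-70, length(v))),
                    (seq_along(v) - 1) * dt, "current_clamp", "mV",
                    command = data.frame(sweep = 1:2,
                                         amplitude_pA = c(0, 50),
                                         onset_s = 0.1, duration_s = 0.6))
  expect_true(is.na(computeFi(quiet)$rheobase_pA))
})

test_that("PSC amplitudes and PPR are exact on isolated pulses", {
  dt <- 1e-4; n <- 5000
  tt <- (seq_len(n) - 1) * dt
  y <- oracleTrain(c(0.05, 0.25), c(100, 80), 1e-3, 7.2e-3, dt, n)
  res <- measurePsc(-y, dt, c(0.05, 0.25))
  expect_equal(res$amplitudes_pA, c(100, 80), tolerance = 1e-6)
  expect_equal(res$ppr_2_1, 0.8, tolerance = 1e-6)
  expect_error(measurePsc(-y, dt, c(0.05, 1.0)), "outside")
})

test_that("superposed trains re-baseline to within 3 percent of truth", {
  ss <- genSynapticSweeps(pprFactors = c(1, 0.8, 0.7, 0.65),
                          intensities_uA = 300, noiseSd_pA = 0, seed = 1)
  tr <- sweepTruth(ss)
  res <- measurePsc(sweepData(ss)[, 1], sweepDt(ss), tr$stim_times_s)
  expect_lt(max(abs(res$amplitudes_pA - tr$amplitudes_pA[1, ]) /
                  tr$amplitudes_pA[1, ]), 0.03)
  expect_equal(res$ppr_2_1, 0.8, tolerance = 0.03)
  expect_equal(res$ppr_4_1, 0.65, tolerance = 0.03)
  # decay constant recovered within 1 percent on noiseless input
  expect_lt(abs(res$decay_tau_ms - 7.2) / 7.2, 0.01)
})

test_that("E/I ratios divide matched intensities", {
  e <- data.frame(intensity_uA = c(100, 300), amplitude_pA = c(500, 900))
  i <- data.frame(intensity_uA = c(100, 300), amplitude_pA = c(500, 500))
  r <- eiRatio(e, i)
  expect_equal(r$ei_ratio, c(1, 1.8))
  iz <- i; iz$amplitude_pA <- c(0, 500)
  expect_true(is.na(eiRatio(e, iz)$ei_ratio[1]))
  bad <- data.frame(intensity_uA = c(100, 400), amplitude_pA = c(1, 1))
  expect_error(eiRatio(e, bad), "match")
})

test_that("one-site binding fits and the extra-SS F test are exact", {
  x <- c(100, 200, 300, 400, 500)
  mk <- function(bmax, k) data.frame(intensity = x,
                                     amplitude = bmax * x / (k + x))
  res <- fitBindingAndCompare(list(WT = mk(1000, 200), HET = mk(1800, 250)))
  expect_lt(abs(res$fits$WT@bmax - 1000) / 1000, 1e-6)
  expect_lt(abs(res$fits$WT@k - 200) / 200, 1e-6)
  expect_lt(abs(res$fits$HET@bmax - 1800) / 1800, 1e-6)
  # identical groups: pooled fit is as good as separate fits
  set.seed(140)
  noisy <- mk(1000, 200); noisy$amplitude <- noisy$amplitude + rnorm(5, 0, 20)
  same <- fitBindingAndCompare(list(A = noisy, B = noisy))
  expect_lt(same$f, 1e-6)
  expect_gt(same$p, 0.99)
  expect_error(fitBindingAndCompare(list(A = mk(1, 1)[1:2, ],
                                         B = mk(1, 1))), "3 intensities")
})

test_that("the F statistic matches a hand computation on a toy dataset", {
  set.seed(141)
  x <- c(50, 150, 400)
  g1 <- data.frame(intensity = x,
                   amplitude = 800 * x / (180 + x) + c(12, -9, 4))
  g2 <- data.frame(intensity = x,
                   amplitude = 1400 * x / (220 + x) + c(-7, 11, -3))
  res <- fitBindingAndCompare(list(A = g1, B = g2))
  # recompute every sum of squares from the returned parameters and plug
  # into the F formula written out by hand
  rssOf <- function(fit, df) sum((df$amplitude -
                                    fit@bmax * df$intensity /
                                    (fit@k + df$intensity))^2)
  ssSep <- rssOf(res$fits$A, g1) + rssOf(res$fits$B, g2)
  pooledData <- rbind(g1, g2)
  ssPool <- rssOf(res$pooled, pooledData)
  dfSep <- 6 - 4; dfPool <- 6 - 2
  fHand <- ((ssPool - ssSep) / (dfPool - dfSep)) / (ssSep / dfSep)
  expect_equal(res$f, fHand, tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 2)
  # separate fits can never be worse than the pooled fit
  expect_gte(res$f, -1e-10)
})

test_that("separate binding fits never exceed the pooled residual", {
  set.seed(150)
  x <- c(100, 200, 300, 400, 500)
  for (r in 1:10) {
    g1 <- data.frame(intensity = x,
                     amplitude = 700 * x / (150 + x) + rnorm(5, 0, 30))
    g2 <- data.frame(intensity = x,
                     amplitude = (700 + 100 * r) * x / (150 + 20 * r + x) +
                       rnorm(5, 0, 30))
    res <- fitBindingAndCompare(list(A = g1, B = g2))
    ssSep <- res$fits$A@rss + res$fits$B@rss
    expect_lte(ssSep, res$pooled@rss + 1e-6)
  }
})
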