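# Hierarchical mixed models: collapse-to-GLM oracle, LRT definition,
# paired within-field tests, amplitude model.

test_that("zero random variance collapses the GLMM to plain probit regression", {
  d <- populationDesign(nMicePerGenotype = 8, nCellsPerField = 40,
                        randomSdMouse = 0, randomSdSlice = 0,
                        randomSdField = 0, seed = 101L)
  pop <- genPopulationDataset(d)
  fit <- suppressMessages(suppressWarnings(
    fitGlmm(pop, "active", genotypeBy = "shift")))
  glm0 <- glm(active ~ factor(genotype, levels = c("WT", "HET")) +
                factor(intensity_uA),
              family = binomial("probit"), data = pop)
  feMixed <- fixedEffects(fit)$estimate
  feGlm <- unname(coef(glm0))
  expect_lt(max(abs(feMixed - feGlm)), 1e-4)
})

test_that("the genotype LRT equals twice the log-likelihood difference", {
  pop <- genPopulationDataset(populationDesign(nMicePerGenotype = 3,
                                               seed = 103L))
  fit <- suppressMessages(suppressWarnings(fitGlmm(pop, "active")))
  lrt <- suppressMessages(suppressWarnings(compareGenotypeCurves(fit)))
  byHand <- 2 * (as.numeric(stats::logLik(lrt$full)) -
                   as.numeric(stats::logLik(lrt$reduced)))
  expect_equal(lrt$statistic, max(0, byHand), tolerance = 1e-10)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 4)          # genotype main effect + 3 interactions
})

test_that("duplicated genotype data give a near-zero LRT", {
  d <- populationDesign(nMicePerGenotype = 3, genotypeEffectProbit = 0,
                        randomSdMouse = 0, randomSdSlice = 0,
                        randomSdField = 0, seed = 107L)
  pop <- genPopulationDataset(d)
  # literal copy: HET rows are the WT rows relabelled
  wt <- pop[pop$genotype == "WT", ]
  het <- wt
  het$genotype <- "HET"
  for (col in c("mouse", "slice", "field", "cell"))
    het[[col]] <- sub("^WT", "HET", het[[col]])
  dup <- rbind(wt, het)
  fit <- suppressMessages(suppressWarnings(fitGlmm(dup, "active")))
  lrt <- suppressMessages(suppressWarnings(compareGenotypeCurves(fit)))
  expect_lt(lrt$statistic, 1e-4)
  expect_gt(lrt$p, 0.99)
})

test_that("a large genotype effect is detected by the curve comparison", {
  pop <- genPopulationDataset(populationDesign(seed = 109L))
  fit <- suppressMessages(suppressWarnings(fitGlmm(pop, "active")))
  lrt <- suppressMessages(suppressWarnings(compareGenotypeCurves(fit)))
  expect_lt(lrt$p, 0.05)
})

test_that("the amplitude model recovers the genotype log-ratio", {
  d <- populationDesign(nMicePerGenotype = 6, nCellsPerField = 25,
                        seed = 113L)
  pop <- genPopulationDataset(d)
  fit <- suppressMessages(suppressWarnings(
    fitGlmm(pop, "amplitude", genotypeBy = "shift")))
  est <- genotypeWald(fit)$estimate
  truth <- log(1.15) - log(0.5)    # generator default log-mean contrast
  expect_lt(abs(est - truth), 0.25)
  expect_equal(fit@family, "normal-log")
})

test_that("paired within-field test matches the closed-form paired t-test", {
  set.seed(121)
  # single-level data: every field its own mouse
  n <- 12
  df <- data.frame(mouse = sprintf("m%02d", 1:n), slice = "s1",
                   field = "f1",
                   value_a = rnorm(n, 0.5, 0.1),
                   value_b = rnorm(n, 0.4, 0.1))
  res <- pairedWithinFieldTest(df)
  oracle <- oraclePairedT(df$value_a - df$value_b)
  expect_equal(res$method, "paired-t")
  expect_equal(res$statistic, oracle$statistic, tolerance = 1e-8)
  expect_equal(res$p, oracle$p, tolerance = 1e-8)
})

test_that("paired test handles identical and shifted conditions", {
  base <- data.frame(mouse = rep(sprintf("m%d", 1:4), each = 3),
                     slice = "s1", field = sprintf("f%02d", 1:12),
                     value_a = seq(0.3, 0.8, length.out = 12))
  same <- base; same$value_b <- same$value_a
  res <- pairedWithinFieldTest(same)
  expect_equal(res$estimate, 0)
  expect_equal(res$p, 1)
  set.seed(123)
  shifted <- base
  shifted$value_b <- shifted$value_a - 0.33 + rnorm(12, 0, 0.02)
  res2 <- pairedWithinFieldTest(shifted)
  expect_lt(res2$p, 0.001)
  expect_equal(res2$estimate, 0.33, tolerance = 0.05)
  dup <- rbind(base[1, ], base[1, ])
  dup$value_b <- dup$value_a
  expect_error(pairedWithinFieldTest(dup), "duplicated")
})

test_that("model fitting reports convergence honestly", {
  pop <- genPopulationDataset(populationDesign(nMicePerGenotype = 2,
                                               seed = 131L))
  fit <- suppressMessages(suppressWarnings(fitGlmm(pop, "active")))
  expect_true(is.logical(fit@converged))
  expect_error(fitGlmm(pop[pop$mouse == pop$mouse[1], ], "active"),
               "2 mice")
})
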