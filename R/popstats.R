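# Hierarchical mixed-model comparison of activation curves and amplitudes,
# paired within-field tests, and operating-characteristic simulation.

.addNesting <- function(data) {
  data$mouseF <- factor(data$mouse)
  data$sliceF <- factor(paste(data$mouse, data$slice, sep = ":"))
  data$fieldF <- factor(paste(data$mouse, data$slice, data$field, sep = ":"))
  data$cellF <- factor(paste(data$mouse, data$slice, data$field, data$cell,
                             sep = ":"))
  data
}

.mergedMessages <- function(model) {
  msgs <- character(0)
  oi <- model@optinfo
  if (!is.null(oi$conv$lme4$messages))
    msgs <- c(msgs, unlist(oi$conv$lme4$messages))
  if (!is.null(oi$warnings) && length(oi$warnings))
    msgs <- c(msgs, unlist(lapply(oi$warnings, as.character)))
  msgs
}

#' Fit a hierarchical mixed model to a population dataset
#'
#' Activation is modelled as binomial with a probit link; response
#' amplitudes and deconvolved spike counts are modelled on the log scale
#' with a linear mixed model (the lognormal formulation of a
#' normal/log-link magnitude model). Nested random intercepts cover mouse,
#' slice and field; a cell-level intercept is added for the magnitude
#' responses, which are repeated across conditions within a cell. The
#' stimulation intensity enters as an ordered categorical factor by default
#' or as centred log intensity (\code{intensityAs = "log"}).
#'
#' @param data population data.frame (columns mouse, slice, field, cell,
#'   genotype, intensity_uA, active, and amplitude or est_spikes)
#' @param response "active", "amplitude" or "est_spikes"
#' @param intensityAs "factor" (default) or "log"
#' @param genotypeBy "shift" (genotype main effect; default when only one
#'   intensity is present) or "curve" (genotype x intensity interaction)
#' @return a \linkS4class{GlmmFit}; non-convergence is flagged in
#'   \code{@converged} with diagnostics in \code{@messages}, never silent
#' @export
fitGlmm <- function(data, response = c("active", "amplitude", "est_spikes"),
                    intensityAs = c("factor", "log"),
                    genotypeBy = NULL) {
  response <- match.arg(response)
  intensityAs <- match.arg(intensityAs)
  data <- .addNesting(data)
  data$genotype <- factor(data$genotype, levels = c("WT", "HET"))
  nInt <- length(unique(data$intensity_uA))
  if (is.null(genotypeBy)) genotypeBy <- if (nInt > 1) "curve" else "shift"
  if (intensityAs == "factor") {
    data$intensity <- factor(data$intensity_uA)
  } else {
    data$intensity <- log(data$intensity_uA) -
      max(log(data$intensity_uA))
  }
  if (length(unique(data$mouseF)) < 2)
    stop("need >= 2 mice so every random factor has >= 2 levels")
  fixedRhs <- if (nInt == 1) "genotype"
  else if (genotypeBy == "curve") "genotype * intensity"
  else "genotype + intensity"
  if (response == "active") {
    # aggregate Bernoulli cells to binomial counts per field x condition
    # (identical likelihood, much faster); covariates are field-constant
    grp <- paste(data$fieldF, data$intensity_uA, data$genotype)
    k <- tapply(data$active, grp, sum)
    nn <- tapply(data$active, grp, length)
    first <- !duplicated(grp)
    agg <- data[first, c("mouseF", "sliceF", "fieldF", "genotype",
                         "intensity", "intensity_uA")]
    key <- paste(agg$fieldF, agg$intensity_uA, agg$genotype)
    agg$k <- as.numeric(k[key])
    agg$n <- as.numeric(nn[key])
    fml <- as.formula(paste("cbind(k, n - k) ~", fixedRhs,
                            "+ (1 | mouseF) + (1 | sliceF) + (1 | fieldF)"))
    m <- lme4::glmer(fml, data = agg, family = binomial(link = "probit"))
    data <- agg
    fam <- "binomial-probit"
  } else {
    ycol <- response
    data <- data[!is.na(data[[ycol]]) & data[[ycol]] > 0, , drop = FALSE]
    data$logResp <- log(data[[ycol]])
    rex <- "+ (1 | mouseF) + (1 | sliceF) + (1 | fieldF)"
    if (any(table(data$cellF) > 1)) rex <- paste(rex, "+ (1 | cellF)")
    fml <- as.formula(paste("logResp ~", fixedRhs, rex))
    m <- lmerTest::lmer(fml, data = data, REML = FALSE)
    fam <- "normal-log"
  }
  msgs <- .mergedMessages(m)
  conv <- !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  new("GlmmFit", model = m, response = response, family = fam,
      formula = fml, data = data, converged = conv,
      messages = if (length(msgs)) msgs else character(0))
}

#' Likelihood-ratio comparison of genotype activation curves
#'
#' Refits the model without any genotype term (main effect and
#' interactions) and reports the likelihood-ratio test of all dropped
#' terms.
#'
#' @param fit a \linkS4class{GlmmFit} whose formula contains genotype
#' @return list: \code{statistic} (2 x log-likelihood difference),
#'   \code{df}, \code{p}, and both models
#' @export
compareGenotypeCurves <- function(fit) {
  fml <- fit@formula
  rhs <- paste(deparse(fml[[3]]), collapse = " ")
  if (!grepl("genotype", rhs)) stop("model contains no genotype term")
  reduced <- . ~ . - genotype - genotype:intensity
  fmlRed <- update(fml, reduced)
  data <- fit@data
  mRed <- if (fit@family == "binomial-probit")
    lme4::glmer(fmlRed, data = data, family = binomial(link = "probit"))
  else lmerTest::lmer(fmlRed, data = data, REML = FALSE)
  llF <- as.numeric(logLik(fit@model))
  llR <- as.numeric(logLik(mRed))
  dfDiff <- attr(logLik(fit@model), "df") - attr(logLik(mRed), "df")
  stat <- max(0, 2 * (llF - llR))
  list(statistic = stat, df = dfDiff,
       p = pchisq(stat, dfDiff, lower.tail = FALSE),
       full = fit@model, reduced = mRed)
}

#' Wald test of the genotype effect of a mixed-model fit
#'
#' Genotype is a between-mouse effect, so the Wald statistic is referred to
#' a t distribution with between-cluster degrees of freedom (number of
#' mice minus the number of genotype groups), the between-within rule used
#' for hierarchical designs with few clusters. \code{df = Inf} recovers the
#' asymptotic z test.
#'
#' @param fit a \linkS4class{GlmmFit}
#' @param df degrees of freedom for the reference t distribution; default
#'   number of mice - 2
#' @return list: \code{estimate}, \code{se}, \code{statistic}, \code{df},
#'   \code{p}, and the 95\% confidence bounds \code{ci_lo}, \code{ci_hi}
#' @export
genotypeWald <- function(fit, df = NULL) {
  co <- coef(summary(fit@model))
  row <- which(rownames(co) == "genotypeHET")
  if (length(row) != 1) stop("no genotype main-effect coefficient found")
  if (is.null(df)) df <- length(unique(fit@data$mouseF)) - 2
  est <- co[row, 1]; se <- co[row, 2]
  tstat <- est / se
  q <- qt(0.975, df)
  list(estimate = est, se = se, statistic = tstat, df = df,
       p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       ci_lo = est - q * se, ci_hi = est + q * se)
}

#' Mouse-summary genotype test of maximal-stimulus activation
#'
#' The two-stage summary-measures analysis for a between-mouse contrast
#' with few animals: each mouse is reduced to the probit of its activation
#' proportion at the maximal stimulus (with the continuity correction
#' \eqn{\Phi^{-1}((k + 1/2)/(n + 1))} so empty and full fields stay
#' finite), and the genotypes are compared with a Welch t test across
#' mice. Because mouse summaries are independent, the test keeps its
#' nominal level at small numbers of animals, where the mixed-model Wald
#' test is anticonservative; the price is a slight attenuation of the
#' effect estimate (marginalisation over the slice/field random effects).
#'
#' @param data population data.frame (columns mouse, genotype,
#'   intensity_uA, active)
#' @param intensity stimulus intensity defining the summary; default the
#'   maximal intensity present
#' @return list: \code{estimate} (probit difference HET - WT), \code{se},
#'   \code{statistic}, \code{df}, \code{p}, \code{ci_lo}, \code{ci_hi},
#'   \code{mouse_summaries}
#' @export
genotypeMouseTest <- function(data, intensity = NULL) {
  if (is.null(intensity)) intensity <- max(data$intensity_uA)
  sub <- data[data$intensity_uA == intensity, , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows at the requested intensity")
  k <- tapply(sub$active, sub$mouse, sum)
  nn <- tapply(sub$active, sub$mouse, length)
  z <- qnorm((k + 0.5) / (nn + 1))
  geno <- tapply(as.character(sub$genotype), sub$mouse, `[`, 1)
  if (length(unique(geno)) != 2) stop("need both genotypes")
  zh <- z[geno == "HET"]; zw <- z[geno == "WT"]
  tt <- t.test(zh, zw)
  list(estimate = unname(diff(rev(tt$estimate))),
       se = tt$stderr, statistic = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
       mouse_summaries = data.frame(mouse = names(z), genotype = geno,
                                    probit = as.numeric(z),
                                    row.names = NULL))
}

#' Paired within-field comparison of two conditions
#'
#' Tests whether the field-level difference between matched conditions is
#' zero. With grouping above the field level (>= 2 mice with >= 2 fields
#' each) the difference is modelled with random intercepts for mouse and
#' slice; with only field-level variation the test reduces to (and is
#' computed as) a paired t-test.
#'
#' @param fieldSummaries data.frame with columns mouse, slice, field,
#'   value_a, value_b; one row per field, conditions matched by field
#' @return list: \code{estimate} (mean A - B), \code{statistic}, \code{df},
#'   \code{p}, \code{method}
#' @export
pairedWithinFieldTest <- function(fieldSummaries) {
  need <- c("mouse", "slice", "field", "value_a", "value_b")
  if (!all(need %in% names(fieldSummaries)))
    stop("fieldSummaries must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(with(fieldSummaries, paste(mouse, slice, field))))
    stop("data-integrity error: duplicated field keys")
  d <- fieldSummaries
  d$diff <- d$value_a - d$value_b
  if (sd(d$diff) == 0) {
    # degenerate: identical (or constantly shifted) conditions
    return(list(estimate = d$diff[1], statistic = if (d$diff[1] == 0) 0
                else Inf, df = nrow(d) - 1,
                p = if (d$diff[1] == 0) 1 else 0, method = "degenerate"))
  }
  nMice <- length(unique(d$mouse))
  multi <- nMice >= 2 && any(table(d$mouse) >= 2)
  if (multi) {
    d <- .addNesting(d)
    m <- tryCatch(
      lmerTest::lmer(diff ~ 1 + (1 | mouseF) + (1 | sliceF), data = d),
      error = function(e) NULL)
    if (!is.null(m) && !lme4::isSingular(m, tol = 1e-6)) {
      co <- coef(summary(m))
      return(list(estimate = co[1, "Estimate"],
                  statistic = co[1, "t value"], df = co[1, "df"],
                  p = co[1, "Pr(>|t|)"], method = "mixed"))
    }
  }
  tt <- t.test(d$diff)
  list(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, method = "paired-t")
}

#' Operating characteristics of the genotype comparison by simulation
#'
#' Simulates the full hierarchical design (all stimulation intensities)
#' for a grid of genotype effects (probit scale), fits the binomial-probit
#' mixed model with a genotype shift plus intensity curve to each
#' replicate, and reports the Wald rejection rate at \code{alpha} (t
#' reference with between-mouse df), the mean genotype-effect estimate,
#' its bias relative to the simulated effect, and confidence-interval
#' coverage.
#'
#' @param design a \linkS4class{PopulationDesign} (its genotype effect is
#'   overridden by the grid)
#' @param effectGrid probit-scale genotype effects to simulate; 0 gives the
#'   type-I error
#' @param nSims replicates per effect (>= 50)
#' @param seed integer seed
#' @param alpha nominal level (default 0.05)
#' @param method "mouse-summary" (default; the calibrated two-stage test of
#'   \code{\link{genotypeMouseTest}}) or "glmm-wald" (Wald t from the
#'   mixed-model fit)
#' @return data.frame per effect: \code{effect}, \code{rejection_rate},
#'   \code{mean_estimate}, \code{bias}, \code{coverage}, \code{n_converged}
#' @export
simulateOperatingCharacteristics <- function(design = populationDesign(),
                                             effectGrid = c(0, NULL),
                                             nSims = 50, seed = 1L,
                                             alpha = 0.05,
                                             method = c("mouse-summary",
                                                        "glmm-wald")) {
  if (nSims < 50) stop("nSims must be >= 50")
  method <- match.arg(method)
  validObject(design)
  out <- lapply(seq_along(effectGrid), function(ei) {
    eff <- effectGrid[ei]
    pvals <- ests <- cover <- rep(NA_real_, nSims)
    for (r in seq_len(nSims)) {
      des <- design
      des@genotypeEffectProbit <- eff
      des@seed <- as.integer((seed + 7919L * (ei - 1L) + r) %% .Machine$integer.max)
      dat <- genPopulationDataset(des)
      w <- if (method == "mouse-summary") {
        tryCatch(genotypeMouseTest(dat), error = function(e) NULL)
      } else {
        fit <- suppressMessages(suppressWarnings(
          fitGlmm(dat, response = "active", genotypeBy = "shift")))
        tryCatch(genotypeWald(fit), error = function(e) NULL)
      }
      if (is.null(w)) next
      pvals[r] <- w$p
      ests[r] <- w$estimate
      cover[r] <- (eff >= w$ci_lo && eff <= w$ci_hi)
    }
    ok <- !is.na(pvals)
    data.frame(effect = eff,
               rejection_rate = mean(pvals[ok] < alpha),
               mean_estimate = mean(ests[ok]),
               bias = if (eff != 0) mean(ests[ok]) - eff else NA_real_,
               coverage = mean(cover[ok]),
               n_converged = sum(ok))
  })
  do.call(rbind, out)
}

#' @importFrom stats pchisq
NULL
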