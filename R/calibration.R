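# Ground-truth calibration: AP <-> calcium linear model, genotype
# comparison, normal-fit detection threshold, single-AP resolution.

#' Linear fit of peak dF/F0 against action-potential count
#'
#' Ordinary least squares of peak dF/F0 on the simultaneously recorded
#' spike count (intercept included by default).
#'
#' @param pairs data.frame with columns \code{spikes} and \code{peak_dff}
#' @param intercept include an intercept term (default TRUE)
#' @return list of class \code{"apCalciumFit"}: \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{n}, \code{residual_sd} and
#'   the underlying \code{lm} in \code{$model}
#' @examples
#' fitApCalciumLine(data.frame(spikes = 0:5, peak_dff = 0.3 * (0:5)))
#' @export
fitApCalciumLine <- function(pairs, intercept = TRUE) {
  stopifnot(all(c("spikes", "peak_dff") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  if (length(unique(pairs$spikes)) < 2)
    stop("singular fit: spike counts do not vary")
  fm <- if (intercept) peak_dff ~ spikes else peak_dff ~ spikes - 1
  m <- lm(fm, data = pairs)
  cf <- coef(m)
  ssTot <- sum((pairs$peak_dff - mean(pairs$peak_dff))^2)
  r2 <- if (ssTot > 0) 1 - sum(resid(m)^2) / ssTot else 0
  structure(list(slope = unname(cf[["spikes"]]),
                 intercept = if (intercept) unname(cf[["(Intercept)"]]) else 0,
                 r_squared = max(0, r2), n = nrow(pairs),
                 residual_sd = summary(m)$sigma, model = m),
            class = "apCalciumFit")
}

#' @export
print.apCalciumFit <- function(x, ...) {
  cat("AP-calcium linear fit: slope", signif(x$slope, 4),
      "dF/F0 per AP, intercept", signif(x$intercept, 4), ", R^2",
      signif(x$r_squared, 4), "(n =", x$n, ")\n")
  invisible(x)
}

#' Test whether the AP-calcium line differs between genotypes
#'
#' Fits a pooled regression with a group-by-count interaction and reports
#' the Wald test on the interaction (difference in slopes).
#'
#' @param pairsByGroup named list of two data.frames, each with columns
#'   \code{spikes} and \code{peak_dff}
#' @return list: \code{estimate} (slope difference), \code{se},
#'   \code{statistic}, \code{p}, \code{model}
#' @export
compareGenotypeLines <- function(pairsByGroup) {
  if (length(pairsByGroup) != 2 || is.null(names(pairsByGroup)))
    stop("pairsByGroup must be a named list of two groups")
  if (any(vapply(pairsByGroup, nrow, 1L) < 3))
    stop("each group needs at least 3 pairs")
  df <- do.call(rbind, lapply(names(pairsByGroup), function(g)
    cbind(pairsByGroup[[g]], group = g)))
  df$group <- factor(df$group, levels = names(pairsByGroup))
  m <- lm(peak_dff ~ spikes * group, data = df)
  co <- coef(summary(m))
  row <- grep("spikes:group", rownames(co))
  list(estimate = co[row, "Estimate"], se = co[row, "Std. Error"],
       statistic = co[row, "t value"], p = co[row, "Pr(>|t|)"],
       model = m)
}

#' Fit the single-AP detection threshold from zero-spike dF/F0 values
#'
#' Maximum-likelihood normal fit (sample mean; SD with denominator n) to
#' dF/F0 values recorded with 0 action potentials; the detection threshold
#' is the upper \code{1 - pTail} quantile of the fitted distribution.
#'
#' @param zeroApValues numeric vector of dF/F0 values from 0-AP trials
#' @param pTail upper-tail probability defining the threshold
#'   (default 0.001)
#' @return a \linkS4class{DetectionThreshold}
#' @examples
#' fitDetectionThreshold(rnorm(1000), pTail = 0.001)
#' @export
fitDetectionThreshold <- function(zeroApValues, pTail = 0.001) {
  if (length(zeroApValues) < 5) stop("need at least 5 null values")
  if (pTail <= 0 || pTail > 0.5) stop("pTail must lie in (0, 0.5]")
  m <- mean(zeroApValues)
  s <- sqrt(mean((zeroApValues - m)^2))   # MLE (n denominator)
  if (s <= 0) stop("degenerate null sample: zero variance")
  new("DetectionThreshold", noiseMean = m, noiseSd = s, pTail = pTail,
      threshold = m + qnorm(1 - pTail) * s)
}

#' Sensitivity and specificity of a threshold for single-AP resolution
#'
#' @param threshold a \linkS4class{DetectionThreshold} or a single number
#' @param labels integer/numeric vector of 0 (no AP) and 1 (single AP)
#' @param values dF/F0 values matching \code{labels}
#' @return list: \code{sensitivity} (fraction of 1-AP values above the
#'   threshold), \code{specificity} (fraction of 0-AP values below),
#'   \code{n0}, \code{n1}
#' @export
evaluateResolution <- function(threshold, labels, values) {
  if (is(threshold, "DetectionThreshold")) threshold <- threshold@threshold
  stopifnot(length(labels) == length(values))
  if (!any(labels == 0) || !any(labels == 1))
    stop("both 0-AP and 1-AP labels must be present")
  v0 <- values[labels == 0]; v1 <- values[labels == 1]
  list(sensitivity = mean(v1 > threshold),
       specificity = mean(v0 <= threshold),
       n0 = length(v0), n1 = length(v1))
}
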