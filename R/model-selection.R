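# Information-criterion machinery shared by all analysis arms.

#' Small-sample Akaike information criterion
#'
#' AICc with the standard small-sample correction,
#' \deqn{AICc = -2\,\log L + 2k + \frac{2k(k+1)}{n-k-1},}
#' where `k` counts all estimated parameters (fixed effects plus variance
#' components for mixed models) and `n` is the number of observations. The
#' correction vanishes as `n` grows, so AICc converges to AIC.
#'
#' @param logLik maximized log-likelihood of the fit.
#' @param k number of estimated parameters (positive integer).
#' @param n number of observations; must exceed `k + 1`.
#' @return The AICc value (scalar).
#' @examples
#' aiccFromFit(0, k = 2, n = 10)  # 4 + 12/7
#' @export
aiccFromFit <- function(logLik, k, n) {
  stopifnot(is.finite(logLik), k >= 1, k == round(k), n == round(n))
  if (n <= k + 1)
    stop("AICc undefined: need n > k + 1 (got n = ", n, ", k = ", k, ")")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Pairwise Akaike probability of a candidate model
#'
#' Evidence that the candidate model is correct relative to a reference
#' model, computed from the AICc difference `D = aiccRef - aiccCandidate`
#' (positive `D` favors the candidate):
#' \deqn{p = \frac{e^{0.5D}}{1 + e^{0.5D}}.}
#' At `D = 0` both models are equally supported (p = 0.5); `D = 2`, the
#' customary decision threshold, corresponds to p = 73.1%. The two models'
#' probabilities sum to one.
#'
#' @param aiccRef AICc of the reference (typically simpler) model.
#' @param aiccCandidate AICc of the candidate model.
#' @param names length-2 character: names of reference and candidate.
#' @return A [ModelComparison-class] for the pair. `probability` refers to
#'   the preferred (lower-AICc) model.
#' @examples
#' akaikeProbability(-682.2, -699.8)  # 99.98% for the candidate
#' @export
akaikeProbability <- function(aiccRef, aiccCandidate,
                              names = c("reference", "candidate")) {
  if (!is.finite(aiccRef) || !is.finite(aiccCandidate))
    stop("AICc values must be finite")
  D <- aiccRef - aiccCandidate
  preferred <- if (D >= 0) names[2] else names[1]
  delta <- abs(D)
  p <- stats::plogis(0.5 * delta)
  new("ModelComparison", preferred = preferred, delta = delta,
      probability = p, decisive = delta > 2,
      table = data.frame())
}

#' Describe a single model fit for trajectory comparison
#'
#' Bundles a fit's log-likelihood with its parameter and sample counts and
#' derives AIC and AICc. Used as input rows for [compareTrajectories()].
#'
#' @param name model name, one of `"linear"`, `"asymptotic"`, `"quadratic"`.
#' @param logLik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return One-row data.frame with columns `model`, `k`, `n`, `logLik`,
#'   `aic`, `aicc`.
#' @export
modelFit <- function(name, logLik, k, n) {
  name <- match.arg(name, TRAJECTORY_SHAPES)
  data.frame(model = name, k = k, n = n, logLik = logLik,
             aic = -2 * logLik + 2 * k,
             aicc = aiccFromFit(logLik, k, n))
}

#' Compare trajectory-model fits by AICc
#'
#' Selects the model with the lowest AICc among two or more fits of the same
#' response, and reports the AICc margin over the runner-up, the pairwise
#' Akaike probability, and whether the preference is decisive
#' (delta-AICc > 2). Fits must share `n`; ties in AICc are broken toward the
#' model with fewer parameters.
#'
#' @param fits data.frame of fits as produced by rbinding [modelFit()] rows
#'   (columns `model`, `k`, `n`, `logLik`, and optionally `aic`, `aicc`).
#' @return A [ModelComparison-class]; its `table` slot carries one row per
#'   model with AIC, AICc, delta-AICc and probability (percent, serialized
#'   with two decimals by [writeComparisonTsv()]).
#' @export
compareTrajectories <- function(fits) {
  stopifnot(is.data.frame(fits), nrow(fits) >= 2,
            all(c("model", "k", "n", "logLik") %in% names(fits)))
  if (length(unique(fits$n)) != 1)
    stop("fits are incomparable: observation counts differ")
  if (anyDuplicated(fits$model)) stop("duplicate model names")
  fits$aic <- -2 * fits$logLik + 2 * fits$k
  fits$aicc <- mapply(aiccFromFit, fits$logLik, fits$k, fits$n)
  # ties (to within numerical noise) break toward the simpler model
  ord <- order(round(fits$aicc, 9), fits$k)
  fits <- fits[ord, , drop = FALSE]
  delta <- max(0, fits$aicc[2] - fits$aicc[1])
  p <- stats::plogis(0.5 * delta)
  tab <- data.frame(model = fits$model, k = fits$k, n = fits$n,
                    logLik = fits$logLik, AIC = fits$aic, AICc = fits$aicc,
                    deltaAICc = fits$aicc - fits$aicc[1])
  # pairwise probabilities against the preferred model (the preferred row
  # carries its evidence over the runner-up), so a two-model table matches
  # the published percentage pairs summing to 100
  tab$probability_pct <- 100 * stats::plogis(-0.5 * tab$deltaAICc)
  tab$probability_pct[1] <- 100 * p
  new("ModelComparison", preferred = fits$model[1], delta = delta,
      probability = p, decisive = delta > 2, table = tab)
}

#' Serialize a model comparison as TSV
#'
#' Writes the per-model table (model, k, n, logLik, AIC, AICc, deltaAICc,
#' probability_pct with two decimals) to a tab-separated file.
#'
#' @param comparison a [ModelComparison-class] from [compareTrajectories()].
#' @param file output path.
#' @return The file path, invisibly.
#' @export
writeComparisonTsv <- function(comparison, file) {
  stopifnot(is(comparison, "ModelComparison"))
  tab <- comparison@table
  if (!nrow(tab)) stop("comparison carries no per-model table")
  tab$probability_pct <- sprintf("%.2f", tab$probability_pct)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
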