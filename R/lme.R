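# Per-voxel linear mixed models for the group-by-time interaction.

#' Assemble the long-format panel for voxelwise fitting
#'
#' Expands subject metadata over sessions, drops missing subject-sessions,
#' and attaches the trajectory regressor. The returned panel is shared by
#' every voxel of a given shape.
#'
#' @param subjects data.frame with columns `id`, `group`, `tiv`.
#' @param sessionDays numeric vector of experimental days.
#' @param missing optional logical `[subject, session]` matrix.
#' @param shape trajectory shape for the regressor.
#' @param T training horizon (days).
#' @return data.frame with columns `subject`, `session`, `group` (0 control,
#'   1 trained), `tiv`, `f`.
#' @keywords internal
.buildPanel <- function(subjects, sessionDays, missing = NULL,
                        shape = "asymptotic", T = max(sessionDays)) {
  ns <- nrow(subjects)
  nt <- length(sessionDays)
  panel <- data.frame(
    subject = factor(rep(subjects$id, nt), levels = subjects$id),
    session = rep(seq_len(nt), each = ns),
    group = as.numeric(rep(subjects$group, nt) == "trained"),
    tiv = rep(subjects$tiv, nt)
  )
  panel$f <- trajectoryBasis(shape, sessionDays[panel$session], T)
  if (!is.null(missing)) panel <- panel[!as.vector(missing), , drop = FALSE]
  panel
}

#' Fit the longitudinal mixed model at one voxel
#'
#' Maximum-likelihood fit of
#' \deqn{y = \beta_0 + \beta_1 TIV + \beta_2 group + \beta_3 f(t) +
#'       \beta_4\, group \cdot f(t) + b_{0i} + b_{1i} f(t) + \epsilon,}
#' with subject random intercept and slope on the trajectory regressor
#' `f(t)`. The group-by-time interaction coefficient (named `beta3`,
#' matching the usual notation for the interaction of interest) carries the
#' learning effect; its two-sided Wald p-value uses a t reference with
#' between-subject denominator degrees of freedom (number of subjects minus
#' the two slope-stratum fixed effects), the containment convention for a
#' group contrast on subject slopes — a normal reference is anti-conservative
#' in the far tails that drive voxelwise FDR. ML (not REML) is used so that
#' log-likelihoods are comparable across fixed-effect structures; `k` counts
#' fixed effects plus variance components.
#'
#' Degenerate responses (zero variance) are flagged with the convention
#' p = 1; non-convergence is flagged so [voxelwiseMaps()] can exclude the
#' voxel.
#'
#' @param y response values aligned with the rows of `panel`.
#' @param panel long-format design from [.buildPanel()]: columns `subject`,
#'   `group` (0/1), `tiv`, `f`.
#' @return List with `beta3` (interaction estimate), `se3`, `p3`, `beta`
#'   (all fixed effects), `logLik`, `k`, `n`, `aic`, `aicc`, `singular`,
#'   `converged`, `degenerate`.
#' @examples
#' panel <- .buildPanel(
#'   data.frame(id = paste0("s", 1:6),
#'              group = rep(c("trained", "control"), each = 3),
#'              tiv = rep(400, 6)),
#'   c(0, 2, 6, 8, 10, 14), shape = "asymptotic")
#' y <- 1 + 0.05 * panel$group * panel$f + rnorm(nrow(panel), 0, 0.01)
#' fitVoxelLme(y, panel)$beta3
#' @export
fitVoxelLme <- function(y, panel) {
  stopifnot(length(y) == nrow(panel))
  n <- length(y)
  if (stats::sd(y) < 1e-12) {
    return(list(beta3 = 0, se3 = NA_real_, p3 = 1, beta = NULL,
                logLik = NA_real_, k = NA_integer_, n = n,
                aic = NA_real_, aicc = NA_real_,
                singular = TRUE, converged = FALSE, degenerate = TRUE))
  }
  dat <- panel
  dat$y <- y
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore",
                            calc.derivs = FALSE)
  fit <- tryCatch(
    lme4::lmer(y ~ tiv + group + f + group:f + (1 + f | subject),
               data = dat, REML = FALSE, control = ctrl),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(beta3 = NA_real_, se3 = NA_real_, p3 = NA_real_, beta = NULL,
                logLik = NA_real_, k = NA_integer_, n = n,
                aic = NA_real_, aicc = NA_real_,
                singular = NA, converged = FALSE, degenerate = FALSE))
  }
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  beta <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  i3 <- which(names(beta) == "group:f")
  se3 <- sqrt(vc[i3, i3])
  z <- beta[[i3]] / se3
  df3 <- max(1, nlevels(droplevels(panel$subject)) - 2)
  list(beta3 = beta[[i3]], se3 = se3, p3 = 2 * stats::pt(-abs(z), df3),
       beta = beta, logLik = as.numeric(ll), k = k, n = n,
       aic = -2 * as.numeric(ll) + 2 * k,
       aicc = if (n > k + 1) aiccFromFit(as.numeric(ll), k, n) else NA_real_,
       singular = lme4::isSingular(fit), converged = TRUE,
       degenerate = FALSE)
}

# Mass-univariate driver: same model as fitVoxelLme, fitted to every column
# of Y through lme4's modular interface (one deviance function per design,
# response swapped in place, warm-started optimizer). Returns a data.frame
# with one row per column of Y.
.fitVoxelBatch <- function(Y, panel) {
  stopifnot(nrow(Y) == nrow(panel))
  nv <- ncol(Y)
  n <- nrow(Y)
  dat <- panel
  dat$y <- Y[, 1]
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore",
                            calc.derivs = FALSE)
  lmod <- lme4::lFormula(y ~ tiv + group + f + group:f + (1 + f | subject),
                         data = dat, REML = FALSE, control = ctrl)
  devfun <- do.call(lme4::mkLmerDevfun, lmod)
  rho <- environment(devfun)
  i3 <- which(colnames(lmod$X) == "group:f")
  optCtrl <- list(xtol_abs = 1e-7, ftol_abs = 1e-7)
  df3 <- max(1, nlevels(droplevels(panel$subject)) - 2)

  out <- data.frame(beta3 = rep(NA_real_, nv), se3 = NA_real_, p3 = NA_real_,
                    logLik = NA_real_, k = NA_integer_, n = n,
                    aic = NA_real_, aicc = NA_real_,
                    singular = NA, converged = FALSE, degenerate = FALSE)
  theta0 <- NULL
  for (v in seq_len(nv)) {
    yv <- Y[, v]
    if (stats::sd(yv) < 1e-12) {
      out$beta3[v] <- 0; out$p3[v] <- 1
      out$degenerate[v] <- TRUE; out$singular[v] <- TRUE
      next
    }
    rho$resp$setResp(yv)
    # optimizer chatter (roundoff notices near convergence) is per-voxel
    # noise; genuine failures are caught and logged in the QC table
    opt <- tryCatch(
      suppressWarnings(
        lme4::optimizeLmer(devfun, start = theta0, control = optCtrl)),
      error = function(e) e)
    if (inherits(opt, "error")) next
    theta0 <- opt$par
    beta <- rho$pp$beta(1)
    sigma2 <- rho$resp$wrss() + rho$pp$sqrL(1)
    sigma2 <- sigma2 / n
    vcF <- sigma2 * chol2inv(rho$pp$RX())
    se3 <- sqrt(vcF[i3, i3])
    k <- length(beta) + length(opt$par) + 1L  # fixed + theta + sigma
    ll <- -opt$fval / 2
    out$beta3[v] <- beta[i3]
    out$se3[v] <- se3
    out$p3[v] <- 2 * stats::pt(-abs(beta[i3] / se3), df3)
    out$logLik[v] <- ll
    out$k[v] <- k
    out$aic[v] <- -2 * ll + 2 * k
    out$aicc[v] <- if (n > k + 1) aiccFromFit(ll, k, n) else NA_real_
    out$singular[v] <- any(abs(opt$par[c(1, 3)]) < 1e-6)
    out$converged[v] <- TRUE
  }
  out
}
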