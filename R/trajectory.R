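# Time-course regressors for the longitudinal models.

#' Trajectory basis functions
#'
#' The three candidate time courses of learning-induced volume change over
#' the training horizon `T` (days), each anchored at 0 on day 0 and bounded
#' by 1 in magnitude:
#'
#' * `linear`: `t / T` — steady change across the whole horizon;
#' * `asymptotic`: `1 - (1 - t/T)^2` — change followed by stabilization
#'   (quadratic rise with zero slope at `T`);
#' * `quadratic`: `4 t (T - t) / T^2` — change followed by renormalization
#'   toward baseline, peaking at `T/2`.
#'
#' Decreases are modeled with the same bases through the sign of the fitted
#' interaction coefficient (the "opposite function" of each shape is its
#' negative).
#'
#' @param shape one of `"linear"`, `"asymptotic"`, `"quadratic"`.
#' @param t day(s) within `[0, T]` (vectorized).
#' @param T training horizon in days (default 14).
#' @return Numeric vector `f(t)` with `f(0) = 0` and `|f| <= 1`.
#' @examples
#' trajectoryBasis("asymptotic", c(0, 2, 6, 8, 10, 14))
#' @export
trajectoryBasis <- function(shape, t, T = 14) {
  shape <- match.arg(shape, TRAJECTORY_SHAPES)
  stopifnot(T > 0)
  if (any(t < 0 | t > T)) stop("t must lie within [0, T]")
  u <- t / T
  switch(shape,
    linear = u,
    asymptotic = 1 - (1 - u)^2,
    quadratic = 4 * u * (1 - u)
  )
}
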