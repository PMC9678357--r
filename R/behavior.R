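# Single-pellet reaching: session scoring and learning rates.

#' Score one reaching session
#'
#' From per-trial records of a single-pellet reaching session:
#'
#' * `successPct` — valid successful trials as a percentage of all completed
#'   trials (trials flagged invalid — e.g. reaching with the non-trained
#'   forelimb or tongue use — never count as successes);
#' * `accuracyPct` — valid successes normalized by the total number of
#'   attempts pooled over the successful trials (ratio of sums);
#' * `accuracyMeanPct` — the alternative per-trial convention, the mean of
#'   `1/attempts` over successful trials (reported so either reading of the
#'   normalization can be checked);
#' * `firstAttemptPct` — successes achieved on the first attempted reach, as
#'   a percentage of completed trials.
#'
#' @param trials data.frame with columns `success` (logical), `attempts`
#'   (integer >= 1) and optionally `invalid` (logical).
#' @return List of class `"SessionScore"`: `nTrials`, `successPct`,
#'   `accuracyPct`, `accuracyMeanPct`, `firstAttemptPct`. Accuracy is `NA`
#'   when there is no valid success.
#' @examples
#' scoreSession(data.frame(success = rep(c(TRUE, FALSE), 15),
#'                         attempts = rep(c(3, 1), 15)))
#' @export
scoreSession <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("success", "attempts") %in% names(trials)))
  if (nrow(trials) == 0) stop("empty session")
  if (any(trials$attempts < 1)) stop("attempts must be >= 1")
  invalid <- if ("invalid" %in% names(trials)) trials$invalid else
    rep(FALSE, nrow(trials))
  n <- nrow(trials)
  succ <- trials$success & !invalid
  nSucc <- sum(succ)
  attemptsOfSucc <- sum(trials$attempts[succ])
  structure(list(
    nTrials = n,
    successPct = 100 * nSucc / n,
    accuracyPct = if (nSucc > 0) 100 * nSucc / attemptsOfSucc else NA_real_,
    accuracyMeanPct = if (nSucc > 0)
      100 * mean(1 / trials$attempts[succ]) else NA_real_,
    firstAttemptPct = 100 * sum(succ & trials$attempts == 1) / n
  ), class = "SessionScore")
}

#' @export
print.SessionScore <- function(x, ...) {
  cat(sprintf(paste0("SessionScore: %d trials; success %.1f%%, accuracy ",
                     "%.1f%%, first-attempt %.1f%%\n"),
              x$nTrials, x$successPct, x$accuracyPct, x$firstAttemptPct))
  invisible(x)
}

#' Score a multi-animal, multi-day trial table
#'
#' Applies [scoreSession()] per animal and day.
#'
#' @param trials data.frame with columns `animal`, `day`, `success`,
#'   `attempts`, and optionally `invalid`.
#' @return data.frame with one row per animal-day: `animal`, `day`,
#'   `nTrials`, `successPct`, `accuracyPct`, `accuracyMeanPct`,
#'   `firstAttemptPct`.
#' @export
scoreTrials <- function(trials) {
  stopifnot(all(c("animal", "day") %in% names(trials)))
  parts <- split(trials, list(trials$animal, trials$day), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(p) {
    s <- scoreSession(p)
    data.frame(animal = p$animal[1], day = p$day[1], nTrials = s$nTrials,
               successPct = s$successPct, accuracyPct = s$accuracyPct,
               accuracyMeanPct = s$accuracyMeanPct,
               firstAttemptPct = s$firstAttemptPct)
  }))
  out <- out[order(out$animal, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Logarithmic learning rate of one animal
#'
#' Slope of the logarithmic model `successPct = a + b log(day)` fitted by
#' ordinary least squares to the animal's learning curve (training days
#' indexed from 1). Larger `b` means faster improvement.
#'
#' @param successPct per-session success percentages.
#' @param days matching training days (>= 1; at least 3 sessions).
#' @return The slope `b`.
#' @examples
#' learningRate(2 + 5 * log(1:12), 1:12)  # 5
#' @export
learningRate <- function(successPct, days) {
  ok <- is.finite(successPct) & is.finite(days)
  successPct <- successPct[ok]; days <- days[ok]
  if (length(successPct) < 3) stop("need at least 3 sessions")
  if (any(days < 1)) stop("training days must be >= 1")
  unname(stats::coef(stats::lm(successPct ~ log(days)))[2])
}
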