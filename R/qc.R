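# Sample-level quality filters: z-score outlier removal on any feature and
# knee/elbow detection on the normalized cumulative feature curve.

#' z-score outlier filter
#'
#' Standardizes a feature with the population standard deviation (divide by
#' N) and flags samples at `|z| >= k` for removal. With zero variance every
#' sample is kept and the result is marked degenerate.
#'
#' @param values Numeric feature vector (one per sample, names kept).
#' @param k Threshold in standard deviations (default 3).
#' @return List of class `cn_zscore`: `mu`, `sigma`, `z`, `keep` (logical,
#'   `TRUE` iff `|z| < k`), `k`, `degenerate`.
#' @export
zscore_filter <- function(values, k = 3) {
  stopifnot(is.numeric(values), length(values) >= 2, k > 0)
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) {
    z <- rep(0, length(values))
    keep <- rep(TRUE, length(values))
    degenerate <- TRUE
  } else {
    z <- (values - mu) / sigma
    keep <- abs(z) < k
    degenerate <- FALSE
  }
  names(z) <- names(keep) <- names(values)
  structure(list(mu = mu, sigma = sigma, z = z, keep = keep, k = k,
                 degenerate = degenerate), class = "cn_zscore")
}

#' Knee/elbow detection on a cumulative feature curve
#'
#' Builds the sorted distinct feature values `T` and the cumulative counts
#' `Y` (samples with value <= t), unit-normalizes both, and at every
#' interior candidate evaluates the angle between the vector from the
#' origin to the normalized point and the vector from the point to (1, 1).
#' The candidate with the maximum absolute angle is returned; the sign of
#' the cross product classifies it: negative (clockwise, curve above the
#' diagonal) is a *knee*, positive an *elbow*. Ties resolve to the
#' smallest threshold. A perfectly linear curve has angle 0 everywhere and
#' is flagged degenerate.
#'
#' @param values Numeric feature vector over samples.
#' @param upper Optional pre-filter: only samples with `values <= upper`
#'   enter the curve (used e.g. to find a knee among low-activity samples).
#' @return List of class `cn_knee`: `thresholds`, `counts`, `t_norm`,
#'   `y_norm`, `angle` (per candidate, radians, signed), `index`,
#'   `knee_value`, `kind` (`"knee"`/`"elbow"`), `degenerate`.
#' @export
knee_point <- function(values, upper = NULL) {
  stopifnot(is.numeric(values))
  if (!is.null(upper)) values <- values[values <= upper]
  tt <- sort(unique(values))
  if (length(tt) < 3)
    stop("knee_point needs at least 3 distinct values", call. = FALSE)
  yy <- vapply(tt, function(t) sum(values <= t), 0)
  n <- length(tt)
  t_norm <- (tt - tt[1]) / (tt[n] - tt[1])
  y_norm <- (yy - yy[1]) / (yy[n] - yy[1])
  angle <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    v1 <- c(t_norm[i], y_norm[i])
    v2 <- c(1 - t_norm[i], 1 - y_norm[i])
    cross <- v1[1] * v2[2] - v1[2] * v2[1]
    dot <- sum(v1 * v2)
    angle[i] <- atan2(cross, dot)
  }
  cand <- 2:(n - 1)
  best <- cand[which.max(abs(angle[cand]))]  # which.max takes the first tie
  degenerate <- max(abs(angle[cand])) < sqrt(.Machine$double.eps)
  structure(list(thresholds = tt, counts = yy, t_norm = t_norm,
                 y_norm = y_norm, angle = angle, index = best,
                 knee_value = if (degenerate) NA_real_ else tt[best],
                 kind = if (degenerate) NA_character_
                        else if (angle[best] < 0) "knee" else "elbow",
                 degenerate = degenerate),
            class = "cn_knee")
}

#' @export
print.cn_knee <- function(x, ...) {
  if (x$degenerate) cat("<cn_knee> degenerate (collinear curve)\n")
  else cat(sprintf("<cn_knee> %s at %g (angle %.3f rad, %d candidates)\n",
                   x$kind, x$knee_value, x$angle[x$index],
                   length(x$thresholds) - 2L))
  invisible(x)
}
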