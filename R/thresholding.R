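#' Automatic iterative (isodata) thresholding
#'
#' Finds the threshold `t` that is the fixed point of the iterative
#' intermeans rule: starting from the global mean, `t` is repeatedly
#' replaced by the midpoint of the mean of intensities at or below `t` and
#' the mean of intensities strictly above `t`, until the update falls below
#' `1e-6` of the dynamic range. "Above threshold" means strictly greater
#' throughout the package.
#'
#' The iteration runs on the raw intensity values, not on a binned
#' histogram; on two-level images the fixed point is the midpoint of the
#' two levels.
#'
#' @param image An [image_stack()], or a numeric array/vector of
#'   intensities (e.g. the voxels of a masked region).
#' @return A `threshold_result`: list with the automatic threshold `t`, the
#'   mean `m1` of pixels strictly above `t`, the flexibility `d` (0 here)
#'   and the effective threshold `T` (equal to `t` here).
#' @examples
#' auto_threshold(c(0, 0, 10, 10))  # t = 5, m1 = 10
#' @export
auto_threshold <- function(image) {
  vals <- threshold_values(image)
  rng <- range(vals)
  if (rng[2] - rng[1] <= 0)
    stop("degenerate histogram: image has a single intensity value")
  tol <- 1e-6 * (rng[2] - rng[1])
  t <- mean(vals)
  converged <- FALSE
  for (iter in seq_len(500L)) {
    above <- vals > t
    t_new <- (mean(vals[!above]) + mean(vals[above])) / 2
    delta <- abs(t_new - t)
    t <- t_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("isodata iteration failed to converge within 500 rounds")
  m1 <- mean(vals[vals > t])
  structure(list(t = t, m1 = m1, d = 0, T = t, iterations = iter),
            class = "threshold_result")
}

#' Flexible thresholding with a single parameter d
#'
#' Shifts the automatic isodata threshold `t` towards the above-threshold
#' mean `m1` under the control of one parameter `d` in `[0, 1]`:
#' `T = t + d (m1 - t)`. At `d = 0` this is the automatic threshold; at
#' `d = 1` it is the mean of the above-threshold class. Because `m1 >= t`,
#' `T` is non-decreasing in `d`, so a single value of `d` gives visually
#' consistent thresholds across images of similar character.
#'
#' @inheritParams auto_threshold
#' @param d Flexibility parameter in `[0, 1]`.
#' @return A `threshold_result` with the effective threshold in `T`.
#' @examples
#' flexible_threshold(c(0, 0, 10, 10), d = 0.5)  # T = 7.5
#' @export
flexible_threshold <- function(image, d) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 0 || d > 1)
    stop("'d' must be a single value in [0, 1]")
  res <- auto_threshold(image)
  res$d <- d
  res$T <- res$t + d * (res$m1 - res$t)
  res
}

threshold_values <- function(image) {
  v <- if (inherits(image, "image_stack")) image$voxels else image
  as.numeric(v)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold_result: t = %g, m1 = %g, d = %g, T = %g (%d iterations)\n",
              x$t, x$m1, x$d, x$T, x$iterations))
  invisible(x)
}

#' Binary mask of voxels above a threshold
#'
#' @param stack An [image_stack()].
#' @param threshold Effective threshold `T` (a `threshold_result` or a
#'   number); voxels strictly above it are TRUE.
#' @return Logical array of the stack's shape.
#' @export
threshold_mask <- function(stack, threshold) {
  T_ <- if (inherits(threshold, "threshold_result")) threshold$T else threshold
  stack$voxels > T_
}
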