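#' Seven-parameter channel-alignment transform
#'
#' Chromatic aberration between channels of the microscope is modelled with
#' seven parameters: translations `(tz, ty, tx)` in nm, a rotation
#' `theta_z` (degrees) about the z axis, and per-axis magnifications
#' `(mz, my, mx)` close to 1 (independent lateral magnifications absorb the
#' astigmatism of per-channel focusing optics). The identity is
#' `(0, 0, 0, 0, 1, 1, 1)`.
#'
#' Composition order is fixed and serialized with the parameters: a physical
#' point `q` (nm, ordered `(z, y, x)`) is mapped to
#' `T(q) = R S (q - c) + c + t`, where `S = diag(mz, my, mx)`, `R` rotates
#' the `(y, x)` plane about the z axis, and `c` is the geometric center of
#' the stack. [apply_transform()] resamples by pulling back through `T`.
#'
#' @param tz,ty,tx Translations in nm.
#' @param theta_z Rotation about the z axis in degrees.
#' @param mz,my,mx Per-axis magnifications (> 0).
#' @return An object of class `transform_params`.
#' @export
transform_params <- function(tz = 0, ty = 0, tx = 0, theta_z = 0,
                             mz = 1, my = 1, mx = 1) {
  if (any(c(mz, my, mx) <= 0)) stop("magnifications must be > 0")
  structure(list(tz = tz, ty = ty, tx = tx, theta_z = theta_z,
                 mz = mz, my = my, mx = mx,
                 composition = "scale-rotate-translate about center"),
            class = "transform_params")
}

#' @export
print.transform_params <- function(x, ...) {
  cat(sprintf(
    "transform_params: t = (%.2f, %.2f, %.2f) nm, theta_z = %.4f deg, m = (%.5f, %.5f, %.5f)\n",
    x$tz, x$ty, x$tx, x$theta_z, x$mz, x$my, x$mx))
  invisible(x)
}

#' Write transform parameters to JSON
#' @param p A [transform_params()].
#' @param path Output path.
#' @export
write_transform <- function(p, path) {
  stopifnot(inherits(p, "transform_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read transform parameters from JSON
#' @param path JSON file written by [write_transform()].
#' @export
read_transform <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform_params(tz = v$tz, ty = v$ty, tx = v$tx, theta_z = v$theta_z,
                   mz = v$mz, my = v$my, mx = v$mx)
}

# 3x3 matrix (acting on (z,y,x) physical coordinates) and offset for a
# transform relative to a stack's geometric center.
transform_affine <- function(p, stack) {
  th <- p$theta_z * pi / 180
  S <- diag(c(p$mz, p$my, p$mx))
  R <- rbind(c(1, 0, 0),
             c(0, cos(th), -sin(th)),
             c(0, sin(th), cos(th)))
  A <- R %*% S
  cen <- dim(stack$voxels) * stack$voxel_size / 2
  b <- as.numeric(cen - A %*% cen + c(p$tz, p$ty, p$tx))
  list(A = A, b = b)
}

# Exact inverse of the affine map (general affine; with mx != my the
# inverse is not expressible in the same 7-parameter family).
invert_affine <- function(aff) {
  Ai <- solve(aff$A)
  list(A = Ai, b = as.numeric(-Ai %*% aff$b))
}

apply_affine <- function(stack, aff, with_inframe = FALSE,
                         interp = c("trilinear", "cubic")) {
  interp <- match.arg(interp)
  sampler <- if (interp == "cubic") .affine_sample_cubic_cpp
             else .affine_sample_cpp
  res <- sampler(stack$voxels, dim(stack$voxels),
                 stack$voxel_size, as.numeric(t(aff$A)), aff$b)
  v <- res$values
  v[v < 0] <- 0  # cubic kernels can undershoot below zero
  out <- as_stack_like(v, stack)
  if (with_inframe) list(stack = out, inframe = res$inframe) else out
}

#' Resample a stack under a channel-alignment transform
#'
#' Pull-back resampling on the input grid: each output voxel's physical
#' center `q` is mapped through the transform (scale about center, rotate
#' about z through center, then translate) and the intensity at `T(q)` is
#' fetched from the input by trilinear interpolation; positions outside the
#' frame yield 0. With a pure translation `t`, the output at `q` equals the
#' input at `q + t`.
#'
#' @param stack An [image_stack()].
#' @param p A [transform_params()].
#' @return The resampled [image_stack()].
#' @export
apply_transform <- function(stack, p) {
  stopifnot(inherits(stack, "image_stack"), inherits(p, "transform_params"))
  apply_affine(stack, transform_affine(p, stack))
}

#' Invert a channel-alignment transform
#'
#' Returns the exact inverse as a general affine map (class
#' `affine_transform`), usable with [apply_inverse_transform()]. When
#' `mx != my` the inverse of rotate-compose-scale is a shear and therefore
#' leaves the 7-parameter family; it is kept in matrix form rather than
#' re-approximated.
#'
#' @param p A [transform_params()].
#' @param stack The stack defining the center of the transform.
#' @return An `affine_transform` (list with matrix `A` and offset `b`).
#' @export
invert_transform <- function(p, stack) {
  aff <- invert_affine(transform_affine(p, stack))
  class(aff) <- "affine_transform"
  aff
}

#' Resample a stack under a general affine map
#' @param stack An [image_stack()].
#' @param aff An `affine_transform` from [invert_transform()].
#' @export
apply_inverse_transform <- function(stack, aff) {
  stopifnot(inherits(aff, "affine_transform"))
  apply_affine(stack, unclass(aff))
}

# Integer-voxel translation seed from the cross-correlation peak (FFT).
# Returns the translation (nm, (z,y,x)) such that moving sampled at
# q + t best matches reference at q.
translation_seed <- function(reference, moving) {
  a <- reference$voxels - mean(reference$voxels)
  b <- moving$voxels - mean(moving$voxels)
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE))
  d <- dim(a)
  peak <- arrayInd(which.max(cc), d) - 1L
  shift <- ifelse(peak > d / 2, peak - d, peak)  # wrap to signed shifts
  as.numeric(shift) * reference$voxel_size
}

normalize_params <- function(p, voxel_size) {
  c(p$tz / voxel_size[1], p$ty / voxel_size[2], p$tx / voxel_size[3],
    p$theta_z / 0.1,
    (p$mz - 1) / 0.001, (p$my - 1) / 0.001, (p$mx - 1) / 0.001)
}

denormalize_params <- function(u, voxel_size) {
  transform_params(tz = u[1] * voxel_size[1], ty = u[2] * voxel_size[2],
                   tx = u[3] * voxel_size[3], theta_z = u[4] * 0.1,
                   mz = 1 + u[5] * 0.001, my = 1 + u[6] * 0.001,
                   mx = 1 + u[7] * 0.001)
}

params_within_bounds <- function(p, bounds) {
  all(abs(c(p$tz, p$ty, p$tx)) <= bounds$translation_nm + 1e-9) &&
    abs(p$theta_z) <= bounds$rotation_deg + 1e-12 &&
    all(abs(c(p$mz, p$my, p$mx) - 1) <= bounds$magnification_dev + 1e-12)
}

# Pearson correlation between reference and the resampled moving stack.
# With mask = NULL the correlation runs over the in-frame voxels of the
# resampled image; during optimization a fixed mask (in-frame under every
# transform within the bounds) is used instead, so that the voxel set --
# and with it the statistic -- does not change with the parameters.
transform_correlation <- function(reference, moving, p, mask = NULL,
                                  interp = "trilinear") {
  res <- apply_affine(moving, transform_affine(p, moving),
                      with_inframe = TRUE, interp = interp)
  sel <- if (is.null(mask)) res$inframe else mask
  if (sum(sel) < 32) return(-1)
  a <- reference$voxels[sel]
  b <- res$stack$voxels[sel]
  if (sd(a) == 0 || sd(b) == 0) return(-1)
  cor(a, b)
}

# Logical mask of voxels whose pulled-back source position stays inside the
# frame for every transform within the bounds: the frame eroded per axis by
# the maximum displacement (translation + magnification reach + in-plane
# rotation sweep).
bounded_inframe_mask <- function(stack, bounds) {
  d <- dim(stack$voxels)
  vs <- stack$voxel_size
  ext <- d * vs
  rot <- sin(bounds$rotation_deg * pi / 180) *
    sqrt(sum((ext[2:3] / 2)^2))
  disp <- c(bounds$translation_nm + bounds$magnification_dev * ext[1] / 2,
            bounds$translation_nm + bounds$magnification_dev * ext[2] / 2 + rot,
            bounds$translation_nm + bounds$magnification_dev * ext[3] / 2 + rot)
  m <- pmin(ceiling(disp / vs) + 1L, floor((d - 1) / 2))
  mask <- array(FALSE, d)
  mask[(m[1] + 1):(d[1] - m[1]), (m[2] + 1):(d[2] - m[2]),
       (m[3] + 1):(d[3] - m[3])] <- TRUE
  mask
}

#' Estimate the channel-alignment transform by correlation
#'
#' Finds the seven transform parameters maximizing the Pearson correlation
#' between the reference stack and the resampled moving stack, the
#' criterion used for channel alignment of multicolour bead and specimen
#' images. The search seeds the translations at the integer-voxel
#' cross-correlation peak (computed by FFT, starting from `initial`), then
#' refines all free parameters with a Nelder-Mead simplex in normalized
#' parameter space (translations in voxels, rotation in 0.1 degree units,
#' magnification deviations in 1e-3 units), restarted once from the first
#' optimum. The correlation at the returned parameters is never below the
#' correlation at the initial guess.
#'
#' @param reference,moving [image_stack()] objects on the same grid.
#' @param initial Starting [transform_params()] (default identity); must be
#'   within `bounds`.
#' @param bounds Search bounds: list with `translation_nm` (absolute bound
#'   per axis), `rotation_deg`, and `magnification_dev` (absolute deviation
#'   of each magnification from 1). Defaults from [analysis_config()].
#' @param translation_only If TRUE only `(tz, ty, tx)` are optimized;
#'   rotation and magnifications are passed through from `initial`.
#' @param tol Relative convergence tolerance in normalized parameter space.
#' @return The estimated [transform_params()], with the achieved
#'   correlation in attribute `"correlation"`.
#' @export
estimate_transform <- function(reference, moving,
                               initial = transform_params(),
                               bounds = analysis_config()$register_bounds,
                               translation_only = FALSE,
                               tol = 1e-4) {
  stopifnot(inherits(reference, "image_stack"), inherits(moving, "image_stack"))
  if (!all(dim(reference$voxels) == dim(moving$voxels)))
    stop("reference and moving stacks must share grid shape")
  if (!all(reference$voxel_size == moving$voxel_size))
    stop("reference and moving stacks must share voxel size")
  if (sd(reference$voxels) == 0 || sd(moving$voxels) == 0)
    stop("flat image: correlation undefined")
  if (!params_within_bounds(initial, bounds))
    stop("'initial' outside search bounds")
  vs <- reference$voxel_size

  # Pre-smooth both stacks with a one-voxel Gaussian for the search:
  # trilinear resampling smooths the moving image's noise by an amount that
  # depends on the fractional offsets, which biases raw-image correlation
  # toward transforms that maximize that smoothing; a common pre-filter of
  # both images makes the differential effect negligible.
  smooth1 <- function(s)
    image_stack(pmax(gaussian_blur(s$voxels, s$voxel_size, s$voxel_size), 0),
                s$voxel_size, s$channel)
  ref_s <- smooth1(reference)
  mov_s <- smooth1(moving)

  # translation seeding: residual integer shift after the initial guess
  mov0 <- apply_transform(mov_s, initial)
  shift <- translation_seed(ref_s, mov0)
  seed <- initial
  seed$tz <- seed$tz + shift[1]
  seed$ty <- seed$ty + shift[2]
  seed$tx <- seed$tx + shift[3]
  # clamp the seed into bounds
  seed$tz <- max(min(seed$tz, bounds$translation_nm), -bounds$translation_nm)
  seed$ty <- max(min(seed$ty, bounds$translation_nm), -bounds$translation_nm)
  seed$tx <- max(min(seed$tx, bounds$translation_nm), -bounds$translation_nm)

  free <- if (translation_only) 1:3 else 1:7
  u_full <- normalize_params(seed, vs)
  ub <- c(rep(bounds$translation_nm, 3) / vs, bounds$rotation_deg / 0.1,
          rep(bounds$magnification_dev / 0.001, 3))
  # The objective correlates over a fixed voxel selection: voxels that
  # stay in-frame under every transform within the bounds (so the voxel
  # set cannot shrink as the parameters move) and that carry signal (top
  # 15% of smoothed reference intensity; the empty background adds cost
  # but almost no information).
  box <- bounded_inframe_mask(reference, bounds)
  sel <- which(box & ref_s$voxels >=
                 quantile(ref_s$voxels[box], 0.85, names = FALSE))
  ref_vals <- ref_s$voxels[sel]
  if (sd(ref_vals) == 0) stop("flat image within the correlation mask")
  mdim <- dim(mov_s$voxels)
  objective_for <- function(interp_code) function(u_free) {
    u <- u_full
    u[free] <- u_free
    aff <- transform_affine(denormalize_params(u, vs), mov_s)
    smp <- .sample_indices_cpp(mov_s$voxels, mdim, vs,
                               as.numeric(t(aff$A)), aff$b, sel - 1L,
                               interp_code)
    if (sd(smp$values) == 0) return(1)
    -cor(ref_vals, smp$values)
  }
  # Bounded quasi-Newton refinement in two stages: a fast pass with the
  # trilinear sampler, then a polish with the cubic sampler (whose lower
  # interpolation error removes the sub-voxel bias of trilinear
  # resampling). Finite-difference steps are 1e-2 in normalized units
  # (0.01 voxel, 1e-3 degree, 1e-5 magnification).
  fit <- optim(u_full[free], objective_for(0L), method = "L-BFGS-B",
               lower = -ub[free], upper = ub[free],
               control = list(factr = 1e6, maxit = 200,
                              ndeps = rep(1e-2, length(free))))
  fit <- optim(fit$par, objective_for(1L), method = "L-BFGS-B",
               lower = -ub[free], upper = ub[free],
               control = list(factr = 1e5, maxit = 100,
                              ndeps = rep(1e-2, length(free))))
  u <- u_full
  u[free] <- fit$par
  best <- denormalize_params(u, vs)
  if (translation_only) {
    best$theta_z <- initial$theta_z
    best$mz <- initial$mz
    best$my <- initial$my
    best$mx <- initial$mx
  }
  if (!params_within_bounds(best, bounds))
    stop("optimizer left the search bounds")
  # never return worse than the initial guess
  cor_best <- transform_correlation(reference, moving, best)
  cor_init <- transform_correlation(reference, moving, initial)
  if (cor_init > cor_best) {
    best <- initial
    cor_best <- cor_init
  }
  attr(best, "correlation") <- cor_best
  best
}

#' Per-stack adaptive refinement of the translations
#'
#' Chromatic aberration differs between bead calibration slides and
#' biological specimens, and between slides, mostly as a translational
#' offset (particularly along z). This re-optimizes only `(tz, ty, tx)` of
#' a bead-derived calibration using the DAPI signal imaged through both
#' channels' optical paths, leaving rotation and magnifications untouched.
#'
#' @param reference_dapi,moving_dapi The DAPI signal imaged in the reference
#'   and moving channel's optical path, as [image_stack()] objects.
#' @param calibration Bead-derived [transform_params()].
#' @param bounds,tol As in [estimate_transform()].
#' @return [transform_params()] with refined translations; rotation and
#'   magnification fields are copied from `calibration` unchanged.
#' @export
refine_translation <- function(reference_dapi, moving_dapi, calibration,
                               bounds = analysis_config()$register_bounds,
                               tol = 1e-4) {
  estimate_transform(reference_dapi, moving_dapi, initial = calibration,
                     bounds = bounds, translation_only = TRUE, tol = tol)
}
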