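#' Separable Gaussian blur of a 3D array (FFT)
#'
#' Circular (FFT) convolution with an anisotropic Gaussian kernel given by
#' per-axis sigmas in nm. Used both as the point-spread-function model of
#' the scene generator and as the pre-smoothing of the knob caller; with
#' the small sigmas involved and border margins around objects, the
#' periodic wrap-around is negligible.
#'
#' @param arr 3D numeric array (z, y, x).
#' @param sigma_nm Per-axis Gaussian sigmas `(z, y, x)` in nm.
#' @param voxel_size `(dz, dy, dx)` in nm.
#' @return Blurred array of the same shape.
#' @export
gaussian_blur <- function(arr, sigma_nm, voxel_size) {
  d <- dim(arr)
  stopifnot(length(d) == 3, length(sigma_nm) == 3, length(voxel_size) == 3)
  k1 <- function(n, sigma_vox) {
    if (sigma_vox <= 0) {
      k <- numeric(n); k[1] <- 1
      return(k)
    }
    i <- 0:(n - 1)
    dist <- pmin(i, n - i)
    k <- dnorm(dist, sd = sigma_vox)
    k / sum(k)
  }
  sv <- sigma_nm / voxel_size
  kern <- outer(outer(k1(d[1], sv[1]), k1(d[2], sv[2])), k1(d[3], sv[3]))
  dim(kern) <- d
  Re(fft(fft(arr) * fft(kern), inverse = TRUE)) / prod(d)
}

# FWHM (nm) -> Gaussian sigma (nm)
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Evaluate an expression with a fixed RNG seed, restoring the caller's
# random state afterwards, so the generators are pure functions of
# (params, seed).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Parameters of the synthetic nucleus-scene generator
#'
#' Defaults emulate the study conditions of the imaging experiments: ~2 um
#' nuclei, a point spread function with 120 nm lateral / 300 nm axial
#' resolution (FWHM, modelled as a Gaussian), condensed knobs at 2.5x the
#' median nuclear DNA density (default one per nucleus, 300 nm radius),
#' decondensed silent foci at 0.6x median density near the nuclear rim,
#' and mixed Poisson/Gaussian camera noise giving a signal-to-noise ratio
#' of about 10 at the median nuclear intensity.
#'
#' @param n_nuclei Number of nuclei in the scene.
#' @param nucleus_diameter_nm Nucleus diameter (default 2,000 nm).
#' @param voxel_size `(dz, dy, dx)` in nm.
#' @param shape Optional stack shape `(nz, ny, nx)`; computed from the
#'   nucleus layout when NULL.
#' @param knob_count Knobs planted per nucleus.
#' @param knob_radius_nm,knob_density Knob radius and density multiplier
#'   relative to the median nuclear intensity.
#' @param silent_focus_count,silent_focus_radius_nm,silent_focus_density
#'   Peripheral decondensed focus count, radius and density multiplier.
#' @param markers Named numeric vector of marker-channel colocalization
#'   weights in `[0, 1]`: each marker is `w x` (chromatin template)
#'   `+ (1 - w) x` (independent field).
#' @param marker_transforms Named list of true [transform_params()]
#'   mis-registrations per marker (identity when missing).
#' @param locus NULL, or a list with `proximal_prob`, `radius_nm` and
#'   `channel` describing a tagged-locus channel: in each nucleus one
#'   compact locus focus is planted, adjacent to the knob with probability
#'   `proximal_prob` and far from it otherwise.
#' @param psf_fwhm_nm `(axial, lateral)` PSF FWHM in nm (default 300/120).
#' @param texture_log_sd,texture_correlation_nm Chromatin texture: log-sd
#'   and correlation length of the smoothed lognormal field.
#' @param base_intensity Mean chromatin intensity (arbitrary units).
#' @param background Background level as a fraction of `base_intensity`.
#' @param noise_gain Photons per intensity unit for the Poisson component
#'   (0.1 gives SNR ~ 10 at intensity 1,000); `0` disables Poisson noise.
#' @param noise_read_sd Additive Gaussian read noise s.d. (intensity
#'   units); `0` disables it.
#' @return A `scene_params` list.
#' @export
scene_params <- function(n_nuclei = 1,
                         nucleus_diameter_nm = 2000,
                         voxel_size = c(125, 40, 40),
                         shape = NULL,
                         knob_count = 1,
                         knob_radius_nm = 300,
                         knob_density = 2.5,
                         silent_focus_count = 1,
                         silent_focus_radius_nm = 150,
                         silent_focus_density = 0.6,
                         markers = c(GFP = 0.8),
                         marker_transforms = list(),
                         locus = NULL,
                         psf_fwhm_nm = c(300, 120),
                         texture_log_sd = 0.15,
                         texture_correlation_nm = 100,
                         base_intensity = 1000,
                         background = 0.02,
                         noise_gain = 0.1,
                         noise_read_sd = 10) {
  stopifnot(n_nuclei >= 1, nucleus_diameter_nm > 0, knob_count >= 0,
            knob_radius_nm > 0, knob_density > 0, silent_focus_count >= 0,
            base_intensity > 0, noise_gain >= 0, noise_read_sd >= 0)
  if (length(markers) > 0 && (any(markers < 0) || any(markers > 1)))
    stop("marker weights must lie in [0, 1]")
  if (!is.null(locus))
    stopifnot(locus$proximal_prob >= 0, locus$proximal_prob <= 1)
  structure(as.list(environment()), class = "scene_params")
}

# smoothed lognormal random texture with unit median, inside-mask values
lognormal_texture <- function(shape, log_sd, correlation_nm, voxel_size) {
  w <- array(rnorm(prod(shape)), shape)
  s <- gaussian_blur(w, rep(correlation_nm, 3), voxel_size)
  s <- (s - mean(s)) / sd(s)
  exp(log_sd * s)
}

# squared physical distance of every voxel center to a point (nm)
dist2_to_point <- function(shape, voxel_size, point) {
  z <- ((seq_len(shape[1]) - 0.5) * voxel_size[1] - point[1])^2
  y <- ((seq_len(shape[2]) - 0.5) * voxel_size[2] - point[2])^2
  x <- ((seq_len(shape[3]) - 0.5) * voxel_size[3] - point[3])^2
  outer(outer(z, y, `+`), x, `+`)
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic multichannel nucleus scene with ground truth
#'
#' Builds SIM-like stacks: a DAPI channel made of a smoothed lognormal
#' chromatin field inside each nucleus with planted knobs (compact bodies
#' at `knob_density` x the median nuclear density) and peripheral silent
#' foci; marker channels mixing the chromatin template with an independent
#' field according to their colocalization weight; an optional tagged-locus
#' channel. Every channel is blurred with the Gaussian PSF; marker channels
#' are mis-registered by their true transform (resampled under its inverse,
#' so that registering with the true parameters restores alignment); then
#' Poisson and Gaussian read noise are applied. The generator is a pure
#' function of `(params, seed)`.
#'
#' @param params A [scene_params()] object.
#' @param seed Integer seed.
#' @return List with `channels` (named list of [image_stack()]s, always
#'   including `"DAPI"`) and `truth` (nucleus/knob/focus/locus geometry,
#'   marker weights, transforms, seed).
#' @export
generate_nucleus_scene <- function(params = scene_params(), seed = 1) {
  stopifnot(inherits(params, "scene_params"))
  if (!is.null(params$locus) && params$knob_count < 1)
    stop("a locus channel requires at least one knob per nucleus")
  with_seed(seed, {
    p <- params
    vs <- p$voxel_size
    R <- p$nucleus_diameter_nm / 2
    margin <- 600
    # lay nuclei out on a jittered grid
    ncol_ <- ceiling(sqrt(p$n_nuclei))
    nrow_ <- ceiling(p$n_nuclei / ncol_)
    pitch <- 2 * R + 2 * margin
    shape <- p$shape
    if (is.null(shape))
      shape <- ceiling(c(2 * R + 2 * 500,
                         nrow_ * pitch,
                         ncol_ * pitch) / vs)
    ext <- shape * vs
    centers <- matrix(0, p$n_nuclei, 3)
    for (i in seq_len(p$n_nuclei)) {
      r <- (i - 1) %/% ncol_
      cc <- (i - 1) %% ncol_
      centers[i, ] <- c(ext[1] / 2,
                        (r + 0.5) * pitch,
                        (cc + 0.5) * pitch) + c(0, runif(2, -100, 100))
    }

    base <- p$base_intensity
    chroma <- array(0, shape)
    nucleus_truth <- data.frame(id = seq_len(p$n_nuclei),
                                z_nm = centers[, 1], y_nm = centers[, 2],
                                x_nm = centers[, 3], radius_nm = R)
    knob_truth <- silent_truth <- locus_truth <- list()
    locus_clean <- if (!is.null(p$locus)) array(0, shape) else NULL

    for (i in seq_len(p$n_nuclei)) {
      cen <- centers[i, ]
      d2 <- dist2_to_point(shape, vs, cen)
      inside <- d2 <= R^2
      tex <- lognormal_texture(shape, p$texture_log_sd,
                               p$texture_correlation_nm, vs)
      field <- tex * base
      med <- median(field[inside])
      knob_centers <- list()
      for (k in seq_len(p$knob_count)) {
        repeat {  # knobs well inside the nucleus, apart from each other
          kc <- cen + random_unit_vector() * 0.5 * R
          ok <- all(vapply(knob_centers, function(o)
            sqrt(sum((kc - o)^2)) > 2.5 * p$knob_radius_nm, logical(1)))
          if (ok) break
        }
        knob_centers[[k]] <- kc
        kreg <- dist2_to_point(shape, vs, kc) <= p$knob_radius_nm^2
        field[kreg] <- p$knob_density * med
        knob_truth[[length(knob_truth) + 1]] <- data.frame(
          nucleus = i, z_nm = kc[1], y_nm = kc[2], x_nm = kc[3],
          radius_nm = p$knob_radius_nm,
          volume_nm3 = sphere_volume(p$knob_radius_nm))
      }
      for (k in seq_len(p$silent_focus_count)) {
        sc <- cen + random_unit_vector() * 0.9 * R
        sreg <- dist2_to_point(shape, vs, sc) <= p$silent_focus_radius_nm^2 &
          inside
        field[sreg] <- p$silent_focus_density * med
        silent_truth[[length(silent_truth) + 1]] <- data.frame(
          nucleus = i, z_nm = sc[1], y_nm = sc[2], x_nm = sc[3],
          radius_nm = p$silent_focus_radius_nm)
      }
      chroma[inside] <- field[inside]

      if (!is.null(p$locus)) {
        lr <- p$locus$radius_nm
        proximal <- runif(1) < p$locus$proximal_prob
        kc <- knob_centers[[1]]
        if (proximal) {
          # just off the knob surface: edge gap well under 0.2 um
          lc <- kc + random_unit_vector() *
            (p$knob_radius_nm + lr + runif(1, 0, 40))
        } else {
          repeat {  # far from every knob, still inside the nucleus
            lc <- cen + random_unit_vector() * runif(1, 0, 0.8) * R
            gaps <- vapply(knob_centers, function(o)
              sqrt(sum((lc - o)^2)) - p$knob_radius_nm - lr, numeric(1))
            if (all(gaps > 600)) break
          }
        }
        lreg <- dist2_to_point(shape, vs, lc) <= lr^2
        locus_clean[lreg] <- 3 * base
        locus_truth[[length(locus_truth) + 1]] <- data.frame(
          nucleus = i, z_nm = lc[1], y_nm = lc[2], x_nm = lc[3],
          radius_nm = lr, proximal = proximal)
      }
    }

    bg <- p$background * base
    sigma_psf <- fwhm_to_sigma(c(p$psf_fwhm_nm[1], p$psf_fwhm_nm[2],
                                 p$psf_fwhm_nm[2]))
    finish_channel <- function(clean, label, transform = NULL) {
      img <- gaussian_blur(clean + bg, sigma_psf, vs)
      img[img < 0] <- 0
      stack <- image_stack(img, voxel_size = vs, channel = label)
      if (!is.null(transform))
        stack <- apply_inverse_transform(stack, invert_transform(transform,
                                                                 stack))
      v <- stack$voxels
      if (p$noise_gain > 0)
        v <- rpois(length(v), lambda = p$noise_gain * v) / p$noise_gain
      if (p$noise_read_sd > 0)
        v <- v + rnorm(length(v), sd = p$noise_read_sd)
      v[v < 0] <- 0
      dim(v) <- shape
      image_stack(v, voxel_size = vs, channel = label)
    }

    channels <- list(DAPI = finish_channel(chroma, "DAPI"))
    all_inside <- chroma > 0
    for (mk in names(p$markers)) {
      w <- p$markers[[mk]]
      indep <- lognormal_texture(shape, p$texture_log_sd,
                                 p$texture_correlation_nm, vs) * base
      indep[!all_inside] <- 0
      mix <- w * chroma + (1 - w) * indep
      channels[[mk]] <- finish_channel(mix, mk, p$marker_transforms[[mk]])
    }
    if (!is.null(p$locus)) {
      ch <- p$locus$channel %||% "lacI"
      channels[[ch]] <- finish_channel(locus_clean, ch)
    }

    rbind_or_empty <- function(lst) if (length(lst)) do.call(rbind, lst)
      else NULL
    truth <- list(seed = seed,
                  shape = shape,
                  voxel_size = vs,
                  nuclei = nucleus_truth,
                  knobs = rbind_or_empty(knob_truth),
                  silent_foci = rbind_or_empty(silent_truth),
                  loci = rbind_or_empty(locus_truth),
                  marker_weights = p$markers,
                  transforms = p$marker_transforms)
    list(channels = channels, truth = truth)
  })
}

#' Generate a multicolour-bead calibration field
#'
#' Renders `n_beads` Gaussian beads (PSF-sized) at random positions as the
#' reference stack, and the same beads at their transformed positions as
#' the moving stack, emulating the multicolour bead slides used to
#' prepare channel-registration parameters. The moving stack is the
#' reference as seen through the mis-registered channel: registering it
#' with `true_transform` (see [estimate_transform()]) brings it back onto
#' the reference.
#'
#' @param true_transform A [transform_params()].
#' @param n_beads Number of beads (>= 3).
#' @param seed Integer seed.
#' @param shape Stack shape `(nz, ny, nx)`.
#' @param voxel_size `(dz, dy, dx)` nm.
#' @param bead_sigma_nm Bead Gaussian sigmas `(z, y, x)` nm (default: the
#'   PSF of the instrument class).
#' @param intensity Mean bead peak intensity.
#' @param noise_sd Additive Gaussian noise s.d. (0 = noise-free).
#' @param margin_nm Minimum distance of bead centers from the frame border
#'   (both before and after the transform; beads whose transformed
#'   position leaves the frame are redrawn).
#' @return List with `reference`, `moving` (both [image_stack()]) and
#'   `truth` (bead positions and the transform).
#' @export
generate_bead_field <- function(true_transform, n_beads = 300, seed = 1,
                                shape = c(32, 128, 128),
                                voxel_size = c(125, 40, 40),
                                bead_sigma_nm = fwhm_to_sigma(c(300, 120, 120)),
                                intensity = 1000,
                                noise_sd = 0,
                                margin_nm = 600) {
  stopifnot(inherits(true_transform, "transform_params"), n_beads >= 3)
  with_seed(seed, {
    ext <- shape * voxel_size
    template <- image_stack(array(0, shape), voxel_size = voxel_size)
    aff <- transform_affine(true_transform, template)
    fwd <- function(q) as.numeric(aff$A %*% q + aff$b)
    pos <- matrix(0, n_beads, 3)
    pos_mov <- matrix(0, n_beads, 3)
    for (i in seq_len(n_beads)) {
      placed <- FALSE
      for (try in 1:200) {
        q <- runif(3, margin_nm, ext - margin_nm)
        qm <- fwd(q)
        if (all(qm > margin_nm / 2) && all(qm < ext - margin_nm / 2)) {
          pos[i, ] <- q
          pos_mov[i, ] <- qm
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("transform pushes beads out of frame")
    }
    amp <- intensity * exp(rnorm(n_beads, sd = 0.1))
    ref <- render_beads(pos, amp, shape, voxel_size, bead_sigma_nm)
    # the moving stack is the reference seen through the transform: bead
    # centers move to T(p) and the pulled-back Gaussian widths scale with
    # the per-axis magnifications (the z rotation leaves the laterally
    # isotropic bead shape unchanged)
    mov_sigma <- bead_sigma_nm * c(true_transform$mz, true_transform$my,
                                   true_transform$mx)
    mov <- render_beads(pos_mov, amp, shape, voxel_size, mov_sigma)
    if (noise_sd > 0) {
      ref <- pmax(ref + rnorm(length(ref), sd = noise_sd), 0)
      mov <- pmax(mov + rnorm(length(mov), sd = noise_sd), 0)
      dim(ref) <- dim(mov) <- shape
    }
    list(reference = image_stack(ref, voxel_size, "beads-ref"),
         moving = image_stack(mov, voxel_size, "beads-mov"),
         truth = list(positions = pos, positions_moving = pos_mov,
                      transform = true_transform, seed = seed))
  })
}

# additively render Gaussian beads at physical positions (nm), each
# evaluated on a local +/- 4 sigma window
render_beads <- function(positions, amplitudes, shape, voxel_size,
                         sigma_nm) {
  arr <- array(0, shape)
  half <- ceiling(4 * sigma_nm / voxel_size)
  for (i in seq_len(nrow(positions))) {
    p <- positions[i, ]
    cv <- ceiling(p / voxel_size)  # 1-based voxel containing the center
    lo <- pmax(cv - half, 1)
    hi <- pmin(cv + half, shape)
    if (any(lo > hi)) next
    gz <- exp(-(((lo[1]:hi[1]) - 0.5) * voxel_size[1] - p[1])^2 /
                (2 * sigma_nm[1]^2))
    gy <- exp(-(((lo[2]:hi[2]) - 0.5) * voxel_size[2] - p[2])^2 /
                (2 * sigma_nm[2]^2))
    gx <- exp(-(((lo[3]:hi[3]) - 0.5) * voxel_size[3] - p[3])^2 /
                (2 * sigma_nm[3]^2))
    arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
      amplitudes[i] * outer(outer(gz, gy), gx)
  }
  arr
}
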