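#' Label 26-connected components of a 3D mask
#'
#' @param mask Logical 3D array (z, y, x).
#' @return Integer array of labels (0 = background), with the number of
#'   components in attribute `"n_labels"`.
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  .label3d_cpp(mask, dim(mask))
}

#' Distance transform of a mask in physical units
#'
#' Exact Euclidean distance (nm) from every voxel center to the nearest
#' voxel center inside the mask, honoring anisotropic voxel sizes.
#'
#' @param mask Logical 3D array with at least one TRUE voxel.
#' @param voxel_size `(dz, dy, dx)` in nm.
#' @return Numeric array of distances (0 inside the mask).
#' @export
mask_distance <- function(mask, voxel_size) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, any(mask))
  .edt3d_cpp(mask, dim(mask), as.numeric(voxel_size))
}

new_nucleus <- function(id, voxels_lin, dims, voxel_size) {
  zyx <- linear_to_zyx(voxels_lin, dims)
  centers <- voxel_centers(zyx, voxel_size)
  structure(list(id = id,
                 voxels = voxels_lin,
                 dims = dims,
                 voxel_size = voxel_size,
                 centroid = colMeans(centers),
                 volume = length(voxels_lin) * prod(voxel_size),
                 members = list(),
                 unassigned = NULL),
            class = "nucleus_object")
}

#' @export
print.nucleus_object <- function(x, ...) {
  cat(sprintf("nucleus %d: %d voxels, volume %.3g nm^3, centroid (%.0f, %.0f, %.0f) nm, %d member channel(s)\n",
              x$id, length(x$voxels), x$volume,
              x$centroid[1], x$centroid[2], x$centroid[3],
              length(x$members)))
  invisible(x)
}

nucleus_mask <- function(nucleus) {
  m <- array(FALSE, nucleus$dims)
  m[nucleus$voxels] <- TRUE
  m
}

#' Segment individual nuclei from the DAPI channel
#'
#' Binarizes the DAPI stack at the flexible threshold (parameter `d`),
#' labels 26-connected components, drops components smaller than
#' `min_volume` (speckle suppression) and returns the remaining components
#' as nucleus objects sorted by volume, largest first. An all-zero (or
#' otherwise constant) stack yields an empty list.
#'
#' @param dapi DAPI [image_stack()].
#' @param d Threshold flexibility parameter (see [flexible_threshold()]).
#' @param min_volume Minimum nucleus volume in nm^3 (default: 400 nm-radius
#'   sphere).
#' @return List of `nucleus_object`s (possibly empty), each carrying its
#'   voxel set, centroid (nm), and volume (nm^3).
#' @export
segment_nuclei <- function(dapi, d = analysis_config()$threshold_d,
                           min_volume = analysis_config()$segment_min_volume_nm3) {
  stopifnot(inherits(dapi, "image_stack"))
  if (diff(range(dapi$voxels)) <= 0) return(list())  # no signal
  thr <- flexible_threshold(dapi, d)
  mask <- threshold_mask(dapi, thr)
  if (!any(mask)) return(list())
  lab <- label_components(mask)
  n <- attr(lab, "n_labels")
  if (n == 0) return(list())
  vols <- tabulate(lab[lab > 0], nbins = n) * voxel_volume(dapi)
  keep <- which(vols >= min_volume)
  keep <- keep[order(vols[keep], decreasing = TRUE)]
  dims <- dim(dapi$voxels)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    out[[i]] <- new_nucleus(i, which(lab == keep[i]), dims, dapi$voxel_size)
    out[[i]]$threshold <- thr$T
  }
  out
}

#' Group thresholded objects from other channels to nuclei
#'
#' Using DAPI as the reference, an object in another channel is grouped
#' with a nucleus when its minimum edge-to-edge distance to the nucleus
#' mask is at most `max_dist` (default 200 nm, the 0.2 um rule). Distances
#' are physical, computed through the distance transform of each nucleus
#' mask, so the rule is independent of voxel anisotropy. An object within
#' range of several nuclei is assigned to each of them and flagged
#' ambiguous; objects assigned to no nucleus are reported in the
#' `unassigned` field of the first nucleus.
#'
#' @param nuclei List of `nucleus_object`s from [segment_nuclei()].
#' @param channel_objects Named list (one entry per channel) of either an
#'   integer label array (as from [label_components()]) or a logical mask
#'   (labelled internally), on the same registered grid as the nuclei.
#' @param max_dist Grouping distance in nm.
#' @return The nuclei with `members[[channel]]` filled: each member is a
#'   list with the object's voxel set, its distance to the nucleus, and an
#'   `ambiguous` flag.
#' @export
group_channels <- function(nuclei, channel_objects,
                           max_dist = analysis_config()$grouping_distance_nm) {
  if (length(nuclei) == 0) return(nuclei)
  stopifnot(is.list(channel_objects), !is.null(names(channel_objects)))
  dims <- nuclei[[1]]$dims
  vs <- nuclei[[1]]$voxel_size
  # per-nucleus distance fields
  dist_fields <- lapply(nuclei, function(nuc) mask_distance(nucleus_mask(nuc), vs))

  unassigned <- list()
  for (ch in names(channel_objects)) {
    obj <- channel_objects[[ch]]
    if (is.logical(obj)) obj <- label_components(obj)
    stopifnot(all(dim(obj) == dims))
    n_obj <- max(0L, max(obj))
    if (n_obj == 0) next
    obj_vox <- split(which(obj > 0), obj[obj > 0])
    # distance of each object to each nucleus
    dmat <- matrix(Inf, n_obj, length(nuclei))
    for (i in seq_len(n_obj))
      for (j in seq_along(nuclei))
        dmat[i, j] <- min(dist_fields[[j]][obj_vox[[i]]])
    for (i in seq_len(n_obj)) {
      hits <- which(dmat[i, ] <= max_dist)
      if (length(hits) == 0) {
        unassigned[[length(unassigned) + 1]] <-
          list(channel = ch, object = i, voxels = obj_vox[[i]],
               min_distance = min(dmat[i, ]))
        next
      }
      for (j in hits) {
        member <- list(channel = ch, object = i, voxels = obj_vox[[i]],
                       distance = dmat[i, j],
                       ambiguous = length(hits) > 1)
        nuclei[[j]]$members[[ch]] <-
          c(nuclei[[j]]$members[[ch]], list(member))
      }
    }
  }
  if (length(unassigned) > 0) nuclei[[1]]$unassigned <- unassigned
  nuclei
}

#' Crop all channels of a scene around one nucleus
#'
#' Takes the axis-aligned bounding box of the nucleus mask, expands it by
#' `margin` (nm, converted per axis), clips to the frame, and crops every
#' channel identically. The nucleus mask is shifted into crop coordinates.
#'
#' @param stacks Named list of [image_stack()] objects on the nucleus grid.
#' @param nucleus A `nucleus_object`.
#' @param margin Margin in nm added on every side of the bounding box.
#' @return List with `channels` (named list of cropped stacks), `mask`
#'   (logical array in crop coordinates), `offset` (1-based array index of
#'   the crop origin in the full frame) and `bbox`.
#' @export
crop_nucleus <- function(stacks, nucleus, margin = 0) {
  stopifnot(is.list(stacks), length(stacks) > 0)
  dims <- nucleus$dims
  vs <- nucleus$voxel_size
  zyx <- linear_to_zyx(nucleus$voxels, dims)
  mvox <- ceiling(margin / vs)
  lo <- pmax(apply(zyx, 2, min) - mvox, 1)
  hi <- pmin(apply(zyx, 2, max) + mvox, dims)
  crop_one <- function(s) {
    stopifnot(all(dim(s$voxels) == dims))
    as_stack_like(s$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                           drop = FALSE], s)
  }
  channels <- lapply(stacks, crop_one)
  mask_full <- nucleus_mask(nucleus)
  mask <- mask_full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  list(channels = channels, mask = mask, offset = lo, bbox = rbind(lo = lo, hi = hi))
}

# Minimum edge-to-edge physical distance between two voxel sets (linear
# indices into the same grid). Exact pairwise computation; intended for
# compact objects (foci, knobs).
min_voxel_distance <- function(vox_a, vox_b, dims, voxel_size) {
  a <- voxel_centers(linear_to_zyx(vox_a, dims), voxel_size)
  b <- voxel_centers(linear_to_zyx(vox_b, dims), voxel_size)
  if (length(vox_a) == 0 || length(vox_b) == 0) return(Inf)
  if (any(vox_a %in% vox_b)) return(0)
  dmin <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    dmin <- min(dmin, min(d2))
  }
  sqrt(dmin)
}

#' Per-nucleus summary table
#'
#' @param nuclei List of `nucleus_object`s, possibly with members grouped.
#' @return `data.frame` with id, centroid (nm), volume (nm^3) and member
#'   counts per channel.
#' @export
nucleus_table <- function(nuclei) {
  if (length(nuclei) == 0)
    return(data.frame(id = integer(0), centroid_z_nm = numeric(0),
                      centroid_y_nm = numeric(0), centroid_x_nm = numeric(0),
                      volume_nm3 = numeric(0)))
  channels <- unique(unlist(lapply(nuclei, function(n) names(n$members))))
  df <- data.frame(
    id = vapply(nuclei, `[[`, integer(1) * 1, "id"),
    centroid_z_nm = vapply(nuclei, function(n) n$centroid[1], numeric(1)),
    centroid_y_nm = vapply(nuclei, function(n) n$centroid[2], numeric(1)),
    centroid_x_nm = vapply(nuclei, function(n) n$centroid[3], numeric(1)),
    volume_nm3 = vapply(nuclei, `[[`, numeric(1), "volume"))
  for (ch in channels)
    df[[paste0("n_", ch)]] <-
      vapply(nuclei, function(n) length(n$members[[ch]]), numeric(1))
  df
}
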