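#' 3D image stacks with physical voxel sizes
#'
#' An `image_stack` is the unit all image operations in this package consume:
#' a 3D grid of non-negative intensities indexed `(z, y, x)` together with the
#' physical voxel size `(dz, dy, dx)` in nanometres and a free-text channel
#' label.
#'
#' The coordinate convention is fixed package-wide: voxel `(z, y, x)`
#' (0-based) has its center at physical position
#' `((z + 0.5) dz, (y + 0.5) dy, (x + 0.5) dx)` nm. In R the same voxel is
#' addressed with 1-based indices, so the center of `voxels[i, j, k]` is
#' `((i - 0.5) dz, (j - 0.5) dy, (k - 0.5) dx)`. Anisotropic voxels are
#' expected (axial spacing typically exceeds lateral spacing); all physical
#' distances elsewhere in the package are computed through `voxel_size`,
#' never as voxel counts.
#'
#' @param voxels 3D numeric array of finite, non-negative intensities,
#'   dimension order `(z, y, x)`.
#' @param voxel_size Numeric length-3 vector `(dz, dy, dx)` in nm, all
#'   components positive.
#' @param channel Character channel label, e.g. `"DAPI"` or `"GFP"`.
#' @return An object of class `image_stack`.
#' @examples
#' s <- image_stack(array(runif(8 * 16 * 16), c(8, 16, 16)),
#'                  voxel_size = c(125, 40, 40), channel = "DAPI")
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, voxel_size = c(125, 40, 40), channel = "") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array ordered (z, y, x)")
  storage.mode(voxels) <- "double"
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("intensities must be finite")
  if (any(voxels < 0))
    stop("intensities must be >= 0")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be three positive values (dz, dy, dx) in nm")
  names(voxel_size) <- c("dz", "dy", "dx")
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 channel = as.character(channel)[1]),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack [%s] %d x %d x %d (z,y,x), voxel %g x %g x %g nm, range [%g, %g]\n",
              if (nzchar(x$channel)) x$channel else "unlabelled",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

as_stack_like <- function(x, template) {
  image_stack(x, voxel_size = template$voxel_size, channel = template$channel)
}

#' Physical volume of one voxel in nm^3
#' @param stack An `image_stack` (or voxel-size vector).
#' @return Scalar volume in nm^3.
#' @export
voxel_volume <- function(stack) {
  vs <- if (inherits(stack, "image_stack")) stack$voxel_size else stack
  prod(vs)
}

# Physical center coordinates (nm) of voxels given 1-based array indices
# (matrix with columns z, y, x).
voxel_centers <- function(index_mat, voxel_size) {
  sweep(index_mat - 0.5, 2, voxel_size, `*`)
}

# linear index -> (z, y, x) 1-based array index matrix
linear_to_zyx <- function(lin, dims) {
  lin0 <- lin - 1L
  z <- lin0 %% dims[1]
  y <- (lin0 %/% dims[1]) %% dims[2]
  x <- lin0 %/% (dims[1] * dims[2])
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}
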