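#' Read a 3D image stack from a multipage TIFF
#'
#' Stacks are stored one channel per file as multipage TIFFs (one page per z
#' slice) with a JSON sidecar (`<stem>.json`) carrying the physical voxel
#' size, the channel label and the intensity scale. Files written by
#' [write_stack()] round-trip bit-exactly for integer-valued data.
#'
#' @param path Path to a multipage TIFF written by [write_stack()] or any
#'   single-channel multipage TIFF.
#' @param voxel_size_override Optional `(dz, dy, dx)` in nm, used when the
#'   sidecar metadata is absent. An error is raised if neither source of
#'   voxel size is available.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, voxel_size_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("not a single-channel 3D stack: ", path,
         " (need >= 2 z slices)")
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("not a single-channel 3D stack: ", path,
         " (pages carry extra sample dimensions)")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  if (any(vapply(pages, function(p) nrow(p) != ny || ncol(p) != nx,
                 logical(1))))
    stop("inconsistent page dimensions in ", path)
  nz <- length(pages)
  vox <- array(0, c(nz, ny, nx))
  for (i in seq_len(nz)) vox[i, , ] <- pages[[i]]

  meta <- stack_sidecar_path(path)
  channel <- ""
  voxel_size <- voxel_size_override
  if (file.exists(meta)) {
    info <- jsonlite::read_json(meta, simplifyVector = TRUE)
    vox <- vox * info$scale
    if (identical(info$kind, "integer")) vox <- round(vox)
    voxel_size <- info$voxel_size_nm
    channel <- info$channel %||% ""
  }
  if (is.null(voxel_size))
    stop("no voxel size: ", path,
         " has no metadata sidecar and no 'voxel_size_override' was given")
  image_stack(vox, voxel_size = voxel_size, channel = channel)
}

#' Write a 3D image stack to a multipage TIFF
#'
#' Intensities are stored as 32-bit samples after division by a scale factor
#' recorded in the JSON sidecar. Integer-valued stacks use the full 32-bit
#' code range and are restored exactly; other stacks use a power-of-two
#' scale and are restored to within 32-bit quantization (relative error
#' below 1e-9).
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  v <- stack$voxels
  mx <- max(v)
  integer_valued <- all(v == round(v)) && mx <= 2^32 - 1
  if (integer_valued) {
    scale <- 2^32 - 1
    kind <- "integer"
  } else {
    scale <- if (mx > 0) 2^ceiling(log2(mx)) else 1
    kind <- "float"
  }
  nz <- dim(v)[1]
  pages <- lapply(seq_len(nz), function(i) v[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(voxel_size_nm = unname(stack$voxel_size), channel = stack$channel,
         scale = scale, kind = kind, dim = dim(v)),
    stack_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

stack_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a multichannel scene to a directory
#'
#' A scene is a set of co-acquired channel stacks on a common grid. Each
#' channel goes to its own TIFF (plus sidecar) and a `manifest.json` ties
#' them together; any ground-truth object supplied is serialized alongside.
#'
#' @param channels Named list of [image_stack()] objects.
#' @param dir Output directory (created if needed).
#' @param truth Optional list of ground-truth scene parameters.
#' @return Path to the manifest, invisibly.
#' @export
write_scene <- function(channels, dir, truth = NULL) {
  stopifnot(is.list(channels), length(channels) > 0,
            !is.null(names(channels)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (ch in names(channels)) {
    f <- file.path(dir, paste0(ch, ".tif"))
    write_stack(channels[[ch]], f)
    files[ch] <- basename(f)
  }
  manifest <- list(channels = as.list(files),
                   voxel_size_nm = unname(channels[[1]]$voxel_size))
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    manifest$truth <- "truth.json"
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' Read a multichannel scene written by [write_scene()]
#'
#' @param dir Scene directory or path to its `manifest.json`.
#' @return Named list of [image_stack()] objects, with the manifest stored
#'   in attribute `"manifest"`.
#' @export
read_scene <- function(dir) {
  mf <- if (dir.exists(dir)) file.path(dir, "manifest.json") else dir
  if (!file.exists(mf)) stop("no scene manifest at ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  base <- dirname(mf)
  channels <- lapply(manifest$channels,
                     function(f) read_stack(file.path(base, f)))
  attr(channels, "manifest") <- manifest
  channels
}
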