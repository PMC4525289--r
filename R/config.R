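#' Analysis configuration
#'
#' Bundles every tunable constant of the imaging pipeline in one
#' serializable object. The defaults reproduce the published constants of
#' the method: the 0.2 um (200 nm) cross-channel grouping distance and the
#' 250x zero-padding factor of the overlap statistic. All distances are in
#' nm, volumes in nm^3.
#'
#' @param threshold_d Flexibility parameter `d` of [flexible_threshold()],
#'   in `[0, 1]`. 0 keeps the automatic isodata threshold, 1 raises it to
#'   the above-threshold mean. Default 0.5, midway between the two anchors.
#' @param grouping_distance_nm Maximum edge-to-edge distance at which
#'   objects in other channels are grouped with a DAPI nucleus (default
#'   200 nm, i.e. 0.2 um).
#' @param padding_factor Zero-padding factor of the overlap statistic
#'   (default 250: padded volume is 250x the crop volume).
#' @param segment_min_volume_nm3 Minimum nucleus volume; smaller components
#'   are treated as speckles. Default: volume of a 400 nm-radius sphere.
#' @param knob_smoothing_sigma_nm Gaussian pre-smoothing of the knob caller,
#'   `(axial, lateral)` sigmas in nm (default 150/60).
#' @param knob_zscore_cutoff Within-nucleus intensity z-score at which
#'   voxels become knob candidates (default 2).
#' @param knob_min_volume_nm3 Minimum knob volume (default: 150 nm-radius
#'   sphere).
#' @param knob_max_volume_frac Maximum knob volume as a fraction of its
#'   nucleus volume (default 0.05).
#' @param knob_min_intensity_ratio Minimum mean raw intensity of a knob
#'   relative to the within-nucleus median (default 1.5).
#' @param register_bounds Search bounds of [estimate_transform()]: list with
#'   `translation_nm`, `rotation_deg`, `magnification_dev` (absolute
#'   deviation of each magnification from 1).
#' @param register_tol Relative convergence tolerance of the simplex
#'   refinement in normalized parameter space (default 1e-4).
#' @param seed Integer seed used by pipeline entry points that draw random
#'   numbers.
#' @return An object of class `analysis_config` (a named list).
#' @seealso [read_config()], [write_config()]
#' @export
analysis_config <- function(threshold_d = 0.5,
                            grouping_distance_nm = 200,
                            padding_factor = 250L,
                            segment_min_volume_nm3 = sphere_volume(400),
                            knob_smoothing_sigma_nm = c(150, 60),
                            knob_zscore_cutoff = 2,
                            knob_min_volume_nm3 = sphere_volume(150),
                            knob_max_volume_frac = 0.05,
                            knob_min_intensity_ratio = 1.5,
                            register_bounds = list(translation_nm = 500,
                                                   rotation_deg = 1,
                                                   magnification_dev = 0.005),
                            register_tol = 1e-4,
                            seed = 1L) {
  stopifnot(threshold_d >= 0, threshold_d <= 1,
            grouping_distance_nm > 0, padding_factor >= 1,
            segment_min_volume_nm3 >= 0, length(knob_smoothing_sigma_nm) == 2,
            knob_zscore_cutoff >= 0, knob_min_volume_nm3 >= 0,
            knob_max_volume_frac > 0, knob_max_volume_frac <= 1,
            knob_min_intensity_ratio >= 0, register_tol > 0)
  cfg <- list(threshold_d = threshold_d,
              grouping_distance_nm = grouping_distance_nm,
              padding_factor = as.integer(padding_factor),
              segment_min_volume_nm3 = segment_min_volume_nm3,
              knob_smoothing_sigma_nm = as.numeric(knob_smoothing_sigma_nm),
              knob_zscore_cutoff = knob_zscore_cutoff,
              knob_min_volume_nm3 = knob_min_volume_nm3,
              knob_max_volume_frac = knob_max_volume_frac,
              knob_min_intensity_ratio = knob_min_intensity_ratio,
              register_bounds = register_bounds,
              register_tol = register_tol,
              seed = as.integer(seed))
  class(cfg) <- "analysis_config"
  cfg
}

#' Volume of a sphere of radius r (nm -> nm^3)
#' @param r_nm Radius in nm.
#' @export
sphere_volume <- function(r_nm) 4 / 3 * pi * r_nm^3

#' Write an analysis configuration to JSON
#' @param config An [analysis_config()].
#' @param path Output JSON path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an analysis configuration from JSON
#'
#' Unknown keys are rejected so that typos in hand-edited configuration
#' files fail loudly instead of silently falling back to defaults.
#'
#' @param path JSON file written by [write_config()] (or hand-authored with
#'   the same keys).
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (!is.null(vals$register_bounds))
    vals$register_bounds <- as.list(vals$register_bounds)
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.list(v)) v <- paste(names(v), unlist(v), sep = "=", collapse = ", ")
    cat(sprintf("  %-26s %s\n", k, paste(signif(unlist(v), 6), collapse = " ")))
  }
  invisible(x)
}
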