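#' Image metadata
#'
#' Physical calibration and value-kind tag attached to every image the package
#' reads or writes. The defaults reflect a holotomography system with 156 nm
#' lateral sampling; the axial sampling interval of an RI stack is instrument
#' configuration, so `z_step` defaults to 1 micron and should be set from the
#' acquisition.
#'
#' @param pixel_size_xy lateral size of one pixel, in microns (> 0).
#' @param z_step axial distance between consecutive slices, in microns (> 0).
#' @param kind value kind, one of `"ri"` (refractive index, float),
#'   `"rgb"` (8-bit colour) or `"label"` (16-bit integer mask).
#' @param axes axes-order tag; arrays in this package are always `(z, y, x)`
#'   with an optional trailing channel axis.
#' @return An object of class `image_meta`.
#' @export
image_meta <- function(pixel_size_xy = 0.156, z_step = 1.0,
                       kind = c("ri", "rgb", "label"), axes = "zyx") {
  kind <- match.arg(kind)
  if (!is.numeric(pixel_size_xy) || pixel_size_xy <= 0)
    vs_error("vistain_value_error", "pixel_size_xy must be > 0")
  if (!is.numeric(z_step) || z_step <= 0)
    vs_error("vistain_value_error", "z_step must be > 0")
  structure(list(pixel_size_xy = pixel_size_xy, z_step = z_step,
                 kind = kind, axes = axes),
            class = "image_meta")
}

#' @export
print.image_meta <- function(x, ...) {
  cat(sprintf("<image_meta> kind=%s pixel=%.4g um z_step=%.4g um axes=%s\n",
              x$kind, x$pixel_size_xy, x$z_step, x$axes))
  invisible(x)
}

#' Pipeline configuration
#'
#' Central configuration for the staining pipeline. Field semantics:
#' `patch_size`/`overlap_fraction` control wide-field tiling (the reference
#' workflow uses 1024-pixel patches with 50% overlap); `pcc_keep_threshold`
#' is the Pearson-correlation floor below which a training patch pair is
#' discarded; `ri_display_range` is the physical refractive-index window used
#' to normalize network inputs.
#'
#' @param patch_size side of square patches, in pixels; must be even.
#' @param overlap_fraction fractional overlap between neighbouring patches,
#'   strictly between 0 and 1.
#' @param pcc_keep_threshold minimum Pearson correlation for a curated pair.
#' @param ri_display_range length-2 numeric, RI window mapped to `[-1, 1]`.
#' @param seed integer seed for all stochastic stages.
#' @param train named list of training hyper-parameters merged into
#'   [train_config()].
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(patch_size = 1024L, overlap_fraction = 0.5,
                            pcc_keep_threshold = 0.65,
                            ri_display_range = c(1.33, 1.60),
                            seed = 1L, train = list()) {
  if (patch_size %% 2 != 0 || patch_size < 2)
    vs_error("vistain_value_error", "patch_size must be even and >= 2")
  if (!(overlap_fraction > 0 && overlap_fraction < 1))
    vs_error("vistain_value_error", "overlap_fraction must be in (0, 1)")
  if (!(pcc_keep_threshold >= -1 && pcc_keep_threshold <= 1))
    vs_error("vistain_value_error", "pcc_keep_threshold must lie in [-1, 1]")
  if (length(ri_display_range) != 2 || diff(ri_display_range) <= 0)
    vs_error("vistain_value_error", "ri_display_range must be increasing")
  structure(list(patch_size = as.integer(patch_size),
                 overlap_fraction = overlap_fraction,
                 pcc_keep_threshold = pcc_keep_threshold,
                 ri_display_range = ri_display_range,
                 seed = as.integer(seed), train = train),
            class = "pipeline_config")
}

#' Load and merge configuration
#'
#' Configuration is resolved as defaults < YAML file < explicit overrides, so
#' a run is fully determined by its file plus command-line flags. The
#' effective configuration is what [run_cli()] echoes to its log.
#'
#' @param file optional path to a YAML file with any subset of the
#'   [pipeline_config()] fields.
#' @param overrides named list applied last (e.g. parsed CLI flags).
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(file = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(file)) {
    if (!file.exists(file))
      vs_error("vistain_io_error", sprintf("config file not found: %s", file))
    vals <- yaml::read_yaml(file)
  }
  vals <- utils::modifyList(vals, overrides[!vapply(overrides, is.null, TRUE)])
  defaults <- formals(pipeline_config)
  keep <- intersect(names(vals), names(defaults))
  do.call(pipeline_config, vals[keep])
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  patch_size: %d  overlap: %.2f  pcc_keep_threshold: %.2f\n",
              x$patch_size, x$overlap_fraction, x$pcc_keep_threshold))
  cat(sprintf("  ri_display_range: [%.3f, %.3f]  seed: %d\n",
              x$ri_display_range[1], x$ri_display_range[2], x$seed))
  invisible(x)
}
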