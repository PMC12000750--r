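#' Analysis configuration
#'
#' One container for every tunable parameter of the image, mechanics and
#' secretome pipelines, serializable losslessly to YAML. Defaults reflect the
#' acquisition geometry (0.42 um lateral pixels, 2 um z-step) and the
#' documented analysis choices; see the methods vignette for rationale.
#'
#' @param nuclei_threshold,actin_threshold,nascent_threshold,collagen_threshold
#'   per-channel segmentation threshold: the string `"otsu"` (automatic) or a
#'   fixed numeric intensity on the channel's own scale.
#' @param min_nucleus_volume_um3 smallest accepted nucleus, in cubic um.
#' @param split_min_distance_um distance-transform maxima closer than this are
#'   merged before watershed splitting of touching nuclei.
#' @param crop_padding_um padding added around each seed bounding box when
#'   cropping single cells.
#' @param detection_min_voxels voxel floor below which a cell's nascent signal
#'   counts as undetectable (class `negative`).
#' @param min_object_volume_um3 smallest counted object in viability images.
#' @param poisson_ratio Poisson ratio used by the Hertz fit (0.5 =
#'   incompressible hydrogel).
#' @param fit_window_um indentation interval (um) used by the Hertz fit.
#' @param contact_baseline_frac fraction of leading samples treated as
#'   pre-contact baseline during contact-point detection.
#' @param contact_k baseline-crossing threshold in robust baseline SDs.
#' @param variance_threshold analytes with sample variance strictly below this
#'   are excluded before clustering.
#' @param excluded_analytes analytes removed before sample PCA (the spiked
#'   inflammatory stimuli).
#' @param saturation_threshold fraction of the source level defining
#'   "saturated" in diffusion series.
#' @param seed default random seed for stochastic stages.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return a validated list of class `analysis_config`.
#' @export
analysis_config <- function(nuclei_threshold = "otsu",
                            actin_threshold = "otsu",
                            nascent_threshold = "otsu",
                            collagen_threshold = "otsu",
                            min_nucleus_volume_um3 = 25,
                            split_min_distance_um = 5,
                            crop_padding_um = 10,
                            detection_min_voxels = 5,
                            min_object_volume_um3 = 25,
                            poisson_ratio = 0.5,
                            fit_window_um = c(1, 4),
                            contact_baseline_frac = 0.2,
                            contact_k = 5,
                            variance_threshold = 0.9,
                            excluded_analytes = c("IL-1 beta", "TNF alpha"),
                            saturation_threshold = 0.95,
                            seed = 1L,
                            voxel_size = c(2, 0.42, 0.42)) {
  cfg <- list(nuclei_threshold = nuclei_threshold,
              actin_threshold = actin_threshold,
              nascent_threshold = nascent_threshold,
              collagen_threshold = collagen_threshold,
              min_nucleus_volume_um3 = min_nucleus_volume_um3,
              split_min_distance_um = split_min_distance_um,
              crop_padding_um = crop_padding_um,
              detection_min_voxels = detection_min_voxels,
              min_object_volume_um3 = min_object_volume_um3,
              poisson_ratio = poisson_ratio,
              fit_window_um = as.numeric(fit_window_um),
              contact_baseline_frac = contact_baseline_frac,
              contact_k = contact_k,
              variance_threshold = variance_threshold,
              excluded_analytes = as.character(excluded_analytes),
              saturation_threshold = saturation_threshold,
              seed = as.integer(seed),
              voxel_size = as.numeric(voxel_size))
  validate_config(cfg)
  structure(cfg, class = c("analysis_config", "list"))
}

chk_threshold <- function(x, name) {
  ok <- (is.character(x) && length(x) == 1 && x == "otsu") ||
    (is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0)
  if (!ok) oc_abort(sprintf("`%s` must be \"otsu\" or a non-negative number",
                            name), "invalid_config")
}

chk_pos <- function(x, name, lo = 0, hi = Inf, lo_ok = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    all(if (lo_ok) x >= lo else x > lo) && all(x <= hi)
  if (!ok) oc_abort(sprintf("`%s` out of valid range", name), "invalid_config")
}

validate_config <- function(cfg) {
  for (nm in c("nuclei_threshold", "actin_threshold", "nascent_threshold",
               "collagen_threshold"))
    chk_threshold(cfg[[nm]], nm)
  chk_pos(cfg$min_nucleus_volume_um3, "min_nucleus_volume_um3")
  chk_pos(cfg$split_min_distance_um, "split_min_distance_um")
  chk_pos(cfg$crop_padding_um, "crop_padding_um", lo_ok = TRUE)
  chk_pos(cfg$detection_min_voxels, "detection_min_voxels", lo_ok = TRUE)
  chk_pos(cfg$min_object_volume_um3, "min_object_volume_um3", lo_ok = TRUE)
  chk_pos(cfg$poisson_ratio, "poisson_ratio", lo = 0, hi = 0.5, lo_ok = TRUE)
  chk_pos(cfg$fit_window_um, "fit_window_um")
  if (length(cfg$fit_window_um) != 2 ||
      cfg$fit_window_um[1] >= cfg$fit_window_um[2])
    oc_abort("`fit_window_um` must be an increasing (lo, hi) pair",
             "invalid_config")
  chk_pos(cfg$contact_baseline_frac, "contact_baseline_frac", hi = 0.9)
  chk_pos(cfg$contact_k, "contact_k")
  chk_pos(cfg$variance_threshold, "variance_threshold", lo_ok = TRUE)
  chk_pos(cfg$saturation_threshold, "saturation_threshold", hi = 1)
  chk_pos(cfg$voxel_size, "voxel_size")
  if (length(cfg$voxel_size) != 3)
    oc_abort("`voxel_size` must have 3 components", "invalid_config")
  invisible(cfg)
}

#' Read / write an analysis configuration
#'
#' YAML round-trips are lossless: `read_config(write_config(cfg, f))` equals
#' `cfg` for every valid configuration.
#'
#' @param cfg an [analysis_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated [analysis_config()].
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    oc_abort(sprintf("config file not found: %s", path), "missing_file")
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw)
}
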