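# Run configuration: a single nested list, serializable to YAML, validated
# against the default schema before any computation (unknown keys are
# rejected so typos cannot silently fall back to defaults).

#' Default pipeline configuration
#'
#' @return Nested list of class `run_config` covering all tunable
#'   parameters: channel roles, pixel calibration, segmentation, midline,
#'   focus detection, curation, chromosome 1 filter, statistics options,
#'   and the synthetic-dataset block.
#' @export
default_config <- function() {
  structure(list(
    channels = list(red = "SYCP3", green = "MLH1", blue = "CREST"),
    px_per_um = 9.8152,
    segmentation = list(threshold_offset = 0, min_area = 150, max_area = 6000,
                        min_skeleton = 30, max_skeleton = 400,
                        min_eccentricity = 0.85, min_solidity = 0.25,
                        max_branch_points = 0, border_margin = 3, spur_px = 5),
    midline = list(spur_px = 5, resample_step = 0.5, max_spline_dev = 1,
                   max_extension_px = 20),
    foci = list(k_sd = 6, min_separation = 5, centrality_frac = 0.75,
                tie_tol = 1e-3, half_width = 5),
    curation = list(max_foci = 4, offset_frac = 0.6, length_mad_k = 3.5,
                    min_cell_n = 5, min_skeleton_px = 30),
    chr1 = list(sc_length_um_min = 10, sc_length_um_max = 17,
                centromere_norm_min = 0.15, centromere_norm_max = 0.40,
                require_longest_in_cell = TRUE),
    stats = list(bin_width = 0.05, n_perm = 10000, seed = 1,
                 outlier_min_distance_um = 1, cM_per_focus = 50),
    simulate = list(n_cells = 10, base_seed = 1, n_bivalents = 23,
                    include_xy = TRUE, overlap_fraction = 0,
                    noise_sd = 0.02, illumination_gradient = 0.1,
                    canvas_height = 900, canvas_width = 900,
                    len_min = 95, len_max = 185, ribbon_width = 5,
                    foci_sigma = 2, n_background_foci = 0,
                    salt_fraction = 0, curviness = 0.3)
  ), class = "run_config")
}

#' Validate a configuration against the default schema
#'
#' Every key must exist in [default_config()]; unknown keys raise an
#' error naming the offending path.
#'
#' @param config nested list.
#' @return The merged configuration (defaults overridden by `config`),
#'   invisibly classed `run_config`.
#' @export
validate_config <- function(config) {
  ref <- unclass(default_config())
  check <- function(cfg, ref, path = "") {
    for (nm in names(cfg)) {
      full <- if (nzchar(path)) paste0(path, ".", nm) else nm
      if (!nm %in% names(ref)) stop("unknown config key: ", full)
      if (is.list(ref[[nm]]) && is.list(cfg[[nm]]))
        check(cfg[[nm]], ref[[nm]], full)
    }
  }
  check(config, ref)
  merged <- utils::modifyList(ref, config)
  class(merged) <- "run_config"
  invisible(merged)
}

#' Load a YAML configuration file
#' @param path YAML file; keys override [default_config()].
#' @return Validated `run_config`.
#' @export
load_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validate_config(cfg)
}

#' Hash of a configuration
#' @param config a config list.
#' @return Character md5 of the YAML rendering (used in output headers).
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

# parameter-object constructors from a validated config
params_from_config <- function(config) {
  s <- config$segmentation
  m <- config$midline
  f <- config$foci
  cu <- config$curation
  list(
    seg = segmentation_params(threshold_offset = s$threshold_offset,
                              min_area = s$min_area, max_area = s$max_area,
                              min_skeleton = s$min_skeleton,
                              max_skeleton = s$max_skeleton,
                              min_eccentricity = s$min_eccentricity,
                              min_solidity = s$min_solidity,
                              max_branch_points = s$max_branch_points,
                              border_margin = s$border_margin,
                              spur_px = s$spur_px),
    mid = midline_params(spur_px = m$spur_px,
                         resample_step = m$resample_step,
                         px_per_um = config$px_per_um,
                         max_spline_dev = m$max_spline_dev,
                         max_extension_px = m$max_extension_px),
    foc = foci_params(k_sd = f$k_sd, min_separation = f$min_separation,
                      centrality_frac = f$centrality_frac,
                      tie_tol = f$tie_tol),
    half_width = f$half_width,
    cur = curation_params(max_foci = cu$max_foci,
                          offset_frac = cu$offset_frac,
                          half_width = f$half_width,
                          length_mad_k = cu$length_mad_k,
                          min_cell_n = cu$min_cell_n,
                          min_skeleton_px = cu$min_skeleton_px),
    chr1 = chr1_filter(sc_length_um_window = c(config$chr1$sc_length_um_min,
                                               config$chr1$sc_length_um_max),
                       centromere_norm_window = c(config$chr1$centromere_norm_min,
                                                  config$chr1$centromere_norm_max),
                       require_longest_in_cell = config$chr1$require_longest_in_cell)
  )
}
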