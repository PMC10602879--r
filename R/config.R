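#' Pipeline run configuration
#'
#' Bundles the tunable parameters of every analysis stage with a master seed.
#' Any block can be partially overridden; unspecified entries keep their
#' defaults, which are listed below.
#'
#' @param seed integer master seed for all stochastic stages.
#' @param detection focus detection parameters: `sigma_um` expected focus
#'   Gaussian sigma (default 0.15 um), `k_mad` threshold in MADs above the
#'   filtered-image background (default 5), `rel_cutoff` region-growing
#'   cutoff as a fraction of the peak above local background (default 0.5),
#'   `measure` either `"aperture"` (local-background-subtracted sum within a
#'   `aperture_factor * sigma` ball; default) or `"region"` (raw sum over the
#'   grown region), `aperture_factor` (default 3),
#'   `min_volume_um3`/`max_volume_um3` nucleus size filter (defaults 4, 150),
#'   `watershed` whether to split touching nuclei (default TRUE),
#'   `split_min_radius_um` minimum core radius for a split marker (default 1),
#'   `marker_merge_um` markers closer than this merge (default 1.6).
#' @param zonation `convention`: `"equal_area"` (zone boundaries at
#'   `sqrt(1/3)` and `sqrt(2/3)` of the normalized radius; default) or
#'   `"equal_volume"` (boundaries `(1/3)^(1/3)`, `(2/3)^(1/3)`).
#' @param coloc `tolerance_um` added to the sum of object radii (default 0),
#'   `n_shuffles` (default 100), `alpha` (default 0.05).
#' @param spt `max_displacement_um` linking gate (default 1), `min_length`
#'   minimum track length in frames (default 5), `n_fit_lags` lags in the
#'   initial MSD fit (default 4), `max_lag_frac` fraction of the track length
#'   used as maximum MSD lag (default 0.25), `d_stationary` stationary
#'   threshold on D in um^2/s (default 0.01), `plateau_slope_frac` local
#'   slope fraction locating the plateau time (default 0.15),
#'   `plateau_level_frac` tail-secant fraction declaring a plateau (default
#'   0.5), `plateau_lag_frac` track fraction used as maximum lag for plateau
#'   detection (default 0.5), `window` and `step` for state segmentation
#'   (defaults 10, 1), `scale_um_per_px` applied to pixel-unit track tables
#'   (default 1).
#' @param qpcr `error_mode` `"corrected"` (default) or `"paper"`.
#' @return A validated list of class `RunConfig`.
#' @export
run_config <- function(seed = 1L,
                       detection = list(),
                       zonation = list(),
                       coloc = list(),
                       spt = list(),
                       qpcr = list()) {
  defaults <- list(
    seed = 1L,
    detection = list(
      sigma_um = 0.15, k_mad = 5, rel_cutoff = 0.5,
      measure = "aperture", aperture_factor = 3,
      min_volume_um3 = 4, max_volume_um3 = 150,
      watershed = TRUE, split_min_radius_um = 1.0, marker_merge_um = 1.6
    ),
    zonation = list(convention = "equal_area"),
    coloc = list(tolerance_um = 0, n_shuffles = 100L, alpha = 0.05),
    spt = list(
      max_displacement_um = 1.0, min_length = 5L, n_fit_lags = 4L,
      max_lag_frac = 0.25, d_stationary = 0.01, plateau_slope_frac = 0.15,
      plateau_level_frac = 0.5, plateau_lag_frac = 0.5,
      window = 10L, step = 1L, scale_um_per_px = 1.0
    ),
    qpcr = list(error_mode = "corrected")
  )
  cfg <- defaults
  cfg$seed <- as.integer(seed)
  merge_block <- function(block, user, name) {
    if (length(user) == 0L) return(block)
    bad <- setdiff(names(user), names(block))
    if (length(bad)) stop("unknown ", name, " parameter(s): ",
                          paste(bad, collapse = ", "))
    block[names(user)] <- user
    block
  }
  cfg$detection <- merge_block(cfg$detection, detection, "detection")
  cfg$zonation  <- merge_block(cfg$zonation, zonation, "zonation")
  cfg$coloc     <- merge_block(cfg$coloc, coloc, "coloc")
  cfg$spt       <- merge_block(cfg$spt, spt, "spt")
  cfg$qpcr      <- merge_block(cfg$qpcr, qpcr, "qpcr")
  validate_config(cfg)
  structure(cfg, class = "RunConfig")
}

validate_config <- function(cfg) {
  stopifnot(
    is.finite(cfg$seed),
    cfg$detection$sigma_um > 0,
    cfg$detection$k_mad > 0,
    cfg$detection$rel_cutoff > 0, cfg$detection$rel_cutoff < 1,
    cfg$detection$measure %in% c("aperture", "region"),
    cfg$detection$aperture_factor > 0,
    cfg$detection$min_volume_um3 > 0,
    cfg$detection$max_volume_um3 > cfg$detection$min_volume_um3,
    cfg$zonation$convention %in% c("equal_area", "equal_volume"),
    cfg$coloc$tolerance_um >= 0,
    cfg$coloc$n_shuffles >= 0,
    cfg$coloc$alpha > 0, cfg$coloc$alpha < 1,
    cfg$spt$max_displacement_um > 0,
    cfg$spt$min_length >= 2,
    cfg$spt$n_fit_lags >= 2,
    cfg$spt$max_lag_frac > 0, cfg$spt$max_lag_frac <= 1,
    cfg$spt$d_stationary >= 0,
    cfg$spt$plateau_slope_frac > 0, cfg$spt$plateau_slope_frac < 1,
    cfg$spt$plateau_level_frac > 0, cfg$spt$plateau_level_frac < 1,
    cfg$spt$plateau_lag_frac > 0, cfg$spt$plateau_lag_frac <= 1,
    cfg$spt$window >= 3,
    cfg$spt$step >= 1,
    cfg$spt$scale_um_per_px > 0,
    cfg$qpcr$error_mode %in% c("corrected", "paper")
  )
  invisible(cfg)
}

#' Read a run configuration from a YAML or JSON file
#'
#' The file may define any subset of the [run_config()] blocks; missing
#' parameters keep their defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file
#' @return A `RunConfig`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  run_config(
    seed = if (!is.null(raw$seed)) raw$seed else 1L,
    detection = raw$detection %||% list(),
    zonation = raw$zonation %||% list(),
    coloc = raw$coloc %||% list(),
    spt = raw$spt %||% list(),
    qpcr = raw$qpcr %||% list()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run all stochastic code under a local, restored RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}
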