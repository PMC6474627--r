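#' Pipeline configuration with documented defaults
#'
#' Collects every tunable parameter of the pipeline in one flat list.
#' All downstream functions accept a `config` argument and read their
#' parameters from it, so a single serialized file reproduces a run.
#'
#' Parameters (units in brackets; px = pixels, iu = arbitrary intensity
#' units):
#' \describe{
#'   \item{sigma_f \[px\]}{LoG filter scale for single-molecule spots
#'     (default 1.5, matched to a near-diffraction-limited PSF).}
#'   \item{burst_sigma_factor}{Multiplier on `sigma_f` for the coarser
#'     burst-site LoG scale (default 3).}
#'   \item{threshold_grid_n, threshold_pct_lo, threshold_pct_hi}{The
#'     automatic threshold scan grid: `threshold_grid_n` geometrically
#'     spaced points spanning the `threshold_pct_lo`th to
#'     `threshold_pct_hi`th percentile of the positive LoG response
#'     (defaults 100, 50, 100, i.e. up to the response maximum).}
#'   \item{plateau_frac, plateau_width, plateau_smooth}{Plateau rule for
#'     threshold selection: smallest threshold at which the
#'     `plateau_smooth`-point moving average of |dN/dT|, normalized to
#'     its maximum, stays at or below `plateau_frac` for `plateau_width`
#'     consecutive grid points (defaults 0.02, 5, 5).}
#'   \item{fit_window \[px\]}{Side of the square fitting window around
#'     each candidate (default 9, must be odd).}
#'   \item{qc_sigma_lo, qc_sigma_hi}{Width gates as multiples of
#'     `sigma_f` (defaults 0.5 and 2).}
#'   \item{qc_snr_min}{Minimum amplitude in units of the local
#'     background noise SD (default 3).}
#'   \item{qc_residual_max}{Ceiling on residual RMS relative to fitted
#'     amplitude (default 0.5).}
#'   \item{burst_rmin}{Acceptance floor for burst sites: integrated
#'     intensity must be at least `burst_rmin` times the single-copy
#'     reference (default 5).}
#'   \item{min_nucleus_area, min_cell_area \[px\]}{Minimum object areas
#'     (defaults 100 and 400, sized for the simulator geometry).}
#'   \item{r_close, w_med \[px\]}{Closing radius and median-filter width
#'     in mask cleanup (defaults 2 and 3).}
#'   \item{fish_dilate \[px\]}{Dilation radius applied to the FISH
#'     high-expression foreground (default 3).}
#'   \item{pc_nscale, pc_norient, pc_k}{Phase congruency: number of
#'     log-Gabor scales, orientations, and the noise-compensation factor
#'     (defaults 4, 6, 2).}
#'   \item{pc_downsample}{Integer factor by which the bright-field
#'     image is binned before phase congruency (default 2). Cell rims
#'     are tens of pixels across at camera sampling, so halving the
#'     resolution does not move them materially but cuts the FFT cost
#'     about eightfold.}
#'   \item{pc_quantile}{Quantile at which the edge-strength map is
#'     binarized for segmentation (default 0.90).}
#'   \item{exclude_border_cells}{Drop cells touching the image border
#'     from per-cell tables (default TRUE).}
#'   \item{exclude_anomalous_cells}{Drop cells flagged with more than
#'     two burst sites from statistics (default FALSE: retained but
#'     flagged).}
#'   \item{protein_metric}{Which protein summary correlation analyses
#'     use: "integrated" (default) or "mean".}
#'   \item{seed}{Root RNG seed for every stochastic operation
#'     (default 1).}
#' }
#'
#' @param ... Name-value overrides of the defaults.
#' @return A named list of class `smfish_config`.
#' @export
smfish_config <- function(...) {
  defaults <- list(
    sigma_f = 1.5,
    burst_sigma_factor = 3,
    threshold_grid_n = 100L,
    threshold_pct_lo = 50,
    threshold_pct_hi = 100,
    plateau_frac = 0.02,
    plateau_width = 5L,
    plateau_smooth = 5L,
    fit_window = 9L,
    qc_sigma_lo = 0.5,
    qc_sigma_hi = 2,
    qc_snr_min = 3,
    qc_residual_max = 0.5,
    burst_rmin = 5,
    min_nucleus_area = 100L,
    min_cell_area = 400L,
    r_close = 2L,
    w_med = 3L,
    fish_dilate = 3L,
    pc_nscale = 4L,
    pc_norient = 6L,
    pc_k = 2,
    pc_downsample = 2L,
    pc_quantile = 0.90,
    exclude_border_cells = TRUE,
    exclude_anomalous_cells = FALSE,
    protein_metric = "integrated",
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
      stop("unknown config parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    defaults[names(over)] <- over
  }
  structure(defaults, class = c("smfish_config", "list"))
}

#' Serialize / restore a configuration (lossless round-trip)
#' @param config An `smfish_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "smfish_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(smfish_config, vals)
}
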