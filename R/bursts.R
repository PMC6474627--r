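#' Detect transcriptional burst sites in an intron channel
#'
#' Bursting sites are bright nuclear foci where many nascent
#' transcripts co-localize at the active locus; they are an order of
#' magnitude brighter and several times wider than single molecules.
#' The spot-detection pipeline is rerun with coarser parameters: the
#' LoG scale is `burst_sigma_factor * sigma_f` and acceptance requires
#' an integrated intensity of at least `burst_rmin` times the
#' single-copy reference. Sites are assigned to cells and to
#' nucleus/cytoplasm; a cell carrying more than two sites is flagged
#' anomalous (segmentation error or mitosis).
#'
#' @param x An `smfish_scene`.
#' @param intron_channel Channel role, e.g. `"intron:IL1B"`. If the
#'   scene lacks it, an empty result is returned.
#' @param seg An `smfish_segmentation`.
#' @param config An [smfish_config()].
#' @param reference Single-copy reference integrated intensity; by
#'   default computed from isolated QC-passed single-molecule spots in
#'   the same intron channel via [single_copy_reference()], falling
#'   back to `reference_channel`.
#' @param reference_channel Optional fallback channel (typically the
#'   gene's mRNA channel) for the single-copy reference.
#' @return Object of class `smfish_bursts`: list with `sites` (tibble:
#'   position, fit, `integrated`, `estimated_copies`, `cell_id`,
#'   `in_nucleus`, `anomaly_flag`), `per_cell` (tibble `cell_id`,
#'   `bursts`, `burst_copies`), `reference` and `reference_channel`.
#' @export
detect_bursts <- function(x, intron_channel, seg,
                          config = smfish_config(), reference = NULL,
                          reference_channel = NULL) {
  stopifnot(inherits(x, "smfish_scene"),
            inherits(seg, "smfish_segmentation"))
  if (is.null(scene_channel(x, intron_channel)))
    return(new_bursts(empty_burst_tibble(), seg, NA_real_, NA_character_))

  sigma_b <- config$burst_sigma_factor * config$sigma_f
  win <- as.integer(2 * ceiling(3 * sigma_b) + 1)
  cfg_b <- config
  cfg_b$fit_window <- max(cfg_b$fit_window, win)
  # burst widths legitimately range from single-spot to several sigma
  cfg_b$qc_sigma_lo <- config$qc_sigma_lo / config$burst_sigma_factor
  res <- count_spots(x, intron_channel, seg, config = cfg_b,
                     sigma_f = sigma_b)

  ref_channel_used <- intron_channel
  if (is.null(reference)) {
    ref <- tryCatch(
      single_copy_reference(fit_single_molecules(x, intron_channel, seg,
                                                 config)),
      error = function(e) NULL)
    if (is.null(ref) && !is.null(reference_channel)) {
      ref <- single_copy_reference(
        fit_single_molecules(x, reference_channel, seg, config))
      ref_channel_used <- reference_channel
    }
    if (is.null(ref))
      stop("too few isolated single-molecule spots for a single-copy ",
           "reference; supply `reference` or `reference_channel`",
           call. = FALSE)
    reference <- ref
  }

  sites <- res$spots[res$spots$passed_qc, , drop = FALSE]
  sites$estimated_copies <- estimate_copies(sites, reference)
  sites <- sites[sites$integrated >= config$burst_rmin * reference, ,
                 drop = FALSE]
  per_cell_n <- table(factor(sites$cell_id[sites$cell_id > 0L],
                             levels = seg$cells$cell_id))
  sites$anomaly_flag <- sites$cell_id > 0L &
    as.integer(per_cell_n[as.character(sites$cell_id)]) > 2L
  sites$anomaly_flag[is.na(sites$anomaly_flag)] <- FALSE
  new_bursts(sites, seg, reference, ref_channel_used)
}

new_bursts <- function(sites, seg, reference, reference_channel) {
  per_cell <- bursts_per_cell(sites, seg)
  structure(list(sites = sites, per_cell = per_cell,
                 reference = reference,
                 reference_channel = reference_channel),
            class = "smfish_bursts")
}

empty_burst_tibble <- function() {
  out <- empty_spot_tibble()
  out$channel <- character(0)
  out$cell_id <- integer(0)
  out$in_nucleus <- logical(0)
  out$estimated_copies <- numeric(0)
  out$anomaly_flag <- logical(0)
  out
}

#' @export
print.smfish_bursts <- function(x, ...) {
  cat("<smfish_bursts> ", nrow(x$sites), " site(s), reference ",
      signif(x$reference, 4), " (", x$reference_channel, ")\n", sep = "")
  invisible(x)
}

#' Single-copy reference intensity from isolated molecules
#'
#' The median integrated intensity of QC-passed isolated
#' single-molecule fits. The median is robust to the occasional
#' unresolved doublet or focus in the reference set.
#'
#' @param spots Tibble of QC-passed spot fits with an `integrated`
#'   column (already restricted to isolated single molecules).
#' @param min_spots Minimum reference spots required (default 20).
#' @return Scalar reference integrated intensity.
#' @export
single_copy_reference <- function(spots, min_spots = 20L) {
  ok <- spots[spots$passed_qc, , drop = FALSE]
  if (nrow(ok) < min_spots)
    stop("only ", nrow(ok), " isolated reference spots (need >= ",
         min_spots, "); use the mRNA channel as fallback reference",
         call. = FALSE)
  median(ok$integrated)
}

# Fit single molecules in a channel at the single-molecule scale and
# keep isolated ones (no neighbour within 4*sigma_f).
fit_single_molecules <- function(x, channel, seg, config) {
  res <- count_spots(x, channel, seg, config = config)
  sp <- res$spots[res$spots$passed_qc, , drop = FALSE]
  if (nrow(sp) < 2L) return(sp)
  d <- as.matrix(stats::dist(cbind(sp$x0, sp$y0)))
  diag(d) <- Inf
  sp[apply(d, 1, min) > 4 * config$sigma_f, , drop = FALSE]
}

#' Transcript copies in a focus from its intensity ratio
#'
#' The dimensionless ratio of a site's integrated fluorescence
#' intensity to the single-copy reference estimates how many
#' transcripts the focus contains.
#'
#' @param site Tibble (or list) with an `integrated` field.
#' @param reference Positive single-copy reference intensity.
#' @return Numeric vector of estimated copies.
#' @export
estimate_copies <- function(site, reference) {
  if (!is.numeric(reference) || length(reference) != 1L ||
      !is.finite(reference) || reference <= 0)
    stop("reference must be a positive scalar", call. = FALSE)
  site$integrated / reference
}

#' Per-cell burst-site counts
#'
#' Integer site counts (and summed estimated copies) for every
#' segmented cell, including zeros for site-free cells.
#'
#' @param sites Tibble of burst sites with `cell_id` and
#'   `estimated_copies`.
#' @param seg An `smfish_segmentation`.
#' @return Tibble: `cell_id`, `bursts`, `burst_copies`.
#' @export
bursts_per_cell <- function(sites, seg) {
  stopifnot(inherits(seg, "smfish_segmentation"))
  base <- tibble(cell_id = seg$cells$cell_id)
  if (!nrow(sites))
    return(dplyr::mutate(base, bursts = 0L, burst_copies = 0))
  base |>
    dplyr::left_join(
      sites |>
        dplyr::filter(.data$cell_id > 0L) |>
        dplyr::group_by(.data$cell_id) |>
        dplyr::summarise(bursts = dplyr::n(),
                         burst_copies = sum(.data$estimated_copies),
                         .groups = "drop"),
      by = "cell_id") |>
    dplyr::mutate(bursts = as.integer(tidyr::replace_na(.data$bursts, 0L)),
                  burst_copies = tidyr::replace_na(.data$burst_copies, 0))
}
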