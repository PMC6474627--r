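#' Assign fitted spots to segmented cells
#'
#' Each spot takes the cell label at its rounded (row, col) center
#' (0 = background/unassigned) and an `in_nucleus` flag from the
#' nucleus mask at the same pixel. Assignment is by center pixel, not
#' overlap area: spots are sub-pixel point emitters.
#'
#' @param spots Tibble with `x0` (row) and `y0` (col) columns.
#' @param seg An `smfish_segmentation`.
#' @return `spots` with `cell_id` and `in_nucleus` columns.
#' @export
assign_spots <- function(spots, seg) {
  stopifnot(inherits(seg, "smfish_segmentation"))
  n <- nrow(spots)
  if (!n) {
    spots$cell_id <- integer(0)
    spots$in_nucleus <- logical(0)
    return(spots)
  }
  r <- round(spots$x0); c <- round(spots$y0)
  ok <- !is.na(r) & !is.na(c)
  if (any(ok & (r < 1 | r > nrow(seg$cell_labels) |
                c < 1 | c > ncol(seg$cell_labels))))
    stop("spot center outside image bounds", call. = FALSE)
  cell_id <- rep(0L, n); in_nuc <- rep(FALSE, n)
  idx <- (c[ok] - 1L) * nrow(seg$cell_labels) + r[ok]
  cell_id[ok] <- seg$cell_labels[idx]
  in_nuc[ok] <- seg$nucleus_labels[idx] > 0L
  spots$cell_id <- cell_id
  spots$in_nucleus <- in_nuc
  spots
}

#' Per-cell protein signal from an antibody channel
#'
#' Background is the median intensity over non-cell pixels; each
#' cell's signal is the mean of (intensity - background, floored at 0)
#' over its pixels, reported both as that mean and as mean times cell
#' area (integrated).
#'
#' @param x An `smfish_scene`.
#' @param protein_channel Channel role, e.g. `"protein:IL1B"`.
#' @param seg An `smfish_segmentation`.
#' @return Tibble: `cell_id`, `protein_mean`, `protein_integrated`.
#' @export
protein_per_cell <- function(x, protein_channel, seg) {
  stopifnot(inherits(x, "smfish_scene"),
            inherits(seg, "smfish_segmentation"))
  img <- scene_channel(x, protein_channel)
  if (is.null(img)) stop("scene has no channel '", protein_channel,
                         "'", call. = FALSE)
  img <- max_project(img)
  if (seg$n_cells == 0L) stop("segmentation is empty", call. = FALSE)
  bg <- median(img[seg$cell_labels == 0L])
  net <- pmax(img - bg, 0)
  ids <- seg$cells$cell_id
  means <- vapply(ids, function(i) mean(net[seg$cell_labels == i]),
                  numeric(1))
  tibble(cell_id = ids, protein_mean = means,
         protein_integrated = means * seg$cells$area_px)
}

#' Assemble the per-cell record table for one scene
#'
#' Joins segmentation geometry with per-channel spot counts, burst
#' sites and protein signal into one row per cell, in the fixed
#' cell-table schema (see [write_cell_table()]). Channels that were
#' not measured get NA fields (absent, never zero). Border cells are
#' excluded by default (`exclude_border_cells`).
#'
#' @param seg An `smfish_segmentation`.
#' @param spots_by_channel Named list of `smfish_spots` (or their
#'   `per_cell` tibbles), keyed by gene name.
#' @param bursts_by_channel Named list of `smfish_bursts` keyed by gene.
#' @param protein_by_channel Named list of [protein_per_cell()] tibbles
#'   keyed by gene.
#' @param condition,time_minutes,scan_id Experimental coordinates
#'   recorded in every row.
#' @param config An [smfish_config()].
#' @return A validated cell-table tibble.
#' @export
build_cell_table <- function(seg, spots_by_channel = list(),
                             bursts_by_channel = list(),
                             protein_by_channel = list(),
                             condition = "none", time_minutes = 0,
                             scan_id = "s1",
                             config = smfish_config()) {
  stopifnot(inherits(seg, "smfish_segmentation"))
  tab <- seg$cells |>
    dplyr::mutate(source_id = seg$source_id, condition = condition,
                  time_minutes = time_minutes, scan_id = scan_id,
                  anomaly_flag = FALSE, .before = 1)

  for (gene in names(spots_by_channel)) {
    pc <- spots_by_channel[[gene]]
    if (inherits(pc, "smfish_spots")) pc <- pc$per_cell
    check_cell_ids(pc$cell_id, seg)
    pc <- setNames(pc, c("cell_id", paste0(c("count_", "nuclear_",
                                             "cyto_"), gene)))
    tab <- dplyr::left_join(tab, pc, by = "cell_id")
  }
  for (gene in names(bursts_by_channel)) {
    bs <- bursts_by_channel[[gene]]
    if (inherits(bs, "smfish_bursts")) bs <- bs$per_cell
    check_cell_ids(bs$cell_id, seg)
    bs <- setNames(bs, c("cell_id", paste0(c("bursts_", "burst_copies_"),
                                           gene)))
    tab <- dplyr::left_join(tab, bs, by = "cell_id")
    tab$anomaly_flag <- tab$anomaly_flag |
      tidyr::replace_na(tab[[paste0("bursts_", gene)]] > 2L, FALSE)
  }
  for (gene in names(protein_by_channel)) {
    pr <- protein_by_channel[[gene]]
    check_cell_ids(pr$cell_id, seg)
    pr <- setNames(pr, c("cell_id", paste0(c("protein_mean_",
                                             "protein_integrated_"),
                                           gene)))
    tab <- dplyr::left_join(tab, pr, by = "cell_id")
  }

  if (isTRUE(config$exclude_border_cells))
    tab <- dplyr::filter(tab, !.data$border_flag)
  validate_cell_table(tab)
}

check_cell_ids <- function(ids, seg) {
  bad <- setdiff(ids, c(0L, seg$cells$cell_id))
  if (length(bad))
    stop("cell id(s) ", paste(bad, collapse = ", "),
         " not present in the segmentation", call. = FALSE)
  invisible(TRUE)
}
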