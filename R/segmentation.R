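#' Detect and label nuclei in a DAPI image
#'
#' Conventional edge-based nucleus detection: Sobel gradient magnitude,
#' Otsu threshold on the gradient, morphological closing to seal the
#' edge rings, hole filling, small-object removal, then a
#' distance-transform watershed to split touching nuclei.
#'
#' @param dapi_image 2-D non-negative numeric matrix.
#' @param config An [smfish_config()]; uses `min_nucleus_area` and
#'   `r_close`.
#' @return Integer label matrix (0 = background), labels consecutive.
#' @export
detect_nuclei <- function(dapi_image, config = smfish_config()) {
  assert_image(dapi_image, "dapi_image")
  if (diff(range(dapi_image)) == 0)
    return(matrix(0L, nrow(dapi_image), ncol(dapi_image)))

  gm <- sobel_magnitude(dapi_image)
  edges <- gm > otsu_threshold(gm)
  mask <- fill_holes(close_disc(edges, config$r_close))
  mask <- drop_small(mask, config$min_nucleus_area)
  if (!any(mask))
    return(matrix(0L, nrow(dapi_image), ncol(dapi_image)))

  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- matrix(as.integer(ws), nrow(mask), ncol(mask))
  # watershed can carve sub-minimum fragments; re-apply the area gate
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < config$min_nucleus_area)
  if (length(small)) lab[lab %in% small] <- 0L
  relabel_consecutive(lab)
}

sobel_magnitude <- function(image) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  ky <- t(kx)
  gx <- as.matrix(EBImage::filter2(EBImage::Image(image), kx))
  gy <- as.matrix(EBImage::filter2(EBImage::Image(image), ky))
  sqrt(gx^2 + gy^2)
}

#' High-expression FISH foreground mask
#'
#' LoG-filters the smFISH channel at the single-molecule scale,
#' thresholds the response with the automatic spots-versus-threshold
#' scan (shared with spot detection), and dilates the supra-threshold
#' pixels so that clusters of expressing pixels form contiguous
#' regions. Regions of high gene expression are thereby guaranteed to
#' fall inside the segmented cell boundaries.
#'
#' @param fish_image 2-D numeric matrix.
#' @param config An [smfish_config()]; uses `sigma_f`, the threshold
#'   scan parameters and `fish_dilate`.
#' @return Logical matrix.
#' @export
fish_foreground <- function(fish_image, config = smfish_config()) {
  assert_image(fish_image, "fish_image")
  resp <- log_filter(fish_image, config$sigma_f)
  if (!any(resp > 0))
    return(matrix(FALSE, nrow(fish_image), ncol(fish_image)))
  scan <- suppressWarnings(threshold_scan(resp, config = config))
  # no plateau means no spot population stands out from the noise:
  # there are no high-expression regions to protect
  if (scan$fallback)
    return(matrix(FALSE, nrow(fish_image), ncol(fish_image)))
  mask <- resp > scan$selected
  if (!any(mask)) return(mask)
  if (config$fish_dilate > 0) {
    mask <- matrix(
      as.numeric(EBImage::dilate(EBImage::Image(mask * 1),
                                 disc_kernel(config$fish_dilate))) > 0.5,
      nrow(mask), ncol(mask))
  }
  mask
}

#' Fuse the three per-channel binaries into one cell foreground
#'
#' The three binary images are added and any pixel with sum >= 1 is
#' foreground, i.e. the pixelwise union.
#'
#' @param dapi_bin,bf_bin,fish_bin Logical (or 0/1) matrices of equal
#'   shape.
#' @return Logical matrix.
#' @export
combine_binaries <- function(dapi_bin, bf_bin, fish_bin) {
  if (!identical(dim(dapi_bin), dim(bf_bin)) ||
      !identical(dim(dapi_bin), dim(fish_bin)))
    stop("binary images must share the same shape", call. = FALSE)
  (dapi_bin + bf_bin + fish_bin) >= 1
}

#' Morphological cleanup of the fused foreground
#'
#' Closing (dilate-then-erode, disc radius `r_close`), median filter of
#' width `w_med`, hole filling, and removal of connected components
#' below `min_cell_area`.
#'
#' @param binary Logical matrix.
#' @param config An [smfish_config()].
#' @return Logical matrix.
#' @export
morphological_cleanup <- function(binary, config = smfish_config()) {
  out <- close_disc(binary, config$r_close)
  if (config$w_med > 1) {
    # median of a binary image = majority vote over the window
    w <- config$w_med
    box <- as.matrix(EBImage::filter2(EBImage::Image(out * 1),
                                      matrix(1, w, w)))
    out <- box > w^2 / 2
  }
  out <- fill_holes(out)
  drop_small(out, config$min_cell_area)
}

#' Partition the foreground into cells seeded at nuclei
#'
#' Grows each nucleus to the foreground boundary: every foreground
#' pixel is assigned to the nucleus nearest in Euclidean distance
#' (watershed on the inverted distance-from-nucleus transform), so the
#' boundary between two nuclei sharing a blob is their equidistance
#' line; equidistant pixels resolve deterministically to one side
#' within one pixel of that line. Foreground components
#' containing no nucleus are dropped; a nucleus falling outside the
#' foreground becomes its own cell (with a warning).
#'
#' @param foreground Logical matrix.
#' @param nucleus_labels Integer label matrix from [detect_nuclei()].
#' @return Integer cell label matrix; cell label i contains nucleus i.
#' @export
watershed_cells <- function(foreground, nucleus_labels) {
  if (!identical(dim(foreground), dim(nucleus_labels)))
    stop("foreground and nucleus_labels must share shape", call. = FALSE)
  nr <- nrow(foreground); nc <- ncol(foreground)
  labs <- sort(unique(nucleus_labels[nucleus_labels > 0]))
  if (!length(labs)) return(matrix(0L, nr, nc))

  outside <- vapply(labs, function(k)
    any(nucleus_labels == k & !foreground), logical(1))
  if (any(outside)) {
    warning("nucleus label(s) ", paste(labs[outside], collapse = ", "),
            " extend outside the foreground; using the nucleus itself",
            call. = FALSE)
    foreground <- foreground | nucleus_labels > 0
  }

  # keep only foreground components containing at least one nucleus
  comp <- EBImage::bwlabel(foreground * 1)
  with_nuc <- unique(comp[nucleus_labels > 0])
  with_nuc <- with_nuc[with_nuc > 0]
  keep <- matrix(comp %in% with_nuc, nr, nc)

  # seeded region growing by geodesic distance from the nuclei; with a
  # constant intensity image this is the distance-from-nucleus
  # watershed (equidistant pixels land on either side within one px)
  ws <- EBImage::propagate(EBImage::Image(matrix(0, nr, nc)),
                           seeds = EBImage::Image(nucleus_labels),
                           mask = EBImage::Image(keep * 1),
                           lambda = 1e8)
  matrix(as.integer(ws), nr, nc)
}

#' Segment a scene into labeled single cells
#'
#' The full three-channel segmentation: nuclei from DAPI (edge
#' detection + watershed), cell rims from bright-field phase
#' congruency, high-expression regions from the smFISH channel, fused
#' by union, cleaned morphologically, and partitioned by
#' nucleus-seeded watershed. Missing bright-field or FISH channels
#' contribute empty binaries (nuclei alone then define the cells).
#'
#' @param x An `smfish_scene` with at least a `dapi` channel.
#' @param fish_role Channel role used for the expression foreground
#'   (default: first `fish:` channel present).
#' @param config An [smfish_config()].
#' @return An object of class `smfish_segmentation`: list with
#'   `nucleus_labels`, `cell_labels`, `n_cells`, a `cells` tibble
#'   (cell_id, area_px, nucleus_area_px, border_flag), and the `params`
#'   echoed from `config`.
#' @export
segment <- function(x, fish_role = NULL, config = smfish_config()) {
  stopifnot(inherits(x, "smfish_scene"))
  x <- project_scene(x)
  dapi <- scene_channel(x, "dapi")
  if (is.null(dapi)) stop("scene has no dapi channel", call. = FALSE)

  nuc <- detect_nuclei(dapi, config)
  if (!any(nuc > 0)) {
    warning("no nuclei found; returning empty segmentation",
            call. = FALSE)
    return(new_segmentation(nuc, nuc, config, x$source_id))
  }

  dapi_bin <- nuc > 0

  bf <- scene_channel(x, "brightfield")
  bf_bin <- if (is.null(bf)) {
    matrix(FALSE, nrow(dapi), ncol(dapi))
  } else {
    ds <- max(1L, as.integer(config$pc_downsample))
    bf_small <- if (ds > 1L)
      as.matrix(EBImage::resize(EBImage::Image(bf), nrow(bf) %/% ds,
                                ncol(bf) %/% ds)) else bf
    pc <- phase_congruency_edges(bf_small, nscale = config$pc_nscale,
                                 norient = config$pc_norient,
                                 k = config$pc_k)
    if (ds > 1L)
      pc <- as.matrix(EBImage::resize(EBImage::Image(pc), nrow(bf),
                                      ncol(bf)))
    edge_bin <- pc >= quantile(pc[pc > 0], config$pc_quantile)
    close_disc(edge_bin, config$r_close)
  }

  if (is.null(fish_role)) {
    fr <- grep("^fish:", names(x$channels), value = TRUE)
    fish_role <- if (length(fr)) fr[1] else NULL
  }
  fish_bin <- if (is.null(fish_role) ||
                  is.null(scene_channel(x, fish_role))) {
    matrix(FALSE, nrow(dapi), ncol(dapi))
  } else {
    fish_foreground(scene_channel(x, fish_role), config)
  }

  fg <- combine_binaries(dapi_bin, bf_bin, fish_bin)
  fg <- morphological_cleanup(fg, config)
  fg <- fg | dapi_bin  # nuclei are always part of their cells
  cells <- watershed_cells(fg, nuc)
  # drop nuclei whose cells vanished in cleanup (none in practice)
  nuc[!(nuc %in% unique(cells[cells > 0]))] <- 0L

  # relabel both maps consecutively and in step
  old <- sort(unique(cells[cells > 0]))
  map <- integer(if (length(old)) max(old) else 0)
  map[old] <- seq_along(old)
  cells[cells > 0] <- map[cells[cells > 0]]
  nuc[nuc > 0] <- map[nuc[nuc > 0]]

  new_segmentation(nuc, cells, config, x$source_id)
}

new_segmentation <- function(nucleus_labels, cell_labels, config,
                             source_id = "scene") {
  nr <- nrow(cell_labels); nc <- ncol(cell_labels)
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  border <- unique(c(cell_labels[1, ], cell_labels[nr, ],
                     cell_labels[, 1], cell_labels[, nc]))
  cells <- tibble(
    cell_id = ids,
    area_px = as.integer(tabulate(cell_labels[cell_labels > 0],
                                  nbins = max(ids, 0L))[ids]),
    nucleus_area_px = as.integer(tabulate(
      nucleus_labels[nucleus_labels > 0], nbins = max(ids, 0L))[ids]),
    border_flag = ids %in% border)
  structure(
    list(nucleus_labels = nucleus_labels, cell_labels = cell_labels,
         n_cells = length(ids), cells = cells,
         params = unclass(config), source_id = source_id),
    class = "smfish_segmentation")
}

#' @export
print.smfish_segmentation <- function(x, ...) {
  cat("<smfish_segmentation> ", x$source_id, ": ", x$n_cells,
      " cell(s), ", sum(x$cells$border_flag), " on border\n", sep = "")
  invisible(x)
}

# Structural invariants of a segmentation: one nucleus per cell,
# nucleus inside cell, disjoint cells. Called from tests and segment().
check_segmentation_invariants <- function(seg) {
  cl <- seg$cell_labels; nl <- seg$nucleus_labels
  ids <- sort(unique(cl[cl > 0]))
  if (length(ids) && !identical(ids, seq_along(ids)))
    stop("cell labels are not consecutive")
  if (seg$n_cells != length(ids)) stop("n_cells mismatch")
  for (i in ids) {
    inside <- unique(nl[cl == i])
    inside <- inside[inside > 0]
    if (!identical(inside, i))
      stop("cell ", i, " does not contain exactly nucleus ", i)
    if (any(cl[nl == i] != i))
      stop("nucleus ", i, " leaks outside cell ", i)
  }
  invisible(TRUE)
}
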