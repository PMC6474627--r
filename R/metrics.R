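#' Match detected spots against planted ground truth
#'
#' Greedy nearest-neighbour matching: among all (detected, truth)
#' pairs within `radius` pixels, the closest pair is matched first,
#' both members removed, and so on. Reports recall (matched / planted)
#' and precision (matched / detected). Candidate pairs are found by
#' spatial binning, so matching is near-linear in the number of spots.
#'
#' @param detected Tibble with `x0` (row) and `y0` (col) columns.
#' @param truth Tibble with `row` and `col` columns.
#' @param radius Match radius in pixels (default 2).
#' @return List: `n_matched`, `n_detected`, `n_truth`, `recall`,
#'   `precision`.
#' @export
match_spots <- function(detected, truth, radius = 2) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (!nd || !nt)
    return(list(n_matched = 0L, n_detected = nd, n_truth = nt,
                recall = if (nt) 0 else NA_real_,
                precision = if (nd) 0 else NA_real_))
  # bin truth spots on a grid of cell size `radius`
  bw <- max(radius, 1e-6)
  key <- function(r, c) paste(floor(r / bw), floor(c / bw))
  tkey <- split(seq_len(nt), key(truth$row, truth$col))
  pairs_i <- integer(0); pairs_j <- integer(0); pairs_d <- numeric(0)
  br <- floor(detected$x0 / bw); bc <- floor(detected$y0 / bw)
  for (i in seq_len(nd)) {
    cand <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      k <- paste(br[i] + dr, bc[i] + dc)
      cand <- c(cand, tkey[[k]])
    }
    if (!length(cand)) next
    d <- sqrt((detected$x0[i] - truth$row[cand])^2 +
                (detected$y0[i] - truth$col[cand])^2)
    ok <- d <= radius
    pairs_i <- c(pairs_i, rep(i, sum(ok)))
    pairs_j <- c(pairs_j, cand[ok])
    pairs_d <- c(pairs_d, d[ok])
  }
  used_i <- logical(nd); used_j <- logical(nt); n_match <- 0L
  for (p in order(pairs_d)) {
    i <- pairs_i[p]; j <- pairs_j[p]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    n_match <- n_match + 1L
  }
  list(n_matched = n_match, n_detected = nd, n_truth = nt,
       recall = n_match / nt, precision = n_match / nd)
}

#' Per-cell overlap between a segmentation and ground-truth masks
#'
#' Matches segmented cells to planted cells greedily by descending
#' intersection-over-union and reports one row per planted cell.
#'
#' @param seg An `smfish_segmentation`.
#' @param truth_labels Ground-truth cell label matrix.
#' @return Tibble: `truth_cell`, `seg_cell` (NA if unmatched), `iou`.
#' @export
segmentation_iou <- function(seg, truth_labels) {
  stopifnot(inherits(seg, "smfish_segmentation"))
  sl <- seg$cell_labels
  if (!identical(dim(sl), dim(truth_labels)))
    stop("segmentation and truth masks differ in shape", call. = FALSE)
  t_ids <- sort(unique(truth_labels[truth_labels > 0]))
  s_ids <- sort(unique(sl[sl > 0]))
  if (!length(t_ids) || !length(s_ids))
    return(tibble(truth_cell = t_ids, seg_cell = NA_integer_,
                  iou = rep(0, length(t_ids))))
  mask <- truth_labels > 0 | sl > 0
  tab <- table(factor(truth_labels[mask], levels = c(0L, t_ids)),
               factor(sl[mask], levels = c(0L, s_ids)))
  t_area <- rowSums(tab); s_area <- colSums(tab)
  inter <- tab[-1, -1, drop = FALSE]
  iou <- inter / (outer(t_area[-1], s_area[-1], `+`) - inter)
  out <- tibble(truth_cell = t_ids, seg_cell = NA_integer_, iou = 0)
  repeat {
    m <- which.max(iou)
    if (!length(m) || iou[m] <= 0) break
    ti <- (m - 1) %% nrow(iou) + 1; si <- (m - 1) %/% nrow(iou) + 1
    out$seg_cell[ti] <- s_ids[si]
    out$iou[ti] <- iou[m]
    iou[ti, ] <- -1; iou[, si] <- -1
  }
  out
}
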