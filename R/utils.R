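# Internal helpers shared across modules. Images are base-R numeric
# matrices indexed [row, col], 1-based, pixel centers at integers.

assert_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(name, " must be a 2-D numeric matrix", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(name, " contains non-finite values", call. = FALSE)
  invisible(x)
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 3x3 grey dilation (maximum over the 8-neighbourhood and centre).
dilate8 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- pmax(out, shift_mat(m, dr, dc))
  }
  out
}

# 8-connected local maxima strictly above `threshold`; equal-valued
# plateaus are reduced to the lexicographically smallest (row, col)
# pixel of each connected plateau component.
local_maxima <- function(m, threshold = -Inf) {
  cand <- (m >= dilate8(m)) & (m > threshold)
  if (!any(cand)) return(matrix(integer(0), 0, 2,
                                dimnames = list(NULL, c("row", "col"))))
  lab <- EBImage::bwlabel(cand)
  idx <- which(cand)
  rows <- ((idx - 1L) %% nrow(m)) + 1L
  cols <- ((idx - 1L) %/% nrow(m)) + 1L
  labs <- lab[idx]
  ord <- order(labs, rows, cols)
  keep <- !duplicated(labs[ord])
  cbind(row = rows[ord][keep], col = cols[ord][keep])
}

# Otsu threshold on an arbitrary-range image (EBImage::otsu expects [0,1]).
otsu_threshold <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (m - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  th * diff(rng) + rng[1]
}

# Binary disc structuring element of radius r (EBImage brush).
disc_kernel <- function(r) {
  EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
}

# Morphological closing with a disc of radius r.
close_disc <- function(binary, r) {
  if (r <= 0) return(binary)
  k <- disc_kernel(r)
  out <- EBImage::erode(EBImage::dilate(EBImage::Image(binary * 1), k), k)
  matrix(as.numeric(out) > 0.5, nrow(binary), ncol(binary))
}

# Fill holes in a binary mask.
fill_holes <- function(binary) {
  out <- EBImage::fillHull(EBImage::Image(binary * 1))
  matrix(as.numeric(out) > 0.5, nrow(binary), ncol(binary))
}

# Remove connected components smaller than min_area pixels.
drop_small <- function(binary, min_area) {
  if (!any(binary)) return(binary)
  lab <- EBImage::bwlabel(binary * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(binary), ncol(binary))
}

# Relabel a label image so nonzero labels are consecutive 1..n,
# preserving order of first appearance by original label value.
relabel_consecutive <- function(lab) {
  vals <- sort(unique(lab[lab > 0]))
  if (!length(vals)) return(lab)
  map <- integer(max(vals))
  map[vals] <- seq_along(vals)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

# Centroids of a label image as a tibble (label, row, col, area).
label_centroids <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx))
    return(tibble(label = integer(0), row = numeric(0),
                  col = numeric(0), area = integer(0)))
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  labs <- lab[idx]
  tibble(label = labs, row = rows, col = cols) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(row = mean(.data$row), col = mean(.data$col),
                     area = dplyr::n(), .groups = "drop")
}

# Moving average of width w (odd), edges handled by shrinking window.
moving_average <- function(x, w) {
  n <- length(x)
  if (n == 0 || w <= 1) return(x)
  half <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
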