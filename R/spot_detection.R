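#' Scale-normalized Laplacian-of-Gaussian filter
#'
#' Convolves the image with the negated, scale-normalized LoG kernel
#' `-sigma_f^2 * laplacian(G_sigma_f)`, so near-diffraction-limited
#' bright spots of radius about `sigma_f * sqrt(2)` become positive
#' local maxima whose height is comparable across scales. The kernel is
#' zero-sum, so a constant image maps to zero response.
#'
#' @param image 2-D numeric matrix.
#' @param sigma_f Filter scale in pixels (> 0).
#' @return Filtered matrix, same size.
#' @export
log_filter <- function(image, sigma_f) {
  assert_image(image)
  if (!is.numeric(sigma_f) || sigma_f <= 0)
    stop("sigma_f must be positive", call. = FALSE)
  half <- max(2L, ceiling(4 * sigma_f))
  half <- min(half, (min(dim(image)) - 1L) %/% 2L)
  xs <- -half:half
  r2 <- outer(xs^2, xs^2, `+`)
  g <- exp(-r2 / (2 * sigma_f^2)) / (2 * pi * sigma_f^2)
  k <- (2 - r2 / sigma_f^2) * g  # = -sigma^2 * laplacian(G)
  k <- k - mean(k)               # enforce zero DC response
  as.matrix(EBImage::filter2(EBImage::Image(image), k))
}

#' Automatic detection threshold from the spots-versus-threshold curve
#'
#' Counts LoG local maxima above each threshold of an ascending grid
#' and selects the threshold at which the spot count has stopped
#' changing quickly: the smoothed |dN/dT|, normalized to its maximum,
#' must stay at or below `plateau_frac` for `plateau_width`
#' consecutive grid intervals, and the threshold at the end of that
#' first sustained-flat run is selected (so the residual noise tail
#' inside the run is cleared). If no such plateau exists the grid
#' midpoint is returned with a warning.
#'
#' @param filtered LoG-filtered image from [log_filter()].
#' @param grid Ascending numeric threshold grid; default
#'   `threshold_grid_n` geometrically spaced points spanning the
#'   `threshold_pct_lo` to `threshold_pct_hi` percentiles of the
#'   positive response. Geometric spacing gives the bright real-spot
#'   regime, which spans decades above the noise floor, as many grid
#'   points as the noise regime, so the plateau is resolvable at any
#'   image size.
#' @param config An [smfish_config()].
#' @return An object of class `smfish_threshold_scan`: list with
#'   `curve` (tibble: threshold, n_spots), `derivative` (per grid
#'   interval), `selected`, `fallback` flag and the rule parameters.
#' @export
threshold_scan <- function(filtered, grid = NULL,
                           config = smfish_config()) {
  assert_image(filtered, "filtered")
  if (is.null(grid)) {
    pos <- filtered[filtered > 0]
    if (!length(pos)) pos <- 1e-12
    ends <- quantile(pos, c(config$threshold_pct_lo,
                            config$threshold_pct_hi) / 100,
                     names = FALSE)
    ends <- pmax(ends, 1e-12)
    grid <- unique(exp(seq(log(ends[1]), log(ends[2]),
                           length.out = config$threshold_grid_n)))
  }
  if (is.unsorted(grid)) stop("grid must be ascending", call. = FALSE)

  peaks <- local_maxima(filtered, threshold = min(grid))
  vals <- filtered[peaks]
  n_spots <- vapply(grid, function(t) sum(vals > t), integer(1))

  if (length(grid) == 1L) {
    return(new_threshold_scan(grid, n_spots, numeric(0), grid, FALSE,
                              config))
  }

  deriv <- abs(diff(n_spots) / diff(grid))
  sm <- moving_average(deriv, config$plateau_smooth)
  selected <- NA_real_; fallback <- FALSE
  if (max(sm) == 0) {
    selected <- grid[1]  # count never changes: already flat
  } else {
    norm <- sm / max(sm)
    w <- min(config$plateau_width, length(norm))
    ok <- norm <= config$plateau_frac
    runs <- which(vapply(seq_len(length(ok) - w + 1L),
                         function(i) all(ok[i:(i + w - 1L)]), logical(1)))
    if (length(runs)) {
      selected <- grid[min(runs[1] + w, length(grid))]
    } else {
      selected <- grid[ceiling(length(grid) / 2)]
      fallback <- TRUE
      warning("no plateau in the spots-vs-threshold curve; ",
              "falling back to the grid midpoint", call. = FALSE)
    }
  }
  new_threshold_scan(grid, n_spots, deriv, selected, fallback, config)
}

new_threshold_scan <- function(grid, n_spots, deriv, selected, fallback,
                               config) {
  structure(
    list(curve = tibble(threshold = grid, n_spots = n_spots),
         derivative = deriv, selected = selected, fallback = fallback,
         rule = list(plateau_frac = config$plateau_frac,
                     plateau_width = config$plateau_width,
                     plateau_smooth = config$plateau_smooth)),
    class = "smfish_threshold_scan")
}

#' @export
print.smfish_threshold_scan <- function(x, ...) {
  cat("<smfish_threshold_scan> ", nrow(x$curve), " thresholds, selected ",
      signif(x$selected, 4),
      if (x$fallback) " (fallback: no plateau)" else "",
      ", n_spots at selection ",
      x$curve$n_spots[which.min(abs(x$curve$threshold - x$selected))],
      "\n", sep = "")
  invisible(x)
}

#' Candidate spot positions above a threshold
#'
#' 8-connected local maxima of the filtered image with response
#' strictly above `threshold`; equal-valued plateaus are reduced to the
#' lexicographically smallest (row, col) pixel.
#'
#' @param filtered LoG-filtered image.
#' @param threshold Non-negative scalar.
#' @return Tibble with integer `row`, `col` and `response`.
#' @export
detect_candidates <- function(filtered, threshold) {
  assert_image(filtered, "filtered")
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  pk <- local_maxima(filtered, threshold = threshold)
  tibble(row = as.integer(pk[, "row"]), col = as.integer(pk[, "col"]),
         response = filtered[pk])
}

#' Sub-pixel 2-D Gaussian fit of one spot
#'
#' Levenberg-Marquardt least squares of the isotropic model
#' `I(r, c) = b + A * exp(-((r - x0)^2 + (c - y0)^2) / (2 sigma^2))`
#' on a square window around the candidate. Initialization from
#' moments: background from the window-border median, amplitude from
#' the peak above background, width from `sigma_init`. Coordinates are
#' 1-based continuous: `x0` along rows, `y0` along columns.
#'
#' @param image 2-D numeric matrix.
#' @param center Integer `c(row, col)` candidate position (inside the
#'   image).
#' @param window Odd window side in pixels (default 9); clipped at the
#'   image border.
#' @param sigma_init Initial width in pixels (default 1.5).
#' @return One-row tibble: `x0`, `y0`, `A`, `sigma`, `b`,
#'   `integrated` (= 2 pi A sigma^2), `residual_rms`, `noise_sd`
#'   (robust SD of fit residuals), `converged`.
#' @export
fit_gaussian2d <- function(image, center, window = 9L,
                           sigma_init = 1.5) {
  assert_image(image)
  p <- fit_gaussian2d_core(image, round(center[1]), round(center[2]),
                           as.integer(window), sigma_init)
  tibble(x0 = p[1], y0 = p[2], A = p[3], sigma = p[4], b = p[5],
         integrated = p[6], residual_rms = p[7], noise_sd = p[8],
         converged = is.finite(p[1]))
}

# numeric-vector core of the Gaussian fit, shared by fit_gaussian2d()
# and the bulk-fitting loop in count_spots(); returns
# c(x0, y0, A, sigma, b, integrated, residual_rms, noise_sd), all NA
# on failure.
fit_gaussian2d_core <- function(image, r0, c0, window, sigma_init) {
  if (r0 < 1 || r0 > nrow(image) || c0 < 1 || c0 > ncol(image))
    stop("candidate center outside image bounds", call. = FALSE)
  half <- (window - 1L) %/% 2L
  rs <- max(1L, r0 - half):min(nrow(image), r0 + half)
  cs <- max(1L, c0 - half):min(ncol(image), c0 + half)
  win <- image[rs, cs, drop = FALSE]
  rr <- matrix(rs, length(rs), length(cs))
  cc <- matrix(cs, length(rs), length(cs), byrow = TRUE)

  border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
  b0 <- median(border)
  a0 <- max(win[r0 - rs[1] + 1L, c0 - cs[1] + 1L] - b0, 1e-6)
  p0 <- c(x0 = r0, y0 = c0, A = a0, sigma = sigma_init, b = b0)

  model <- function(p) {
    p[5] + p[3] * exp(-((rr - p[1])^2 + (cc - p[2])^2) / (2 * p[4]^2))
  }
  resid_fn <- function(p) as.vector(win - model(p))
  jac_fn <- function(p) {
    e <- exp(-((rr - p[1])^2 + (cc - p[2])^2) / (2 * p[4]^2))
    s2 <- p[4]^2
    cbind(
      x0 = -as.vector(p[3] * e * (rr - p[1]) / s2),
      y0 = -as.vector(p[3] * e * (cc - p[2]) / s2),
      A = -as.vector(e),
      sigma = -as.vector(p[3] * e *
                           ((rr - p[1])^2 + (cc - p[2])^2) / p[4]^3),
      b = rep(-1, length(e)))
  }

  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = p0, fn = resid_fn, jac = jac_fn,
      lower = c(rs[1], cs[1], 0, 0.05, -Inf),
      upper = c(rs[length(rs)], cs[length(cs)], Inf,
                length(rs), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 60))),
    error = function(e) NULL)

  if (is.null(fit) || fit$info == 0L) return(rep(NA_real_, 8))
  p <- unname(fit$par)
  res <- resid_fn(p)
  c(p[1], p[2], p[3], p[4], p[5], 2 * pi * p[3] * p[4]^2,
    sqrt(mean(res^2)), stats::mad(res))
}

#' Quality-gate fitted spots
#'
#' Flags each fitted spot as passing or failing the fit-quality gates:
#' width inside `[sigma_lo, sigma_hi]`, amplitude inside
#' `[A_min, A_max]` and above `snr_min` times the local residual noise
#' SD, and residual RMS at most `residual_max` times the amplitude.
#' Non-converged fits always fail.
#'
#' @param spots Tibble of fits from [fit_gaussian2d()].
#' @param config An [smfish_config()]; gates derive from `sigma_f`,
#'   `qc_sigma_lo`, `qc_sigma_hi`, `qc_snr_min`, `qc_residual_max`.
#' @param sigma_ref Reference width the sigma gates multiply
#'   (default `config$sigma_f`).
#' @param A_min,A_max Absolute amplitude gates (defaults 0, Inf).
#' @return `spots` with `passed_qc` and `reject_reason` columns.
#' @export
qc_gate <- function(spots, config = smfish_config(),
                    sigma_ref = config$sigma_f, A_min = 0,
                    A_max = Inf) {
  if (A_min > A_max)
    stop("inverted amplitude gate bounds", call. = FALSE)
  s_lo <- config$qc_sigma_lo * sigma_ref
  s_hi <- config$qc_sigma_hi * sigma_ref
  if (s_lo > s_hi) stop("inverted sigma gate bounds", call. = FALSE)
  reason <- dplyr::case_when(
    !spots$converged ~ "no_convergence",
    spots$sigma < s_lo ~ "too_narrow",
    spots$sigma > s_hi ~ "too_wide",
    spots$A < A_min ~ "amplitude_low",
    spots$A > A_max ~ "amplitude_high",
    spots$A <= config$qc_snr_min * spots$noise_sd ~ "low_snr",
    spots$residual_rms > config$qc_residual_max * spots$A ~
      "poor_residual",
    TRUE ~ NA_character_)
  spots$passed_qc <- is.na(reason)
  spots$reject_reason <- reason
  spots
}

#' Count single-molecule spots in one channel of a scene
#'
#' End-to-end spot counting: LoG filtering at `sigma_f`, automatic
#' threshold selection (unless `threshold` is given), candidate
#' picking, sub-pixel Gaussian fitting, QC gating, and assignment of
#' every QC-passed spot to a segmented cell (cell_id 0 = background).
#'
#' @param x An `smfish_scene`.
#' @param channel Channel role to count, e.g. `"fish:IL1B"`.
#' @param seg An `smfish_segmentation` for the same scene.
#' @param config An [smfish_config()].
#' @param threshold Optional fixed detection threshold, bypassing the
#'   automatic scan.
#' @param sigma_f Optional filter scale override.
#' @return Object of class `smfish_spots`: list with `spots` (tibble,
#'   one row per fitted candidate: position, fit parameters,
#'   `passed_qc`, `cell_id`, `in_nucleus`), `per_cell` (tibble
#'   `cell_id`, `count`, `nuclear`, `cyto` over all segmented cells),
#'   `scan` (the threshold scan, or NULL), `channel` and `n_unassigned`.
#' @export
count_spots <- function(x, channel, seg, config = smfish_config(),
                        threshold = NULL, sigma_f = config$sigma_f) {
  stopifnot(inherits(x, "smfish_scene"),
            inherits(seg, "smfish_segmentation"))
  img <- scene_channel(x, channel)
  if (is.null(img)) stop("scene has no channel '", channel, "'",
                         call. = FALSE)
  img <- max_project(img)
  filt <- log_filter(img, sigma_f)

  scan <- NULL
  if (is.null(threshold)) {
    if (any(filt > 0)) {
      scan <- threshold_scan(filt, config = config)
      threshold <- scan$selected
    } else {
      threshold <- Inf
    }
  }
  cand <- detect_candidates(filt, threshold)

  if (nrow(cand)) {
    raw <- vapply(seq_len(nrow(cand)), function(i)
      fit_gaussian2d_core(img, cand$row[i], cand$col[i],
                          as.integer(config$fit_window), sigma_f),
      numeric(8))
    fits <- tibble(x0 = raw[1, ], y0 = raw[2, ], A = raw[3, ],
                   sigma = raw[4, ], b = raw[5, ],
                   integrated = raw[6, ], residual_rms = raw[7, ],
                   noise_sd = raw[8, ], converged = is.finite(raw[1, ]),
                   response = cand$response)
    fits <- qc_gate(fits, config, sigma_ref = sigma_f)
  } else {
    fits <- empty_spot_tibble()
  }
  fits$channel <- rep(channel, nrow(fits))

  fits <- assign_spots(fits, seg)
  per_cell <- per_cell_counts(fits, seg)
  structure(
    list(spots = fits, per_cell = per_cell, scan = scan,
         channel = channel,
         n_unassigned = sum(fits$passed_qc & fits$cell_id == 0L)),
    class = "smfish_spots")
}

empty_spot_tibble <- function() {
  tibble(x0 = numeric(0), y0 = numeric(0), A = numeric(0),
         sigma = numeric(0), b = numeric(0), integrated = numeric(0),
         residual_rms = numeric(0), noise_sd = numeric(0),
         converged = logical(0), response = numeric(0),
         passed_qc = logical(0), reject_reason = character(0))
}

#' @export
print.smfish_spots <- function(x, ...) {
  cat("<smfish_spots> ", x$channel, ": ", nrow(x$spots),
      " candidates, ", sum(x$spots$passed_qc), " passed QC, ",
      x$n_unassigned, " unassigned\n", sep = "")
  invisible(x)
}

# Per-cell spot tallies over all segmented cells (zeros included).
per_cell_counts <- function(spots, seg) {
  ids <- seg$cells$cell_id
  ok <- spots[spots$passed_qc & spots$cell_id > 0L, ]
  tibble(cell_id = ids) |>
    dplyr::left_join(
      ok |>
        dplyr::group_by(.data$cell_id) |>
        dplyr::summarise(count = dplyr::n(),
                         nuclear = sum(.data$in_nucleus),
                         cyto = sum(!.data$in_nucleus),
                         .groups = "drop"),
      by = "cell_id") |>
    dplyr::mutate(dplyr::across(c("count", "nuclear", "cyto"),
                                ~ as.integer(tidyr::replace_na(.x, 0L))))
}
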