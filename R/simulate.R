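#' Simulation parameters for synthetic smFISH scenes
#'
#' Defines the statistical structure of a simulated field: cell
#' geometry, optics, noise, per-gene count model with between-gene
#' copula correlation, burst-site model and protein model. The
#' defaults emulate an LPS-stimulated monocyte field: heavy-tailed
#' (log-normal) per-cell mRNA counts around 100 copies/cell, 0-2
#' nuclear burst sites per cell averaging 0.9 sites/cell with ~100
#' transcripts each, burst sites biased toward the nuclear rim, a
#' baseline between-gene correlation of 0.36, and a mild
#' count-versus-area scaling so the size confound has signal.
#'
#' The default geometry is camera-native: a 2048 x 2048 field sampled
#' at ~0.065 um/px (100x objective, 6.5 um camera pixels), where a
#' PMA-differentiated monocyte of 16-20 um diameter spans 120-150 px
#' in radius and its nucleus 55-70 px, and the diffraction-limited PSF
#' is sigma ~1.5 px. At this sampling ~100 molecules per cell sit well
#' below the crowding density at which neighbouring PSFs merge, so
#' single-molecule counting is identifiable.
#'
#' @param ... Name-value overrides. Parameters:
#' \describe{
#'   \item{width, height}{Image size in px (2048 x 2048).}
#'   \item{n_cells}{Cells per field (20).}
#'   \item{nucleus_radius, cell_radius}{Radius ranges in px
#'     (55-70 and 120-150).}
#'   \item{sigma_psf}{PSF width in px (1.5).}
#'   \item{molecule_amplitude, molecule_amp_cv}{Per-molecule peak
#'     brightness in iu and its CV (200, 0.1).}
#'   \item{background, read_noise_sd, shot_noise}{Camera model: offset
#'     100 iu, Gaussian read noise SD 6 iu, Poisson shot noise on.}
#'   \item{genes}{Gene names (IL1B, TNFA).}
#'   \item{count_meanlog, count_sdlog}{Log-normal per-cell count
#'     marginals (log 100, 1).}
#'   \item{rho}{Between-gene Gaussian-copula correlation (0.36).}
#'   \item{area_exponent}{Counts scale with (area/mean area)^gamma
#'     (0.5).}
#'   \item{cytoplasm_frac}{Fraction of mRNA placed outside the nucleus
#'     (0.8).}
#'   \item{burst_site_probs}{P(0, 1, 2 sites/cell) = (0.3, 0.5, 0.2),
#'     i.e. 0.9 sites/cell.}
#'   \item{burst_copies_meanlog, burst_copies_sdlog}{Transcripts per
#'     site, log-normal (log 100, 0.3).}
#'   \item{burst_copies_fixed}{Optional numeric vector of exact
#'     transcripts per site, recycled over sites in planting order
#'     (overrides the log-normal copies model); for controlled
#'     copy-number recovery experiments.}
#'   \item{burst_rim_bias}{Place sites near the nuclear rim (TRUE).}
#'   \item{lone_introns_per_cell}{Isolated single-intron molecules per
#'     cell, guaranteeing a single-copy reference (2).}
#'   \item{protein_base, protein_slope, protein_cv}{Protein latent =
#'     base + slope x mRNA count, with multiplicative noise
#'     (20, 1, 0.2); rendered as a per-cell uniform fill in iu.}
#'   \item{protein_gene, intron_genes}{Which genes get protein/intron
#'     channels (first gene; all genes).}
#'   \item{seed}{Root RNG seed (1).}
#' }
#' @return Named list of class `smfish_sim_params`.
#' @export
sim_params <- function(...) {
  defaults <- list(
    width = 2048L, height = 2048L, n_cells = 20L,
    nucleus_radius = c(55, 70), cell_radius = c(120, 150),
    sigma_psf = 1.5,
    molecule_amplitude = 200, molecule_amp_cv = 0.1,
    background = 100, read_noise_sd = 6, shot_noise = TRUE,
    genes = c("IL1B", "TNFA"),
    count_meanlog = log(100), count_sdlog = 1,
    rho = 0.36,
    area_exponent = 0.5,
    cytoplasm_frac = 0.8,
    burst_site_probs = c(0.3, 0.5, 0.2),
    burst_copies_meanlog = log(100), burst_copies_sdlog = 0.3,
    burst_copies_fixed = NULL,
    burst_rim_bias = TRUE,
    lone_introns_per_cell = 2L,
    protein_base = 20, protein_slope = 1, protein_cv = 0.2,
    protein_gene = NULL, intron_genes = NULL,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown sim parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  defaults[names(over)] <- over
  p <- defaults
  if (is.null(p$protein_gene)) p$protein_gene <- p$genes[1]
  if (is.null(p$intron_genes)) p$intron_genes <- p$genes
  stopifnot(all(p$nucleus_radius > 0), all(p$cell_radius > 0),
            max(p$nucleus_radius) < min(p$cell_radius),
            p$rho >= -1, p$rho <= 1,
            abs(sum(p$burst_site_probs) - 1) < 1e-9)
  structure(p, class = c("smfish_sim_params", "list"))
}

#' Sample correlated per-cell counts
#'
#' Draws per-cell counts for each gene with log-normal marginals
#' (`count_meanlog`, `count_sdlog`) and between-gene dependence from a
#' Gaussian copula with correlation `rho`: correlated standard
#' normals are mapped through their CDF to uniforms and then through
#' the marginal quantile function, preserving the marginals exactly
#' while imposing the rank dependence. Counts are rounded to integers.
#'
#' @param params An [sim_params()].
#' @param n_cells Number of cells (default `params$n_cells`).
#' @param seed RNG seed (default `params$seed`).
#' @return Tibble with `cell` plus one integer count column per gene.
#' @export
sample_counts <- function(params = sim_params(),
                          n_cells = params$n_cells,
                          seed = params$seed) {
  stopifnot(inherits(params, "smfish_sim_params"))
  set.seed(seed)
  g <- length(params$genes)
  z <- matrix(rnorm(n_cells * g), n_cells, g) %*%
    copula_root(g, params$rho)
  u <- pnorm(z)
  counts <- qlnorm(u, params$count_meanlog, params$count_sdlog)
  out <- tibble(cell = seq_len(n_cells))
  for (j in seq_len(g))
    out[[params$genes[j]]] <- as.integer(round(counts[, j]))
  out
}

#' Render a synthetic scene with ground truth
#'
#' Builds a full multi-channel field: cells as non-overlapping discs
#' with nuclei inside; DAPI as bright nucleus discs; bright-field as a
#' dim cell interior with a bright rim (so phase congruency finds the
#' edges); each mRNA as a Gaussian PSF at a uniform position in its
#' cell (cytoplasm-biased); burst sites as `copies` co-located PSFs
#' jittered within 1 px near the nuclear rim, plus a few isolated
#' lone introns; protein as a per-cell uniform fill proportional to
#' the protein latent. Poisson shot noise and Gaussian read noise are
#' applied last and intensities rounded to camera integers. The same
#' seed reproduces the scene bit-identically.
#'
#' Counts are scaled by `(cell area / mean area)^area_exponent` before
#' rendering, planting the size confound.
#'
#' @param params An [sim_params()].
#' @param counts Optional tibble from [sample_counts()]; sampled if
#'   NULL.
#' @param seed RNG seed (default `params$seed`).
#' @param source_id Scene identifier.
#' @return List of class `smfish_sim`: `scene` (an `smfish_scene`) and
#'   `truth` (list: `nucleus_labels`, `cell_labels`, `cells` tibble
#'   with planted per-gene counts, latents and geometry; `spots`,
#'   `bursts`, `lone_introns` tibbles).
#' @export
render_scene <- function(params = sim_params(), counts = NULL,
                         seed = params$seed, source_id = "sim") {
  stopifnot(inherits(params, "smfish_sim_params"))
  set.seed(seed)
  nr <- params$height; nc <- params$width
  n <- params$n_cells

  geom <- place_cells(params)
  cell_lab <- geom$cell_labels; nuc_lab <- geom$nucleus_labels
  cells <- geom$cells

  if (is.null(counts)) {
    counts <- sample_counts(params, n, seed = seed + 1L)
  } else if (nrow(counts) != n) {
    stop("counts has ", nrow(counts), " rows but n_cells = ", n,
         call. = FALSE)
  }

  area_scale <- (cells$area_px / mean(cells$area_px))^params$area_exponent

  bg <- params$background
  chans <- list()
  chans$dapi <- matrix(bg, nr, nc) + (nuc_lab > 0) * 5 * bg
  rim <- cell_rim(cell_lab)
  chans$brightfield <- matrix(5 * bg, nr, nc) -
    (cell_lab > 0) * 0.8 * bg + rim * 3 * bg

  truth_spots <- list(); truth_bursts <- list(); truth_lone <- list()
  planted <- cells
  sigma <- params$sigma_psf

  for (gene in params$genes)
    planted[[paste0("count_", gene)]] <- 0L
  for (gene in params$intron_genes)
    planted[[paste0("bursts_", gene)]] <- 0L

  for (gene in params$genes) {
    img <- matrix(0, nr, nc)
    spots <- list()
    for (i in seq_len(n)) {
      k <- max(0L, round(counts[[gene]][i] * area_scale[i]))
      if (k > 0) {
        pos <- sample_in_cell(k, cells[i, ], nuc_lab, cell_lab,
                              params$cytoplasm_frac)
        amp <- params$molecule_amplitude *
          exp(rnorm(k, 0, params$molecule_amp_cv))
        img <- add_psfs(img, pos$row, pos$col, amp, sigma)
        spots[[i]] <- tibble(gene = gene, cell = i, row = pos$row,
                             col = pos$col, amplitude = amp)
      }
      planted[[paste0("count_", gene)]][i] <- k
    }
    truth_spots[[gene]] <- dplyr::bind_rows(spots)
    chans[[paste0("fish:", gene)]] <- apply_noise(img + bg, params)
  }

  site_counter <- 0L
  for (gene in params$intron_genes) {
    img <- matrix(0, nr, nc)
    bursts <- list(); lone <- list()
    for (i in seq_len(n)) {
      nsite <- sample(0:2, 1, prob = params$burst_site_probs)
      if (nsite > 0) {
        ctr <- burst_positions(nsite, cells[i, ], params$burst_rim_bias)
        copies <- if (!is.null(params$burst_copies_fixed)) {
          fx <- params$burst_copies_fixed
          idx <- (site_counter + seq_len(nsite) - 1L) %% length(fx) + 1L
          as.integer(fx[idx])
        } else {
          pmax(1L, round(exp(rnorm(
            nsite, params$burst_copies_meanlog,
            params$burst_copies_sdlog))))
        }
        site_counter <- site_counter + nsite
        for (s in seq_len(nsite)) {
          kk <- copies[s]
          jr <- ctr$row[s] + runif(kk, -1, 1)
          jc <- ctr$col[s] + runif(kk, -1, 1)
          amp <- params$molecule_amplitude *
            exp(rnorm(kk, 0, params$molecule_amp_cv))
          img <- add_psfs(img, jr, jc, amp, sigma)
        }
        bursts[[i]] <- tibble(gene = gene, cell = i, row = ctr$row,
                              col = ctr$col, copies = copies)
      }
      nl <- params$lone_introns_per_cell
      if (nl > 0) {
        pos <- sample_in_cell(nl, cells[i, ], nuc_lab, cell_lab,
                              params$cytoplasm_frac)
        amp <- params$molecule_amplitude *
          exp(rnorm(nl, 0, params$molecule_amp_cv))
        img <- add_psfs(img, pos$row, pos$col, amp, sigma)
        lone[[i]] <- tibble(gene = gene, cell = i, row = pos$row,
                            col = pos$col, amplitude = amp)
      }
      planted[[paste0("bursts_", gene)]][i] <- nsite
    }
    truth_bursts[[gene]] <- dplyr::bind_rows(bursts)
    truth_lone[[gene]] <- dplyr::bind_rows(lone)
    chans[[paste0("intron:", gene)]] <- apply_noise(img + bg, params)
  }

  pg <- params$protein_gene
  latent <- params$protein_base + params$protein_slope *
    planted[[paste0("count_", pg)]] * exp(rnorm(n, 0, params$protein_cv))
  img <- matrix(0, nr, nc)
  for (i in seq_len(n)) img[cell_lab == i] <- latent[i]
  chans[[paste0("protein:", pg)]] <- apply_noise(img + bg, params)
  planted$protein_latent <- latent

  chans$dapi <- apply_noise(chans$dapi, params)
  chans$brightfield <- apply_noise(chans$brightfield, params)

  sc <- scene(chans, source_id = source_id)
  structure(
    list(scene = sc,
         truth = list(nucleus_labels = nuc_lab, cell_labels = cell_lab,
                      cells = planted,
                      spots = dplyr::bind_rows(truth_spots),
                      bursts = dplyr::bind_rows(truth_bursts),
                      lone_introns = dplyr::bind_rows(truth_lone)),
         params = params),
    class = "smfish_sim")
}

#' @export
print.smfish_sim <- function(x, ...) {
  cat("<smfish_sim> ", x$scene$source_id, ": ",
      x$params$n_cells, " cells, ", nrow(x$truth$spots),
      " planted spots, ", nrow(x$truth$bursts), " burst sites\n",
      sep = "")
  invisible(x)
}

# --- internal geometry/rendering helpers -------------------------------

place_cells <- function(params) {
  nr <- params$height; nc <- params$width; n <- params$n_cells
  rc <- runif(n, params$cell_radius[1], params$cell_radius[2])
  rn <- runif(n, params$nucleus_radius[1], params$nucleus_radius[2])
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:2000) {
      r0 <- runif(1, rc[i] + 3, nr - rc[i] - 3)
      c0 <- runif(1, rc[i] + 3, nc - rc[i] - 3)
      if (i == 1L) { centers[i, ] <- c(r0, c0); placed <- TRUE; break }
      dd <- sqrt((centers[1:(i - 1), 1] - r0)^2 +
                   (centers[1:(i - 1), 2] - c0)^2)
      if (all(dd > rc[i] + rc[1:(i - 1)] + 2)) {
        centers[i, ] <- c(r0, c0); placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping cells in a ",
           nr, "x", nc, " field", call. = FALSE)
  }
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cell_lab <- matrix(0L, nr, nc); nuc_lab <- matrix(0L, nr, nc)
  for (i in seq_len(n)) {
    d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
    cell_lab[d2 <= rc[i]^2] <- i
    nuc_lab[d2 <= rn[i]^2] <- i
  }
  cells <- tibble(
    cell_id = seq_len(n), row = centers[, 1], col = centers[, 2],
    cell_radius = rc, nucleus_radius = rn,
    area_px = as.integer(tabulate(cell_lab[cell_lab > 0], n)),
    nucleus_area_px = as.integer(tabulate(nuc_lab[nuc_lab > 0], n)))
  list(cell_labels = cell_lab, nucleus_labels = nuc_lab, cells = cells)
}

# one-pixel rim of each labeled cell (boundary with background)
cell_rim <- function(cell_lab) {
  fg <- cell_lab > 0
  er <- matrix(as.numeric(EBImage::erode(EBImage::Image(fg * 1),
                                         disc_kernel(1))) > 0.5,
               nrow(fg), ncol(fg))
  fg & !er
}

# k uniform positions inside a cell disc, cytoplasm-biased
sample_in_cell <- function(k, cell, nuc_lab, cell_lab, cyto_frac) {
  rows <- numeric(k); cols <- numeric(k)
  for (j in seq_len(k)) {
    want_cyto <- runif(1) < cyto_frac
    for (try in 1:100) {
      a <- runif(1, 0, 2 * pi)
      # margin keeps the PSF clear of the cell rim
      rr <- sqrt(runif(1)) * (cell$cell_radius - 3)
      r0 <- cell$row + rr * sin(a); c0 <- cell$col + rr * cos(a)
      in_nuc <- nuc_lab[round(r0), round(c0)] > 0
      if (!want_cyto || !in_nuc || try == 100L) break
    }
    rows[j] <- r0; cols[j] <- c0
  }
  list(row = rows, col = cols)
}

# burst-site centers inside the nucleus, optionally near its rim
burst_positions <- function(nsite, cell, rim_bias) {
  a <- runif(nsite, 0, 2 * pi)
  frac <- if (rim_bias) runif(nsite, 0.6, 0.85) else
    sqrt(runif(nsite)) * 0.85
  rr <- frac * cell$nucleus_radius
  list(row = cell$row + rr * sin(a), col = cell$col + rr * cos(a))
}

# additively render isotropic Gaussian PSFs at sub-pixel positions
add_psfs <- function(img, rows, cols, amps, sigma) {
  half <- ceiling(4 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  for (j in seq_along(rows)) {
    r0 <- rows[j]; c0 <- cols[j]
    rs <- max(1L, floor(r0) - half):min(nr, ceiling(r0) + half)
    cs <- max(1L, floor(c0) - half):min(nc, ceiling(c0) + half)
    pr <- exp(-(rs - r0)^2 / (2 * sigma^2))
    pc <- exp(-(cs - c0)^2 / (2 * sigma^2))
    img[rs, cs] <- img[rs, cs] + amps[j] * outer(pr, pc)
  }
  img
}

apply_noise <- function(img, params) {
  if (isTRUE(params$shot_noise))
    img <- matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
  if (params$read_noise_sd > 0)
    img <- img + rnorm(length(img), 0, params$read_noise_sd)
  round(pmax(img, 0))
}

#' Simulate a stimulation time course
#'
#' Generates per-(time, scan) fields whose planted mean mRNA counts
#' and burst-site rates follow user curves, with several scans per
#' time point so the scan-level error-bar convention of
#' [timecourse_summary()] is exercised. With `render = TRUE` each scan
#' is a fully rendered scene plus ground truth; with `render = FALSE`
#' (the default) only the planted per-cell count tables are generated,
#' which is what the statistics stages consume and is orders of
#' magnitude faster.
#'
#' @param time_minutes Numeric vector of time points.
#' @param mean_counts Named list (per gene) of planted mean counts,
#'   each a vector along `time_minutes`.
#' @param burst_rate Optional named list (per gene) of planted mean
#'   sites/cell along `time_minutes` (values in \[0, 2\]; realized as
#'   P(1) = rate for rate <= 1, else P(2) = rate - 1, P(1) = 2 - rate).
#' @param rho_by_time Optional vector of copula correlations along
#'   `time_minutes` (default `params$rho` throughout).
#' @param n_scans Scans per time point (default 3).
#' @param params Base [sim_params()] shared geometry.
#' @param seed Root seed; every (time, scan) derives its own stream.
#' @param render Render full scenes (slow) or tables only.
#' @param condition Condition label (default "LPS").
#' @return List: `manifest` (tibble: condition, time_minutes, scan_id,
#'   scene key), `cell_table` (planted per-cell counts in cell-table
#'   schema), and, when rendered, `scenes` and `truth` keyed lists.
#' @export
simulate_timecourse <- function(time_minutes, mean_counts,
                                burst_rate = NULL, rho_by_time = NULL,
                                n_scans = 3L, params = sim_params(),
                                seed = params$seed, render = FALSE,
                                condition = "LPS") {
  stopifnot(length(time_minutes) >= 1,
            all(vapply(mean_counts, length, 1L) == length(time_minutes)))
  genes <- names(mean_counts)
  scenes <- list(); truths <- list(); rows <- list(); tabs <- list()
  k <- 0L
  for (ti in seq_along(time_minutes)) {
    for (s in seq_len(n_scans)) {
      k <- k + 1L
      seed_ts <- (seed + 7919L * ti + 104729L * s) %% .Machine$integer.max
      p <- params
      p$genes <- genes
      p$count_meanlog <- NULL  # per-gene means below
      if (!is.null(rho_by_time)) p$rho <- rho_by_time[ti]
      key <- sprintf("t%03d_scan%d", round(time_minutes[ti]), s)

      # per-gene lognormal meanlog chosen so E[count] hits the curve
      mls <- vapply(genes, function(g)
        log(mean_counts[[g]][ti]) - params$count_sdlog^2 / 2, numeric(1))
      cnt <- sample_counts_multi(p, params$count_sdlog, mls, seed_ts)

      site_probs <- params$burst_site_probs
      if (!is.null(burst_rate)) {
        rate <- burst_rate[[1]][ti]
        site_probs <- if (rate <= 1) c(1 - rate, rate, 0) else
          c(0, 2 - rate, rate - 1)
      }

      if (render) {
        p2 <- params
        p2$genes <- genes
        p2$burst_site_probs <- site_probs
        if (!is.null(rho_by_time)) p2$rho <- rho_by_time[ti]
        sim <- render_scene(p2, counts = cnt, seed = seed_ts,
                            source_id = key)
        # re-plant the per-gene means: render_scene samples via params,
        # so pass explicit counts (done above)
        scenes[[key]] <- sim$scene
        truths[[key]] <- sim$truth
        tab <- sim$truth$cells
      } else {
        set.seed(seed_ts + 1L)
        nsite <- lapply(genes, function(g)
          sample(0:2, params$n_cells, replace = TRUE, prob = site_probs))
        names(nsite) <- genes
        tab <- tibble(cell_id = seq_len(params$n_cells),
                      area_px = NA_real_, nucleus_area_px = NA_real_)
        for (g in genes) {
          tab[[paste0("count_", g)]] <- cnt[[g]]
          tab[[paste0("bursts_", g)]] <- nsite[[g]]
        }
      }
      tab$source_id <- key
      tab$condition <- condition
      tab$time_minutes <- time_minutes[ti]
      tab$scan_id <- paste0("scan", s)
      tab$border_flag <- FALSE
      tab$anomaly_flag <- FALSE
      tabs[[k]] <- tab
      rows[[k]] <- tibble(path = key, condition = condition,
                          time_minutes = time_minutes[ti],
                          scan_id = paste0("scan", s))
    }
  }
  cell_table <- dplyr::bind_rows(tabs)
  keep <- intersect(c(cell_table_core_cols,
                      grep(measure_col_rx, names(cell_table),
                           value = TRUE)), names(cell_table))
  out <- list(manifest = dplyr::bind_rows(rows),
              cell_table = cell_table[keep])
  if (render) { out$scenes <- scenes; out$truth <- truths }
  out
}

# symmetric square root of the equicorrelation matrix; tolerates the
# comonotone boundary rho = +/-1 where Cholesky breaks down
copula_root <- function(g, rho) {
  sig <- matrix(rho, g, g); diag(sig) <- 1
  e <- eigen(sig, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# copula sampling with per-gene meanlogs
sample_counts_multi <- function(params, sdlog, meanlogs, seed) {
  set.seed(seed)
  g <- length(params$genes)
  z <- matrix(rnorm(params$n_cells * g), ncol = g) %*%
    copula_root(g, params$rho)
  u <- pnorm(z)
  out <- tibble(cell = seq_len(params$n_cells))
  for (j in seq_len(g))
    out[[params$genes[j]]] <-
      as.integer(round(qlnorm(u[, j], meanlogs[j], sdlog)))
  out
}
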