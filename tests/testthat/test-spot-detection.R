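# LoG filtering, automatic threshold selection, candidate picking,
# sub-pixel Gaussian fitting and QC gating.

test_that("LoG response is zero on constants and peaks on matched spots", {
  expect_lt(max(abs(log_filter(matrix(42, 32, 32), 1.5))), 1e-9)
  expect_error(log_filter(matrix(1, 8, 8), 0), "positive")
  img <- render_spot(r0 = 11, c0 = 11, A = 100, sigma = 1.5, b = 10)
  resp <- log_filter(img, 1.5)
  peak <- which(resp == max(resp), arr.ind = TRUE)
  expect_lte(max(abs(peak - 11)), 0.5)
})

test_that("the response over a sigma_f grid is maximal near sigma_psf", {
  img <- render_spot(31, 31, 16, 16, A = 100, sigma = 2, b = 0)
  grid <- seq(0.8, 4, by = 0.2)
  peak_resp <- vapply(grid, function(s) max(log_filter(img, s)),
                      numeric(1))
  expect_lt(abs(grid[which.max(peak_resp)] - 2), 0.45)
})

test_that("N(T) is non-increasing and planted spots are counted at selection", {
  set.seed(9)
  img <- matrix(100, 512, 512)
  # 10x10 jittered grid: spots stay resolvable by construction
  g <- expand.grid(r = seq(30, 480, length.out = 10),
                   c = seq(30, 480, length.out = 10))
  rows <- g$r + runif(100, -5, 5); cols <- g$c + runif(100, -5, 5)
  for (k in 1:100)
    img <- img + 500 * render_spot(512, 512, rows[k], cols[k], A = 1,
                                   sigma = 1.5, b = 0)
  img <- matrix(rpois(512^2, img), 512, 512)
  scan <- threshold_scan(log_filter(img, 1.5))
  expect_true(all(diff(scan$curve$n_spots) <= 0))
  expect_false(scan$fallback)
  n_sel <- scan$curve$n_spots[findInterval(scan$selected,
                                           scan$curve$threshold)]
  expect_equal(n_sel, 100L)
})

test_that("degenerate scans: single-point grid and plateau-free curves", {
  img <- render_spot(31, 31, 16, 16)
  filt <- log_filter(img, 1.5)
  s1 <- threshold_scan(filt, grid = 5)
  expect_equal(s1$selected, 5)
  # a curve whose count falls linearly forever has no plateau
  set.seed(4)
  stair <- matrix(0, 64, 64)
  ks <- seq(5, 60, by = 3)
  for (i in seq_along(ks)) stair[ks[i], ks[i]] <- i
  s2 <- suppressWarnings(threshold_scan(stair,
                                        grid = seq(0.5, 19.5, by = 1)))
  expect_true(s2$fallback)
  expect_equal(s2$selected, 9.5)  # grid midpoint
})

test_that("candidate picking resolves plateaus to one representative", {
  m <- matrix(0, 16, 16)
  m[5, 5] <- 10
  m[10:12, 9:11] <- 8  # 3x3 constant plateau
  cand <- detect_candidates(m, 1)
  expect_equal(nrow(cand), 2L)
  expect_true(any(cand$row == 5 & cand$col == 5))
  expect_true(any(cand$row == 10 & cand$col == 9))  # lexicographic min
  two <- matrix(0, 16, 16); two[4, 4] <- 5; two[4, 14] <- 5
  expect_equal(nrow(detect_candidates(two, 1)), 2L)
  expect_error(detect_candidates(m, -1), ">= 0")
})

test_that("a noiseless spot is recovered to 1e-6 in all five parameters", {
  img <- render_spot(r0 = 11.3, c0 = 10.6, A = 100, sigma = 1.5, b = 10)
  fit <- fit_gaussian2d(img, c(11, 11), window = 11)
  expect_true(fit$converged)
  expect_lt(abs(fit$x0 - 11.3), 1e-6)
  expect_lt(abs(fit$y0 - 10.6), 1e-6)
  expect_lt(abs(fit$A - 100) / 100, 1e-6)
  expect_lt(abs(fit$sigma - 1.5) / 1.5, 1e-6)
  expect_lt(abs(fit$b - 10) / 10, 1e-6)
  expect_lt(abs(fit$integrated - 2 * pi * 100 * 1.5^2) / fit$integrated,
            1e-9)
})

test_that("refitting a rendered fit reproduces its parameters (self-consistency)", {
  img <- render_spot(r0 = 10.7, c0 = 11.4, A = 80, sigma = 1.8, b = 25)
  f1 <- fit_gaussian2d(img, c(11, 11), window = 13)
  img2 <- render_spot(r0 = f1$x0, c0 = f1$y0, A = f1$A,
                      sigma = f1$sigma, b = f1$b)
  f2 <- fit_gaussian2d(img2, c(11, 11), window = 13)
  expect_lt(abs(f2$x0 - f1$x0), 1e-6)
  expect_lt(abs(f2$A - f1$A) / f1$A, 1e-6)
  expect_lt(abs(f2$sigma - f1$sigma) / f1$sigma, 1e-6)
})

test_that("burst-vs-single intensity ratio follows 2 pi A sigma^2", {
  # a focus ~20x brighter and ~2.24x wider than a single molecule has
  # ~100x the integrated intensity
  single <- fit_gaussian2d(render_spot(A = 100, sigma = 1.5, b = 10),
                           c(11, 11), window = 11)
  burst <- fit_gaussian2d(
    render_spot(31, 31, 16, 16, A = 2000, sigma = 1.5 * 2.24, b = 10),
    c(16, 16), window = 21)
  ratio <- burst$integrated / single$integrated
  expect_equal(burst$A / single$A, 20, tolerance = 1e-6)
  expect_equal(burst$sigma / single$sigma, 2.24, tolerance = 1e-6)
  expect_equal(ratio, 20 * 2.24^2, tolerance = 1e-6)
  expect_equal(ratio, 100.4, tolerance = 0.01)
})

test_that("centroid bias under Poisson noise at SNR 10 is below 0.1 px", {
  clean <- render_spot(r0 = 11.3, c0 = 10.6, A = 100, sigma = 1.5,
                       b = 100)  # shot noise SD ~ sqrt(100) -> SNR 10
  set.seed(12)
  dev <- replicate(100, {
    noisy <- matrix(rpois(441, clean), 21, 21)
    f <- fit_gaussian2d(noisy, c(11, 11), window = 11)
    c(f$x0 - 11.3, f$y0 - 10.6)
  })
  expect_lt(max(abs(rowMeans(dev))), 0.1)
})

test_that("QC gates reject misfits and pass everything when disabled", {
  spots <- tibble::tibble(
    x0 = 1, y0 = 1, A = c(100, 100, 100, 5, 100),
    sigma = c(1.5, 15, 0.2, 1.5, 1.5), b = 0,
    integrated = 1, residual_rms = c(1, 1, 1, 1, 90),
    noise_sd = 10, converged = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  out <- qc_gate(spots, smfish_config())
  expect_equal(out$reject_reason,
               c(NA, "too_wide", "too_narrow", "low_snr",
                 "poor_residual"))
  loose <- qc_gate(spots, smfish_config(qc_sigma_lo = 0,
                                        qc_sigma_hi = Inf,
                                        qc_snr_min = 0,
                                        qc_residual_max = Inf))
  expect_true(all(loose$passed_qc))
  expect_error(qc_gate(spots, smfish_config(), A_min = 10, A_max = 1),
               "inverted")
})

test_that("end-to-end counting on the fixture meets recall and precision", {
  sim <- fixture_sim()
  seg <- fixture_seg()
  res <- count_spots(sim$scene, "fish:IL1B", seg)
  det <- res$spots[res$spots$passed_qc, ]
  tr <- sim$truth$spots[sim$truth$spots$gene == "IL1B", ]
  m <- match_spots(det, tr, radius = 2)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  # conservation: per-cell counts + unassigned = all QC-passed spots
  expect_equal(sum(res$per_cell$count) + res$n_unassigned, nrow(det))
  expect_equal(res$per_cell$count,
               res$per_cell$nuclear + res$per_cell$cyto)
})

test_that("an empty channel yields zero spots", {
  sim <- fixture_sim()
  flat <- scene(list(dapi = scene_channel(sim$scene, "dapi"),
                     "fish:EMPTY" = matrix(50, 768, 768)))
  res <- count_spots(flat, "fish:EMPTY", fixture_seg())
  expect_equal(sum(res$spots$passed_qc), 0L)
})

test_that("detection is equivariant under integer translation", {
  img <- matrix(100, 64, 64)
  img <- img + 300 * render_spot(64, 64, 30.4, 25.7, A = 1,
                                 sigma = 1.5, b = 0)
  shifted <- matrix(100, 64, 64)
  shifted <- shifted + 300 * render_spot(64, 64, 30.4 + 7, 25.7 - 4,
                                         A = 1, sigma = 1.5, b = 0)
  f1 <- fit_gaussian2d(img, c(30, 26), window = 11)
  f2 <- fit_gaussian2d(shifted, c(37, 22), window = 11)
  expect_lt(abs((f2$x0 - f1$x0) - 7), 1e-6)
  expect_lt(abs((f2$y0 - f1$y0) + 4), 1e-6)
})

test_that("doubling planted density doubles counts within binomial error", {
  set.seed(21)
  mk <- function(n) {
    img <- matrix(100, 512, 512)
    for (k in seq_len(n))
      img <- img + 300 * render_spot(512, 512, runif(1, 15, 495),
                                     runif(1, 15, 495), A = 1,
                                     sigma = 1.5, b = 0)
    matrix(rpois(512^2, img), 512, 512)
  }
  count_at <- function(img) {
    filt <- log_filter(img, 1.5)
    scan <- threshold_scan(filt)
    nrow(detect_candidates(filt, scan$selected))
  }
  n1 <- count_at(mk(80)); n2 <- count_at(mk(160))
  expect_lt(abs(n2 - 2 * n1), 2 * sqrt(160) + 10)
})
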