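# Nucleus detection, binary fusion, cleanup, seeded watershed, and the
# full three-channel segmentation with its structural invariants.

test_that("well-separated nuclei are found at their planted centroids", {
  img <- matrix(20, 128, 128)
  img <- draw_disc(img, 40, 40, 16, 600)
  img <- draw_disc(img, 90, 85, 18, 600)
  set.seed(2); img <- img + matrix(rnorm(128^2, 0, 3), 128, 128)
  lab <- detect_nuclei(pmax(img, 0))
  expect_equal(max(lab), 2L)
  cen <- smfishr:::label_centroids(lab)
  cen <- cen[order(cen$row), ]
  expect_lt(max(abs(cen$row - c(40, 90))), 1.5)
  expect_lt(max(abs(cen$col - c(40, 85))), 1.5)
})

test_that("an all-zero DAPI image yields zero nuclei, non-2-D input errors", {
  expect_equal(max(detect_nuclei(matrix(0, 64, 64))), 0L)
  expect_error(detect_nuclei(array(0, c(4, 4, 2))), "matrix")
})

test_that("touching nuclei are split by the distance-transform watershed", {
  # two discs overlapping by ~20% of a radius; oracle assigns each
  # pixel of the union to the nearer planted center
  img <- matrix(10, 96, 96)
  r <- 15
  c1 <- c(48, 34); c2 <- c(48, 34 + round(1.8 * r))
  img <- draw_disc(img, c1[1], c1[2], r, 500)
  img <- draw_disc(img, c2[1], c2[2], r, 500)
  lab <- detect_nuclei(img)
  expect_equal(max(lab), 2L)
  l1 <- lab[c1[1], c1[2]]; l2 <- lab[c2[1], c2[2]]
  expect_true(l1 > 0 && l2 > 0 && l1 != l2)
  # oracle comparison on the union
  rows <- matrix(seq_len(96), 96, 96)
  cols <- t(rows)
  d1 <- sqrt((rows - c1[1])^2 + (cols - c1[2])^2)
  d2 <- sqrt((rows - c2[1])^2 + (cols - c2[2])^2)
  inside <- d1 <= r | d2 <= r
  oracle <- ifelse(d1 < d2, l1, l2)
  agree <- mean((lab[inside] == oracle[inside])[abs(d1 - d2)[inside] > 2])
  expect_gt(agree, 0.9)
})

test_that("combine_binaries is the pixelwise union (brute-force oracle)", {
  set.seed(3)
  a <- matrix(runif(64) < 0.3, 8, 8)
  b <- matrix(runif(64) < 0.3, 8, 8)
  c <- matrix(runif(64) < 0.3, 8, 8)
  got <- combine_binaries(a, b, c)
  for (i in 1:8) for (j in 1:8)
    expect_identical(got[i, j], a[i, j] || b[i, j] || c[i, j])
  expect_false(any(combine_binaries(a & FALSE, b & FALSE, c & FALSE)))
  # a pixel set in exactly one input is foreground (the >= 1 rule)
  one <- matrix(FALSE, 8, 8); one[4, 5] <- TRUE
  expect_true(combine_binaries(one, one & FALSE, one & FALSE)[4, 5])
  expect_error(combine_binaries(a, b, matrix(FALSE, 4, 4)), "shape")
})

test_that("cleanup fills holes, drops specks, and preserves clean masks", {
  cfg <- smfish_config(min_cell_area = 50L)
  m <- matrix(FALSE, 64, 64)
  m <- draw_disc(m, 32, 32, 14, TRUE)
  holed <- m; holed[30:33, 30:33] <- FALSE
  out <- morphological_cleanup(holed, cfg)
  expect_true(all(out[30:33, 30:33]))
  speck <- matrix(FALSE, 64, 64); speck[5, 5] <- TRUE
  expect_false(any(morphological_cleanup(speck, cfg)))
  clean <- morphological_cleanup(m, cfg)
  core <- draw_disc(matrix(FALSE, 64, 64), 32, 32, 11, TRUE)
  expect_true(all(clean[core]))     # interior untouched
  halo <- !draw_disc(matrix(FALSE, 64, 64), 32, 32, 17, TRUE)
  expect_false(any(clean[halo]))    # boundary moves < r_close + w_med
})

test_that("watershed from nuclei partitions blobs at the equidistance line", {
  fg <- matrix(FALSE, 64, 64)
  fg[10:54, 6:60] <- TRUE
  nuc <- matrix(0L, 64, 64)
  nuc <- draw_disc(nuc, 30, 20, 5, 1L)
  nuc <- draw_disc(nuc, 34, 46, 5, 2L)
  lab <- watershed_cells(fg, nuc)
  expect_setequal(unique(lab[lab > 0]), c(1L, 2L))
  expect_true(all(lab[fg] > 0))
  # brute-force nearest-nucleus oracle: disagreements may only sit
  # within one pixel of the equidistance line
  idx_n1 <- which(nuc == 1L); idx_n2 <- which(nuc == 2L)
  rc <- function(idx) cbind((idx - 1) %% 64 + 1, (idx - 1) %/% 64 + 1)
  n1 <- rc(idx_n1); n2 <- rc(idx_n2)
  for (i in seq(10, 54, by = 4)) for (j in seq(6, 60, by = 4)) {
    d1 <- min(sqrt((n1[, 1] - i)^2 + (n1[, 2] - j)^2))
    d2 <- min(sqrt((n2[, 1] - i)^2 + (n2[, 2] - j)^2))
    oracle <- if (d1 < d2) 1L else 2L
    if (abs(d1 - d2) > 1.5) expect_equal(lab[i, j], oracle)
  }
})

test_that("nucleus-free blobs are dropped; stranded nuclei become their own cell", {
  fg <- matrix(FALSE, 64, 64)
  fg <- draw_disc(fg, 16, 16, 10, TRUE)   # has a nucleus
  fg <- draw_disc(fg, 48, 48, 10, TRUE)   # no nucleus
  nuc <- draw_disc(matrix(0L, 64, 64), 16, 16, 4, 1L)
  lab <- watershed_cells(fg, nuc)
  expect_equal(sort(unique(lab[lab > 0])), 1L)
  expect_equal(max(lab[40:56, 40:56]), 0L)
  # nucleus entirely outside the foreground
  nuc2 <- draw_disc(nuc, 48, 16, 4, 2L)
  fg2 <- draw_disc(matrix(FALSE, 64, 64), 16, 16, 10, TRUE)
  expect_warning(lab2 <- watershed_cells(fg2, nuc2), "outside")
  expect_true(all(lab2[nuc2 == 2L] == 2L))
})

test_that("fish_foreground is empty on background and covers spot clusters", {
  set.seed(5)
  bgonly <- matrix(rpois(128^2, 100), 128, 128)
  expect_lt(mean(fish_foreground(bgonly)), 0.01)
  img <- matrix(100, 128, 128)
  rows <- runif(50, 40, 90); cols <- runif(50, 40, 90)
  for (k in 1:50)
    img <- img + 300 * render_spot(128, 128, rows[k], cols[k],
                                   A = 1, sigma = 1.5, b = 0)
  img <- matrix(rpois(128^2, img), 128, 128)
  mask <- fish_foreground(img)
  covered <- mask[cbind(round(rows), round(cols))]
  expect_gte(mean(covered), 0.95)
})

test_that("full segmentation recovers planted cells and its invariants hold", {
  sim <- fixture_sim()
  seg <- fixture_seg()
  expect_equal(seg$n_cells, sim$params$n_cells)
  expect_silent(smfishr:::check_segmentation_invariants(seg))
  iou <- segmentation_iou(seg, sim$truth$cell_labels)
  expect_gte(min(iou$iou), 0.8)
  # DAPI-only segmentation still finds every cell, with smaller areas
  dapi_only <- scene(list(dapi = scene_channel(sim$scene, "dapi")),
                     source_id = "dapi-only")
  seg2 <- segment(dapi_only)
  expect_equal(seg2$n_cells, sim$params$n_cells)
  expect_lt(sum(seg2$cells$area_px), sum(seg$cells$area_px))
})

test_that("cell count is invariant to uniform intensity scaling", {
  sim <- fixture_sim()
  scaled <- sim$scene
  scaled$channels <- lapply(scaled$channels, function(ch) ch * 3)
  seg3 <- segment(scaled)
  expect_equal(seg3$n_cells, fixture_seg()$n_cells)
})

test_that("a scene with no nuclei gives an empty result with a warning", {
  flat <- scene(list(dapi = matrix(5, 96, 96)))
  expect_warning(seg <- segment(flat), "no nuclei")
  expect_equal(seg$n_cells, 0L)
})
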