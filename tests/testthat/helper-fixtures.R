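# Shared fixtures, built in code and memoised per test run. The test
# geometry keeps the camera-native sampling (sigma_psf = 1.5 px, cell
# radius ~80-95 px) but a smaller field and fewer cells, so full-scene
# tests run in seconds.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

test_sim_params <- function(...) {
  sim_params(width = 768L, height = 768L, n_cells = 6L,
             cell_radius = c(80, 95), nucleus_radius = c(35, 45),
             genes = "IL1B", count_meanlog = log(40),
             count_sdlog = 0.4, lone_introns_per_cell = 4L, ...)
}

# one rendered scene + its segmentation, reused across test files
fixture_sim <- function() memo("sim", render_scene(test_sim_params(),
                                                   seed = 42))
fixture_seg <- function() memo("seg", segment(fixture_sim()$scene))

# a segmentation object wrapping ground-truth masks directly, for
# tests that need perfect cell assignment
truth_segmentation <- function(sim) {
  smfishr:::new_segmentation(sim$truth$nucleus_labels,
                             sim$truth$cell_labels,
                             smfish_config(),
                             source_id = sim$scene$source_id)
}

# draw a filled disc into a matrix
draw_disc <- function(m, r0, c0, radius, value = 1) {
  rows <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  cols <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  m[(rows - r0)^2 + (cols - c0)^2 <= radius^2] <- value
  m
}

# render one isotropic Gaussian spot on a constant background
render_spot <- function(nr = 21, nc = 21, r0 = 11, c0 = 11, A = 100,
                        sigma = 1.5, b = 10) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  b + A * exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * sigma^2))
}
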