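#' Phase congruency edge strength (log-Gabor formulation)
#'
#' Computes a dimensionless, contrast-invariant edge/feature strength
#' map in \[0, 1\] from local phase agreement across frequency scales,
#' using a bank of log-Gabor quadrature filters (geometric scale
#' spacing, raised-cosine angular spread) and Rayleigh-statistics noise
#' compensation. Because every term in the phase-congruency ratio is
#' linear in image intensity (including the data-driven noise
#' threshold), scaling the input by a positive constant leaves the map
#' unchanged; this is what makes it suitable for bright-field images
#' whose absolute intensity is arbitrary.
#'
#' @param image 2-D numeric matrix.
#' @param nscale Number of log-Gabor scales (default 4).
#' @param norient Number of filter orientations (default 6).
#' @param k Noise-compensation factor: threshold is the estimated mean
#'   noise energy plus `k` standard deviations (default 2).
#' @param min_wavelength Wavelength of the smallest-scale filter in
#'   pixels (default 3).
#' @param mult Scale multiplier between successive filters (default 2.1).
#' @param sigma_onf Ratio of the log-Gabor's standard deviation to its
#'   center frequency, on a log axis (default 0.55).
#' @return Matrix of edge strengths in \[0, 1\], same size as `image`.
#' @export
phase_congruency_edges <- function(image, nscale = 4L, norient = 6L,
                                   k = 2, min_wavelength = 3,
                                   mult = 2.1, sigma_onf = 0.55) {
  assert_image(image)
  nr <- nrow(image); nc <- ncol(image)
  eps <- 1e-4

  if (diff(range(image)) == 0) return(matrix(0, nr, nc))

  IM <- stats::fft(image)

  # Normalized frequency coordinates, zero frequency at [1, 1].
  fy <- ((seq_len(nr) - 1 + floor(nr / 2)) %% nr - floor(nr / 2)) / nr
  fx <- ((seq_len(nc) - 1 + floor(nc / 2)) %% nc - floor(nc / 2)) / nc
  u <- matrix(fx, nr, nc, byrow = TRUE)
  v <- matrix(fy, nr, nc)
  radius <- sqrt(u^2 + v^2)
  radius[1, 1] <- 1  # avoid log(0); DC handled by the filters being 0 there
  theta <- atan2(-v, u)
  sintheta <- sin(theta); costheta <- cos(theta)

  # Butterworth low-pass to suppress frequencies near Nyquist.
  lp <- 1 / (1 + (radius / 0.45)^(2 * 15))

  # Radial log-Gabor components per scale.
  log_gabor <- vector("list", nscale)
  for (s in seq_len(nscale)) {
    wavelength <- min_wavelength * mult^(s - 1)
    f0 <- 1 / wavelength
    lg <- exp(-(log(radius / f0))^2 / (2 * log(sigma_onf)^2)) * lp
    lg[1, 1] <- 0
    log_gabor[[s]] <- lg
  }

  d_theta_sigma <- 1.5  # angular spread: sigma = pi/norient * this
  theta_sigma <- pi / norient * d_theta_sigma

  total_energy <- matrix(0, nr, nc)
  total_sum_an <- matrix(0, nr, nc)

  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sintheta * cos(angl) - costheta * sin(angl)
    dc <- costheta * cos(angl) + sintheta * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))

    sum_e <- matrix(0, nr, nc); sum_o <- matrix(0, nr, nc)
    sum_an <- matrix(0, nr, nc)
    e_list <- vector("list", nscale); o_list <- vector("list", nscale)
    tau <- NULL

    for (s in seq_len(nscale)) {
      filt <- log_gabor[[s]] * spread
      eo <- stats::fft(IM * filt, inverse = TRUE) / (nr * nc)
      re <- Re(eo); im <- Im(eo)
      an <- sqrt(re^2 + im^2)
      sum_an <- sum_an + an
      sum_e <- sum_e + re
      sum_o <- sum_o + im
      e_list[[s]] <- re; o_list[[s]] <- im
      if (s == 1L) tau <- median(an) / sqrt(log(4))
    }

    x_energy <- sqrt(sum_e^2 + sum_o^2) + eps
    mean_e <- sum_e / x_energy
    mean_o <- sum_o / x_energy

    energy <- matrix(0, nr, nc)
    for (s in seq_len(nscale)) {
      energy <- energy + e_list[[s]] * mean_e + o_list[[s]] * mean_o -
        abs(e_list[[s]] * mean_o - o_list[[s]] * mean_e)
    }

    # Rayleigh noise model: expected total noise amplitude over scales
    # from the smallest-scale estimate tau.
    total_tau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sd <- total_tau * sqrt((4 - pi) / 2)
    t_noise <- noise_mean + k * noise_sd
    energy <- pmax(energy - t_noise, 0)

    total_energy <- total_energy + energy
    total_sum_an <- total_sum_an + sum_an
  }

  pc <- total_energy / (total_sum_an + eps)
  pmin(pmax(pc, 0), 1)
}
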