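# Count-distribution MLEs with AIC comparison, time-course summaries,
# correlations, and the supplementary-table ingest.

test_that("Poisson MLE equals the sample mean to machine precision", {
  expect_equal(fit_count_distribution(rep(5, 10), "poisson")$parameters$lambda,
               5)
  set.seed(1)
  x <- rpois(500, 37.2)
  fit <- fit_count_distribution(x, "poisson")
  expect_equal(fit$parameters$lambda, mean(x), tolerance = 1e-12)
  expect_error(fit_count_distribution(c(1.5, 2, 3), "poisson"),
               "integer")
  expect_error(fit_count_distribution(c(1, 2), "poisson"), "at least 3")
})

test_that("log-normal MLE matches the closed form on logs", {
  set.seed(2)
  x <- round(rlnorm(800, 4, 1))
  x <- x[x > 0]
  fit <- fit_count_distribution(x, "lognormal")
  expect_equal(fit$parameters$mu, mean(log(x)), tolerance = 1e-12)
  expect_equal(fit$parameters$sigma,
               sqrt(mean((log(x) - mean(log(x)))^2)), tolerance = 1e-12)
  # independent oracle: fitdistrplus MLE on the same sample
  skip_if_not_installed("fitdistrplus")
  or <- fitdistrplus::fitdist(as.numeric(x), "lnorm")
  expect_equal(fit$parameters$mu, unname(or$estimate["meanlog"]),
               tolerance = 1e-4)
  expect_equal(fit$parameters$sigma, unname(or$estimate["sdlog"]),
               tolerance = 1e-4)
  expect_equal(fit$loglik, or$loglik, tolerance = 1e-6)
})

test_that("gamma shape is recovered by the Newton iteration", {
  set.seed(3)
  x <- rgamma(2000, shape = 2, scale = 30)
  fit <- fit_count_distribution(x, "gamma")
  expect_gt(fit$parameters$shape, 1.8)
  expect_lt(fit$parameters$shape, 2.2)
  expect_equal(fit$parameters$shape * fit$parameters$scale, mean(x),
               tolerance = 1e-9)  # MLE preserves the mean
  skip_if_not_installed("fitdistrplus")
  or <- fitdistrplus::fitdist(x, "gamma")
  expect_equal(fit$parameters$shape, unname(or$estimate["shape"]),
               tolerance = 1e-3)
  expect_equal(fit$loglik, or$loglik, tolerance = 1e-4)
})

test_that("zeros are excluded for the positive families, with a note", {
  x <- c(0, 0, 0, 5, 9, 14, 22)
  fit <- fit_count_distribution(x, "lognormal")
  expect_equal(fit$n_cells, 4L)
  expect_equal(fit$zero_fraction, 3 / 7)
  expect_match(fit$note, "positive")
  expect_error(fit_count_distribution(c(0, 0, 0, 1, 2), "gamma"),
               "positive")
})

test_that("overdispersed counts prefer log-normal and gamma over Poisson", {
  set.seed(4)
  x <- round(rlnorm(1000, 4, 1))
  cmp <- compare_count_fits(x)
  aic <- setNames(cmp$AIC, cmp$family)
  expect_lt(aic["lognormal"], aic["poisson"])
  expect_lt(aic["gamma"], aic["poisson"])
  expect_gt(var(x) / mean(x), 5)  # index of dispersion: bursting regime
  expect_equal(cmp$delta_aic[1], 0)
  # tidy/glance accessors
  fit <- cmp$fit[[1]]
  expect_named(tidy(fit), c("term", "estimate"))
  expect_equal(glance(fit)$AIC, fit$aic)
})

test_that("time-course summary separates cell mean from scan-level error", {
  tab <- tibble::tibble(
    source_id = "x", condition = "LPS", time_minutes = 60,
    scan_id = rep(c("a", "b"), each = 4), cell_id = 1:8,
    area_px = 100, nucleus_area_px = 10, border_flag = FALSE,
    anomaly_flag = FALSE, count_G = c(10, 10, 10, 10, 20, 20, 20, 20))
  s <- timecourse_summary(tab, "count_G")
  expect_equal(s$mean, 15)
  expect_equal(s$scan_sd, sd(c(10, 20)), tolerance = 1e-9)
  expect_equal(s$n_scans, 2L)
  # unequal scan sizes: grand mean is cell-weighted
  tab2 <- tab[c(1, 5:8), ]
  expect_equal(timecourse_summary(tab2, "count_G")$mean, 18)
  # single scan: no error value
  expect_true(is.na(timecourse_summary(tab[1:4, ], "count_G")$scan_sd))
  expect_error(timecourse_summary(tab, "count_NOPE"), "no column")
})

test_that("Pearson correlation handles exact, degenerate and grouped input", {
  tab <- tibble::tibble(
    condition = "LPS", time_minutes = rep(c(0, 60), each = 10),
    x = c(1:10, 1:10), y = c(2 * (1:10) + 1, rep(4, 10)))
  out <- correlate(tab, "x", "y")
  r0 <- out$r[out$time_minutes == 0]
  expect_equal(r0, 1)
  expect_true(is.na(out$r[out$time_minutes == 60]))
  expect_match(out$reason[out$time_minutes == 60], "zero variance")
  # affine invariance with positive slope
  tab$y2 <- 100 + 3 * tab$y
  out2 <- correlate(tab, "x", "y2")
  expect_equal(out2$r[out2$time_minutes == 0], r0)
  # pairwise-complete exclusion of missing cells
  tab$y[1] <- NA
  out3 <- correlate(tab[tab$time_minutes == 0, ], "x", "y")
  expect_equal(out3$n_cells, 9L)
})

test_that("planted copula correlation is recovered at n = 500", {
  for (rho in c(0, 0.36, 0.8)) {
    cnt <- sample_counts(sim_params(rho = rho), n_cells = 500,
                         seed = 17)
    r <- copula_correlation(cnt$IL1B, cnt$TNFA)
    se <- 1 / sqrt(500 - 3)
    expect_lt(abs(atanh(r) - atanh(rho)), 3 * se)
  }
})

test_that("area correlation flags the size confound without inflating it", {
  set.seed(6)
  n <- 400
  area <- runif(n, 3e4, 7e4)
  tab <- tibble::tibble(
    condition = "LPS", time_minutes = 60, area_px = area,
    count_G = rpois(n, 50),                    # independent of area
    count_H = round(0.002 * area))             # purely size-driven
  null_r <- area_correlation(tab, "G")$r
  expect_lt(abs(null_r), 3 / sqrt(n))
  expect_gt(area_correlation(tab, "H")$r, 0.999)
})

test_that("a CSV sheet directory ingests through the declared sheet map", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(`IL1B mRNA` = c(10, 20, 30),
                       `TNFA mRNA` = c(1, 2, 3),
                       Area = c(100, 200, 300), check.names = FALSE),
            file.path(dir, "t0.csv"), row.names = FALSE)
  write.csv(data.frame(`IL1B mRNA` = c(5, 6), `TNFA mRNA` = c(7, 8),
                       Area = c(10, 20), check.names = FALSE),
            file.path(dir, "t60.csv"), row.names = FALSE)
  map <- list(
    t0 = list(cols = c(count_IL1B = "IL1B mRNA",
                       count_TNFA = "TNFA mRNA", area_px = "Area"),
              condition = "LPS", time_minutes = 0),
    t60 = list(cols = c(count_IL1B = "IL1B mRNA",
                        count_TNFA = "TNFA mRNA", area_px = "Area"),
               condition = "LPS", time_minutes = 60))
  tab <- ingest_supplementary_table(dir, map)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$count_IL1B[tab$time_minutes == 0], c(10, 20, 30))
  expect_equal(mean(tab$count_TNFA[tab$time_minutes == 60]), 7.5)
  expect_error(
    ingest_supplementary_table(dir, list(nope = map$t0)),
    "t0, t60")  # error lists the sheets that were found
  expect_error(
    ingest_supplementary_table(
      dir, list(t0 = list(cols = c(count_IL1B = "Missing")))),
    "lacks column")
})

test_that("an xlsx workbook ingests identically to its CSV twin", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  dir <- withr::local_tempdir()
  xlsx <- file.path(dir, "raw.xlsx")
  code <- sprintf("
import openpyxl
wb = openpyxl.Workbook()
ws = wb.active; ws.title = 't0'
ws.append(['IL1B mRNA', 'TNFA mRNA'])
for r in [[10, 1], [20, 2], [30, 3]]: ws.append(r)
ws2 = wb.create_sheet('t60')
ws2.append(['IL1B mRNA', 'TNFA mRNA'])
for r in [[5, 7], [6, 8]]: ws2.append(r)
wb.save(r'%s')
", xlsx)
  res <- system2(py, c("-c", shQuote(code)))
  skip_if(res != 0, "openpyxl unavailable")
  map <- list(
    t0 = list(cols = c(count_IL1B = "IL1B mRNA",
                       count_TNFA = "TNFA mRNA"),
              condition = "LPS", time_minutes = 0),
    t60 = list(cols = c(count_IL1B = "IL1B mRNA",
                        count_TNFA = "TNFA mRNA"),
               condition = "LPS", time_minutes = 60))
  tab <- ingest_supplementary_table(xlsx, map)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$count_IL1B[tab$time_minutes == 0], c(10, 20, 30))
  expect_equal(mean(tab$count_IL1B[tab$time_minutes == 60]), 5.5)
  # statistics stages run directly on the ingested table
  s <- timecourse_summary(tab, "count_IL1B")
  expect_equal(s$mean[s$time_minutes == 0], 20)
})
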