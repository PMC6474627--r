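#' Maximum-likelihood fit of a per-cell count distribution
#'
#' Fits one of three families to single-cell counts and reports the
#' log-likelihood and AIC (`2 k - 2 logL`). Bursting gene expression
#' produces heavy-tailed, overdispersed counts that log-normal and
#' gamma describe well and Poisson describes poorly; the AIC ordering
#' quantifies that.
#'
#' MLEs: Poisson `lambda` = sample mean; log-normal `mu`, `sigma` from
#' the mean and (1/n-denominator) SD of log counts; gamma shape by
#' Newton iteration on `log(k) - digamma(k) = log(mean) - mean(log)`
#' with moment initialization, scale = mean/shape. Log-normal and
#' gamma are fit on the positive counts only, with the zero fraction
#' reported; use [compare_count_fits()] to compare families on an
#' identical (positive-restricted) sample.
#'
#' @param counts Numeric vector of per-cell counts (>= 3 values; >= 3
#'   positive for lognormal/gamma; integers for Poisson).
#' @param family One of `"poisson"`, `"lognormal"`, `"gamma"`.
#' @return Object of class `smfish_fit` with fields `family`,
#'   `parameters` (named list), `loglik`, `aic`, `n_cells`,
#'   `zero_fraction` and `note`.
#' @export
fit_count_distribution <- function(counts,
                                   family = c("poisson", "lognormal",
                                              "gamma")) {
  family <- match.arg(family)
  counts <- counts[!is.na(counts)]
  if (length(counts) < 3L)
    stop("need at least 3 counts", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  zero_frac <- mean(counts == 0)

  if (family == "poisson") {
    if (any(abs(counts - round(counts)) > 1e-8))
      stop("Poisson likelihood requires integer counts", call. = FALSE)
    lambda <- mean(counts)
    ll <- sum(dpois(round(counts), lambda, log = TRUE))
    return(new_count_fit(family, list(lambda = lambda), ll, 1L,
                         length(counts), zero_frac,
                         "fit on all counts including zeros"))
  }

  x <- counts[counts > 0]
  if (length(x) < 3L)
    stop("need at least 3 positive counts for ", family, call. = FALSE)
  note <- if (zero_frac > 0)
    sprintf("fit on the %d positive counts (zero fraction %.3f)",
            length(x), zero_frac) else "fit on all counts (none zero)"

  if (family == "lognormal") {
    lx <- log(x)
    mu <- mean(lx)
    sigma <- sqrt(mean((lx - mu)^2))
    ll <- sum(dlnorm(x, mu, sigma, log = TRUE))
    return(new_count_fit(family, list(mu = mu, sigma = sigma), ll, 2L,
                         length(x), zero_frac, note))
  }

  # gamma: Newton on the shape from the log-mean relation
  s <- log(mean(x)) - mean(log(x))
  m <- mean(x); v <- var(x)
  k <- if (v > 0) m^2 / v else 1 / (2 * s)
  for (i in 1:50) {
    step <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * k) { k <- k_new; break }
    k <- k_new
  }
  theta <- m / k
  ll <- sum(dgamma(x, shape = k, scale = theta, log = TRUE))
  new_count_fit("gamma", list(shape = k, scale = theta), ll, 2L,
                length(x), zero_frac, note)
}

new_count_fit <- function(family, parameters, loglik, n_params,
                          n_cells, zero_fraction, note) {
  aic <- 2 * n_params - 2 * loglik
  if (n_cells >= 3L && !is.finite(aic))
    stop("non-finite AIC for ", family, " fit", call. = FALSE)
  structure(list(family = family, parameters = parameters,
                 loglik = loglik, n_params = n_params, aic = aic,
                 n_cells = n_cells, zero_fraction = zero_fraction,
                 note = note),
            class = "smfish_fit")
}

#' @export
print.smfish_fit <- function(x, ...) {
  cat("<smfish_fit> ", x$family, ": ",
      paste(names(x$parameters), signif(unlist(x$parameters), 4),
            sep = " = ", collapse = ", "),
      "; AIC ", signif(x$aic, 6), " (n = ", x$n_cells, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.smfish_fit <- function(x, ...) {
  tibble(term = names(x$parameters),
         estimate = unlist(x$parameters, use.names = FALSE))
}

#' @export
glance.smfish_fit <- function(x, ...) {
  tibble(family = x$family, logLik = x$loglik, AIC = x$aic,
         nobs = x$n_cells, zero_fraction = x$zero_fraction)
}

#' Compare count-distribution families on one sample
#'
#' Fits every requested family to the same positive-restricted sample
#' (zeros are dropped for all families alike, so AICs are comparable)
#' and returns them ranked by AIC.
#'
#' @param counts Per-cell counts.
#' @param families Character vector of families to fit.
#' @return Tibble: family, parameter estimates (list column `fit`),
#'   logLik, AIC, delta_aic; ordered by AIC.
#' @export
compare_count_fits <- function(counts,
                               families = c("poisson", "lognormal",
                                            "gamma")) {
  counts <- counts[!is.na(counts) & counts > 0]
  fits <- purrr::map(families, ~ fit_count_distribution(counts, .x))
  out <- purrr::map_dfr(fits, glance)
  out$fit <- fits
  out <- dplyr::arrange(out, .data$AIC)
  out$delta_aic <- out$AIC - out$AIC[1]
  out
}

#' Time-course summary with scan-level error bars
#'
#' For each group (by default each condition x time point): the grand
#' mean of `variable` over all cells (cell-weighted), the per-scan
#' means, and the standard deviation across scan means as the error
#' estimate — the error bar is the scan-to-scan reproducibility, not
#' the (much broader) single-cell spread. A group measured by a single
#' scan has no error value (NA).
#'
#' @param cell_table A cell-table tibble carrying `scan_id`.
#' @param variable Column name to summarise (string).
#' @param group_keys Grouping columns (default condition and time).
#' @return Tibble: group keys, `n_cells`, `n_scans`, `mean`
#'   (cell-weighted grand mean), `scan_sd`, and a `scan_means` list
#'   column.
#' @export
timecourse_summary <- function(cell_table, variable,
                               group_keys = c("condition",
                                              "time_minutes")) {
  if (!variable %in% names(cell_table))
    stop("no column '", variable, "' in cell table", call. = FALSE)
  if (!"scan_id" %in% names(cell_table))
    stop("cell table has no scan_id column", call. = FALSE)
  cell_table |>
    dplyr::filter(!is.na(.data[[variable]])) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_keys))) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_scans = dplyr::n_distinct(.data$scan_id),
      mean = mean(.data[[variable]]),
      scan_means = list(tapply(.data[[variable]], .data$scan_id, mean)),
      .groups = "drop") |>
    dplyr::mutate(
      scan_sd = purrr::map_dbl(.data$scan_means, ~ {
        if (length(.x) < 2L) NA_real_ else sd(.x)
      }),
      variable = variable, .before = 1)
}

#' Pairwise single-cell correlation
#'
#' Pearson correlation of two per-cell variables on their raw values,
#' per group; cells with a missing value in either variable are
#' excluded pairwise. Zero-variance input yields NA with an
#' explanatory reason rather than an error.
#'
#' @param cell_table A cell-table tibble.
#' @param var_x,var_y Column names (strings).
#' @param group_keys Grouping columns (default condition and time).
#' @param spearman Also report Spearman's rank correlation.
#' @return Tibble: group keys, `var_x`, `var_y`, `n_cells`, `r`,
#'   optional `rho`, `reason` (NA when defined).
#' @export
correlate <- function(cell_table, var_x, var_y,
                      group_keys = c("condition", "time_minutes"),
                      spearman = FALSE) {
  for (v in c(var_x, var_y))
    if (!v %in% names(cell_table))
      stop("no column '", v, "' in cell table", call. = FALSE)
  out <- cell_table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_keys))) |>
    dplyr::summarise(
      var_x = var_x, var_y = var_y,
      res = list(pearson_or_reason(.data[[var_x]], .data[[var_y]],
                                   spearman)),
      .groups = "drop") |>
    tidyr::unnest_wider("res")
  out
}

pearson_or_reason <- function(x, y, spearman = FALSE) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  base <- list(n_cells = n, r = NA_real_, reason = NA_character_)
  if (spearman) base$rho <- NA_real_
  if (n < 3L) { base$reason <- "fewer than 3 complete cells"; return(base) }
  if (var(x) == 0 || var(y) == 0) {
    base$reason <- "zero variance"
    return(base)
  }
  base$r <- cor(x, y)
  if (spearman) base$rho <- cor(x, y, method = "spearman")
  base
}

#' Normal-scores estimate of a Gaussian-copula correlation
#'
#' Pearson correlation computed on the normal scores
#' `qnorm((rank - 0.5) / n)` of each variable. Raw Pearson on
#' heavy-tailed counts is attenuated toward zero relative to the
#' copula correlation that generated the dependence (for log-normal
#' marginals with log-SD `s`, population Pearson is
#' `(exp(rho s^2) - 1) / (exp(s^2) - 1)`), whereas the normal-scores
#' correlation is invariant to the monotone marginal transform and so
#' estimates the copula parameter itself.
#'
#' @param x,y Paired numeric vectors.
#' @return Scalar correlation estimate (NA if degenerate).
#' @export
copula_correlation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(qnorm((rank(x) - 0.5) / n), qnorm((rank(y) - 0.5) / n))
}

#' Cell-area versus count correlation (size-confound control)
#'
#' Larger cells hold more transcripts of any gene, so some mRNA-mRNA
#' correlation is expected from size alone. This reports the Pearson
#' correlation between `area_px` and the per-cell count of one gene,
#' per group, for comparison against the gene-gene correlations.
#'
#' @param cell_table A cell-table tibble with `area_px`.
#' @param gene Gene name whose `count_<gene>` column is used.
#' @param group_keys Grouping columns.
#' @return As [correlate()].
#' @export
area_correlation <- function(cell_table, gene,
                             group_keys = c("condition",
                                            "time_minutes")) {
  correlate(cell_table, "area_px", paste0("count_", gene), group_keys)
}

#' Ingest a per-cell supplementary workbook into a cell table
#'
#' Reads a spreadsheet (xlsx) or a directory of per-sheet CSV files of
#' raw per-cell measurements into the package's cell-table schema, so
#' the statistics stages run on published per-cell data exactly as on
#' pipeline output. The layout is declared, not guessed: `sheet_map`
#' is a named list with one entry per sheet, each entry a list with
#' \describe{
#'   \item{cols}{Named character vector mapping cell-table columns to
#'     sheet column names, e.g.
#'     `c(count_IL1B = "IL1B mRNA", area_px = "Cell area")`.}
#'   \item{condition, time_minutes, scan_id}{Constants for the sheet,
#'     or (as a one-element character vector) a sheet column name.}
#' }
#'
#' @param path Path to an `.xlsx` workbook or a directory of
#'   `<sheet>.csv` files.
#' @param sheet_map Layout declaration as above.
#' @return A validated cell-table tibble (one row per cell).
#' @export
ingest_supplementary_table <- function(path, sheet_map) {
  if (!length(sheet_map) || is.null(names(sheet_map)))
    stop("sheet_map must be a named list with one entry per sheet",
         call. = FALSE)
  if (dir.exists(path)) {
    found <- sub("\\.csv$", "", list.files(path, pattern = "\\.csv$"))
    reader <- function(sheet)
      as_tibble(read.csv(file.path(path, paste0(sheet, ".csv")),
                         check.names = FALSE))
  } else if (file.exists(path)) {
    found <- readxl::excel_sheets(path)
    reader <- function(sheet)
      readxl::read_excel(path, sheet = sheet, .name_repair = "minimal")
  } else stop("no such file or directory: ", path, call. = FALSE)
  if (!length(found)) stop("workbook is empty", call. = FALSE)

  missing <- setdiff(names(sheet_map), found)
  if (length(missing))
    stop("sheet(s) not found: ", paste(missing, collapse = ", "),
         "; workbook contains: ", paste(found, collapse = ", "),
         call. = FALSE)

  purrr::imap_dfr(sheet_map, function(spec, sheet) {
    df <- reader(sheet)
    cols <- spec$cols
    bad <- setdiff(unname(cols), names(df))
    if (length(bad))
      stop("sheet '", sheet, "' lacks column(s): ",
           paste(bad, collapse = ", "), "; found: ",
           paste(names(df), collapse = ", "), call. = FALSE)
    out <- tibble(.rows = nrow(df))
    for (i in seq_along(cols))
      out[[names(cols)[i]]] <- as.numeric(df[[cols[i]]])
    out$source_id <- sheet
    out$cell_id <- seq_len(nrow(df))
    for (key in c("condition", "time_minutes", "scan_id")) {
      v <- spec[[key]]
      out[[key]] <- if (is.character(v) && length(v) == 1L &&
                        v %in% names(df)) df[[v]] else v %||%
          switch(key, condition = "none", time_minutes = 0,
                 scan_id = "s1")
    }
    if (!"area_px" %in% names(out)) out$area_px <- NA_real_
    if (!"nucleus_area_px" %in% names(out))
      out$nucleus_area_px <- NA_real_
    out$border_flag <- FALSE
    out$anomaly_flag <- FALSE
    out
  }) |> validate_cell_table()
}
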