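# Per-cell record tables. One row per segmented cell; core descriptor
# columns are fixed, measurement columns are per-channel and wide:
#   count_<gene>, nuclear_<gene>, cyto_<gene>      mRNA spot counts
#   bursts_<gene>, burst_copies_<gene>             burst sites / summed copies
#   protein_mean_<gene>, protein_integrated_<gene> antibody signal
# A channel that was not measured is NA (empty CSV field), never 0.

cell_table_core_cols <- c(
  "source_id", "condition", "time_minutes", "scan_id", "cell_id",
  "area_px", "nucleus_area_px", "border_flag", "anomaly_flag")

measure_col_rx <- paste0(
  "^(count|nuclear|cyto|bursts|burst_copies|protein_mean|",
  "protein_integrated)_")

validate_cell_table <- function(records) {
  records <- as_tibble(records)
  missing <- setdiff(cell_table_core_cols, names(records))
  if (length(missing))
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(records), cell_table_core_cols)
  bad <- extra[!grepl(measure_col_rx, extra)]
  if (length(bad))
    stop("unrecognised cell-table column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(records$time_minutes < 0, na.rm = TRUE))
    stop("time_minutes must be >= 0", call. = FALSE)
  num_cols <- setdiff(names(records),
                      c("source_id", "condition", "scan_id"))
  for (cl in num_cols)
    if (!is.numeric(records[[cl]]) && !is.logical(records[[cl]]))
      stop("cell-table column '", cl, "' must be numeric", call. = FALSE)
  records
}

#' Write / read a per-cell record table (CSV)
#'
#' The CSV has the fixed core columns (`source_id`, `condition`,
#' `time_minutes`, `scan_id`, `cell_id`, `area_px`, `nucleus_area_px`,
#' `border_flag`, `anomaly_flag`) plus per-channel measurement columns.
#' Missing measurements are written as empty fields (absent, not zero).
#' `read_cell_table(write_cell_table(x))` returns `x` unchanged.
#'
#' @param records A cell-table tibble (see [build_cell_table()]).
#' @param path CSV path.
#' @return `write_cell_table` returns `path` invisibly;
#'   `read_cell_table` returns a validated tibble.
#' @export
write_cell_table <- function(records, path) {
  records <- validate_cell_table(records)
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(source_id = "character",
                                condition = "character",
                                scan_id = "character"))
  df$border_flag <- as.logical(df$border_flag)
  df$anomaly_flag <- as.logical(df$anomaly_flag)
  validate_cell_table(df)
}

#' Read / write an experiment manifest (CSV)
#'
#' A manifest maps image files to experimental coordinates. Columns:
#' `path`, `condition`, `time_minutes`, `scan_id`, plus one column per
#' channel role (e.g. `dapi`, `brightfield`, `fish.IL1B`) giving the
#' TIFF page index of that role (NA if the role is absent from that
#' image). Scan ids must be unique within each (condition, time).
#'
#' @param manifest Tibble in the layout above.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE))
  validate_manifest(df)
  df
}

validate_manifest <- function(manifest) {
  need <- c("path", "condition", "time_minutes", "scan_id")
  missing <- setdiff(need, names(manifest))
  if (length(missing))
    stop("manifest missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(manifest$time_minutes < 0))
    stop("manifest time_minutes must be >= 0", call. = FALSE)
  dup <- manifest |>
    dplyr::count(.data$condition, .data$time_minutes, .data$scan_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup))
    stop("manifest scan ids are not unique within (condition, time)",
         call. = FALSE)
  invisible(manifest)
}

# Extract the channel-role -> page map for one manifest row. Role
# columns are every column beyond the required four; CSV headers use
# '.' where roles use ':' (fish.IL1B <-> fish:IL1B).
manifest_role_map <- function(manifest_row) {
  roles <- setdiff(names(manifest_row),
                   c("path", "condition", "time_minutes", "scan_id"))
  pages <- unlist(manifest_row[roles])
  pages <- pages[!is.na(pages)]
  setNames(as.integer(pages), sub("\\.", ":", names(pages)))
}

#' Write / read an integer label mask as 16-bit TIFF
#'
#' Labels up to 65535 round-trip exactly.
#'
#' @param labels Integer label matrix (0 = background).
#' @param path TIFF path.
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535L)
    stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}
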