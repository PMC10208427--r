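#' Montage quality-control filter
#'
#' Gaps or discontinuities exclude all connected cells: any cell 4-connected
#' to a gap pixel is dropped.  When gaps exceed `gap_fraction_max` of the
#' total raster area (8% by default) the whole montage is rejected and every
#' cell is excluded.  Cells touching the image border are flagged and never
#' enter polygon or area statistics (their sidedness is unknowable), but are
#' not "excluded" in the QC sense.  The filter is idempotent.
#'
#' @param cells an `epi_cells` collection.
#' @param gap_fraction_max montage rejection threshold on the gap area
#'   fraction.
#' @return a list with `cells` (the collection with `excluded` flags set) and
#'   `report`, an `epi_qc_report` with `gap_fraction`, `excluded_cells`
#'   (label + reason) and `montage_pass`.
#' @export
qc_filter <- function(cells, gap_fraction_max = 0.08) {
  stopifnot(inherits(cells, "epi_cells"))
  df <- cells$cells
  df$excluded <- FALSE
  df$exclude_reason <- ""
  if (cells$gap_fraction > gap_fraction_max) {
    df$excluded <- TRUE
    df$exclude_reason <- "montage gap fraction above threshold"
    pass <- FALSE
  } else {
    df$excluded <- df$touches_gap
    df$exclude_reason[df$excluded] <- "connected to gap"
    pass <- TRUE
  }
  cells$cells <- df
  report <- structure(list(
    gap_fraction = cells$gap_fraction,
    gap_fraction_max = gap_fraction_max,
    excluded_cells = df[df$excluded, c("label", "exclude_reason")],
    montage_pass = pass), class = "epi_qc_report")
  list(cells = cells, report = report)
}

#' @export
print.epi_qc_report <- function(x, ...) {
  cat(sprintf("<epi_qc_report> gap %.2f%% (max %.2f%%): %s; %d cells excluded\n",
              100 * x$gap_fraction, 100 * x$gap_fraction_max,
              if (x$montage_pass) "PASS" else "REJECTED",
              nrow(x$excluded_cells)))
  invisible(x)
}

valid_cells <- function(cells) {
  df <- cells$cells
  df[!df$excluded & !df$touches_border, , drop = FALSE]
}

#' Polygon-class distribution
#'
#' Relative frequency of cells by number of sides, over valid cells (not
#' excluded by QC and not touching the image border), together with the
#' topological balance deviation `|sum(freq, n < 6) - sum(freq, n > 6)|`:
#' in a trivalent tessellation with hexagonal mean the frequencies of
#' sub-hexagonal and super-hexagonal cells are expected to balance.
#'
#' @param x an `epi_cells` collection, an `epi_tessellation`, or an integer
#'   vector of polygon classes.
#' @param ... unused.
#' @return an `epi_polygon_distribution`: `freq` (named numeric, sums to 1),
#'   `balance_deviation` in `[0, 1]`, `n_cells`.
#' @export
polygon_distribution <- function(x, ...) UseMethod("polygon_distribution")

#' @export
polygon_distribution.epi_cells <- function(x, ...) {
  df <- valid_cells(x)
  if (!nrow(df)) .stop_invalid("no valid cells")
  polygon_distribution(df$n_sides)
}

#' @export
polygon_distribution.epi_tessellation <- function(x, ...) {
  polygon_distribution(polygon_classes(x))
}

#' @export
polygon_distribution.default <- function(x, ...) {
  n <- as.integer(x)
  if (!length(n)) .stop_invalid("no valid cells")
  tab <- table(n)
  freq <- as.numeric(tab) / length(n)
  names(freq) <- names(tab)
  ns <- as.integer(names(freq))
  structure(list(freq = freq,
                 balance_deviation = abs(sum(freq[ns < 6]) - sum(freq[ns > 6])),
                 n_cells = length(n)),
            class = "epi_polygon_distribution")
}

#' @export
print.epi_polygon_distribution <- function(x, ...) {
  cat(sprintf("<epi_polygon_distribution> %d cells, balance deviation %.2f%%\n",
              x$n_cells, 100 * x$balance_deviation))
  print(round(x$freq, 4))
  invisible(x)
}

#' Cell-area morphometry
#'
#' Mean, median, interquartile range and extremes of valid-cell areas in
#' square micrometers.
#'
#' @param x an `epi_cells` collection or a numeric vector of areas (um^2).
#' @param ... unused.
#' @return an `epi_area_stats` list: `mean`, `median`, `iqr`, `min`, `max`,
#'   `n_cells`.
#' @export
area_stats <- function(x, ...) UseMethod("area_stats")

#' @export
area_stats.epi_cells <- function(x, ...) {
  df <- valid_cells(x)
  if (!nrow(df)) .stop_invalid("no valid cells")
  area_stats(df$area_um2)
}

#' @export
area_stats.default <- function(x, ...) {
  a <- as.numeric(x)
  if (!length(a)) .stop_invalid("no valid cells")
  structure(list(mean = mean(a), median = median(a),
                 iqr = unname(quantile(a, 0.75) - quantile(a, 0.25)),
                 min = min(a), max = max(a), n_cells = length(a)),
            class = "epi_area_stats")
}

#' @export
print.epi_area_stats <- function(x, ...) {
  cat(sprintf(
    "<epi_area_stats> n = %d: mean %.2f, median %.2f, IQR %.2f, range [%.2f, %.2f] um^2\n",
    x$n_cells, x$mean, x$median, x$iqr, x$min, x$max))
  invisible(x)
}

#' @export
print.epi_cells <- function(x, ...) {
  df <- x$cells
  cat(sprintf(
    "<epi_cells> %d cells (%d border, %d gap-adjacent, %d excluded), gap %.2f%%\n",
    nrow(df), sum(df$touches_border), sum(df$touches_gap), sum(df$excluded),
    100 * x$gap_fraction))
  invisible(x)
}
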