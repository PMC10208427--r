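#' Border polyline helpers
#'
#' Borders are ordered 2-column coordinate matrices (micrometers) running
#' from one junction vertex to the other.  `arc_length` is the traced length,
#' `chord_length` the straight vertex-to-vertex distance.
#'
#' @param pts 2-column coordinate matrix.
#' @name border-polyline
NULL

#' @rdname border-polyline
#' @export
arc_length <- function(pts) {
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' @rdname border-polyline
#' @export
chord_length <- function(pts) {
  sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
}

#' Smooth a pixel-chain polyline
#'
#' Resamples at uniform arc spacing and moving-averages the coordinates,
#' removing the rasterization staircase (which otherwise inflates traced arc
#' lengths by up to ~27% on diagonal runs and injects spurious pixel-scale
#' extrema).  Endpoints are preserved.
#'
#' @param pts 2-column coordinate matrix (um).
#' @param window_um moving-average window along the arc, um.
#' @param spacing resampling spacing, um.
#' @return the smoothed polyline matrix.
#' @export
smooth_polyline <- function(pts, window_um, spacing = 0.25) {
  pts <- resample_polyline(pts, spacing)
  w <- round(window_um / spacing)
  if (w >= 2 && nrow(pts) > w + 2) {
    kern <- rep(1 / w, w)
    sx <- as.numeric(stats::filter(pts[, 1], kern, sides = 2))
    sy <- as.numeric(stats::filter(pts[, 2], kern, sides = 2))
    keep <- !is.na(sx)
    mid <- cbind(sx[keep], sy[keep])
    pts <- rbind(pts[1, ], mid, pts[nrow(pts), ])
  }
  pts
}

# resample a polyline at (approximately) uniform arc-length spacing
resample_polyline <- function(pts, spacing) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(pts[1, , drop = FALSE])
  m <- max(2L, ceiling(total / spacing) + 1L)
  si <- seq(0, total, length.out = m)
  cbind(approx(s, pts[, 1], xout = si)$y, approx(s, pts[, 2], xout = si)$y)
}

#' Redundancy index of a cell border
#'
#' The traced border length divided by the straight distance between its two
#' junction vertices; 1.0 is a straight border without interdigitation.
#'
#' @param border 2-column coordinate matrix (um), vertex to vertex.
#' @return the index, a number >= 1.
#' @export
#' @examples
#' redundancy_index(cbind(seq(0, 10, length.out = 100), 0))   # 1.0
redundancy_index <- function(border) {
  border <- as.matrix(border)
  if (nrow(border) < 2) .stop_invalid("border needs at least 2 points")
  ch <- chord_length(border)
  if (ch <= 0)
    .stop_invalid("undefined chord: border endpoints coincide (closed loop)")
  arc_length(border) / ch
}

# local maxima with topographic prominence >= threshold
count_prominent_peaks <- function(s, prominence) {
  n <- length(s)
  if (n < 3) return(0L)
  peaks <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] > s[3:n]) + 1L
  # plateau maxima: rising into a flat run that then falls
  flat <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] == s[3:n]) + 1L
  for (i in flat) {
    j <- i
    while (j < n && s[j + 1] == s[i]) j <- j + 1
    if (j < n && s[j + 1] < s[i]) peaks <- c(peaks, i)
  }
  peaks <- sort(unique(peaks))
  cnt <- 0L
  for (i in peaks) {
    j <- i; lb <- s[i]
    while (j > 1 && s[j] <= s[i]) { lb <- min(lb, s[j]); j <- j - 1 }
    if (s[j] <= s[i]) lb <- min(lb, s[j])
    j <- i; rb <- s[i]
    while (j < n && s[j] <= s[i]) { rb <- min(rb, s[j]); j <- j + 1 }
    if (s[j] <= s[i]) rb <- min(rb, s[j])
    if (s[i] - max(lb, rb) >= prominence) cnt <- cnt + 1L
  }
  cnt
}

#' Count border interdigitations (peaks)
#'
#' Computes the signed perpendicular deviation of the border from its chord,
#' parameterized by arc position, smooths it with a moving average of width
#' `smooth_window`, and counts local extrema of either sign whose topographic
#' prominence reaches `prominence`.  Extrema of both signs count because the
#' fingers of the two cells alternate: one full sine period contributes two
#' interdigitations.
#'
#' @param border 2-column coordinate matrix (um).
#' @param smooth_window moving-average window along the arc, um.
#' @param prominence minimum peak prominence, um.
#' @param resample_spacing spacing (um) at which pixel-chain borders are
#'   resampled before analysis, decoupling the count from rasterization.
#' @return integer peak count (0 for a straight border).
#' @export
count_interdigitations <- function(border, smooth_window = 1,
                                   prominence = 0.5,
                                   resample_spacing = 0.25) {
  border <- as.matrix(border)
  if (nrow(border) < 2) .stop_invalid("border needs at least 2 points")
  ch <- chord_length(border)
  if (ch <= 0) .stop_invalid("undefined chord: endpoints coincide")
  if (smooth_window >= ch)
    .stop_invalid("invalid-argument: smooth_window must be smaller than the chord")
  pts <- resample_polyline(border, resample_spacing)
  a <- pts[1, ]; b <- pts[nrow(pts), ]
  u <- (b - a) / ch
  dev <- (pts[, 1] - a[1]) * (-u[2]) + (pts[, 2] - a[2]) * u[1]
  w <- max(1L, round(smooth_window / resample_spacing))
  if (w > 1L) {
    kern <- rep(1 / w, w)
    dev <- as.numeric(stats::filter(dev, kern, sides = 2))
    dev[is.na(dev)] <- 0
  }
  count_prominent_peaks(dev, prominence) + count_prominent_peaks(-dev, prominence)
}

#' Interdigitation metrics for every border of a cell collection
#'
#' @param cells an `epi_cells` collection from [extract_cells()].
#' @param smooth_window,prominence,resample_spacing see
#'   [count_interdigitations()].
#' @param polyline_smooth coordinate smoothing window (um) applied to the
#'   traced pixel-chain borders before any metric; defaults to 4 pixels,
#'   enough to cancel the rasterization staircase.
#' @param valid_only drop borders involving excluded or image-border cells.
#' @return data frame with one row per border: `cell_a`, `cell_b`,
#'   `side_length_um` (chord), `arc_length_um`, `peak_count`,
#'   `redundancy_index`.
#' @export
analyze_borders <- function(cells, smooth_window = 1, prominence = 0.5,
                            resample_spacing = 0.25,
                            polyline_smooth = NULL, valid_only = TRUE) {
  stopifnot(inherits(cells, "epi_cells"))
  if (is.null(polyline_smooth))
    polyline_smooth <- 4 * cells$image$pixel_size
  df <- cells$cells
  bad <- df$label[df$excluded | df$touches_border]
  rows <- list()
  for (kkey in names(cells$borders)) {
    ab <- as.integer(strsplit(kkey, "|", fixed = TRUE)[[1]])
    if (valid_only && any(ab %in% bad)) next
    b <- cells$borders[[kkey]]
    if (chord_length(b) > 0 && nrow(b) > 4)
      b <- smooth_polyline(b, polyline_smooth, resample_spacing)
    ch <- chord_length(b)
    if (ch <= 0 || smooth_window >= ch) next   # loop or sub-window border
    rows[[kkey]] <- data.frame(
      cell_a = ab[1], cell_b = ab[2], side_length_um = ch,
      arc_length_um = arc_length(b),
      peak_count = count_interdigitations(b, smooth_window, prominence,
                                          resample_spacing),
      redundancy_index = redundancy_index(b))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_a = integer(0), cell_b = integer(0),
               side_length_um = numeric(0), arc_length_um = numeric(0),
               peak_count = integer(0), redundancy_index = numeric(0))
  rownames(out) <- NULL
  out
}

#' Regression of interdigitation count on side length
#'
#' Ordinary least squares of peak count on border chord length, mirroring the
#' observation that interdigitations become more numerous on longer cell
#' sides.  With a zero-variance response the fit is flat and R^2 is defined
#' as 0.
#'
#' @param results data frame from [analyze_borders()] (columns
#'   `side_length_um`, `peak_count`), or two numeric vectors via `lengths`
#'   and `peaks`.
#' @param lengths,peaks alternative vector interface.
#' @return an `epi_regression` list: `slope`, `intercept`, `r_squared`,
#'   `n_borders`.
#' @export
peaks_vs_length_regression <- function(results = NULL, lengths = NULL,
                                       peaks = NULL) {
  if (!is.null(results)) {
    lengths <- results$side_length_um
    peaks <- results$peak_count
  }
  if (length(lengths) < 3)
    .stop_invalid("need at least 3 borders for the regression")
  if (length(unique(lengths)) < 2)
    .stop_invalid("degenerate design: all side lengths equal")
  fit <- lm(peaks ~ lengths)
  r2 <- if (sd(peaks) == 0) 0 else cor(lengths, peaks)^2
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, n_borders = length(lengths)),
            class = "epi_regression")
}

#' @export
print.epi_regression <- function(x, ...) {
  cat(sprintf(
    "<epi_regression> peaks ~ side length: slope %.4g, intercept %.4g, R^2 %.3f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_borders))
  invisible(x)
}
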