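#' Label images
#'
#' @param pixels integer matrix, 0 = gap/background, >= 1 = cell label.
#' @param pixel_size physical pixel size in micrometers per pixel.
#' @return an object of class `epi_label_image`.
#' @export
epi_label_image <- function(pixels, pixel_size = 1) {
  pixels <- as.matrix(pixels)
  if (any(pixels != round(pixels)) || any(pixels < 0))
    .stop_invalid("labels must be non-negative integers")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    .stop_invalid("pixel_size must be positive (micrometers per pixel)")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "epi_label_image")
}

#' @export
print.epi_label_image <- function(x, ...) {
  cat(sprintf("<epi_label_image> %d x %d px @ %g um/px, %d labels, gap %.2f%%\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              length(setdiff(unique(as.vector(x$pixels)), 0L)),
              100 * mean(x$pixels == 0L)))
  invisible(x)
}

# even-odd ray casting, vectorized over points
point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  jj <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[jj[k], 1]; y2 <- ring[jj[k], 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Rasterize a tessellation to a label image
#'
#' Each pixel is labeled by the cell polygon containing its center; on a
#' periodic domain wrapped copies of the rings are used so the raster tiles
#' seamlessly.  Pixels whose centers fall exactly on a border (numerically
#' unclaimed) are attached to the nearest labeled neighbor.
#'
#' @param tess an `epi_tessellation` or the wavy variant from
#'   [synthesize_wavy()].
#' @param width_px,height_px raster dimensions (>= 64).
#' @param pixel_size micrometers per pixel assigned to the raster; the domain
#'   width maps onto `width_px` pixels.
#' @return an [epi_label_image()].  Cells thinner than one pixel trigger a
#'   warning reporting the lost labels.
#' @export
rasterize <- function(tess, width_px, height_px, pixel_size = 1) {
  if (width_px < 64 || height_px < 64)
    .stop_invalid("invalid-argument: raster must be at least 64 x 64 px")
  rings <- tess$cells
  domain <- tess$domain
  Lx <- diff(domain$xlim); Ly <- diff(domain$ylim)
  sx <- width_px / Lx; sy <- height_px / Ly
  # pixel centers in domain coordinates
  cxs <- domain$xlim[1] + (seq_len(width_px) - 0.5) / sx
  cys <- domain$ylim[1] + (seq_len(height_px) - 0.5) / sy
  L <- matrix(0L, height_px, width_px)
  offsets <- if (domain_is_periodic(domain))
    expand.grid(ox = c(-Lx, 0, Lx), oy = c(-Ly, 0, Ly)) else
    data.frame(ox = 0, oy = 0)
  for (i in seq_along(rings)) {
    ring0 <- rings[[i]]
    for (o in seq_len(nrow(offsets))) {
      ring <- cbind(ring0[, 1] + offsets$ox[o], ring0[, 2] + offsets$oy[o])
      colr <- which(cxs >= min(ring[, 1]) & cxs <= max(ring[, 1]))
      rowr <- which(cys >= min(ring[, 2]) & cys <= max(ring[, 2]))
      if (!length(colr) || !length(rowr)) next
      gg <- expand.grid(r = rowr, c = colr)
      unclaimed <- L[cbind(gg$r, gg$c)] == 0L
      gg <- gg[unclaimed, , drop = FALSE]
      if (!nrow(gg)) next
      hit <- point_in_polygon(cxs[gg$c], cys[gg$r], ring)
      if (any(hit)) L[cbind(gg$r[hit], gg$c[hit])] <- i
    }
  }
  # attach unclaimed border pixels to a labeled 4-neighbor (iteratively)
  for (pass in 1:8) {
    z <- which(L == 0L, arr.ind = TRUE)
    if (!nrow(z)) break
    nr <- nrow(L); nc <- ncol(L)
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r2 <- z[, 1] + d[1]; c2 <- z[, 2] + d[2]
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
      ok[ok] <- L[cbind(r2[ok], c2[ok])] > 0L
      fillable <- ok & L[z] == 0L
      if (any(fillable))
        L[z[fillable, , drop = FALSE]] <-
          L[cbind(r2[fillable], c2[fillable])]
    }
  }
  lost <- setdiff(seq_along(rings), unique(as.vector(L)))
  if (length(lost))
    warning(sprintf("%d cell(s) thinner than one pixel lost in raster: %s",
                    length(lost), paste(head(lost, 10), collapse = ", ")))
  epi_label_image(L, pixel_size)
}

#' Punch gaps into a label image
#'
#' Utility for building QC fixtures: sets pixels to the gap label 0, either a
#' disc (`center_px`, `radius_px`) or a block of exactly
#' `round(fraction * npixels)` pixels filled row-wise from the top-left
#' corner.
#'
#' @param img an [epi_label_image()].
#' @param center_px,radius_px disc center (row, col) and radius in pixels.
#' @param fraction alternative: exact gap area fraction.
#' @return the modified `epi_label_image`.
#' @export
punch_gap <- function(img, center_px = NULL, radius_px = NULL,
                      fraction = NULL) {
  L <- img$pixels
  if (!is.null(fraction)) {
    npix <- floor(fraction * length(L))   # never exceed the requested fraction
    if (npix > 0) {
      idx <- cbind((seq_len(npix) - 1) %% nrow(L) + 1,
                   (seq_len(npix) - 1) %/% nrow(L) + 1)
      L[idx] <- 0L
    }
  } else {
    rr <- row(L) - center_px[1]; cc <- col(L) - center_px[2]
    L[rr^2 + cc^2 <= radius_px^2] <- 0L
  }
  epi_label_image(L, img$pixel_size)
}
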