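#' Synthesize a tessellation with wavy, interdigitated borders
#'
#' Replaces every sufficiently long shared cell border of a bounded
#' tessellation by a smooth sinusoidal oscillation about the straight
#' segment carrying exactly `peaks_per_border` prominence-bearing extrema,
#' and rasterizes the result.  The per-border ground truth (true peak count
#' and true redundancy index) is recorded, giving a fixture with known
#' interdigitation for validating the border metrics.  Amplitude 0
#' reproduces straight borders (truth: 0 peaks, index 1).
#'
#' The tessellation is first scaled so that the domain width spans
#' `resolution_px * pixel_size` micrometers; `amplitude` is in micrometers
#' of that physical frame.  The deviation vanishes at the border endpoints,
#' so waves cannot collide near vertices; a conservative amplitude bound
#' (a fraction of the smallest centroid-to-edge clearance) guarantees simple,
#' non-self-intersecting cell outlines and larger amplitudes are rejected.
#'
#' @param tess a bounded `epi_tessellation`.
#' @param amplitude wave amplitude in um (>= 0).
#' @param peaks_per_border extrema per deformed border (>= 0).
#' @param rng_seed seed for the random phase sign of each border.
#' @param resolution_px raster width and height in pixels.
#' @param pixel_size um per pixel of the raster.
#' @param min_chord_factor borders shorter than
#'   `min_chord_factor * amplitude * peaks_per_border` are left straight
#'   (truth 0 peaks); they are too short to carry the waveform.
#' @return an `epi_wavy` object: `label_image`, `truth` (data frame:
#'   cell_a, cell_b, chord_um, peak_count, redundancy_index, deformed),
#'   `tessellation` (the wavy polygon rings, um frame), and the parameters.
#' @export
synthesize_wavy <- function(tess, amplitude, peaks_per_border, rng_seed = 1L,
                            resolution_px = 512, pixel_size = 1,
                            min_chord_factor = 3) {
  stopifnot(inherits(tess, "epi_tessellation"))
  if (domain_is_periodic(tess$domain))
    .stop_invalid("synthesize_wavy requires a bounded tessellation")
  if (amplitude < 0) .stop_invalid("invalid-argument: amplitude must be >= 0")
  if (peaks_per_border < 0 || peaks_per_border != round(peaks_per_border))
    .stop_invalid("invalid-argument: peaks_per_border must be a non-negative integer")
  s <- resolution_px * pixel_size / diff(tess$domain$xlim)
  tum <- rescale_tessellation(tess, s)

  # simplicity guard: waves of neighboring edges must not collide
  clearance <- min(vapply(seq_along(tum$cells), function(i) {
    ring <- tum$cells[[i]]; ctr <- tum$centroids[i, ]
    m <- nrow(ring); jj <- c(2:m, 1)
    e1 <- ring; e2 <- ring[jj, , drop = FALSE]
    dx <- e2[, 1] - e1[, 1]; dy <- e2[, 2] - e1[, 2]
    min(abs((ctr[1] - e1[, 1]) * dy - (ctr[2] - e1[, 2]) * dx) /
          sqrt(dx^2 + dy^2))
  }, 0))
  if (amplitude > 0.35 * clearance)
    .stop_invalid(sprintf(
      "invalid-argument: amplitude %.3g would self-intersect (max safe ~%.3g um)",
      amplitude, 0.35 * clearance))

  # identify shared edges by rounded endpoint keys
  ptkey <- function(p) paste(round(p[1], 6), round(p[2], 6))
  edges <- new.env(parent = emptyenv())
  for (i in seq_along(tum$cells)) {
    ring <- tum$cells[[i]]; m <- nrow(ring)
    for (k in seq_len(m)) {
      a <- ring[k, ]; b <- ring[if (k < m) k + 1 else 1, ]
      ka <- ptkey(a); kb <- ptkey(b)
      ek <- if (ka < kb) paste(ka, kb) else paste(kb, ka)
      rec <- if (!is.null(edges[[ek]])) edges[[ek]] else
        list(a = if (ka < kb) a else b, b = if (ka < kb) b else a,
             cells = integer(0))
      rec$cells <- c(rec$cells, i)
      edges[[ek]] <- rec
    }
  }
  min_chord <- max(min_chord_factor * amplitude,
                   2 * amplitude * max(1, peaks_per_border))
  curves <- new.env(parent = emptyenv())
  truth <- list()
  with_seed(rng_seed, for (ek in sort(ls(edges))) {
    rec <- edges[[ek]]
    if (length(rec$cells) != 2) next                  # domain-wall edge
    ch <- sqrt(sum((rec$b - rec$a)^2))
    deform <- amplitude > 0 && peaks_per_border > 0 && ch > min_chord
    if (deform) {
      # ~2 samples per pixel and >= 12 per half-period of the wave
      npts <- max(16L, ceiling(2 * ch / pixel_size), 12L * peaks_per_border)
      t <- seq(0, 1, length.out = npts)
      sgn <- sample(c(-1, 1), 1)
      off <- sgn * amplitude * sin(pi * peaks_per_border * t)
      u <- (rec$b - rec$a) / ch
      pts <- cbind(rec$a[1] + t * (rec$b[1] - rec$a[1]) - off * u[2],
                   rec$a[2] + t * (rec$b[2] - rec$a[2]) + off * u[1])
      curves[[ek]] <- pts
      ri <- arc_length(pts) / ch
      pk <- peaks_per_border
    } else {
      ri <- 1.0
      pk <- 0L
    }
    truth[[ek]] <- data.frame(cell_a = min(rec$cells), cell_b = max(rec$cells),
                              chord_um = ch, peak_count = pk,
                              redundancy_index = ri, deformed = deform)
  })
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  # rebuild cell rings with the deformed borders
  wavy_cells <- lapply(seq_along(tum$cells), function(i) {
    ring <- tum$cells[[i]]; m <- nrow(ring)
    out <- NULL
    for (k in seq_len(m)) {
      a <- ring[k, ]; b <- ring[if (k < m) k + 1 else 1, ]
      ka <- ptkey(a); kb <- ptkey(b)
      ek <- if (ka < kb) paste(ka, kb) else paste(kb, ka)
      seg <- if (!is.null(curves[[ek]])) {
        pts <- curves[[ek]]
        if (ka < kb) pts else pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      } else rbind(a, b)
      out <- rbind(out, seg[-nrow(seg), , drop = FALSE])
    }
    out
  })
  wtess <- tum
  wtess$cells <- wavy_cells
  img <- rasterize(wtess, resolution_px, resolution_px, pixel_size)
  structure(list(label_image = img, truth = truth, tessellation = wtess,
                 amplitude = amplitude, peaks_per_border = peaks_per_border,
                 pixel_size = pixel_size, rng_seed = rng_seed),
            class = "epi_wavy")
}

#' @export
print.epi_wavy <- function(x, ...) {
  cat(sprintf(
    "<epi_wavy> %d cells, %d borders (%d deformed), amplitude %.3g um, %d peaks/border\n",
    length(x$tessellation$cells), nrow(x$truth), sum(x$truth$deformed),
    x$amplitude, x$peaks_per_border))
  invisible(x)
}
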