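#' Read a segmented label image
#'
#' Reads a single-channel integer label mask from PNG or TIFF.  8-bit and
#' 16-bit images are supported; values are mapped back to integer labels
#' (0 = gap/background).  Multi-channel (RGB) or non-integer images are
#' rejected with guidance.
#'
#' @param path PNG or TIFF file.
#' @param pixel_size micrometers per pixel.  Required by downstream area and
#'   border statistics; defaults to 1 with a warning because the physical
#'   calibration cannot be recovered from the file.
#' @return an [epi_label_image()].
#' @export
read_label_image <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("cannot read label image: ", path)
  if (is.null(pixel_size)) {
    warning("pixel_size not supplied; assuming 1 um/px")
    pixel_size <- 1
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    m <- png::readPNG(path, info = TRUE)
    bits <- attr(m, "info")$bit.depth
    if (is.null(bits)) bits <- 8L
    vals <- m * (2^bits - 1)
  } else if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
    vals <- m
  } else stop("unsupported label image format: .", ext,
              " (use single-channel PNG or TIFF)")
  if (length(dim(vals)) == 3) {
    if (dim(vals)[3] == 1) vals <- vals[, , 1]
    else stop("label image must be single-channel, got ", dim(vals)[3],
              " channels; export the mask as 8/16-bit grayscale")
  }
  if (max(abs(vals - round(vals))) > 1e-6)
    stop("label image is not integer-valued; expected a label mask")
  epi_label_image(matrix(round(vals), nrow(vals)), pixel_size)
}

#' Write a label image
#'
#' 16-bit single-channel TIFF (any label up to 65535), or 8-bit PNG for
#' masks with at most 255 labels.  Round trips losslessly with
#' [read_label_image()].
#'
#' @param img an [epi_label_image()].
#' @param path destination `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(img, path) {
  m <- img$pixels
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(m) > 65535) .stop_invalid("more than 65535 labels; relabel first")
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (max(m) > 255)
      .stop_invalid("PNG writer is 8-bit (<= 255 labels); use TIFF")
    png::writePNG(m / 255, path)
  } else .stop_invalid("unsupported output format: .", ext)
  invisible(path)
}

#' Write tessellation geometry as JSON
#'
#' Cells (vertex rings), seeds, adjacency and domain in one JSON document.
#'
#' @param tess an `epi_tessellation`.
#' @param path output `.json`.
#' @export
write_tessellation_json <- function(tess, path) {
  jsonlite::write_json(list(
    domain = list(xlim = tess$domain$xlim, ylim = tess$domain$ylim,
                  mode = tess$domain$mode),
    iteration_index = tess$iteration_index,
    seeds = tess$seeds,
    areas = tess$areas,
    adjacency = tess$adjacency,
    cells = lapply(tess$cells, unname)
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
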