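#' Read a scribble image
#'
#' Reads an 8-bit grayscale raster (PNG or TIFF) into the integer intensity
#' matrix used throughout the package (rows = image rows, values 0-255,
#' 0 = black ink, 255 = white paper). Colour images are converted to
#' luminance (Rec. 601 weights) before any thresholding; an alpha channel,
#' if present, is composited over white.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An integer matrix of class `scribble_image` with intensities in
#'   `[0, 255]`. The file's resolution metadata, when present, is attached as
#'   attribute `dpi` (not used by the scale-free SPI itself).
#' @seealso [binarize()], [score_scribble()]
#' @export
read_scribble <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_io_failure(sprintf("cannot read image file '%s'", paste(path, collapse = ", ")))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path, info = TRUE),
    tif = ,
    tiff = tiff::readTIFF(path, info = TRUE),
    stop_io_failure(sprintf("unsupported image format '.%s' (PNG or TIFF expected)", ext))
  )
  dpi <- NULL
  info <- attr(arr, "info")
  if (!is.null(info$dpi)) dpi <- as.numeric(info$dpi)[1]
  as_scribble_image(arr, dpi = dpi)
}

#' Coerce a numeric array to a scribble image
#'
#' Accepts matrices in `[0, 1]` (as returned by png/tiff readers) or
#' `[0, 255]`, and H x W x C arrays (gray+alpha, RGB, RGBA), and returns the
#' 0-255 integer grayscale matrix used internally.
#'
#' @param x Matrix or array of pixel intensities.
#' @param dpi Optional resolution metadata (dots per inch).
#' @return Integer matrix of class `scribble_image`.
#' @export
as_scribble_image <- function(x, dpi = NULL) {
  if (inherits(x, "scribble_image")) return(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    nc <- dim(x)[3]
    if (nc >= 3L) {
      lum <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
      if (nc == 4L) lum <- lum * x[, , 4] + (1 - x[, , 4])  # over white
    } else {
      lum <- x[, , 1]
      if (nc == 2L) lum <- lum * x[, , 2] + (1 - x[, , 2])
    }
    x <- lum
  }
  if (!is.matrix(x)) stop_io_failure("image must be a matrix or H x W x C array")
  if (nrow(x) < 1L || ncol(x) < 1L) stop_io_failure("image has zero extent")
  mx <- suppressWarnings(max(x, na.rm = TRUE))
  if (is.finite(mx) && mx <= 1 && !is.integer(x)) x <- x * 255
  x[] <- pmin(pmax(round(x), 0L), 255L)
  storage.mode(x) <- "integer"
  structure(x, dpi = dpi, class = c("scribble_image", class(matrix())))
}

#' @export
print.scribble_image <- function(x, ...) {
  cat(sprintf("<scribble_image> %d x %d px, intensities %d-%d%s\n",
              nrow(x), ncol(x), min(x), max(x),
              if (!is.null(attr(x, "dpi"))) sprintf(", %g dpi", attr(x, "dpi")) else ""))
  invisible(x)
}

# Write a scribble image (0-255 integer matrix) as 8-bit grayscale PNG.
write_scribble_png <- function(img, path) {
  ok <- try(png::writePNG(unclass(img) / 255, target = path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop_io_failure(sprintf("cannot write PNG to '%s'", path))
  }
  invisible(path)
}
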