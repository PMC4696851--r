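# Image file I/O.  Internally images are H x W x 3 numeric arrays with
# values in [0, 255] (row = image row); EBImage handles the container
# formats (PNG, TIFF, JPEG) and stores pixels as x-by-y in [0, 1], so
# reading and writing transpose and rescale.

#' Read an image file as an 8-bit RGB array
#'
#' Grayscale images are promoted to RGB; an alpha channel is dropped with
#' a warning.
#'
#' @param path PNG, TIFF or JPEG file.
#' @return H x W x 3 numeric array with values in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) dat <- array(rep(dat, 3L), c(dim(dat), 3L))
  if (dim(dat)[3] == 4L) {
    warning("alpha channel dropped from ", path)
    dat <- dat[, , 1:3, drop = FALSE]
  }
  if (dim(dat)[3] != 3L)
    stop("unsupported channel count (", dim(dat)[3], ") in ", path,
         "; expected grayscale, RGB or RGBA")
  aperm(dat, c(2, 1, 3)) * 255
}

#' Write an RGB array to an image file
#'
#' Values are clamped to \[0, 255\] and quantized to 8 bits here, at the
#' file boundary.  Format follows the file extension (PNG or TIFF; PNG
#' recommended as it is lossless).
#'
#' @param image H x W x 3 numeric array, values in \[0, 255\].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  dat <- aperm(round(pmin(pmax(image, 0), 255)) / 255, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(dat, colormode = "Color"), path)
  invisible(path)
}
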