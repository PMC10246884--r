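# Image and mask I/O. Images are H x W x 3 arrays on [0, 255]; masks are
# binary H x W matrices. PNG is the native format; JPEG is accepted on read.

#' Read an RGB image
#'
#' Reads a PNG or JPEG file into the package's image currency: a numeric
#' `H x W x 3` array with values on `[0, 255]`. Grayscale images are
#' replicated across channels; an alpha channel is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return `H x W x 3` numeric array in `[0, 255]`.
#' @export
read_image <- function(path) {
  assert_that(file.exists(path), sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop_rindcast(sprintf("unsupported image format '%s' (use PNG or JPEG)", ext))
  )
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] == 4) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

#' Write an RGB image as PNG
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read a binary fruit mask
#'
#' Masks are stored as single-channel 8-bit PNGs with values 0/255 (the
#' common annotation-export convention); on read they are binarized at
#' intensity > 127.
#'
#' @param path Path to a mask PNG.
#' @return Binary `H x W` matrix (1 = fruit).
#' @export
read_mask <- function(path) {
  assert_that(file.exists(path), sprintf("mask file not found: %s", path))
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  m <- (x > 127 / 255) * 1
  dim(m) <- dim(x)[1:2]
  m
}

#' Write a binary mask as PNG
#'
#' @param mask Binary `H x W` matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
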