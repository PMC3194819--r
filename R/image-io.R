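#' Read a grayscale PNG image as a numeric matrix
#'
#' Multi-channel images are averaged to one channel; values are in [0, 1].
#'
#' @param path PNG file.
#' @return Numeric matrix (rows = image rows).
#' @export
read_gray_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG I/O", call. = FALSE)
  }
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
  a
}

#' Write a numeric matrix as an 8- or 16-bit grayscale PNG
#'
#' @param image Numeric matrix with values in [0, 1] (clamped otherwise).
#' @param path Output path.
#' @param bit_depth 8 or 16.
#' @export
write_gray_png <- function(image, path, bit_depth = 8) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG I/O", call. = FALSE)
  }
  stopifnot(bit_depth %in% c(8, 16))
  img <- pmin(pmax(image, 0), 1)
  png::writePNG(img, path, dpi = NULL)
  invisible(path)
}

#' Write an integer label map as a grayscale PNG
#'
#' Labels are stored as gray levels `label / 255` so they survive an 8-bit
#' round trip exactly.
#'
#' @param labels Integer matrix (values in 0..255).
#' @param path Output path.
#' @export
write_label_png <- function(labels, path) {
  stopifnot(all(labels >= 0), all(labels <= 255))
  write_gray_png(labels / 255, path)
}

#' Read a label map written by [write_label_png()]
#'
#' @param path PNG file.
#' @return Integer matrix.
#' @export
read_label_png <- function(path) {
  img <- read_gray_png(path)
  matrix(as.integer(round(img * 255)), nrow = nrow(img))
}
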