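#' Coerce a numeric matrix to a validated grayscale image
#'
#' Images throughout the package are plain numeric matrices with intensities
#' in \[0, 1\], row = image row, column = image column. This helper validates
#' (and optionally rescales 8-bit integer input) so downstream code can rely
#' on the invariants.
#'
#' @param x Numeric matrix. Values either already in \[0, 1\] or 8-bit
#'   integers in \[0, 255\] (detected when any value exceeds 1 and
#'   `rescale_8bit = TRUE`).
#' @param rescale_8bit Divide by 255 when values look 8-bit. Default `TRUE`.
#' @return A numeric matrix of class `gray_image` with values in \[0, 1\].
#' @examples
#' img <- as_gray_image(matrix(runif(64), 8, 8))
#' @export
as_gray_image <- function(x, rescale_8bit = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(x)))
    stop("image contains non-finite values", call. = FALSE)
  if (rescale_8bit && any(x > 1)) x <- x / 255
  if (any(x < 0) || any(x > 1))
    stop("intensities must lie in [0, 1] (or [0, 255] for 8-bit input)",
         call. = FALSE)
  structure(x, class = c("gray_image", class(unclass(x))))
}

#' @rdname as_gray_image
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

# Correction needs enough pixels to tile into cells and fit a surface.
assert_correctable <- function(img) {
  if (nrow(img) < 8 || ncol(img) < 8)
    stop("image must be at least 8x8 for correction", call. = FALSE)
  invisible(img)
}

#' Read a grayscale PNG or TIFF image as a `gray_image`
#'
#' 8- or 16-bit files are scaled to \[0, 1\] (the readers already return
#' values in \[0, 1\]); RGB(A) input is collapsed to luma by channel mean.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A `gray_image` matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(raw)) == 3) raw <- apply(raw, c(1, 2), mean)
  as_gray_image(pmin(pmax(raw, 0), 1), rescale_8bit = FALSE)
}

#' Write a `gray_image` to disk
#'
#' PNG output is quantized to 8 bits (`round(v * 255)`); TIFF output is
#' written as 32-bit float and preserves full precision (used for bias-field
#' truth maps).
#'
#' @param img Numeric matrix in \[0, 1\] (or any numeric matrix for
#'   float TIFF output).
#' @param path Destination ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  m <- unclass(img)
  if (ext == "png") {
    png::writePNG(round(pmin(pmax(m, 0), 1) * 255) / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 32, reduce = FALSE)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Normalized pixel-center coordinates for an image grid
#'
#' Maps 0-based pixel indices to \[-1, 1\] per axis via
#' `(2 * idx - (len - 1)) / (len - 1)`, the convention under which all
#' polynomial surface coefficients in this package are expressed. `x` runs
#' along columns, `y` along rows.
#'
#' @param nrow,ncol Image dimensions.
#' @return A list with matrices `x` and `y` of dimension `nrow x ncol`.
#' @export
pixel_coords <- function(nrow, ncol) {
  xs <- if (ncol > 1) (2 * (seq_len(ncol) - 1) - (ncol - 1)) / (ncol - 1) else 0
  ys <- if (nrow > 1) (2 * (seq_len(nrow) - 1) - (nrow - 1)) / (nrow - 1) else 0
  list(x = matrix(xs, nrow, ncol, byrow = TRUE),
       y = matrix(ys, nrow, ncol))
}
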