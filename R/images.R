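#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

#' Read an 8-bit RGB image
#'
#' Reads a PNG or TIFF file into a numeric array with values in `[0, 255]`.
#' Greyscale files come back as a `height x width` matrix, colour files as a
#' `height x width x 3` array (an alpha channel, if present, is dropped).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix or 3-d array with intensities in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image format '%s' (expected png/tif/tiff)", ext),
          class = "flystrip_format_error")
  )
  img <- img * 255
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE] else img <- img[, , 1L]
  }
  round(img)
}

#' Write an image to PNG or TIFF
#'
#' @param img Numeric matrix or `height x width x 3` array in `[0, 255]`.
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  x <- pmin(pmax(img / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path),
    abort(sprintf("unsupported image format '%s'", ext), class = "flystrip_format_error")
  )
  invisible(path)
}

is_rgb_image <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L
}

assert_min_size <- function(img, min_dim = 3L) {
  d <- dim(img)
  if (d[1] < min_dim || d[2] < min_dim) {
    abort(sprintf("image must be at least %dx%d pixels", min_dim, min_dim),
          class = "flystrip_format_error")
  }
  invisible(img)
}

#' Collapse an RGB image to 8-bit grey
#'
#' Channels are combined with an unweighted mean by default; alternative
#' weights (e.g. luminance weights) can be supplied.
#'
#' @param rgb `height x width x 3` array in `[0, 255]`.
#' @param weights Length-3 non-negative channel weights, normalised internally.
#' @return Integer-valued grey matrix in `[0, 255]`.
#' @export
to_gray8 <- function(rgb, weights = c(1, 1, 1)) {
  if (!is_rgb_image(rgb)) {
    abort("expected an RGB image (height x width x 3 array)",
          class = "flystrip_format_error")
  }
  if (length(weights) != 3L || any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be 3 non-negative values with positive sum",
          class = "flystrip_parameter_error")
  }
  w <- weights / sum(weights)
  out <- round(rgb[, , 1] * w[1] + rgb[, , 2] * w[2] + rgb[, , 3] * w[3])
  dim(out) <- dim(rgb)[1:2]
  out
}
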