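# Orienting the embryo: principal-axis angle from image moments, rotation to
# a horizontal A-P axis, cropping to the mask, and manual flips.

#' Principal-axis orientation of a binary mask
#'
#' Computes the orientation of the major principal axis of the foreground
#' pixel distribution from central second moments, in degrees relative to
#' the horizontal, in `(-90, 90]`. Positive angles are counter-clockwise in
#' the conventional display orientation (y pointing up). Isotropic masks
#' (e.g. a perfect disk) have no defined major axis; they return 0 with a
#' warning.
#'
#' @param mask Binary matrix; values `> 0` are foreground.
#' @return Angle in degrees.
#' @export
principal_axis_angle <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) < 2L) {
    abort("mask needs at least 2 foreground pixels", class = "flystrip_degenerate_error")
  }
  x <- idx[, 2]
  y <- -idx[, 1]  # y up
  mu20 <- mean(x^2) - mean(x)^2
  mu02 <- mean(y^2) - mean(y)^2
  mu11 <- mean(x * y) - mean(x) * mean(y)
  scale <- mu20 + mu02
  if (abs(2 * mu11) < 1e-9 * scale && abs(mu20 - mu02) < 1e-9 * scale) {
    warn("mask is isotropic; principal axis undefined, returning 0 degrees")
    return(0)
  }
  atan2(2 * mu11, mu20 - mu02) / 2 * 180 / pi
}

# Bilinear rotation about the image centre; output canvas keeps the input
# size, exposed pixels take `fill`. Positive angle rotates the content
# counter-clockwise (y-up convention), consistent with principal_axis_angle.
rotate_plane <- function(m, degrees, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  th <- degrees * pi / 180
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  rr <- matrix(seq_len(h), h, w)
  xc <- cc - cx
  yc <- cy - rr
  xs <- cos(th) * xc + sin(th) * yc
  ys <- -sin(th) * xc + cos(th) * yc
  sc <- cx + xs
  sr <- cy - ys
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  at <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- matrix(fill, h, w)
    v[ok] <- m[cbind(r[ok], c[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * at(r0, c0) +
         (1 - fr) * fc       * at(r0, c0 + 1) +
         fr       * (1 - fc) * at(r0 + 1, c0) +
         fr       * fc       * at(r0 + 1, c0 + 1)
  out
}

#' Rotate an image about its centre
#'
#' Bilinear interpolation; the canvas size is unchanged and uncovered pixels
#' are filled with `fill`. Positive angles rotate counter-clockwise (in the
#' y-up display convention). RGB arrays are rotated channel by channel.
#'
#' @param img Grey matrix or RGB array in `[0, 255]`.
#' @param degrees Rotation angle.
#' @param fill Fill value for exposed pixels.
#' @export
rotate_image <- function(img, degrees, fill = 0) {
  if (is_rgb_image(img)) {
    out <- img
    for (ch in 1:3) out[, , ch] <- rotate_plane(img[, , ch], degrees, fill)
    out
  } else {
    rotate_plane(img, degrees, fill)
  }
}

mask_bbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (!nrow(idx)) abort("empty mask", class = "flystrip_degenerate_error")
  c(r0 = min(idx[, 1]), r1 = max(idx[, 1]), c0 = min(idx[, 2]), c1 = max(idx[, 2]))
}

#' Rotate the embryo to a horizontal A-P axis and crop
#'
#' Rotates the mask and all registered 10x images by `-angle` about the image
#' centre (bilinear interpolation; the mask is re-binarised at 128 after
#' interpolation), then crops everything to the tight bounding box of the
#' rotated mask.
#'
#' @param mask Binary matrix or an `embryo_mask` object.
#' @param images Named list of registered grey matrices / RGB arrays
#'   (e.g. `dic`, `brightfield`, `nuclear`); may be empty.
#' @param angle Angle in degrees to undo, typically from
#'   [principal_axis_angle()].
#' @return A list with `mask` (cropped binary matrix), `images` (cropped,
#'   rotated list), and `orientation`, a one-row tibble with `angle`,
#'   the 0-based half-open `crop_box` fields (`row0`, `col0`, `height`,
#'   `width`) and the residual major-axis angle of the output mask.
#' @export
rotate_and_crop <- function(mask, images = list(), angle = NULL) {
  if (inherits(mask, "embryo_mask")) mask <- mask$mask
  if (is.null(angle)) angle <- principal_axis_angle(mask)
  rmask <- rotate_plane(mask, -angle)
  rmask <- matrix(ifelse(rmask >= 128, 255, 0), nrow(rmask), ncol(rmask))
  if (!any(rmask > 0)) {
    abort("rotated mask is empty", class = "flystrip_internal_error")
  }
  bb <- mask_bbox(rmask)
  crop <- function(img) {
    if (is_rgb_image(img)) img[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], , drop = FALSE]
    else img[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE]
  }
  out_mask <- crop(rmask)
  out_images <- lapply(images, function(img) crop(rotate_image(img, -angle)))
  residual <- suppressWarnings(principal_axis_angle(out_mask))
  orientation <- tibble(
    angle = angle,
    row0 = unname(bb["r0"]) - 1L, col0 = unname(bb["c0"]) - 1L,
    height = unname(bb["r1"] - bb["r0"]) + 1L,
    width = unname(bb["c1"] - bb["c0"]) + 1L,
    residual_angle = residual
  )
  list(mask = out_mask, images = out_images, orientation = orientation)
}

flip_plane <- function(m, hflip, vflip) {
  if (hflip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (vflip) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m
}

#' Mirror images horizontally and/or vertically
#'
#' Flips are the manual step that puts anterior left and dorsal up; applying
#' the same flips twice restores the input exactly.
#'
#' @param images A grey matrix, RGB array, or a (possibly named) list of them.
#' @param hflip Mirror about the vertical midline (left/right exchange).
#' @param vflip Mirror about the horizontal midline (top/bottom exchange).
#' @export
apply_flips <- function(images, hflip = FALSE, vflip = FALSE) {
  flip1 <- function(img) {
    if (is_rgb_image(img)) {
      out <- img
      for (ch in 1:3) out[, , ch] <- flip_plane(img[, , ch], hflip, vflip)
      out
    } else {
      flip_plane(img, hflip, vflip)
    }
  }
  if (is.list(images)) lapply(images, flip1) else flip1(images)
}
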