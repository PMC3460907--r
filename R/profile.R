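# The A-P axis spline, the 10% dorso-ventral extraction strip, and
# per-channel expression profiles.

lagrange_quad <- function(xk, yk) {
  force(xk); force(yk)
  function(x) {
    yk[1] * (x - xk[2]) * (x - xk[3]) / ((xk[1] - xk[2]) * (xk[1] - xk[3])) +
    yk[2] * (x - xk[1]) * (x - xk[3]) / ((xk[2] - xk[1]) * (xk[2] - xk[3])) +
    yk[3] * (x - xk[1]) * (x - xk[2]) / ((xk[3] - xk[1]) * (xk[3] - xk[2]))
  }
}

#' Fit the A-P axis spline
#'
#' A natural cubic spline is interpolated through the (typically five)
#' midline knots; beyond the outer knots the curve follows the Lagrange
#' (quadratic) polynomial through the three outermost knots on that side,
#' extending the midline to the mask borders so the entire A-P axis is
#' covered. The two pieces meet the interior spline continuously at the
#' outer knots.
#'
#' @param knots Tibble with columns `x`, `y` (from [equidistant_knots()] or
#'   a manual knot-override table); x values must be strictly increasing
#'   after sorting.
#' @param mask Oriented binary mask; its horizontal extent defines the range
#'   the spline is meant to cover.
#' @return An `axis_spline` object with fields `knots`, `fun` (vectorised
#'   evaluator), and `col_range`.
#' @export
fit_axis_spline <- function(knots, mask) {
  ord <- order(knots$x)
  kx <- knots$x[ord]; ky <- knots$y[ord]
  if (anyDuplicated(kx)) {
    abort("duplicate x among spline knots", class = "flystrip_degenerate_error")
  }
  k <- length(kx)
  if (k < 3L) abort("need at least 3 knots", class = "flystrip_degenerate_error")
  interior <- stats::splinefun(kx, ky, method = "natural")
  left <- lagrange_quad(kx[1:3], ky[1:3])
  right <- lagrange_quad(kx[(k - 2):k], ky[(k - 2):k])
  fun <- function(x) {
    out <- interior(x)
    lo <- x < kx[1]; hi <- x > kx[k]
    if (any(lo)) out[lo] <- left(x[lo])
    if (any(hi)) out[hi] <- right(x[hi])
    out
  }
  bb <- mask_bbox(mask)
  structure(list(knots = tibble(x = kx, y = ky), fun = fun,
                 col_range = c(unname(bb["c0"]), unname(bb["c1"]))),
            class = "axis_spline")
}

#' Midline spline of an oriented mask
#'
#' Convenience wrapper: skeletonize, select the main branch, place `k`
#' equidistant knots and fit the axis spline.
#'
#' @param mask Oriented binary mask (single blob, A-P horizontal).
#' @param k Number of knots (default 5).
#' @param knot_override Optional tibble with `x`, `y` replacing the automatic
#'   knots (the file-driven equivalent of manual knot dragging).
#' @return An `axis_spline`.
#' @export
axis_spline <- function(mask, k = 5, knot_override = NULL) {
  knots <- if (is.null(knot_override)) {
    equidistant_knots(main_branch(skeletonize(mask)), k = k)
  } else {
    knot_override
  }
  fit_axis_spline(knots, mask)
}

#' Build the 10% dorso-ventral extraction strip
#'
#' The strip is a band centred on the axis spline whose total height is 10%
#' of the embryo's minor (D-V) axis: 5% above and 5% below the midline. The
#' minor-axis length is measured as the maximal vertical extent of the
#' oriented mask; the column range is the mask's horizontal extent.
#'
#' @param spline An `axis_spline`.
#' @param mask Oriented binary mask.
#' @param fraction Total band height as a fraction of the minor axis
#'   (default 0.10).
#' @return An `extraction_strip` object with fields `spline`, `half_width`,
#'   `height`, `minor_axis`, `col_range`.
#' @export
build_strip <- function(spline, mask, fraction = 0.10) {
  bb <- mask_bbox(mask)
  minor <- unname(bb["r1"] - bb["r0"]) + 1
  half_width <- fraction / 2 * minor
  structure(list(spline = spline, half_width = half_width,
                 height = fraction * minor, minor_axis = minor,
                 col_range = c(unname(bb["c0"]), unname(bb["c1"]))),
            class = "extraction_strip")
}

#' Extract per-channel expression profiles along the A-P axis
#'
#' For every pixel column in the strip's range, the mean red, green and blue
#' intensity is taken over the pixels lying within `half_width` of the
#' centreline. Column positions are mapped linearly to percent egg length
#' (%EL), 0 at the anterior (left) edge of the mask and 100 at the posterior.
#'
#' @param brightfield RGB bright-field image registered with the mask.
#' @param strip An `extraction_strip`.
#' @return A tibble (class `expression_profile`) with columns `position`
#'   (%EL), `red`, `green`, `blue`.
#' @export
extract_profile <- function(brightfield, strip) {
  if (!is_rgb_image(brightfield)) {
    abort("bright-field input must be an RGB image", class = "flystrip_format_error")
  }
  h <- dim(brightfield)[1]; w <- dim(brightfield)[2]
  cols <- seq(strip$col_range[1], strip$col_range[2])
  if (min(cols) < 1 || max(cols) > w) {
    abort("extraction strip lies outside the image", class = "flystrip_format_error")
  }
  centres <- strip$spline$fun(cols)
  hw <- strip$half_width
  means <- matrix(NA_real_, length(cols), 3)
  for (i in seq_along(cols)) {
    r0 <- ceiling(centres[i] - hw)
    r1 <- floor(centres[i] + hw)
    if (r1 < r0) { r0 <- r1 <- round(centres[i]) }  # sub-pixel band
    if (r1 < 1 || r0 > h) {
      abort("extraction strip lies outside the image", class = "flystrip_format_error")
    }
    rows <- max(1L, r0):min(h, r1)
    for (ch in 1:3) means[i, ch] <- mean(brightfield[rows, cols[i], ch])
  }
  pos <- (cols - cols[1]) / (cols[length(cols)] - cols[1]) * 100
  out <- tibble(position = pos, red = means[, 1], green = means[, 2], blue = means[, 3])
  class(out) <- c("expression_profile", class(out))
  out
}

#' Stain signal from an expression profile
#'
#' Colorimetric stain intensities are approximated from the RGB channels:
#' NBT/BCIP (purple) as the red channel, and FastRed as the green minus red
#' channel difference (clipped at zero). `invert = TRUE` reports
#' `255 - signal`, for data where dark precipitate lowers the transmitted
#' channel instead of raising it.
#'
#' @param profile An `expression_profile` tibble.
#' @param stain `"NBT_BCIP"` or `"FastRed"`.
#' @param invert Report `255 - signal`.
#' @return The profile with an added `signal` column.
#' @export
stain_signal <- function(profile, stain = c("NBT_BCIP", "FastRed"), invert = FALSE) {
  stain <- match.arg(stain)
  sig <- switch(stain,
    NBT_BCIP = profile$red,
    FastRed = pmax(profile$green - profile$red, 0)
  )
  if (invert) sig <- 255 - sig
  profile$signal <- sig
  profile
}
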