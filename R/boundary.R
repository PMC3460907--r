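# Gene expression domain boundaries ("slopes"): clamped cubic splines fitted
# between the outer edge of a boundary (signal indistinguishable from
# background) and its inner edge (plateau expression).

# Clamped cubic spline through 3 knots: two cubic Hermite pieces joined C1
# at the middle knot, with first derivatives forced to zero at both end
# knots. The midknot slope is the span-weighted average of the two secants,
# limited a la Fritsch-Carlson so monotone knot values yield a monotone
# curve (a single C2 cubic through three knots with both end slopes clamped
# can overshoot).
clamped_spline_slopes <- function(x, y) {
  h0 <- x[2] - x[1]; h1 <- x[3] - x[2]
  d0 <- (y[2] - y[1]) / h0
  d1 <- (y[3] - y[2]) / h1
  m1 <- if (d0 * d1 <= 0) 0 else {
    m <- (d0 * h1 + d1 * h0) / (h0 + h1)
    sign(m) * min(abs(m), 3 * min(abs(d0), abs(d1)))
  }
  c(0, m1, 0)
}

eval_clamped <- function(x, y, m, xx, deriv = 0) {
  i <- ifelse(xx <= x[2], 1L, 2L)
  h <- x[i + 1L] - x[i]
  t <- (xx - x[i]) / h
  yi <- y[i]; yi1 <- y[i + 1L]
  mi <- m[i]; mi1 <- m[i + 1L]
  if (deriv == 0) {
    yi * (2 * t^3 - 3 * t^2 + 1) + h * mi * (t^3 - 2 * t^2 + t) +
      yi1 * (-2 * t^3 + 3 * t^2) + h * mi1 * (t^3 - t^2)
  } else if (deriv == 1) {
    yi * (6 * t^2 - 6 * t) / h + mi * (3 * t^2 - 4 * t + 1) +
      yi1 * (6 * t - 6 * t^2) / h + mi1 * (3 * t^2 - 2 * t)
  } else {
    yi * (12 * t - 6) / h^2 + mi * (6 * t - 4) / h +
      yi1 * (6 - 12 * t) / h^2 + mi1 * (6 * t - 2) / h
  }
}

#' Fit a clamped cubic spline to an expression boundary
#'
#' The user supplies the outer knot position `x0` (where signal becomes
#' distinguishable from background) and the inner knot position `x2` (where
#' plateau expression is attained), in percent egg length. A middle knot is
#' added automatically at the midpoint `x1 = min(x0, x2) + |x2 - x0| / 2`,
#' and all three y values are read from the nearest profile sample. The
#' spline interpolates the three knots with first derivative clamped to zero
#' at `x0` and `x2`.
#'
#' @param profile Tibble with `position` and a signal column (see
#'   [stain_signal()]).
#' @param x0,x2 Outer and inner knot positions in %EL; must differ and lie
#'   within the profile range. For an anterior boundary `x0 < x2`, for a
#'   posterior boundary `x0 > x2`.
#' @param gene Gene name label.
#' @param slope_id Integer boundary identifier within the gene.
#' @param polarity `"anterior"` or `"posterior"`.
#' @param channel `"purple"` (NBT/BCIP) or `"red"` (FastRed).
#' @param signal_col Name of the signal column (default `"signal"`).
#' @return A `boundary_spline` object.
#' @export
fit_boundary <- function(profile, x0, x2, gene = "", slope_id = 1L,
                         polarity = c("anterior", "posterior"),
                         channel = c("purple", "red"),
                         signal_col = "signal") {
  polarity <- match.arg(polarity)
  channel <- match.arg(channel)
  if (!signal_col %in% names(profile)) {
    abort(sprintf("profile has no '%s' column", signal_col),
          class = "flystrip_parameter_error")
  }
  pos <- profile$position
  sig <- profile[[signal_col]]
  rng <- range(pos)
  if (x0 == x2) abort("x0 and x2 must differ", class = "flystrip_parameter_error")
  if (x0 < rng[1] || x0 > rng[2] || x2 < rng[1] || x2 > rng[2]) {
    abort("boundary window outside the profile's position range",
          class = "flystrip_parameter_error")
  }
  x1 <- min(x0, x2) + abs(x2 - x0) / 2
  at <- function(x) sig[which.min(abs(pos - x))]
  y0 <- at(x0); y1 <- at(x1); y2 <- at(x2)

  xs <- c(min(x0, x2), x1, max(x0, x2))
  ys <- if (x0 < x2) c(y0, y1, y2) else c(y2, y1, y0)
  m <- clamped_spline_slopes(xs, ys)
  structure(list(
    gene = gene, slope_id = as.integer(slope_id), polarity = polarity,
    channel = channel,
    knots = tibble(label = c("x0", "x1", "x2"), x = c(x0, x1, x2), y = c(y0, y1, y2)),
    xs = xs, ys = ys, m = m
  ), class = "boundary_spline")
}

#' Evaluate a boundary spline
#'
#' @param spline A `boundary_spline`.
#' @param x Positions in %EL within the spline's span.
#' @param deriv Derivative order 0, 1 or 2.
#' @return Signal intensities (or derivatives) at `x`.
#' @export
eval_boundary <- function(spline, x, deriv = 0) {
  if (any(x < spline$xs[1] - 1e-9 | x > spline$xs[3] + 1e-9)) {
    abort("x outside the boundary spline's span", class = "flystrip_parameter_error")
  }
  eval_clamped(spline$xs, spline$ys, spline$m, pmin(pmax(x, spline$xs[1]), spline$xs[3]),
               deriv = deriv)
}

#' @export
print.boundary_spline <- function(x, ...) {
  cat(sprintf("<boundary_spline> %s slope %d (%s, %s): x0=%.2f x1=%.2f x2=%.2f %%EL\n",
              x$gene, x$slope_id, x$polarity, x$channel,
              x$knots$x[1], x$knots$x[2], x$knots$x[3]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a boundary spline into its knots
#'
#' @param x A `boundary_spline`.
#' @param ... Unused.
#' @return Tibble with one row per knot: `gene`, `slope_id`, `polarity`,
#'   `channel`, `label`, `x`, `y`.
#' @export
tidy.boundary_spline <- function(x, ...) {
  k <- x$knots
  tibble(gene = x$gene, slope_id = x$slope_id, polarity = x$polarity,
         channel = x$channel, label = k$label, x = k$x, y = k$y)
}

#' One-row summary of a boundary spline
#'
#' @param x A `boundary_spline`.
#' @param ... Unused.
#' @return One-row tibble with labels, the three knots, and the window width.
#' @export
glance.boundary_spline <- function(x, ...) {
  k <- x$knots
  tibble(gene = x$gene, slope_id = x$slope_id, polarity = x$polarity,
         channel = x$channel,
         x0 = k$x[1], y0 = k$y[1], x1 = k$x[2], y1 = k$y[2],
         x2 = k$x[3], y2 = k$y[3], width = abs(k$x[3] - k$x[1]))
}

#' Suggest a boundary window from a profile
#'
#' Advisory helper encoding the manual placement guidelines: the inner edge
#' where the signal levels off (here, the position nearest the domain where
#' the smoothed signal reaches 90% of the plateau) and the outer edge where
#' signal stops being distinguishable from background (first position below
#' the background mean + 2 SD, background estimated from the lowest quartile
#' of smoothed values). The suggestion is never auto-committed; manual
#' windows remain the primary interface.
#'
#' @param profile Tibble with `position` and a signal column.
#' @param polarity `"anterior"` (domain to the right of the boundary) or
#'   `"posterior"` (domain to the left).
#' @param signal_col Name of the signal column.
#' @param smooth_window Moving-average width in samples.
#' @return One-row tibble with `x0`, `x2`, `found`; `found = FALSE` with `NA`
#'   positions when no candidate exists.
#' @export
suggest_window <- function(profile, polarity = c("anterior", "posterior"),
                           signal_col = "signal", smooth_window = 5) {
  polarity <- match.arg(polarity)
  sig <- profile[[signal_col]]
  pos <- profile$position
  no_candidate <- tibble(x0 = NA_real_, x2 = NA_real_, found = FALSE)
  if (diff(range(sig)) == 0) return(no_candidate)
  k <- min(smooth_window, length(sig))
  kern <- rep(1 / k, k)
  pad <- (k - 1) %/% 2
  padded <- c(rep(sig[1], pad), sig, rep(sig[length(sig)], k - 1 - pad))
  s <- as.numeric(stats::filter(padded, kern, sides = 2))
  s <- s[(pad + 1):(pad + length(sig))]
  plateau <- max(s)
  low <- s[s <= stats::quantile(s, 0.25)]
  thr_bg <- mean(low) + 2 * stats::sd(low)
  if (!is.finite(thr_bg)) thr_bg <- mean(low)
  thr_hi <- 0.9 * plateau
  idx <- seq_along(s)
  if (polarity == "anterior") {
    i2 <- idx[s >= thr_hi][1]
    if (is.na(i2)) return(no_candidate)
    below <- idx[idx < i2 & s < thr_bg]
    if (!length(below)) return(no_candidate)
    i0 <- max(below)
    tibble(x0 = pos[i0], x2 = pos[i2], found = TRUE)
  } else {
    cand <- idx[s >= thr_hi]
    i2 <- cand[length(cand)]
    if (!length(cand)) return(no_candidate)
    below <- idx[idx > i2 & s < thr_bg]
    if (!length(below)) return(no_candidate)
    i0 <- min(below)
    tibble(x0 = pos[i0], x2 = pos[i2], found = TRUE)
  }
}
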