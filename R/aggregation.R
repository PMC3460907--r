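# Grouping boundaries by gene / slope / time class: median boundaries,
# variability datasets, and space-time tables.

#' Developmental time-class vocabulary
#'
#' Pre-gastrulation stages are cleavage cycles C1..C14A (cycle n spans
#' mitoses n-1 to n); embryos in C14A are further subdivided into eight
#' time points (T1..T8) of 6-7 minutes based on membrane morphology.
#'
#' @return Character vector of valid time classes, in temporal order.
#' @export
time_class_levels <- function() {
  c(paste0("C", 1:13), "C14A", paste0("C14A_T", 1:8))
}

#' Validate a time class
#'
#' @param x Character vector of time-class labels.
#' @return Logical vector: is each label in the controlled vocabulary?
#' @export
is_valid_time_class <- function(x) x %in% time_class_levels()

time_class_factor <- function(x) factor(x, levels = time_class_levels(), ordered = TRUE)

#' Collect boundary splines into a table
#'
#' @param boundaries List of `boundary_spline` objects.
#' @param embryo_id Optional character vector, one id per boundary.
#' @param time_class Optional character vector of time classes.
#' @return Tibble with one row per boundary: labels, knots and window width.
#' @export
boundary_table <- function(boundaries, embryo_id = NULL, time_class = NULL) {
  tbl <- purrr::map_dfr(boundaries, glance)
  if (!is.null(embryo_id)) tbl <- dplyr::mutate(tbl, embryo_id = embryo_id, .before = 1L)
  if (!is.null(time_class)) {
    bad <- unique(time_class[!is_valid_time_class(time_class)])
    if (length(bad)) {
      abort(sprintf("invalid time class: %s", paste(bad, collapse = ", ")),
            class = "flystrip_vocabulary_error")
    }
    tbl <- dplyr::mutate(tbl, time_class = time_class)
  }
  tbl
}

#' Median boundary of a group
#'
#' Takes the median starting and end knots over a group of homologous
#' boundaries: medians of the x0 and x2 values (and of the y values) are
#' computed independently, even-sized groups using the mean of the two
#' central order statistics. The middle knot sits at the midpoint of the
#' median x0 and x2, with y1 the median of the individual y1 values, and the
#' clamped spline is refitted on the median knots.
#'
#' @param boundaries A boundary table (see [boundary_table()]) or a list of
#'   `boundary_spline` objects; all rows must share `gene`, `slope_id`,
#'   `polarity` (and `time_class` if present).
#' @return A `median_boundary` (also a `boundary_spline`) carrying `n`, the
#'   number of boundaries aggregated.
#' @export
median_boundary <- function(boundaries) {
  tbl <- if (is.data.frame(boundaries)) boundaries else boundary_table(boundaries)
  if (!nrow(tbl)) abort("empty boundary group", class = "flystrip_parameter_error")
  keys <- intersect(c("gene", "slope_id", "polarity", "channel", "time_class"), names(tbl))
  if (nrow(dplyr::distinct(tbl[keys])) != 1L) {
    abort("mixed labels in boundary group; group by gene/slope/polarity/time class first",
          class = "flystrip_parameter_error")
  }
  x0 <- stats::median(tbl$x0); x2 <- stats::median(tbl$x2)
  y0 <- stats::median(tbl$y0); y2 <- stats::median(tbl$y2)
  y1 <- stats::median(tbl$y1)
  x1 <- min(x0, x2) + abs(x2 - x0) / 2
  xs <- c(min(x0, x2), x1, max(x0, x2))
  ys <- if (x0 < x2) c(y0, y1, y2) else c(y2, y1, y0)
  m <- clamped_spline_slopes(xs, ys)
  out <- structure(list(
    gene = tbl$gene[1], slope_id = tbl$slope_id[1], polarity = tbl$polarity[1],
    channel = tbl$channel[1],
    knots = tibble(label = c("x0", "x1", "x2"), x = c(x0, x1, x2), y = c(y0, y1, y2)),
    xs = xs, ys = ys, m = m, n = nrow(tbl)
  ), class = c("median_boundary", "boundary_spline"))
  if ("time_class" %in% keys) out$time_class <- tbl$time_class[1]
  out
}

#' Min-max normalise intensities to [0, 1]
#'
#' @param v Numeric vector.
#' @return `(v - min) / (max - min)`; a constant input returns all zeros
#'   with a warning.
#' @export
normalize_intensity <- function(v) {
  r <- range(v)
  if (diff(r) == 0) {
    warn("constant intensity array; normalisation returns zeros")
    return(rep(0, length(v)))
  }
  (v - r[1]) / (r[2] - r[1])
}

refit_row_spline <- function(row) {
  xs <- c(min(row$x0, row$x2), row$x1, max(row$x0, row$x2))
  ys <- if (row$x0 < row$x2) c(row$y0, row$y1, row$y2) else c(row$y2, row$y1, row$y0)
  list(xs = xs, ys = ys, m = clamped_spline_slopes(xs, ys))
}

eval_row_spline <- function(sp, n_grid) {
  xx <- seq(sp$xs[1], sp$xs[3], length.out = n_grid)
  yy <- eval_clamped(sp$xs, sp$ys, sp$m, xx)
  list(x = xx, y = yy)
}

#' Variability dataset for plotting boundary distributions
#'
#' Evaluates individual boundary splines and/or their per-group median
#' spline on a position grid, with intensities min-max normalised per curve.
#' When more than one gene is selected, only median splines are returned.
#'
#' @param boundaries Boundary table with `embryo_id` and `time_class` columns.
#' @param genes,slopes,time_classes Optional filters (`NULL` keeps all).
#' @param mode `"slopes_and_medians"`, `"medians_only"` or `"slopes_only"`.
#' @param n_grid Samples per curve.
#' @return Tibble with columns `gene`, `slope_id`, `polarity`, `time_class`,
#'   `embryo_id` (`NA` for medians), `kind` (`"slope"`/`"median"`),
#'   `position`, `intensity`.
#' @export
variability_dataset <- function(boundaries, genes = NULL, slopes = NULL,
                                time_classes = NULL,
                                mode = c("slopes_and_medians", "medians_only",
                                         "slopes_only"),
                                n_grid = 50) {
  mode <- match.arg(mode)
  tbl <- boundaries
  if (!is.null(genes)) tbl <- dplyr::filter(tbl, .data$gene %in% genes)
  if (!is.null(slopes)) tbl <- dplyr::filter(tbl, .data$slope_id %in% slopes)
  if (!is.null(time_classes)) tbl <- dplyr::filter(tbl, .data$time_class %in% time_classes)
  empty <- tibble(gene = character(), slope_id = integer(), polarity = character(),
                  time_class = character(), embryo_id = character(),
                  kind = character(), position = double(), intensity = double())
  if (!nrow(tbl)) {
    inform("empty selection: no boundaries match")
    return(empty)
  }
  if (dplyr::n_distinct(tbl$gene) > 1L && mode != "medians_only") {
    inform("multiple genes selected: displaying medians only")
    mode <- "medians_only"
  }
  groups <- dplyr::group_split(dplyr::group_by(
    tbl, .data$gene, .data$slope_id, .data$polarity, .data$time_class))
  purrr::map_dfr(groups, function(g) {
    out <- list()
    if (mode %in% c("slopes_and_medians", "slopes_only")) {
      out$slopes <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
        ev <- eval_row_spline(refit_row_spline(g[i, ]), n_grid)
        tibble(gene = g$gene[1], slope_id = g$slope_id[1], polarity = g$polarity[1],
               time_class = g$time_class[1], embryo_id = g$embryo_id[i],
               kind = "slope", position = ev$x,
               intensity = suppressWarnings(normalize_intensity(ev$y)))
      })
    }
    if (mode %in% c("slopes_and_medians", "medians_only")) {
      med <- median_boundary(g)
      ev <- eval_row_spline(list(xs = med$xs, ys = med$ys, m = med$m), n_grid)
      out$median <- tibble(gene = g$gene[1], slope_id = g$slope_id[1],
                           polarity = g$polarity[1], time_class = g$time_class[1],
                           embryo_id = NA_character_, kind = "median",
                           position = ev$x,
                           intensity = suppressWarnings(normalize_intensity(ev$y)))
    }
    dplyr::bind_rows(out)
  })
}

#' Space-time table of median boundary mid-points
#'
#' For each (gene, slope, time class) group, the mid-point x1 of the median
#' boundary, ordered by developmental time. Space-time plots display these
#' mid-points with A-P position on the x-axis and time on the y-axis.
#'
#' @param boundaries Boundary table with a `time_class` column.
#' @param genes Optional gene filter.
#' @param time_classes Optional time-class filter.
#' @return Tibble with `gene`, `slope_id`, `polarity`, `time_class`,
#'   `x1_percent`, `n`, ordered by time class.
#' @export
spacetime_table <- function(boundaries, genes = NULL, time_classes = NULL) {
  tbl <- boundaries
  if (!is.null(genes)) tbl <- dplyr::filter(tbl, .data$gene %in% genes)
  if (!is.null(time_classes)) tbl <- dplyr::filter(tbl, .data$time_class %in% time_classes)
  if (!nrow(tbl)) {
    return(tibble(gene = character(), slope_id = integer(), polarity = character(),
                  time_class = character(), x1_percent = double(), n = integer()))
  }
  groups <- dplyr::group_split(dplyr::group_by(
    tbl, .data$gene, .data$slope_id, .data$polarity, .data$time_class))
  out <- purrr::map_dfr(groups, function(g) {
    med <- median_boundary(g)
    tibble(gene = g$gene[1], slope_id = g$slope_id[1], polarity = g$polarity[1],
           time_class = g$time_class[1], x1_percent = med$knots$x[2], n = med$n)
  })
  dplyr::arrange(out, time_class_factor(.data$time_class), .data$gene, .data$slope_id)
}
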