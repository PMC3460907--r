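# Morphological skeleton of the embryo mask and the midline main branch.

#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning: iteratively peels boundary pixels until a
#' 1-pixel-wide, 8-connected medial representation remains. The skeleton is
#' always a subset of the mask foreground.
#'
#' @param mask Binary matrix (`{0, 255}`), single blob expected.
#' @return Binary matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  if (!any(mask > 0)) abort("empty mask", class = "flystrip_degenerate_error")
  h <- nrow(mask); w <- ncol(mask)
  bb <- mask_bbox(mask)
  # work on the padded bounding box only
  sub <- mask[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE] > 0
  b <- matrix(FALSE, nrow(sub) + 2L, ncol(sub) + 2L)
  b[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub

  neighbours <- function(m) {
    list(
      p2 = shift_logical(m, -1L, 0L), p3 = shift_logical(m, -1L, 1L),
      p4 = shift_logical(m, 0L, 1L),  p5 = shift_logical(m, 1L, 1L),
      p6 = shift_logical(m, 1L, 0L),  p7 = shift_logical(m, 1L, -1L),
      p8 = shift_logical(m, 0L, -1L), p9 = shift_logical(m, -1L, -1L)
    )
  }
  repeat {
    changed <- FALSE
    for (sub_iter in 1:2) {
      nb <- neighbours(b)
      bsum <- Reduce(`+`, nb)
      seq9 <- nb[c(1:8, 1)]
      a <- Reduce(`+`, lapply(1:8, function(i) !seq9[[i]] & seq9[[i + 1]]))
      cond <- b & bsum >= 2 & bsum <= 6 & a == 1
      if (sub_iter == 1L) {
        cond <- cond & !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
      } else {
        cond <- cond & !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
      }
      if (any(cond)) {
        b[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- matrix(0, h, w)
  core <- b[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)]
  out[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"]][core] <- 255
  out
}

#' Extract the skeleton's main branch
#'
#' The main branch is the longest geodesic path between skeleton endpoints
#' (pixels with a single skeleton neighbour), with diagonal steps weighted
#' `sqrt(2)`. The returned path is ordered anterior to posterior (left to
#' right). A cyclic skeleton without endpoints falls back to the leftmost
#' and rightmost skeleton pixels as termini.
#'
#' @param skeleton Binary matrix from [skeletonize()].
#' @return A tibble with columns `row`, `col`: an ordered, duplicate-free,
#'   8-connected pixel path.
#' @export
main_branch <- function(skeleton) {
  pts <- which(skeleton > 0, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0L) abort("empty skeleton", class = "flystrip_degenerate_error")
  if (n == 1L) return(tibble(row = pts[1, 1], col = pts[1, 2]))
  id <- matrix(0L, nrow(skeleton), ncol(skeleton))
  id[pts] <- seq_len(n)

  edges <- NULL
  weights <- NULL
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nr <- pts[, 1] + off[1]; nc <- pts[, 2] + off[2]
    ok <- nr >= 1 & nr <= nrow(skeleton) & nc >= 1 & nc <= ncol(skeleton)
    ok[ok] <- id[cbind(nr[ok], nc[ok])] > 0L
    if (!any(ok)) next
    edges <- rbind(edges, cbind(seq_len(n)[ok], id[cbind(nr[ok], nc[ok])]))
    weights <- c(weights, rep(if (all(off != 0L)) sqrt(2) else 1, sum(ok)))
  }
  if (is.null(edges)) {
    # isolated pixels only: return the widest-spanning single pixel pair
    ord <- order(pts[, 2])
    return(tibble(row = pts[ord[1], 1], col = pts[ord[1], 2]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- weights
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))

  comp <- igraph::components(g)
  main_comp <- which.max(comp$csize)
  members <- which(comp$membership == main_comp)

  deg <- igraph::degree(g)
  ends <- members[deg[members] == 1L]
  if (length(ends) < 2L) {
    # cyclic or blob-like skeleton: leftmost/rightmost pixels as termini
    ends <- c(members[which.min(pts[members, 2])], members[which.max(pts[members, 2])])
  }
  d <- igraph::distances(g, v = ends, to = ends)
  d[!is.finite(d)] <- -Inf
  best <- arrayInd(which.max(d), dim(d))
  if (d[best] <= 0 && length(ends) >= 2L) best <- matrix(c(1L, 2L), 1)
  path <- igraph::shortest_paths(g, from = ends[best[1]], to = ends[best[2]],
                                 output = "vpath")$vpath[[1]]
  path <- as.integer(path)
  out <- tibble(row = pts[path, 1], col = pts[path, 2])
  if (out$col[1] > out$col[nrow(out)]) out <- out[rev(seq_len(nrow(out))), ]
  out
}

#' Place equidistant knots along a path
#'
#' Returns `k` points at arc-length fractions `0, 1/(k-1), ..., 1` of the
#' path, interpolated along the polyline so consecutive spacings are equal.
#'
#' @param path Tibble with `row`, `col` (from [main_branch()]).
#' @param k Number of knots (default 5).
#' @return Tibble with columns `x` (column coordinate) and `y` (row
#'   coordinate), `k` rows.
#' @export
equidistant_knots <- function(path, k = 5) {
  n <- nrow(path)
  if (n < k) {
    abort(sprintf("path has %d pixels; need at least %d", n, k),
          class = "flystrip_degenerate_error")
  }
  seg <- sqrt(diff(path$col)^2 + diff(path$row)^2)
  s <- c(0, cumsum(seg))
  targets <- s[n] * seq(0, 1, length.out = k)
  tibble(
    x = stats::approx(s, path$col, xout = targets, ties = "ordered")$y,
    y = stats::approx(s, path$row, xout = targets, ties = "ordered")$y
  )
}
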