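# Connected-component labelling on binary matrices.
#
# Runs of foreground pixels are extracted per row and merged across rows with
# a union-find; 8-connectivity admits diagonal contact (overlap tolerance of
# one column), 4-connectivity requires direct column overlap.

#' Label connected foreground components
#'
#' @param img Binary matrix; any value `> 0` is foreground.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape; background 0, components
#'   labelled `1..k` in scan order.
#' @export
label_components <- function(img, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  fg <- img > 0
  h <- nrow(fg); w <- ncol(fg)
  tol <- if (connectivity == 8) 1L else 0L

  starts <- vector("list", h)
  ends <- vector("list", h)
  nrun_row <- integer(h)
  for (i in seq_len(h)) {
    d <- diff(c(FALSE, fg[i, ], FALSE))
    s <- which(d == 1L)
    if (length(s)) {
      starts[[i]] <- s
      ends[[i]] <- which(d == -1L) - 1L
      nrun_row[i] <- length(s)
    }
  }
  total <- sum(nrun_row)
  if (total == 0L) return(matrix(0L, h, w))

  parent <- seq_len(total)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }

  first_id <- cumsum(c(0L, nrun_row))[seq_len(h)]  # id offset per row
  for (i in 2:h) {
    na <- nrun_row[i - 1L]; nb <- nrun_row[i]
    if (na == 0L || nb == 0L) next
    sa <- starts[[i - 1L]]; ea <- ends[[i - 1L]]
    sb <- starts[[i]]; eb <- ends[[i]]
    ia <- 1L
    for (b in seq_len(nb)) {
      while (ia <= na && ea[ia] < sb[b] - tol) ia <- ia + 1L
      ja <- ia
      while (ja <= na && sa[ja] <= eb[b] + tol) {
        ra <- find(first_id[i - 1L] + ja)
        rb <- find(first_id[i] + b)
        if (ra != rb) parent[ra] <- rb
        ja <- ja + 1L
      }
    }
  }

  roots <- vapply(seq_len(total), find, integer(1))
  labels <- match(roots, unique(roots))
  lab <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    if (nrun_row[i] == 0L) next
    s <- starts[[i]]; e <- ends[[i]]
    for (k in seq_len(nrun_row[i])) {
      lab[i, s[k]:e[k]] <- labels[first_id[i] + k]
    }
  }
  lab
}

# Shifted logical views used by dilation/thinning: value of the 8-neighbour
# at offset (dr, dc), with out-of-image neighbours equal to `fill`.
shift_logical <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L - dr):min(h, h - dr)
  cs <- max(1L, 1L - dc):min(w, w - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}
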