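# Shared helpers: brute-force image oracles, analytic masks, and cached
# synthetic fixtures (rendered once per test run).

iou <- function(a, b) sum(a > 0 & b > 0) / sum(a > 0 | b > 0)

# queue-based flood-fill labelling, independent of the package's run-length
# union-find implementation
bf_label <- function(img, connectivity = 8) {
  h <- nrow(img); w <- ncol(img)
  offsets <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (img[r, c] > 0 && lab[r, c] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(r, c))
      lab[r, c] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(offsets))) {
          rr <- p[1] + offsets[k, 1]; cc <- p[2] + offsets[k, 2]
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              img[rr, cc] > 0 && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

bf_kill_border_blobs <- function(img) {
  lab <- bf_label(img, 8)
  h <- nrow(img); w <- ncol(img)
  bad <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  bad <- bad[bad > 0]
  img[lab %in% bad] <- 0
  img
}

bf_fill_holes <- function(img) {
  bg <- (img <= 0) * 1
  lab <- bf_label(bg, 4)
  h <- nrow(img); w <- ncol(img)
  open_bg <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  open_bg <- open_bg[open_bg > 0]
  img[lab > 0 & !(lab %in% open_bg)] <- 255
  img
}

# analytic (plain ellipse) binary mask, for orientation oracles
make_ellipse_mask <- function(h, w, a, b, theta_deg = 0) {
  th <- theta_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  rr <- matrix(seq_len(h), h, w)
  xc <- cc - cx; yc <- cy - rr
  u <- cos(th) * xc + sin(th) * yc
  v <- -sin(th) * xc + cos(th) * yc
  255 * ((u / a)^2 + (v / b)^2 <= 1)
}

# half-maximum crossings of a unimodal domain profile, in %EL
half_max_crossings <- function(position, signal) {
  lo <- min(signal); hi <- max(signal)
  half <- (lo + hi) / 2
  above <- which(signal >= half)
  cross <- function(i0, i1) {
    # linear interpolation between the bracketing samples
    if (i0 < 1 || i1 > length(signal)) return(position[max(min(i1, length(signal)), 1)])
    stats::approx(signal[c(i0, i1)], position[c(i0, i1)], xout = half)$y
  }
  c(anterior = cross(min(above) - 1L, min(above)),
    posterior = cross(max(above) + 1L, max(above)))
}

# fixtures rendered once per test run
.fx <- new.env(parent = emptyenv())
fx <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fx_noiseless <- function() fx("noiseless", render_embryo(synthetic_embryo_spec(noise_sd = 0)))

fx_chain <- function() fx("chain", {
  em <- fx_noiseless()
  mk <- make_mask(em$images$dic)
  rc <- rotate_and_crop(mk, list(brightfield = em$images$brightfield))
  strip <- build_strip(axis_spline(rc$mask), rc$mask)
  profile <- extract_profile(rc$images$brightfield, strip)
  list(em = em, mk = mk, rc = rc, strip = strip, profile = profile)
})

fx_chain_default <- function() fx("chain_default", {
  em <- render_embryo(synthetic_embryo_spec())  # default noise level
  mk <- make_mask(em$images$dic)
  rc <- rotate_and_crop(mk, list(brightfield = em$images$brightfield))
  strip <- build_strip(axis_spline(rc$mask), rc$mask)
  profile <- extract_profile(rc$images$brightfield, strip)
  list(em = em, mk = mk, rc = rc, strip = strip, profile = profile)
})

# small, fast-rendering spec for mechanics-only tests
small_spec <- function(...) {
  synthetic_embryo_spec(canvas = c(220, 320), semi_major = 90, semi_minor = 38,
                        nucleus_count = 25, ...)
}
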