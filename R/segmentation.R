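# The embryo-mask pipeline: a fixed sequence of 13 image operations that
# isolates a single embryo blob from a 10x DIC micrograph.

#' Segmentation parameters
#'
#' Bundles the tunable parameters of the mask pipeline. Defaults are the
#' pipeline's standard settings: a strong gamma compression (0.08) that
#' suppresses background texture before Sobel edge detection, an edge
#' threshold of 6, a blob-area divisor (beta) of 13.0 so that blobs smaller
#' than 1/13 of the image area are treated as artefacts, and a Gaussian
#' smoothing of the mask with sigma 31 px (kernel truncated at tail mass
#' 1e-3) followed by re-thresholding at 145.
#'
#' @param gamma Gamma-correction exponent, `> 0`.
#' @param edge_threshold Binarisation cutoff applied to the edge image, in
#'   `[0, 255]`; pixels `<=` the cutoff become background.
#' @param beta Image-area divisor for supernumerary blob removal, `> 0`.
#' @param blur_sigma Standard deviation of the mask-smoothing Gaussian (px).
#' @param blur_accuracy Maximum Gaussian tail mass omitted by kernel
#'   truncation (per axis).
#' @param post_blur_threshold Binarisation cutoff after smoothing.
#' @return A `seg_params` list.
#' @export
seg_params <- function(gamma = 0.08, edge_threshold = 6, beta = 13.0,
                       blur_sigma = 31, blur_accuracy = 1e-3,
                       post_blur_threshold = 145) {
  if (gamma <= 0) abort("gamma must be > 0", class = "flystrip_parameter_error")
  if (beta <= 0) abort("beta must be > 0", class = "flystrip_parameter_error")
  if (edge_threshold < 0 || edge_threshold > 255 ||
      post_blur_threshold < 0 || post_blur_threshold > 255) {
    abort("thresholds must lie in [0, 255]", class = "flystrip_parameter_error")
  }
  if (blur_sigma <= 0) abort("blur_sigma must be > 0", class = "flystrip_parameter_error")
  structure(list(gamma = gamma, edge_threshold = edge_threshold, beta = beta,
                 blur_sigma = blur_sigma, blur_accuracy = blur_accuracy,
                 post_blur_threshold = post_blur_threshold),
            class = "seg_params")
}

#' Gamma-correct a grey image
#'
#' `out = round(255 * (in/255)^gamma)`; 0 and 255 are fixed points.
#'
#' @param img Grey matrix in `[0, 255]`.
#' @param gamma Exponent, `> 0`.
#' @export
gamma_correct <- function(img, gamma = 0.08) {
  if (gamma <= 0) abort("gamma must be > 0", class = "flystrip_parameter_error")
  round(255 * (img / 255)^gamma)
}

#' Invert a grey image
#'
#' `out = 255 - in`; applying it twice restores the input.
#' @param img Grey matrix in `[0, 255]`.
#' @export
invert_gray <- function(img) 255 - img

#' Sobel gradient magnitude
#'
#' 3x3 Sobel kernels in x and y; the magnitude `sqrt(gx^2 + gy^2)` is rounded
#' and clipped to `[0, 255]`. Border pixels use edge replication, which avoids
#' spurious responses along the image frame.
#'
#' @param img Grey matrix in `[0, 255]`.
#' @export
sobel_edges <- function(img) {
  h <- nrow(img); w <- ncol(img)
  p <- img[c(1L, seq_len(h), h), c(1L, seq_len(w), w)]  # replicate borders
  s <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  gx <- (s(-1L, 1L) + 2 * s(0L, 1L) + s(1L, 1L)) -
        (s(-1L, -1L) + 2 * s(0L, -1L) + s(1L, -1L))
  gy <- (s(1L, -1L) + 2 * s(1L, 0L) + s(1L, 1L)) -
        (s(-1L, -1L) + 2 * s(-1L, 0L) + s(-1L, 1L))
  pmin(round(sqrt(gx^2 + gy^2)), 255)
}

#' Threshold to a binary image
#'
#' Pixels with values lower than or equal to `t` are set to 0, all others
#' to 255.
#'
#' @param img Grey matrix.
#' @param t Cutoff in `[0, 255]`.
#' @export
binarize <- function(img, t) {
  if (t < 0 || t > 255) abort("threshold must lie in [0, 255]",
                              class = "flystrip_parameter_error")
  out <- 255 * (img > t)
  dim(out) <- dim(img)
  out
}

#' Binary dilation
#'
#' Iterated morphological dilation with a 3x3 square structuring element
#' (8-connectivity). Zero iterations return the input unchanged.
#'
#' @param img Binary matrix (`{0, 255}`).
#' @param iterations Number of dilations, `>= 0`.
#' @export
dilate <- function(img, iterations = 1) {
  stopifnot(iterations >= 0)
  fg <- img > 0
  for (i in seq_len(iterations)) {
    out <- fg
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      out <- out | shift_logical(fg, dr, dc)
    }
    fg <- out
  }
  out <- 255 * fg
  dim(out) <- dim(img)
  out
}

#' Remove blobs touching the image border
#'
#' Every 8-connected foreground component that contains a border pixel is
#' cleared; interior components are untouched.
#'
#' @param img Binary matrix (`{0, 255}`).
#' @export
kill_border_blobs <- function(img) {
  lab <- label_components(img, connectivity = 8)
  h <- nrow(lab); w <- ncol(lab)
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border <- border[border > 0L]
  if (length(border)) img[lab %in% border] <- 0
  img
}

#' Fill enclosed holes
#'
#' Background regions (4-connected) that do not reach the image border are
#' set to foreground.
#'
#' @param img Binary matrix (`{0, 255}`).
#' @export
fill_holes <- function(img) {
  bg <- 1 * (img <= 0)
  dim(bg) <- dim(img)
  lab <- label_components(bg, connectivity = 4)
  h <- nrow(lab); w <- ncol(lab)
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border <- border[border > 0L]
  hole <- lab > 0L & !(lab %in% border)
  img[hole] <- 255
  img
}

#' Remove supernumerary small blobs
#'
#' If more than one blob is present, every blob with area strictly below
#' `(height * width) / beta` pixels is removed. A lone blob is never removed.
#' If more than one blob survives, all survivors are kept and a warning is
#' recorded.
#'
#' @param img Binary matrix (`{0, 255}`).
#' @param beta Image-area divisor, `> 0`.
#' @return A list with elements `image` (binary matrix) and `warnings`
#'   (character vector).
#' @export
remove_small_blobs <- function(img, beta = 13.0) {
  if (beta <= 0) abort("beta must be > 0", class = "flystrip_parameter_error")
  lab <- label_components(img, connectivity = 8)
  k <- max(lab)
  if (k == 0L) {
    abort("no foreground blobs present", class = "flystrip_no_embryo_error")
  }
  warnings <- character()
  if (k > 1L) {
    areas <- tabulate(lab[lab > 0L], nbins = k)
    thr <- nrow(img) * ncol(img) / beta
    drop <- which(areas < thr)
    if (length(drop) == k) {
      abort("all blobs fell below the area threshold; no embryo found",
            class = "flystrip_no_embryo_error")
    }
    if (length(drop)) img[lab %in% drop] <- 0
    if (k - length(drop) > 1L) {
      warnings <- sprintf("%d blobs remain above the area threshold; expected a single embryo",
                          k - length(drop))
    }
  }
  list(image = img, warnings = warnings)
}

#' Gaussian smoothing
#'
#' Separable Gaussian convolution with edge replication. The kernel is
#' truncated at the radius where the omitted tail mass per axis drops below
#' `accuracy`, and renormalised to unit mass so constant images are fixed
#' points. The result is continuous-valued (in `[0, 255]`), matching
#' float-space blurring of 8-bit input.
#'
#' @param img Grey matrix in `[0, 255]`.
#' @param sigma Standard deviation in pixels, `> 0`.
#' @param accuracy Maximum omitted tail mass.
#' @export
gaussian_smooth <- function(img, sigma = 31, accuracy = 1e-3) {
  if (sigma <= 0) abort("sigma must be > 0", class = "flystrip_parameter_error")
  pmin(pmax(conv_gauss_sep(img, sigma, accuracy), 0), 255)
}

# separable Gaussian convolution with edge replication, as two banded-matrix
# products (BLAS); kernel radius set by the omitted tail mass
conv_gauss_sep <- function(img, sigma, accuracy) {
  r <- ceiling(sigma * stats::qnorm(1 - accuracy / 2))
  kern <- stats::dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  h <- nrow(img); w <- ncol(img)
  p <- img[c(rep(1L, r), seq_len(h), rep(h, r)),
           c(rep(1L, r), seq_len(w), rep(w, r))]
  band <- function(n) {
    k <- matrix(0, n, n + 2L * r)
    idx <- cbind(rep(seq_len(n), each = 2L * r + 1L),
                 as.vector(t(outer(seq_len(n), 0:(2L * r), `+`))))
    k[idx] <- rep(kern, n)
    k
  }
  band(h) %*% p %*% t(band(w))
}

mask_step_names <- c(
  "step01_gray", "step02_gamma", "step03_invert", "step04_edges",
  "step05_binarize", "step06_dilate", "step07_kill_border", "step08_dilate",
  "step09_fill_holes", "step10_kill_border", "step11_remove_small",
  "step12_gaussian", "step13_binarize", "step14_remove_small"
)

#' Create the embryo mask from a DIC image
#'
#' Runs the fixed mask pipeline on a 10x DIC micrograph: grey conversion,
#' gamma correction, inversion, Sobel edges, binarisation, two dilations,
#' border-blob removal, two further dilations, hole filling, border-blob
#' removal, small-blob removal, Gaussian smoothing, re-binarisation, and a
#' final small-blob removal. Every intermediate is recorded under its step
#' name. The input scene must contain a single whole embryo; any other
#' embryos must touch the image border (they are discarded).
#'
#' @param dic RGB DIC image (`height x width x 3`, values in `[0, 255]`).
#' @param params A [seg_params()] list.
#' @return An `embryo_mask` object: `mask` (binary matrix), `intermediates`
#'   (named list of the 14 recorded stages), `params`, `quality` (`"good"`,
#'   `"ok"` or `"not good"`), `warnings`, `n_blobs`.
#' @export
make_mask <- function(dic, params = seg_params()) {
  if (!is_rgb_image(dic)) {
    abort("DIC input must be an RGB image", class = "flystrip_format_error")
  }
  assert_min_size(dic)
  steps <- vector("list", 14L)
  names(steps) <- mask_step_names
  warnings <- character()

  check_alive <- function(img, step) {
    if (!any(img > 0)) {
      abort(sprintf("no embryo found: foreground vanished at %s", step),
            class = "flystrip_no_embryo_error")
    }
    img
  }

  steps[[1]] <- to_gray8(dic)
  steps[[2]] <- gamma_correct(steps[[1]], params$gamma)
  steps[[3]] <- invert_gray(steps[[2]])
  steps[[4]] <- sobel_edges(steps[[3]])
  steps[[5]] <- check_alive(binarize(steps[[4]], params$edge_threshold), "step05_binarize")
  steps[[6]] <- dilate(steps[[5]], 2)
  steps[[7]] <- check_alive(kill_border_blobs(steps[[6]]), "step07_kill_border")
  steps[[8]] <- dilate(steps[[7]], 2)
  steps[[9]] <- fill_holes(steps[[8]])
  steps[[10]] <- check_alive(kill_border_blobs(steps[[9]]), "step10_kill_border")
  r11 <- remove_small_blobs(steps[[10]], params$beta)
  steps[[11]] <- r11$image
  warnings <- c(warnings, r11$warnings)
  steps[[12]] <- gaussian_smooth(steps[[11]], params$blur_sigma, params$blur_accuracy)
  steps[[13]] <- check_alive(binarize(steps[[12]], params$post_blur_threshold), "step13_binarize")
  r14 <- remove_small_blobs(steps[[13]], params$beta)
  steps[[14]] <- r14$image
  warnings <- c(warnings, r14$warnings)

  mask <- steps[[14]]
  n_blobs <- max(label_components(mask, 8))
  h <- nrow(mask); w <- ncol(mask)
  on_border <- any(mask[1, ] > 0) || any(mask[h, ] > 0) ||
    any(mask[, 1] > 0) || any(mask[, w] > 0)
  if (on_border) warnings <- c(warnings, "mask foreground touches the image border")
  quality <- if (n_blobs > 1L || on_border) "not good"
             else if (length(warnings)) "ok" else "good"

  structure(list(mask = mask, intermediates = steps, params = params,
                 quality = quality, warnings = warnings, n_blobs = n_blobs),
            class = "embryo_mask")
}

#' @export
print.embryo_mask <- function(x, ...) {
  cat(sprintf("<embryo_mask> %dx%d px, %d blob(s), quality: %s\n",
              nrow(x$mask), ncol(x$mask), x$n_blobs, x$quality))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
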