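# Synthetic embryo image sets with exact ground truth. The generator
# emulates the four-image acquisition (bright-field, DIC, nuclear
# counterstain, membrane detail) well enough to exercise every pipeline
# stage: a textured ellipse with a dark DIC outline for segmentation, and
# logistic expression ramps written into the bright-field channels so the
# stain-extraction formulas recover the programmed plateaus.

logistic <- function(z) 1 / (1 + exp(-z))

#' Describe a synthetic expression domain
#'
#' Domain intensity along the A-P axis follows
#' `plateau * (logistic((x - anterior)/steepness) - logistic((x - posterior)/steepness))`,
#' the graded-boundary shape the boundary model assumes.
#'
#' @param stain `"NBT_BCIP"` (written into the red channel) or `"FastRed"`
#'   (written as green-over-red excess).
#' @param anterior,posterior Domain boundary positions in %EL, in `(0, 100)`.
#' @param steepness Boundary steepness in %EL.
#' @param plateau Plateau intensity in `(0, 255]`.
#' @export
expression_domain <- function(stain = c("NBT_BCIP", "FastRed"),
                              anterior = 40, posterior = 60,
                              steepness = 1.5, plateau = 150) {
  stain <- match.arg(stain)
  if (anterior <= 0 || anterior >= 100 || posterior <= 0 || posterior >= 100) {
    abort("domain boundaries must lie in (0, 100) %EL", class = "flystrip_parameter_error")
  }
  if (plateau <= 0 || plateau > 255) {
    abort("plateau must lie in (0, 255]", class = "flystrip_parameter_error")
  }
  list(stain = stain, anterior = anterior, posterior = posterior,
       steepness = steepness, plateau = plateau)
}

#' Specify a synthetic embryo image set
#'
#' Defaults emulate a single blastoderm-stage embryo imaged laterally at
#' 10x: a 960x720 px scene with an ovoid embryo of semi-axes
#' 300 x 120 px (roughly a 500 um embryo at typical binned wide-field
#' sampling), mild sensor noise, and one NBT/BCIP-stained abdominal domain.
#'
#' @param canvas `c(height, width)` in pixels.
#' @param semi_major,semi_minor Ellipse semi-axes in pixels
#'   (`semi_major > semi_minor > 0`).
#' @param rotation Embryo rotation in degrees (counter-clockwise, y-up).
#' @param centre_offset `c(row, col)` offset of the embryo centre from the
#'   canvas centre.
#' @param domains List of [expression_domain()] descriptions.
#' @param background Bright-field channel baseline in `[0, 255]`.
#' @param noise_sd Gaussian pixel noise SD (intensity units) on all images.
#' @param nucleus_count Number of nuclei rendered in the counterstain image.
#' @param neighbor_at_border Render a second, border-touching embryo.
#' @param seed RNG seed; rendering is deterministic given the spec.
#' @return A `synthetic_embryo_spec` list.
#' @export
synthetic_embryo_spec <- function(canvas = c(720, 960),
                                  semi_major = 300, semi_minor = 120,
                                  rotation = 0, centre_offset = c(0, 0),
                                  domains = list(expression_domain()),
                                  background = 40, noise_sd = 5,
                                  nucleus_count = 100,
                                  neighbor_at_border = FALSE, seed = 1) {
  if (!(semi_major > semi_minor && semi_minor > 0)) {
    abort("need semi_major > semi_minor > 0", class = "flystrip_parameter_error")
  }
  structure(list(canvas = canvas, semi_major = semi_major, semi_minor = semi_minor,
                 rotation = rotation, centre_offset = centre_offset,
                 domains = domains, background = background, noise_sd = noise_sd,
                 nucleus_count = nucleus_count,
                 neighbor_at_border = neighbor_at_border, seed = seed),
            class = "synthetic_embryo_spec")
}

# body coordinate fields for the canvas: u along the major axis, v along
# the minor axis, rho the normalised superelliptic radius, d a signed
# distance (px) to the body outline (negative inside). The outline is a
# superellipse (exponent n > 2): blastoderm embryos are ovoid with blunt
# poles, not pointed ellipse tips.
ellipse_fields <- function(h, w, cy, cx, a, b, theta_deg, n = 2.5) {
  th <- theta_deg * pi / 180
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  rr <- matrix(seq_len(h), h, w)
  xc <- cc - cx
  yc <- cy - rr
  u <- cos(th) * xc + sin(th) * yc
  v <- -sin(th) * xc + cos(th) * yc
  s <- (abs(u) / a)^n + (abs(v) / b)^n
  rho <- s^(1 / n)
  grad <- s^(1 / n - 1) * sqrt(abs(u)^(2 * n - 2) / a^(2 * n) +
                               abs(v)^(2 * n - 2) / b^(2 * n))
  grad[!is.finite(grad)] <- 1e-9  # exact body centre
  d <- (rho - 1) / pmax(grad, 1e-9)
  d <- pmin(pmax(d, -1e4), 1e4)
  list(u = u, v = v, rho = rho, d = d)
}

clamp8 <- function(m) round(pmin(pmax(m, 0), 255))

# band-limited sensor noise: white Gaussian noise smoothed by a small
# optical-scale kernel and rescaled to the requested
# per-pixel SD. Wide-field images carry no pixel-scale white noise: the
# optical transfer function and demosaicing suppress it.
noise_mat <- function(h, w, sd, corr_sigma = 2) {
  if (sd <= 0) return(matrix(0, h, w))
  n <- conv_gauss_sep(matrix(stats::rnorm(h * w), h, w), corr_sigma, 1e-2)
  n * (sd / stats::sd(n))
}

to_rgb <- function(gray, noise_sd) {
  h <- nrow(gray); w <- ncol(gray)
  out <- array(0, dim = c(h, w, 3))
  if (noise_sd > 0) {
    for (ch in 1:3) {
      out[, , ch] <- clamp8(gray + noise_mat(h, w, noise_sd))
    }
  } else {
    out[] <- clamp8(gray)
  }
  out
}

render_dic_body <- function(gray, f) {
  # smooth interior/background step, dark outline ring, interior texture
  base <- 180 - 25 * logistic(-f$d / 1.5)
  ring <- 120 * exp(-((f$d + 0.5) / 0.8)^2)
  tex <- 12 * sin(f$u / 6) * sin(f$v / 6) * logistic(-(f$d + 5) / 1.5)
  pmin(gray, base - ring + tex)
}

#' Render a synthetic embryo image set
#'
#' Produces the four registered images (bright-field with stained domains,
#' DIC with a dark embryo outline and interior texture, nuclear counterstain
#' dots, and a 40x membrane texture) plus exact ground truth. Deterministic
#' for a fixed spec (byte-identical on re-run).
#'
#' @param spec A [synthetic_embryo_spec()].
#' @return A list with `images` (named list: `brightfield`, `dic`,
#'   `nuclear`, `membrane`, RGB arrays in `[0, 255]`), `truth` (list:
#'   `mask` binary matrix, `angle` degrees, `domains` tibble of boundary
#'   positions in %EL, `midline` tibble), and `spec`.
#' @export
render_embryo <- function(spec) {
  h <- spec$canvas[1]; w <- spec$canvas[2]
  a <- spec$semi_major; b <- spec$semi_minor
  cy <- (h + 1) / 2 + spec$centre_offset[1]
  cx <- (w + 1) / 2 + spec$centre_offset[2]
  th <- spec$rotation * pi / 180
  ext_x <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  ext_y <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  if (cx - ext_x < 2 || cx + ext_x > w - 1 || cy - ext_y < 2 || cy + ext_y > h - 1) {
    abort("embryo exceeds the canvas", class = "flystrip_parameter_error")
  }

  withr::with_seed(spec$seed, {
    f <- ellipse_fields(h, w, cy, cx, a, b, spec$rotation)
    inside <- f$rho <= 1
    el <- (f$u + a) / (2 * a) * 100  # percent egg length along the major axis

    # --- DIC ---
    dic_gray <- matrix(180, h, w)
    dic_gray <- render_dic_body(dic_gray, f)
    if (spec$neighbor_at_border) {
      f2 <- ellipse_fields(h, w, h * 0.85, 1, a * 0.4, b * 0.4, 20)
      dic_gray <- render_dic_body(dic_gray, f2)
    }
    dic <- to_rgb(dic_gray, spec$noise_sd)

    # --- bright-field ---
    bg <- spec$background
    red <- matrix(bg, h, w); green <- matrix(bg, h, w); blue <- matrix(bg, h, w)
    body <- 15 * logistic(-f$d / 1.5)  # faint embryo body, equal in all channels
    red <- red + body; green <- green + body; blue <- blue + body
    for (dom in spec$domains) {
      ramp <- dom$plateau * (logistic((el - dom$anterior) / dom$steepness) -
                             logistic((el - dom$posterior) / dom$steepness))
      ramp[!inside] <- 0
      if (dom$stain == "NBT_BCIP") red <- red + ramp else green <- green + ramp
    }
    bf <- array(0, dim = c(h, w, 3))
    noise <- function() noise_mat(h, w, spec$noise_sd)
    bf[, , 1] <- clamp8(red + noise())
    bf[, , 2] <- clamp8(green + noise())
    bf[, , 3] <- clamp8(blue + noise())

    # --- nuclear counterstain ---
    nuc_gray <- matrix(10, h, w)
    if (spec$nucleus_count > 0) {
      placed <- 0L
      while (placed < spec$nucleus_count) {
        nr <- stats::runif(1, cy - ext_y, cy + ext_y)
        nc <- stats::runif(1, cx - ext_x, cx + ext_x)
        uu <- cos(th) * (nc - cx) + sin(th) * (cy - nr)
        vv <- -sin(th) * (nc - cx) + cos(th) * (cy - nr)
        if ((uu / a)^2 + (vv / b)^2 > 0.95) next
        placed <- placed + 1L
        rs <- max(1L, round(nr) - 4L):min(h, round(nr) + 4L)
        cs <- max(1L, round(nc) - 4L):min(w, round(nc) + 4L)
        dot <- 160 * exp(-(outer((rs - nr)^2, (cs - nc)^2, `+`)) / (2 * 2^2))
        nuc_gray[rs, cs] <- nuc_gray[rs, cs] + dot
      }
    }
    nuc <- to_rgb(nuc_gray, spec$noise_sd)

    # --- membrane detail (40x) ---
    rrm <- matrix(seq_len(h), h, w)
    memb_gray <- 120 + 30 * sin(rrm / 3)
    memb <- to_rgb(memb_gray, spec$noise_sd)

    mask <- 255 * inside
    dim(mask) <- c(h, w)
    t_seq <- seq(-a, a, length.out = 101)
    midline <- tibble(row = cy - t_seq * sin(th), col = cx + t_seq * cos(th))
    domains <- purrr::map_dfr(spec$domains, ~ tibble(
      stain = .x$stain, anterior = .x$anterior, posterior = .x$posterior,
      steepness = .x$steepness, plateau = .x$plateau))

    list(
      images = list(brightfield = bf, dic = dic, nuclear = nuc, membrane = memb),
      truth = list(mask = mask, angle = spec$rotation, domains = domains,
                   midline = midline),
      spec = spec
    )
  })
}

#' Render a batch of synthetic embryo sets
#'
#' Each spec is rendered with its own derived seed. If `dir` is given, the
#' four images per embryo are written as `NNN.png` (bright-field),
#' `NNN_dic.png`, `NNN_nuc.png` and `NNN_memb.png`, plus a ground-truth
#' `manifest.csv`.
#'
#' @param specs List of [synthetic_embryo_spec()] objects.
#' @param dir Optional output directory (created if missing).
#' @param seed Batch seed from which per-embryo seeds are derived.
#' @return List with `sets` (rendered embryos) and `manifest` (tibble, one
#'   row per embryo and domain: id, angle, boundary ground truth).
#' @export
render_batch <- function(specs, dir = NULL, seed = 1) {
  if (!length(specs)) abort("need at least one spec", class = "flystrip_parameter_error")
  sets <- vector("list", length(specs))
  manifest <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sp$seed <- seed * 1000L + i
    sets[[i]] <- render_embryo(sp)
    id <- sprintf("%03d", i)
    mrow <- dplyr::mutate(sets[[i]]$truth$domains, embryo_id = id,
                          angle = sp$rotation, .before = 1L)
    manifest[[i]] <- mrow
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_image(sets[[i]]$images$brightfield, file.path(dir, paste0(id, ".png")))
      write_image(sets[[i]]$images$dic, file.path(dir, paste0(id, "_dic.png")))
      write_image(sets[[i]]$images$nuclear, file.path(dir, paste0(id, "_nuc.png")))
      write_image(sets[[i]]$images$membrane, file.path(dir, paste0(id, "_memb.png")))
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(sets = sets, manifest = manifest)
}
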