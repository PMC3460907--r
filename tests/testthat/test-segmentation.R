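test_that("grey conversion averages channels and validates input", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(to_gray8(px(255, 255, 255))[1, 1], 255)
  expect_equal(to_gray8(px(0, 0, 0))[1, 1], 0)
  expect_equal(to_gray8(px(30, 60, 90))[1, 1], 60)
  # luminance-style weights are honoured
  expect_equal(to_gray8(px(100, 0, 0), weights = c(1, 0, 0))[1, 1], 100)
  expect_error(to_gray8(matrix(0, 3, 3)), class = "flystrip_format_error")
  expect_error(to_gray8(px(1, 1, 1), weights = c(0, 0, 0)),
               class = "flystrip_parameter_error")
})

test_that("gamma correction fixes 0 and 255 and matches the power law", {
  expect_equal(gamma_correct(0, 0.08), 0)
  expect_equal(gamma_correct(255, 0.08), 255)
  expect_equal(gamma_correct(128, 0.08), 241)  # round(255 * (128/255)^0.08)
  v <- 0:255
  expect_equal(gamma_correct(v, 0.5), round(255 * (v / 255)^0.5))
  expect_error(gamma_correct(10, 0), class = "flystrip_parameter_error")
})

test_that("inversion is an involution", {
  m <- matrix(c(0, 100, 255, 42), 2, 2)
  expect_equal(invert_gray(m), 255 - m)
  expect_equal(invert_gray(invert_gray(m)), m)
})

test_that("Sobel magnitude matches hand-applied kernels", {
  expect_true(all(sobel_edges(matrix(77, 10, 10)) == 0))

  # vertical step 0 | 255: pixels adjacent to the step saturate
  step <- cbind(matrix(0, 6, 3), matrix(255, 6, 3))
  e <- sobel_edges(step)
  expect_true(all(e[, 3:4] == 255))
  expect_true(all(e[, c(1, 6)] == 0))

  # 45-degree corner: |gx| == |gy| at the corner pixel by kernel symmetry
  corner <- matrix(0, 7, 7); corner[4:7, 4:7] <- 200
  p <- corner[c(1, 1:7, 7), c(1, 1:7, 7)]
  s <- function(dr, dc, r, c) p[r + 1 + dr, c + 1 + dc]
  gx <- function(r, c) s(-1, 1, r, c) + 2 * s(0, 1, r, c) + s(1, 1, r, c) -
    s(-1, -1, r, c) - 2 * s(0, -1, r, c) - s(1, -1, r, c)
  gy <- function(r, c) s(1, -1, r, c) + 2 * s(1, 0, r, c) + s(1, 1, r, c) -
    s(-1, -1, r, c) - 2 * s(-1, 0, r, c) - s(-1, 1, r, c)
  expect_equal(abs(gx(4, 4)), abs(gy(4, 4)))
  expect_equal(sobel_edges(corner)[4, 4],
               min(255, round(sqrt(gx(4, 4)^2 + gy(4, 4)^2))))
})

test_that("binarize uses <= semantics and is idempotent", {
  expect_equal(binarize(matrix(6), 6)[1, 1], 0)
  expect_equal(binarize(matrix(7), 6)[1, 1], 255)
  expect_equal(binarize(matrix(145), 145)[1, 1], 0)
  withr::with_seed(1, {
    for (t in c(0, 6, 145, 254)) {
      m <- matrix(sample(0:255, 64, TRUE), 8, 8)
      once <- binarize(m, t)
      expect_identical(binarize(once, t), once)
    }
  })
})

test_that("dilation grows by a 3x3 square element and is extensive", {
  m <- matrix(0, 7, 7); m[4, 4] <- 255
  d1 <- dilate(m, 1)
  expect_true(all(d1[3:5, 3:5] == 255))
  expect_equal(sum(d1 > 0), 9)
  expect_equal(dilate(matrix(0, 5, 5), 3), matrix(0, 5, 5))
  expect_identical(dilate(m, 0), m)
  withr::with_seed(2, {
    m <- matrix(sample(c(0, 255), 100, TRUE, prob = c(0.8, 0.2)), 10, 10)
    d1 <- dilate(m, 1); d2 <- dilate(m, 2)
    expect_true(all(d1[m > 0] == 255))       # extensive
    expect_true(all(d2[d1 > 0] == 255))      # monotone in iterations
    expect_identical(dilate(d1, 1), d2)
  })
})

test_that("border blobs are removed and interior blobs survive", {
  m <- matrix(0, 8, 8); m[1:3, 2:4] <- 255
  expect_equal(sum(kill_border_blobs(m)), 0)
  m2 <- matrix(0, 8, 8); m2[5:7, 5:7] <- 255
  expect_identical(kill_border_blobs(m2), m2)
  both <- m + m2
  expect_identical(kill_border_blobs(both) > 0, m2 > 0)
})

test_that("hole filling fills enclosed background only", {
  ring <- matrix(0, 9, 9); ring[3:7, 3:7] <- 255; ring[4:6, 4:6] <- 0
  filled <- fill_holes(ring)
  expect_true(all(filled[3:7, 3:7] == 255))
  solid <- matrix(0, 9, 9); solid[3:7, 3:7] <- 255
  expect_identical(fill_holes(solid), solid)
  # background reaching the border through a gap stays open
  open_ring <- ring; open_ring[5, 3] <- 0
  expect_identical(fill_holes(open_ring), open_ring)
})

test_that("morphology agrees with the brute-force flood-fill oracle", {
  withr::with_seed(3, {
    for (i in 1:60) {
      m <- matrix(sample(c(0, 255), 42, TRUE), 6, 7)
      expect_identical(kill_border_blobs(m), bf_kill_border_blobs(m))
      expect_identical(fill_holes(m), bf_fill_holes(m))
      lab <- label_components(m, 8)
      ora <- bf_label(m, 8)
      expect_equal(max(lab), max(ora))
      # identical partitions up to label permutation
      if (max(lab) > 0) expect_true(all(table(lab[m > 0], ora[m > 0]) %in%
                                          c(0, tabulate(ora[m > 0]))))
    }
  })
})

test_that("dilation and hole filling agree with EBImage", {
  skip_if_not_installed("EBImage")
  withr::with_seed(9, {
    for (i in 1:40) {
      m <- matrix(sample(c(0, 255), 64, TRUE), 8, 8)
      eb_d <- EBImage::dilate(m / 255, EBImage::makeBrush(3, "box")) * 255
      expect_identical(dilate(m, 1), matrix(as.numeric(eb_d), 8, 8))
      eb_f <- EBImage::fillHull(m / 255) * 255
      expect_identical(fill_holes(m), matrix(as.numeric(eb_f), 8, 8))
    }
  })
})

test_that("small-blob removal divides the image area by beta", {
  m <- matrix(0, 130, 100)           # area 13000, threshold 1000 at beta 13
  m[10:49, 10:59] <- 255             # 2000 px
  m[80:99, 70:94] <- 255             # 500 px
  r <- remove_small_blobs(m, 13.0)
  expect_equal(sum(r$image > 0), 2000)
  expect_length(r$warnings, 0)

  lone <- matrix(0, 130, 100); lone[5:6, 5:9] <- 255  # 10 px, single blob
  r2 <- remove_small_blobs(lone, 13.0)
  expect_equal(sum(r2$image > 0), 10)

  two_big <- matrix(0, 130, 100)
  two_big[10:59, 10:49] <- 255; two_big[70:119, 50:89] <- 255  # both 2000 px
  r3 <- remove_small_blobs(two_big, 13.0)
  expect_equal(sum(r3$image > 0), 4000)
  expect_length(r3$warnings, 1)

  expect_error(remove_small_blobs(matrix(0, 5, 5)), class = "flystrip_no_embryo_error")
  expect_error(remove_small_blobs(m, 0), class = "flystrip_parameter_error")
})

test_that("Gaussian smoothing preserves constants and has the right width", {
  cst <- matrix(33, 40, 40)
  expect_equal(gaussian_smooth(cst, 5, 1e-3), cst, tolerance = 1e-9)

  imp <- matrix(0, 151, 151); imp[76, 76] <- 255
  sm <- gaussian_smooth(imp, 7, 1e-3)
  marg <- rowSums(sm)
  mu <- sum(marg * seq_along(marg)) / sum(marg)
  sd_est <- sqrt(sum(marg * (seq_along(marg) - mu)^2) / sum(marg))
  expect_equal(sd_est, 7, tolerance = 0.01)
  expect_equal(sum(sm), 255, tolerance = 255 * 2e-3)  # mass conserved
})

test_that("make_mask records all 14 stages and isolates a single blob", {
  em <- fx_noiseless()
  mk <- make_mask(em$images$dic)
  expect_s3_class(mk, "embryo_mask")
  expect_identical(names(mk$intermediates), flystrip:::mask_step_names)
  expect_equal(mk$n_blobs, 1)
  expect_equal(mk$quality, "good")
  expect_true(all(sort(unique(as.vector(mk$mask))) %in% c(0, 255)))
  # no foreground on the border
  expect_equal(sum(mk$mask[c(1, nrow(mk$mask)), ]) + sum(mk$mask[, c(1, ncol(mk$mask))]), 0)
  expect_true(iou(mk$mask, em$truth$mask) >= 0.98)
})

test_that("make_mask rejects degenerate and embryo-free scenes", {
  blank <- array(200, dim = c(60, 80, 3))
  err <- expect_error(make_mask(blank), class = "flystrip_no_embryo_error")
  expect_match(conditionMessage(err), "step05")
  expect_error(make_mask(array(0, dim = c(2, 2, 3))), class = "flystrip_format_error")
  expect_error(make_mask(matrix(0, 60, 80)), class = "flystrip_format_error")
})

test_that("an embryo touching the border is discarded as required", {
  # place the embryo so its rim crosses the left image border
  sp <- small_spec(noise_sd = 0)
  em <- render_embryo(sp)
  dic <- em$images$dic[, 105:320, , drop = FALSE]  # crop embryo onto the border
  expect_error(make_mask(dic), class = "flystrip_no_embryo_error")
})
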