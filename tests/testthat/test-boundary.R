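logistic_profile <- function(centre = 50, steep = 2, plateau = 100, by = 0.5) {
  pos <- seq(0, 100, by = by)
  tibble::tibble(position = pos, signal = plateau / (1 + exp(-(pos - centre) / steep)))
}

test_that("the midpoint knot and clamped constraints hold exactly", {
  pr <- logistic_profile()
  b <- fit_boundary(pr, 40, 60, gene = "kni", polarity = "anterior")
  expect_equal(b$knots$x[2], 50)
  expect_lt(abs(eval_boundary(b, 40, deriv = 1)), 1e-9)
  expect_lt(abs(eval_boundary(b, 60, deriv = 1)), 1e-9)
  expect_equal(eval_boundary(b, b$knots$x), b$knots$y, tolerance = 1e-9)
  # y values come from the nearest profile samples
  expect_equal(b$knots$y[2], pr$signal[pr$position == 50])

  # posterior windows run from outer (right) to inner (left)
  bp <- fit_boundary(pr, 70, 30, polarity = "posterior")
  expect_equal(bp$knots$x, c(70, 50, 30))
  expect_lt(abs(eval_boundary(bp, 70, deriv = 1)), 1e-9)
})

test_that("degenerate boundary windows are rejected", {
  pr <- logistic_profile()
  expect_error(fit_boundary(pr, 40, 40), class = "flystrip_parameter_error")
  expect_error(fit_boundary(pr, -5, 60), class = "flystrip_parameter_error")
  expect_error(fit_boundary(pr, 40, 105), class = "flystrip_parameter_error")
  expect_error(fit_boundary(pr, 40, 60, signal_col = "nope"),
               class = "flystrip_parameter_error")
  b <- fit_boundary(pr, 40, 60)
  expect_error(eval_boundary(b, 39), class = "flystrip_parameter_error")
  expect_error(eval_boundary(b, 61), class = "flystrip_parameter_error")
})

test_that("a flat window yields the constant spline", {
  pr <- tibble::tibble(position = 0:100, signal = rep(7, 101))
  b <- fit_boundary(pr, 20, 80)
  xx <- seq(20, 80, length.out = 50)
  expect_equal(eval_boundary(b, xx), rep(7, 50), tolerance = 1e-12)
})

test_that("monotone knot values give monotone fits", {
  for (ys in list(c(0, 50, 100), c(0, 10, 100), c(0, 95, 100), c(100, 40, 0))) {
    pr <- tibble::tibble(position = c(0, 50, 100), signal = ys)
    b <- fit_boundary(pr, 0, 100)
    xx <- seq(0, 100, length.out = 301)
    d <- diff(eval_boundary(b, xx))
    if (ys[1] < ys[3]) expect_true(all(d >= -1e-9)) else expect_true(all(d <= 1e-9))
  }
})

test_that("mirrored profiles give mirrored boundary fits", {
  pr <- logistic_profile(centre = 45, steep = 3)
  mirrored <- tibble::tibble(position = rev(100 - pr$position), signal = rev(pr$signal))
  ba <- fit_boundary(pr, 35, 55, polarity = "anterior")
  bp <- fit_boundary(mirrored, 65, 45, polarity = "posterior")
  expect_equal(bp$knots$x, 100 - ba$knots$x, tolerance = 1e-9)
  expect_equal(bp$knots$y, ba$knots$y, tolerance = 1e-9)
  xx <- seq(35, 55, length.out = 21)
  expect_equal(eval_boundary(bp, 100 - xx), eval_boundary(ba, xx), tolerance = 1e-9)
})

test_that("tidy and glance expose knots and labels", {
  b <- fit_boundary(logistic_profile(), 40, 60, gene = "hb", slope_id = 2,
                    polarity = "anterior", channel = "red")
  td <- tidy(b)
  expect_equal(nrow(td), 3)
  expect_equal(td$label, c("x0", "x1", "x2"))
  expect_equal(td$gene, rep("hb", 3))
  gl <- glance(b)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$width, 20)
  expect_equal(gl$slope_id, 2L)
})

test_that("window suggestion brackets a logistic step and respects polarity", {
  pr <- logistic_profile(centre = 50, steep = 2)
  sug <- suggest_window(pr, "anterior")
  expect_true(sug$found)
  q10 <- 50 - 2 * log(9); q90 <- 50 + 2 * log(9)
  expect_lt(sug$x0, q10)
  expect_gt(sug$x2, q90 - 0.5)
  expect_lt(sug$x2, 65)

  flat <- tibble::tibble(position = 0:100, signal = rep(3, 101))
  expect_false(suggest_window(flat, "anterior")$found)

  # falling profile, posterior boundary
  fall <- tibble::tibble(position = 0:100,
                         signal = 100 / (1 + exp(((0:100) - 50) / 2)))
  sugp <- suggest_window(fall, "posterior")
  expect_true(sugp$found)
  expect_gt(sugp$x0, sugp$x2)
})

test_that("suggested windows on fixtures sit near the true boundary", {
  # noiseless chain: the window must contain the boundary centre
  ch <- fx_chain()
  pr <- stain_signal(ch$profile, "NBT_BCIP")
  truth <- ch$em$truth$domains
  sug <- suggest_window(pr, "anterior")
  expect_true(sug$found)
  expect_true(sug$x0 < truth$anterior && truth$anterior < sug$x2)

  # under realistic sensor noise the candidate midpoint tracks ground truth
  chn <- fx_chain_default()
  prn <- stain_signal(chn$profile, "NBT_BCIP")
  sugn <- suggest_window(prn, "anterior")
  expect_true(sugn$found)
  expect_lt(abs((sugn$x0 + sugn$x2) / 2 - chn$em$truth$domains$anterior), 2)
})
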