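test_that("annotation vocabularies accept valid records and flag violations", {
  good <- list(embryo_id = "001", orientation = "lateral", phase = "interphase",
               morphology = "good", mask_quality = "ok", staining = "normal",
               time_class = "C14A_T8")
  rep <- validate_annotation(good)
  expect_true(all(rep$valid))

  bad <- list(embryo_id = "002", orientation = "sideways", time_class = "C13_T8")
  rep2 <- validate_annotation(bad)
  expect_false(rep2$valid[rep2$field == "orientation"])
  expect_match(rep2$message[rep2$field == "orientation"], "orientation")
  expect_false(rep2$valid[rep2$field == "time_class"])

  # bare C14A is a valid (unsubdivided) time class
  expect_true(validate_annotation(list(embryo_id = "x", time_class = "C14A"))$valid[1])
  # missing id is required
  expect_false(all(validate_annotation(list(orientation = "lateral"))$valid))
})

test_that("store tables round-trip exactly", {
  store <- store_create(withr::local_tempdir())
  tbl <- tibble::tibble(embryo_id = c("001", "002"), gamma = c(0.08, 0.1),
                        note = c("a", "b"))
  store_write_table(store, "params", tbl)
  back <- store_read_table(store, "params")
  expect_equal(as.data.frame(back), as.data.frame(tbl))
  expect_equal(nrow(store_read_table(store, "profiles")), 0)
  expect_error(store_open(withr::local_tempdir()), class = "flystrip_store_error")
})

test_that("the batch pipeline processes, logs failures, and is idempotent", {
  data_dir <- withr::local_tempdir()
  specs <- list(small_spec(), small_spec(rotation = 15),
                small_spec(rotation = -20))
  render_batch(specs, dir = data_dir, seed = 5)
  # one deliberately corrupt image set
  writeLines("not a png", file.path(data_dir, "004_dic.png"))

  store <- store_create(withr::local_tempdir())
  res <- run_pipeline(data_dir, store, proc_dir = file.path(data_dir, "proc"))
  expect_equal(nrow(res), 4)
  expect_equal(sum(res$status == "ok"), 3)
  expect_equal(res$status[res$embryo_id == "004"], "failed")

  params <- store_read_table(store, "params")
  expect_equal(sort(params$embryo_id), c("001", "002", "003"))
  expect_true(all(c("gamma", "beta", "angle", "row0", "col0", "height", "width",
                    "mask_quality") %in% names(params)))
  expect_equal(params$gamma, rep(0.08, 3))
  # recorded angles undo the programmed rotations
  expect_equal(sort(round(params$angle / 5) * 5), c(-20, 0, 15))

  profiles <- store_read_table(store, "profiles")
  expect_equal(dplyr::n_distinct(profiles$embryo_id), 3)
  # intermediates and oriented images land in the proc dir
  expect_true(file.exists(file.path(data_dir, "proc", "001_mask.png")))
  expect_true(file.exists(file.path(data_dir, "proc", "001_step04_edges.png")))

  # re-running replaces records instead of duplicating them
  res2 <- run_pipeline(data_dir, store)
  expect_equal(nrow(store_read_table(store, "params")), 3)
  expect_equal(nrow(store_read_table(store, "profiles")), nrow(profiles))
})

test_that("boundary batches and exports round-trip through the store", {
  data_dir <- withr::local_tempdir()
  dom <- expression_domain("NBT_BCIP", 40, 60, steepness = 2, plateau = 150)
  render_batch(list(small_spec(domains = list(dom)),
                    small_spec(domains = list(dom))), dir = data_dir, seed = 11)
  store <- store_create(withr::local_tempdir())
  run_pipeline(data_dir, store)

  windows <- tibble::tibble(
    embryo_id = c("001", "002"), gene = "kni", channel = "purple",
    slope_id = 1L, polarity = "anterior", x0_percent = 33, x2_percent = 47,
    time_class = "C14A_T3"
  )
  btbl <- fit_boundaries_batch(store, windows)
  expect_equal(nrow(btbl), 2)
  expect_equal(btbl$x1, c(40, 40))

  out_dir <- withr::local_tempdir()
  files <- export_tables(store, out_dir)
  expect_true(all(file.exists(file.path(out_dir,
    c("boundaries.csv", "medians.csv", "spacetime.csv",
      "variability.svg", "variability.pdf", "spacetime.svg", "spacetime.pdf")))))
  reread <- utils::read.csv(file.path(out_dir, "boundaries.csv"))
  expect_equal(nrow(reread), 2)
  expect_equal(reread$x0, btbl$x0)
  med <- utils::read.csv(file.path(out_dir, "medians.csv"))
  expect_equal(med$n, 2)

  # empty store exports header-only tables
  empty_store <- store_create(withr::local_tempdir())
  empty_dir <- withr::local_tempdir()
  export_tables(empty_store, empty_dir)
  e <- utils::read.csv(file.path(empty_dir, "boundaries.csv"))
  expect_equal(nrow(e), 0)
  expect_true("x0" %in% names(e))
})
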