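# Plain-text batch store and annotation validation. The store is a
# directory holding one CSV per table plus a JSON manifest, replacing the
# original client-server database with something a desk-scale tool can carry
# around; all processing parameters used for a mask are recoverable from it.

STORE_TABLES <- c("embryos", "params", "profiles", "boundaries", "log")

#' Controlled annotation vocabularies
#'
#' @return Named list of the allowed values for each annotated field.
#' @export
annotation_vocabularies <- function() {
  list(
    orientation = c("lateral", "nearly lateral", "not lateral"),
    phase = c("interphase", "mitosis", "unknown"),
    morphology = c("amnion/serosa present", "bad", "banana", "fat", "good", "ugly"),
    mask_quality = c("good", "ok", "not good"),
    staining = c("normal", "weak", "saturated"),
    time_class = time_class_levels()
  )
}

#' Validate an embryo annotation record
#'
#' Checks every controlled-vocabulary field of a record against its
#' vocabulary and reports all violations; fields that are absent or `NA`
#' are skipped (annotations are filled in incrementally).
#'
#' @param record Named list or one-row data frame with any of: `embryo_id`,
#'   `orientation`, `phase`, `morphology`, `mask_quality`, `staining`,
#'   `time_class`, plus free-text fields (`genotype`, `knock_down`,
#'   `comments`) which are not vocabulary-checked.
#' @return Tibble with columns `field`, `value`, `valid`, `message`; the
#'   record passes when all rows have `valid = TRUE`.
#' @export
validate_annotation <- function(record) {
  record <- as.list(record)
  vocab <- annotation_vocabularies()
  rows <- list()
  for (field in names(vocab)) {
    if (is.null(record[[field]]) || is.na(record[[field]])) next
    value <- as.character(record[[field]])
    ok <- value %in% vocab[[field]]
    rows[[field]] <- tibble(
      field = field, value = value, valid = ok,
      message = if (ok) "" else sprintf(
        "'%s' is not a valid %s (allowed: %s)", value, field,
        paste(vocab[[field]], collapse = ", "))
    )
  }
  if (is.null(record$embryo_id) || is.na(record$embryo_id) || record$embryo_id == "") {
    rows$embryo_id <- tibble(field = "embryo_id", value = "",
                             valid = FALSE, message = "embryo_id is required")
  }
  if (!length(rows)) return(tibble(field = character(), value = character(),
                                   valid = logical(), message = character()))
  dplyr::bind_rows(rows)
}

#' Create a new batch store
#'
#' @param path Directory to create.
#' @return A `flystrip_store` handle.
#' @export
store_create <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  manifest <- list(format = "flystrip-store", version = 1L,
                   tables = STORE_TABLES)
  jsonlite::write_json(manifest, file.path(path, "store.json"), auto_unbox = TRUE)
  store_open(path)
}

#' Open an existing batch store
#'
#' @param path Store directory (from [store_create()]).
#' @return A `flystrip_store` handle.
#' @export
store_open <- function(path) {
  mf <- file.path(path, "store.json")
  if (!file.exists(mf)) {
    abort(sprintf("'%s' is not a flystrip store (missing store.json)", path),
          class = "flystrip_store_error")
  }
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$format, "flystrip-store")) {
    abort("unrecognised store format", class = "flystrip_store_error")
  }
  structure(list(path = path), class = "flystrip_store")
}

store_table_path <- function(store, name) file.path(store$path, paste0(name, ".csv"))

#' Read a store table
#'
#' @param store A `flystrip_store`.
#' @param name One of `"embryos"`, `"params"`, `"profiles"`, `"boundaries"`,
#'   `"log"`.
#' @return Tibble (zero rows if the table has not been written yet).
#' @export
store_read_table <- function(store, name) {
  name <- match.arg(name, STORE_TABLES)
  p <- store_table_path(store, name)
  if (!file.exists(p)) return(tibble())
  hdr <- names(utils::read.csv(p, nrows = 1))
  cls <- if ("embryo_id" %in% hdr) c(embryo_id = "character") else NA
  as_tibble(utils::read.csv(p, stringsAsFactors = FALSE, colClasses = cls))
}

#' Write (replace) a store table
#'
#' @param store A `flystrip_store`.
#' @param name Table name.
#' @param tbl Data frame to store.
#' @export
store_write_table <- function(store, name, tbl) {
  name <- match.arg(name, STORE_TABLES)
  utils::write.csv(tbl, store_table_path(store, name), row.names = FALSE)
  invisible(store)
}

# replace all rows belonging to `id`, then append the new ones (idempotent
# per-embryo re-runs)
store_upsert <- function(store, name, id, rows) {
  old <- store_read_table(store, name)
  if (nrow(old) && "embryo_id" %in% names(old)) {
    old <- dplyr::filter(old, .data$embryo_id != id)
  }
  store_write_table(store, name, dplyr::bind_rows(old, rows))
}

find_embryo_ids <- function(data_dir) {
  files <- list.files(data_dir, pattern = "_dic\\.(png|tif|tiff)$", ignore.case = TRUE)
  sort(unique(sub("_dic\\.(png|tif|tiff)$", "", files, ignore.case = TRUE)))
}

find_image <- function(data_dir, stem) {
  for (ext in c("png", "tif", "tiff")) {
    p <- file.path(data_dir, paste0(stem, ".", ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Run the batch processing pipeline
#'
#' For every embryo in `data_dir` (identified by its `NNN_dic` image):
#' create the mask, orient and crop the registered images, apply any
#' requested flips, extract the 10% strip expression profile, and record
#' masks, intermediates, parameters (gamma, beta, rotation angle, crop box)
#' and profiles in the store. Per-embryo failures are logged and the batch
#' continues. Re-running with the same inputs replaces each embryo's
#' records (idempotent).
#'
#' @param data_dir Directory of raw images named `NNN.png` (bright-field),
#'   `NNN_dic.png`, and optionally `NNN_nuc.png`, `NNN_memb.png` (TIFF also
#'   accepted). Missing bright-field images fall back to the DIC image with
#'   a warning; missing nuclear/membrane images are tolerated.
#' @param store A `flystrip_store`.
#' @param params [seg_params()] used for every mask.
#' @param flips Optional data frame `embryo_id`, `hflip`, `vflip` (the batch
#'   equivalent of the manual orientation step).
#' @param proc_dir Optional directory for processed output: the mask, every
#'   pipeline intermediate, and the oriented, cropped images as PNG.
#' @return Tibble with `embryo_id`, `status` (`"ok"`/`"failed"`), `message`.
#' @export
run_pipeline <- function(data_dir, store, params = seg_params(), flips = NULL,
                         proc_dir = NULL) {
  ids <- find_embryo_ids(data_dir)
  if (!length(ids)) abort(sprintf("no '*_dic' images found in %s", data_dir),
                          class = "flystrip_store_error")
  if (!is.null(proc_dir) && !dir.exists(proc_dir)) dir.create(proc_dir, recursive = TRUE)

  results <- purrr::map_dfr(ids, function(id) {
    status <- tryCatch({
      dic <- read_image(find_image(data_dir, paste0(id, "_dic")))
      bf_path <- find_image(data_dir, id)
      bf <- if (is.null(bf_path)) {
        warn(sprintf("embryo %s: no bright-field image; using DIC as expression source", id))
        dic
      } else read_image(bf_path)
      nuc_path <- find_image(data_dir, paste0(id, "_nuc"))
      nuc <- if (is.null(nuc_path)) NULL else read_image(nuc_path)

      em <- make_mask(dic, params)
      angle <- principal_axis_angle(em$mask)
      imgs <- list(dic = dic, brightfield = bf)
      if (!is.null(nuc)) imgs$nuclear <- nuc
      rc <- rotate_and_crop(em$mask, imgs, angle = angle)

      hflip <- FALSE; vflip <- FALSE
      if (!is.null(flips) && id %in% flips$embryo_id) {
        frow <- flips[flips$embryo_id == id, ][1, ]
        hflip <- isTRUE(as.logical(frow$hflip))
        vflip <- isTRUE(as.logical(frow$vflip))
        rc$mask <- apply_flips(rc$mask, hflip, vflip)
        rc$images <- apply_flips(rc$images, hflip, vflip)
      }

      strip <- build_strip(axis_spline(rc$mask), rc$mask)
      profile <- extract_profile(rc$images$brightfield, strip)

      if (!is.null(proc_dir)) {
        write_image(rc$mask, file.path(proc_dir, paste0(id, "_mask.png")))
        for (nm in names(em$intermediates)) {
          write_image(em$intermediates[[nm]], file.path(proc_dir, paste0(id, "_", nm, ".png")))
        }
        for (nm in names(rc$images)) {
          write_image(rc$images[[nm]], file.path(proc_dir, paste0(id, "_oriented_", nm, ".png")))
        }
      }

      prow <- tibble(
        embryo_id = id, gamma = params$gamma, edge_threshold = params$edge_threshold,
        beta = params$beta, blur_sigma = params$blur_sigma,
        blur_accuracy = params$blur_accuracy,
        post_blur_threshold = params$post_blur_threshold,
        angle = rc$orientation$angle, row0 = rc$orientation$row0,
        col0 = rc$orientation$col0, height = rc$orientation$height,
        width = rc$orientation$width, hflip = hflip, vflip = vflip,
        mask_quality = em$quality,
        warnings = paste(em$warnings, collapse = "; ")
      )
      store_upsert(store, "params", id, prow)
      store_upsert(store, "profiles", id, dplyr::mutate(as_tibble(profile), embryo_id = id, .before = 1L))
      store_upsert(store, "log", id, tibble(embryo_id = id, status = "ok", message = ""))
      tibble(embryo_id = id, status = "ok", message = "")
    }, error = function(e) {
      msg <- conditionMessage(e)
      store_upsert(store, "log", id, tibble(embryo_id = id, status = "failed", message = msg))
      tibble(embryo_id = id, status = "failed", message = msg)
    })
    status
  })
  results
}

#' Fit boundaries for a batch from a window table
#'
#' The file-driven equivalent of the manual slope-placement step: each row
#' of `windows` names an embryo, gene, channel, slope and polarity and gives
#' the outer/inner window positions in %EL. Profiles are read from the
#' store, the stain signal derived from the channel, the clamped spline
#' fitted, and the boundary table stored.
#'
#' @param store A `flystrip_store` whose `profiles` table is populated.
#' @param windows Data frame with columns `embryo_id`, `gene`, `channel`
#'   (`"purple"`/`"red"`), `slope_id`, `polarity`, `x0_percent`,
#'   `x2_percent`, and optionally `time_class`.
#' @return The stored boundary table (tibble).
#' @export
fit_boundaries_batch <- function(store, windows) {
  profiles <- store_read_table(store, "profiles")
  if (!nrow(profiles)) abort("store has no profiles", class = "flystrip_store_error")
  rows <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    wrow <- windows[i, ]
    prof <- dplyr::filter(profiles, .data$embryo_id == wrow$embryo_id)
    if (!nrow(prof)) {
      abort(sprintf("no profile stored for embryo %s", wrow$embryo_id),
            class = "flystrip_store_error")
    }
    stain <- if (wrow$channel == "purple") "NBT_BCIP" else "FastRed"
    prof <- stain_signal(prof, stain)
    bs <- fit_boundary(prof, wrow$x0_percent, wrow$x2_percent,
                       gene = wrow$gene, slope_id = wrow$slope_id,
                       polarity = wrow$polarity, channel = wrow$channel)
    out <- glance(bs)
    out$embryo_id <- wrow$embryo_id
    out$time_class <- if ("time_class" %in% names(windows)) wrow$time_class else NA_character_
    out
  })
  old <- store_read_table(store, "boundaries")
  keep <- if (nrow(old)) dplyr::anti_join(
    old, rows, by = intersect(c("embryo_id", "gene", "channel", "slope_id", "polarity"),
                              names(old))) else old
  tbl <- dplyr::bind_rows(keep, rows)
  store_write_table(store, "boundaries", tbl)
  tbl
}

#' Export analysis tables and plots
#'
#' Writes the (filtered) boundary table, the per-group median-knot table and
#' the space-time table as CSV, plus variability and space-time plots in SVG
#' and PDF. An empty selection produces header-only CSV files.
#'
#' @param store A `flystrip_store` with boundaries.
#' @param out_dir Output directory.
#' @param genes,time_classes Optional filters.
#' @return Invisibly, the character vector of files written.
#' @export
export_tables <- function(store, out_dir, genes = NULL, time_classes = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tbl <- store_read_table(store, "boundaries")
  if (nrow(tbl)) {
    if (!is.null(genes)) tbl <- dplyr::filter(tbl, .data$gene %in% genes)
    if (!is.null(time_classes)) tbl <- dplyr::filter(tbl, .data$time_class %in% time_classes)
  } else {
    tbl <- tibble(gene = character(), slope_id = integer(), polarity = character(),
                  channel = character(), x0 = double(), y0 = double(),
                  x1 = double(), y1 = double(), x2 = double(), y2 = double(),
                  width = double(), embryo_id = character(), time_class = character())
  }
  files <- character()
  wcsv <- function(t, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(t, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wcsv(tbl, "boundaries.csv")

  if (nrow(tbl)) {
    groups <- dplyr::group_split(dplyr::group_by(
      tbl, .data$gene, .data$slope_id, .data$polarity, .data$time_class))
    medians <- purrr::map_dfr(groups, function(g) {
      med <- median_boundary(g)
      dplyr::mutate(glance(med), time_class = g$time_class[1], n = med$n)
    })
    st <- spacetime_table(tbl)
  } else {
    medians <- tibble(gene = character(), slope_id = integer(), polarity = character(),
                      channel = character(), x0 = double(), y0 = double(),
                      x1 = double(), y1 = double(), x2 = double(), y2 = double(),
                      width = double(), time_class = character(), n = integer())
    st <- spacetime_table(tbl)
  }
  wcsv(medians, "medians.csv")
  wcsv(st, "spacetime.csv")

  if (nrow(tbl)) {
    vd <- variability_dataset(tbl, mode = "slopes_and_medians")
    pv <- plot_variability(vd)
    ps <- plot_spacetime(st)
    for (ext in c("svg", "pdf")) {
      dev <- if (ext == "svg") grDevices::svg else grDevices::pdf
      for (nm in c("variability", "spacetime")) {
        p <- file.path(out_dir, paste0(nm, ".", ext))
        ggplot2::ggsave(p, if (nm == "variability") pv else ps,
                        device = dev, width = 7, height = 5)
        files <- c(files, p)
      }
    }
  }
  invisible(files)
}
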