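# Batch execution over an image folder and calibration sweeps.
#
# Every batch run produces the three-output contract: a `parameters.txt`
# key=value dump of the calibration, a results table (CSV/TSV, first
# column = image name), and one overlay image per input image. Outputs are
# a pure function of the input bytes and the configuration, so reruns are
# byte-identical.

.batch_functions <- c("count-spores", "spore-morphology", "mycelium",
                      "traps")

list_images <- function(input_dir) {
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
  files <- list.files(input_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE)
  if (!length(files)) stop("no readable images (.png/.tif/.tiff) in ",
                           input_dir)
  sort(files)
}

run_one <- function(fun, img, params, name, mask, timepoint) {
  switch(fun,
    "count-spores" = {
      r <- count_spores(img, params, name)
      list(rows = data.frame(image = name, n_spores = r$n_spores),
           overlay = overlay_components(img, r, params))
    },
    "traps" = {
      r <- count_traps(img, params, name)
      list(rows = data.frame(image = name, n_traps = r$n_spores),
           overlay = overlay_components(img, r, params))
    },
    "spore-morphology" = {
      r <- measure_spores(img, params, name)
      rows <- if (nrow(r)) data.frame(image = name, spore_id = r$spore_id,
                                      area = r$area, length = r$length,
                                      width = r$width,
                                      circularity = r$circularity)
              else data.frame(image = name, spore_id = NA_integer_,
                              area = NA_real_, length = NA_real_,
                              width = NA_real_, circularity = NA_real_)
      list(rows = rows, overlay = overlay_components(img, r, params))
    },
    "mycelium" = {
      a <- analyze_mycelium_image(img, params, mask)
      m <- a$metrics
      list(rows = data.frame(image = name, timepoint = timepoint,
                             total_length = m$total_length,
                             n_tips = m$n_tips, n_edges = m$n_edges,
                             hull_area = m$hull_area),
           overlay = overlay_mycelium(img, a))
    })
}

#' Run a quantification function over a folder of images
#'
#' Processes every image in `input_dir` (lexicographic filename order,
#' which defines the timepoint order for time series) with one fixed
#' parameter set and writes the three standard outputs to `output_dir`:
#' `parameters.txt`, the results table, and one `<image>_overlay.png` per
#' input. A failure on one image is recorded as an error row (message in
#' the `error` column) and the batch continues.
#'
#' @param input_dir Directory of `.png`/`.tif` images.
#' @param fun One of `"count-spores"`, `"spore-morphology"`, `"mycelium"`,
#'   `"traps"`.
#' @param params A `calibration_params` object.
#' @param output_dir Output directory, created if needed.
#' @param mask_path Optional path to a binary mask image subtracted during
#'   mycelium analysis.
#' @param table_name File name of the results table.
#' @param format `"csv"` or `"tsv"`.
#' @return The results data frame, invisibly.
#' @export
run_batch <- function(input_dir, fun = .batch_functions, params,
                      output_dir, mask_path = NULL,
                      table_name = "results.csv",
                      format = c("csv", "tsv")) {
  fun <- match.arg(fun, .batch_functions)
  format <- match.arg(format)
  stopifnot(inherits(params, "calibration_params"))
  files <- list_images(input_dir)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  mask <- if (!is.null(mask_path)) read_gray_image(mask_path) > 0.5 else NULL
  write_config(params, file.path(output_dir, "parameters.txt"))
  all_rows <- list()
  for (k in seq_along(files)) {
    f <- files[k]
    res <- tryCatch({
      img <- read_gray_image(file.path(input_dir, f))
      out <- run_one(fun, img, params, f, mask, k)
      png::writePNG(out$overlay,
                    file.path(output_dir,
                              paste0(tools::file_path_sans_ext(f),
                                     "_overlay.png")))
      out$rows$error <- ""
      out$rows
    }, error = function(e) {
      message("error processing ", f, ": ", conditionMessage(e))
      data.frame(image = f, error = conditionMessage(e))
    })
    all_rows[[k]] <- res
  }
  cols <- unique(unlist(lapply(all_rows, names)))
  all_rows <- lapply(all_rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    r[cols]
  })
  table <- do.call(rbind, all_rows)
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(table, file.path(output_dir, table_name), sep = sep,
                     row.names = FALSE, quote = TRUE)
  invisible(table)
}

#' Sweep calibration parameters over one image
#'
#' Scriptable replacement for interactive slider calibration: runs the
#' selected function on a single image for every combination of the
#' supplied parameter values and reports a headline metric per grid point
#' (object count for the counting functions, total length for mycelium).
#' Optionally writes one overlay per grid point for visual inspection.
#'
#' @param image A grayscale matrix or a path to an image file.
#' @param fun One of the batch function names, see [run_batch()].
#' @param grid Named list of parameter values to cross (e.g.
#'   `list(b1 = c(0.5, 0.7), min_area = c(20, 50))`); names must be
#'   [calibration_params()] fields.
#' @param params Base `calibration_params` supplying the non-swept values.
#' @param output_dir Optional directory for per-grid-point overlays.
#' @return Data frame: one row per grid point with the parameter values
#'   and the headline `metric`.
#' @export
sweep_calibration <- function(image, fun = .batch_functions, grid,
                              params = calibration_params(),
                              output_dir = NULL) {
  fun <- match.arg(fun, .batch_functions)
  if (!is.list(grid) || is.null(names(grid)) || any(names(grid) == "") ||
      !all(lengths(grid) >= 1))
    stop("grid must be a named list of non-empty parameter value vectors")
  bad <- setdiff(names(grid), .config_keys)
  if (length(bad)) stop("unknown parameter(s) in grid: ",
                        paste(bad, collapse = ", "))
  img <- if (is.character(image)) read_gray_image(image) else image
  check_gray(img)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(output_dir))
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  metric <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    p <- params
    for (nm in names(combos)) p[[nm]] <- combos[i, nm]
    p <- do.call(calibration_params, unclass(p))
    out <- run_one(fun, img, p, "calibration", NULL, 1L)
    metric[i] <- switch(fun,
      "count-spores" = out$rows$n_spores,
      "traps" = out$rows$n_traps,
      "spore-morphology" = sum(!is.na(out$rows$spore_id)),
      "mycelium" = out$rows$total_length)
    if (!is.null(output_dir))
      png::writePNG(out$overlay,
                    file.path(output_dir, sprintf("sweep_%03d.png", i)))
  }
  cbind(combos, metric = metric)
}
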