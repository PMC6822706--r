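make_spore_folder <- function(dir, n = 3, size = c(256, 256)) {
  dir.create(dir, showWarnings = FALSE)
  for (i in seq_len(n)) {
    sc <- generate_spore_scene(n_spores = 5 + i, n_distractors = 2,
                               size = size, seed = 100 + i)
    png::writePNG(sc$image, file.path(dir, sprintf("img_%02d.png", i)))
  }
}

test_that("image reading normalizes bit depth and color", {
  dir <- withr::local_tempdir()
  x <- matrix(seq(0, 1, length.out = 64), 8, 8)
  p8 <- file.path(dir, "a.png")
  png::writePNG(x, p8)
  r8 <- read_gray_image(p8)
  expect_equal(r8, matrix(round(x * 255) / 255, 8, 8), tolerance = 1e-9)

  t16 <- file.path(dir, "b.tif")
  tiff::writeTIFF(x, t16, bits.per.sample = 16)
  expect_lt(max(abs(read_gray_image(t16) - x)), 1 / 65535 + 1e-9)

  rgb <- array(0.5, c(6, 6, 3))
  prgb <- file.path(dir, "c.png")
  png::writePNG(rgb, prgb)
  expect_equal(read_gray_image(prgb), matrix(0.5, 6, 6), tolerance = 0.01)

  writeLines("not an image", file.path(dir, "d.xyz"))
  expect_error(read_gray_image(file.path(dir, "d.xyz")), "unsupported")
  expect_error(read_gray_image(file.path(dir, "nope.png")), "not found")
})

test_that("batch runs produce the three-output contract deterministically", {
  input <- withr::local_tempdir()
  make_spore_folder(input)
  p <- preset_params("spores")
  out1 <- withr::local_tempdir()
  tab <- run_batch(input, "count-spores", p, out1)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$image, sprintf("img_%02d.png", 1:3))
  expect_equal(tab$n_spores, 6:8)
  expect_true(file.exists(file.path(out1, "parameters.txt")))
  expect_true(file.exists(file.path(out1, "results.csv")))
  overlays <- list.files(out1, pattern = "_overlay\\.png$")
  expect_length(overlays, 3)
  expect_equal(unclass(read_config(file.path(out1, "parameters.txt"))),
               unclass(p))

  # rerun into a second directory: byte-identical table and overlays
  out2 <- withr::local_tempdir()
  run_batch(input, "count-spores", p, out2)
  expect_identical(readBin(file.path(out1, "results.csv"), "raw", 1e6),
                   readBin(file.path(out2, "results.csv"), "raw", 1e6))
  expect_identical(
    readBin(file.path(out1, overlays[1]), "raw", 1e7),
    readBin(file.path(out2, overlays[1]), "raw", 1e7))
})

test_that("per-image failures become error rows and the batch continues", {
  input <- withr::local_tempdir()
  make_spore_folder(input, n = 2)
  writeLines("garbage", file.path(input, "img_00_broken.png"))
  out <- withr::local_tempdir()
  tab <- suppressMessages(run_batch(input, "count-spores",
                                    preset_params("spores"), out))
  expect_equal(nrow(tab), 3)  # every input appears exactly once
  bad <- tab[tab$image == "img_00_broken.png", ]
  expect_true(nzchar(bad$error))
  expect_true(is.na(bad$n_spores))
  good <- tab[tab$image != "img_00_broken.png", ]
  expect_true(all(!is.na(good$n_spores)))
})

test_that("batch rejects empty input folders", {
  empty <- withr::local_tempdir()
  expect_error(run_batch(empty, "count-spores", preset_params("spores"),
                         withr::local_tempdir()),
               "no readable images")
})

test_that("mycelium batch emits the time-series results layout", {
  input <- withr::local_tempdir()
  frames <- generate_growth_series(n_frames = 2, growth_per_frame = 3,
                                   seed = 12, size = c(384, 384))
  for (i in seq_along(frames))
    png::writePNG(frames[[i]]$image,
                  file.path(input, sprintf("t%02d.png", i)))
  out <- withr::local_tempdir()
  tab <- run_batch(input, "mycelium", preset_params("mycelium"), out,
                   table_name = "growth.tsv", format = "tsv")
  expect_equal(tab$timepoint, 1:2)
  expect_named(tab, c("image", "timepoint", "total_length", "n_tips",
                      "n_edges", "hull_area", "error"))
  expect_true(file.exists(file.path(out, "growth.tsv")))
})

test_that("calibration sweeps report monotone counts over b1", {
  sc <- generate_spore_scene(n_spores = 15, size = c(384, 384), seed = 13)
  sw <- sweep_calibration(sc$image, "count-spores",
                          grid = list(b1 = c(0.5, 0.7, 0.9)),
                          params = preset_params("spores"))
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$metric) <= 0))

  # a one-point grid equals a direct run, and overlays cover the grid
  outdir <- withr::local_tempdir()
  one <- sweep_calibration(sc$image, "count-spores",
                           grid = list(b1 = 0.5),
                           params = preset_params("spores"),
                           output_dir = outdir)
  expect_equal(one$metric,
               count_spores(sc$image, preset_params("spores"))$n_spores)
  expect_length(list.files(outdir, pattern = "^sweep_.*png$"), 1)

  expect_error(sweep_calibration(sc$image, "count-spores", grid = list()),
               "grid")
  expect_error(sweep_calibration(sc$image, "count-spores",
                                 grid = list(nonsense = 1)),
               "unknown parameter")
})
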