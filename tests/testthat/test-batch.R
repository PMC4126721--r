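test_that("config validates parameters and reads YAML overrides", {
  cfg <- gj_config()
  expect_equal(cfg$max_radius, 40)
  expect_equal(cfg$plateau_tol, 0.005)
  expect_equal(cfg$plateau_window, 3)
  expect_error(gj_config(plateau_tol = 0), "plateau_tol")
  expect_error(gj_config(r_min = 3, r_max = -3))
  f <- tempfile(fileext = ".yaml")
  writeLines(c("max_radius: 25", "plateau_tol: 0.01"), f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$max_radius, 25)
  expect_equal(cfg2$plateau_tol, 0.01)
  writeLines("no_such_key: 1", f)
  expect_error(read_config(f), "unknown config keys")
  unlink(f)
})

test_that("a folder of synthetic images yields one report row each", {
  dir <- file.path(tempdir(), "gj_batch_in")
  dir.create(dir, showWarnings = FALSE)
  for (seed in 1:3)
    write_rgb_image(generate_gj_image(gj_scene_spec(seed = seed))$image,
                    file.path(dir, sprintf("scene%d.tif", seed)))
  rep1 <- file.path(tempdir(), "rep1.csv")
  res <- run_batch(dir, report = rep1, mode = "gj")
  expect_equal(nrow(res$results), 3)
  expect_length(res$failures, 0)
  expect_true(file.exists(rep1))
  df <- read.csv(rep1)
  expect_true(all(abs(df$cx43_ee + df$cx43_ss - df$cx43_total) < 1e-6))
  unlink(dir, recursive = TRUE); unlink(rep1)
})

test_that("a corrupt input is logged as a failure and the batch continues", {
  dir <- file.path(tempdir(), "gj_batch_bad")
  dir.create(dir, showWarnings = FALSE)
  for (seed in 1:2)
    write_rgb_image(generate_gj_image(gj_scene_spec(seed = seed))$image,
                    file.path(dir, sprintf("ok%d.tif", seed)))
  writeLines("not a tiff", file.path(dir, "broken.tif"))
  res <- suppressWarnings(run_batch(dir, report = NULL, mode = "gj"))
  expect_equal(nrow(res$results), 2)
  expect_length(res$failures, 1)
  expect_named(res$failures, "broken")
  unlink(dir, recursive = TRUE)
})

test_that("an empty input folder warns and writes an empty report", {
  dir <- file.path(tempdir(), "gj_batch_empty")
  dir.create(dir, showWarnings = FALSE)
  rep0 <- file.path(tempdir(), "rep0.csv")
  expect_warning(res <- run_batch(dir, report = rep0, mode = "gj"),
                 "no input images")
  expect_equal(nrow(res$results), 0)
  expect_true(file.exists(rep0))
  unlink(dir, recursive = TRUE); unlink(rep0)
})

test_that("identical inputs and config give byte-identical reports", {
  dir <- file.path(tempdir(), "gj_batch_det")
  dir.create(dir, showWarnings = FALSE)
  write_rgb_image(generate_gj_image(gj_scene_spec(seed = 4))$image,
                  file.path(dir, "a.tif"))
  write_rgb_image(generate_mt_image(seed = 4)$image,
                  file.path(dir, "b.png"))
  r1 <- file.path(tempdir(), "d1.csv"); r2 <- file.path(tempdir(), "d2.csv")
  run_batch(dir, report = r1, mode = "collagen")
  run_batch(dir, report = r2, mode = "collagen")
  expect_identical(readBin(r1, "raw", file.size(r1)),
                   readBin(r2, "raw", file.size(r2)))
  unlink(dir, recursive = TRUE); unlink(c(r1, r2))
})

test_that("stack mode reports per-layer, aggregate and projection rows", {
  z <- generate_gj_zstack(gj_scene_spec(seed = 6), n_layers = 3)
  f <- tempfile(fileext = ".tif")
  write_zstack(z$stack, f)
  res <- suppressWarnings(run_batch(f, report = NULL, mode = "stack"))
  expect_equal(nrow(res$results), 3 + 2)   # layers + layerwise + projection
  ids <- res$results$image_id
  expect_true(any(grepl("_layerwise$", ids)))
  expect_true(any(grepl("_maxproj$", ids)))
  unlink(f)
})

test_that("sweep curves export as plottable CSV", {
  sc <- generate_gj_image(gj_scene_spec(seed = 8, width = 96, height = 96,
                                        n_plaques = 2,
                                        cx43_pixels_per_plaque = 60))
  q <- quantify_image(sc$image)
  f <- tempfile(fileext = ".csv")
  write_sweep_curve(q$sweep, f)
  df <- read.csv(f)
  expect_equal(df$radius_ipd, 0:40)
  expect_equal(df$ee_intensity, q$sweep$ee_intensity)
  unlink(f)
})
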