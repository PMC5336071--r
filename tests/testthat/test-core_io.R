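test_that("PNG and TIFF round-trips preserve 8-bit pixels exactly", {
  img <- matrix(c(0, 255, 128, 64), 2, 2)
  for (ext in c("png", "tif")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_gray_image(img, path)
    expect_identical(read_gray_image(path), img)
  }
  const <- matrix(128, 16, 16)
  path <- withr::local_tempfile(fileext = ".png")
  write_gray_image(const, path)
  expect_identical(read_gray_image(path), const)
  # a rendered phantom survives the round trip bit for bit
  rp <- render_phantom(phantom_scene(height = 24, width = 48,
                                     vein_tracks = list(vein_track(cbind(c(12, 12), c(4, 43)))),
                                     seed = 3))
  path2 <- withr::local_tempfile(fileext = ".png")
  write_gray_image(rp$image, path2)
  expect_identical(read_gray_image(path2), rp$image)
})

test_that("color input collapses to the unweighted channel mean", {
  path <- withr::local_tempfile(fileext = ".png")
  arr <- array(0, dim = c(2, 2, 3))
  arr[1, 1, ] <- c(30, 60, 90) / 255    # mean 60
  arr[2, 2, ] <- c(255, 0, 0) / 255     # mean 85
  png::writePNG(arr, path)
  got <- read_gray_image(path)
  expect_equal(got[1, 1], 60)
  expect_equal(got[2, 2], 85)
})

test_that("unreadable input and bad destinations raise input errors", {
  expect_error(read_gray_image(file.path(tempdir(), "nope.png")), "does not exist")
  trunc <- withr::local_tempfile(fileext = ".png")
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47)), trunc)
  expect_error(read_gray_image(trunc), "cannot read")
  expect_error(write_gray_image(matrix(0, 2, 2),
                                file.path(tempdir(), "no_such_dir_xyz", "a.png")),
               "does not exist")
  expect_error(read_gray_image(withr::local_tempfile(fileext = ".bmp")))
})

test_that("config files parse, default, and reject unknown keys", {
  cfgfile <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# pipeline settings",
               "blur_sigma = 2",
               "clahe_tiles = 4x4",
               "clahe_clip = 3",
               "frangi_scales = 1,2,3",
               "frangi_c = auto",
               "thresh_mask_size = 31",
               "thresh_offset = 5",
               "close_se = 9x3",
               "roi = 2,3,10,20",
               "save_intermediates = true"), cfgfile)
  cfg <- read_pipeline_config(cfgfile)
  expect_equal(cfg$blur_sigma, 2)
  expect_equal(cfg$clahe$tile_rows, 4L)
  expect_equal(cfg$vesselness$scales, c(1, 2, 3))
  expect_equal(cfg$segmentation$mask_size, 31L)
  expect_equal(cfg$segmentation$offset, 5)
  expect_equal(cfg$roi$height, 10L)
  expect_true(cfg$save_intermediates)
  # unspecified keys keep package defaults
  expect_equal(cfg$presmooth_sigma, 4)
  expect_equal(cfg$vesselness$beta, 0.5)

  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("blur_sgima = 2", bad)   # typo must be caught
  expect_error(read_pipeline_config(bad), "unknown config key")
})

test_that("pipeline runs are deterministic and compose from the stage functions", {
  rp <- render_phantom(phantom_scene(height = 40, width = 120,
                                     vein_tracks = list(vein_track(cbind(c(20, 20), c(8, 111)))),
                                     seed = 11))
  cfg <- pipeline_config(vesselness = vesselness_params(scales = c(2, 3, 4)),
                         segmentation = segmentation_params(mask_size = 31L))
  r1 <- run_pipeline(rp$image, cfg)
  r2 <- run_pipeline(rp$image, cfg)
  expect_identical(r1$skeleton, r2$skeleton)
  expect_identical(r1$overlay, r2$overlay)

  # manual composition of exported stages reproduces the pipeline exactly
  b <- gaussian_blur(rp$image, cfg$blur_sigma)
  e <- che(b, cfg$clahe)
  p <- gaussian_blur(e, cfg$presmooth_sigma)
  v8 <- vesselness_to_gray(frangi(p, cfg$vesselness))
  m <- adaptive_threshold(v8, cfg$segmentation$mask_size, cfg$segmentation$offset)
  cl <- morph_close(m, cfg$segmentation$se_width, cfg$segmentation$se_height)
  sk <- zhang_suen_skeleton(cl)
  expect_identical(r1$che, e)
  expect_identical(r1$vesselness8, v8)
  expect_identical(r1$mask, m)
  expect_identical(r1$skeleton, sk)
  expect_identical(r1$overlay, overlay_skeleton(e, sk))
})

test_that("ROI is honoured and invalid ROIs are rejected", {
  img <- matrix(rep(0:249, length.out = 50 * 60), 50, 60)
  cfg <- pipeline_config(roi = roi_rect(5, 10, 20, 30),
                         vesselness = vesselness_params(scales = c(1, 2)),
                         segmentation = segmentation_params(mask_size = 9L))
  res <- run_pipeline(img, cfg)
  expect_equal(dim(res$roi), c(20L, 30L))
  expect_identical(res$roi, extract_roi(img, cfg$roi))
  cfg$roi <- roi_rect(45, 10, 20, 30)
  expect_error(run_pipeline(img, cfg), "exceeds image bounds")
})

test_that("a constant image yields an empty skeleton with a warning", {
  img <- matrix(120, 40, 60)
  expect_warning(res <- run_pipeline(img, pipeline_config(
    segmentation = segmentation_params(mask_size = 31L))), "no line structure")
  expect_equal(sum(res$skeleton), 0)
  expect_identical(res$overlay, res$che)
})

test_that("save_intermediates writes the numbered stage files", {
  dir <- withr::local_tempdir()
  rp <- render_phantom(phantom_scene(height = 32, width = 64,
                                     vein_tracks = list(vein_track(cbind(c(16, 16), c(4, 59)))),
                                     seed = 2))
  cfg <- pipeline_config(save_intermediates = TRUE,
                         vesselness = vesselness_params(scales = c(2, 3)),
                         segmentation = segmentation_params(mask_size = 15L))
  res <- run_pipeline(rp$image, cfg, output_dir = dir)
  files <- c("01_roi.png", "02_che.png", "03_vesselness.png", "04_mask.png",
             "05_closed.png", "06_skeleton.png", "07_overlay.png")
  expect_true(all(file.exists(file.path(dir, files))))
  expect_identical(read_gray_image(file.path(dir, "07_overlay.png")), res$overlay)
})
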