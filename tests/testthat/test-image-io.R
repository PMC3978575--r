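test_that("PGM, PNG and TIFF images round-trip pixel-identically", {
  set.seed(11)
  px8 <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  px16 <- matrix(sample(0:65535, 64 * 64, replace = TRUE), 64, 64)
  img8 <- grey_image(px8, 8L, "rt8")
  img16 <- grey_image(px16, 16L, "rt16")

  for (ext in c("pgm", "png", "tif")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_image(img8, f)
    back <- read_image(f)
    expect_identical(back$pixels, img8$pixels, label = paste("8-bit", ext))
    expect_identical(back$bit_depth, 8L)
  }
  for (ext in c("pgm", "tif")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_image(img16, f)
    back <- read_image(f)
    expect_identical(back$pixels, img16$pixels, label = paste("16-bit", ext))
    expect_identical(back$bit_depth, 16L)
  }
})

test_that("constant and extreme intensities survive reading", {
  f <- withr::local_tempfile(fileext = ".pgm")
  write_image(grey_image(matrix(0L, 64, 64), 8L, "zero"), f)
  img <- read_image(f)
  expect_true(all(img$pixels == 0L))
  expect_identical(img$bit_depth, 8L)

  f16 <- withr::local_tempfile(fileext = ".tif")
  px <- matrix(0L, 64, 64)
  px[1, 1] <- 65535L
  write_image(grey_image(px, 16L, "peak"), f16)
  expect_identical(max(read_image(f16)$pixels), 65535L)
})

test_that("plain-text (P2) PGM files are readable", {
  f <- withr::local_tempfile(fileext = ".pgm")
  vals <- matrix(rep(0:63, 64), 64, 64)
  writeLines(c("P2", "# comment", "64 64", "255",
               apply(vals, 1, paste, collapse = " ")), f)
  img <- read_image(f)
  expect_identical(img$pixels, matrix(as.integer(vals), 64, 64))
})

test_that("colour input and unreadable files are rejected with clear errors", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(64 * 64 * 3), c(64, 64, 3)), f)
  expect_error(read_image(f), "colour")
  expect_error(read_image(f), basename(f))
  expect_error(read_image(tempfile(fileext = ".png")), "cannot read")
})

test_that("mask images round-trip byte-identically through write_mask", {
  ph <- generate_phantom(phantom_spec(dense_fraction = 0.2, seed = 21))
  f <- withr::local_tempfile(fileext = ".png")
  write_mask(ph$dense$pixels, f)
  back <- read_image(f)
  expect_identical(back$pixels == 255L, ph$dense$pixels)
})

test_that("overlay writes outline and mask with documented intensities", {
  ph <- generate_phantom(phantom_spec(dense_fraction = 0.25, noise_sd = 0,
                                      seed = 5))
  f_out <- withr::local_tempfile(fileext = ".png")
  f_msk <- withr::local_tempfile(fileext = ".png")
  write_overlay(ph$image, ph$breast, ph$dense, f_out, f_msk)
  mask_img <- read_image(f_msk)
  expect_identical(sum(mask_img$pixels == 255L), ph$dense$area_px)
  outline <- read_image(f_out)$pixels
  expect_true(any(outline == 127L))   # breast boundary at mid-grey
  expect_true(any(outline == 255L))   # dense boundary at maximum

  # all-zero dense mask: no maximal-intensity outline, empty mask image
  empty <- dense_mask(matrix(FALSE, nrow(ph$image$pixels),
                             ncol(ph$image$pixels)))
  write_overlay(ph$image, ph$breast, empty, f_out, f_msk)
  expect_true(all(read_image(f_msk)$pixels == 0L))

  # dense mask equal to breast mask: outlines coincide, all at max
  full <- dense_mask(ph$breast$pixels, breast = ph$breast)
  write_overlay(ph$image, ph$breast, full, f_out, f_msk)
  out2 <- read_image(f_out)$pixels
  expect_false(any(out2 == 127L))

  # dimension mismatch is a contract error
  small <- dense_mask(matrix(FALSE, 64, 64))
  expect_error(write_overlay(ph$image, ph$breast, small, f_out, f_msk),
               "dimensions")
})

test_that("results tables render per contract", {
  ok <- structure(list(source_id = "img1", status = "success",
                       threshold = 120, breast_area_px = 1000L,
                       dense_area_px = 250L, percent_density = 25,
                       degenerate = FALSE), class = "density_result")
  bad <- structure(list(source_id = "img2", status = "failure",
                        reason = "FAIL_BREAST_SEGMENTATION"),
                   class = "density_result")
  tab <- results_table(list(ok, bad))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$status, c("OK", "FAIL_BREAST_SEGMENTATION"))
  expect_true(is.na(tab$percent_density[2]))

  f <- withr::local_tempfile(fileext = ".csv")
  write_results(tab, f)
  lines <- readLines(f)
  expect_identical(
    lines[1],
    "source_id,status,breast_area_px,dense_area_px,percent_density,threshold")
  expect_match(lines[2], ",25\\.00,")                 # >= 2 decimals
  expect_match(lines[3], "FAIL_BREAST_SEGMENTATION,,,,")  # empty numerics

  # empty table -> header-only CSV
  write_results(results_table(list()), f)
  expect_identical(length(readLines(f)), 1L)

  back <- read_results(f)
  expect_identical(nrow(back), 0L)
})
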