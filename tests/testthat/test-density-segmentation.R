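test_that("two-level breasts threshold exactly at the criterion maximiser", {
  vals <- c(rep(50L, 614), rep(200L, 410))   # ~60/40 split
  fx <- rect_breast(vals)
  thr <- compute_threshold(fx$image, fx$mask)
  expect_false(thr$degenerate)
  expect_identical(thr$threshold,
                   oracle_threshold(fx$image$pixels[fx$mask$pixels]))
  expect_identical(thr$threshold, 50)        # any t in [50,200) separates;
                                             # smallest candidate wins
  dense <- segment_dense(fx$image, fx$mask, thr$threshold)
  expect_identical(dense$area_px, 410L)
})

test_that("constant breasts degenerate to zero dense area without failing", {
  fx <- rect_breast(100L)
  thr <- compute_threshold(fx$image, fx$mask)
  expect_true(thr$degenerate)
  expect_identical(thr$threshold, 100)
  dense <- segment_dense(fx$image, fx$mask, thr$threshold)
  expect_identical(dense$area_px, 0L)
})

test_that("bimodal breasts threshold between the modes, matching the oracle", {
  set.seed(15)
  n <- 32 * 32
  vals <- as.integer(pmin(pmax(round(c(rnorm(615, 80, 10),
                                       rnorm(409, 180, 10))), 0), 255))
  fx <- rect_breast(vals)
  thr <- compute_threshold(fx$image, fx$mask)
  # the cut falls between the two modes and recovers the bright cluster
  expect_gt(thr$threshold, 80)
  expect_lt(thr$threshold, 180)
  dense <- segment_dense(fx$image, fx$mask, thr$threshold)
  expect_lt(abs(dense$area_px - 409) / 1024, 0.02)
  expect_identical(thr$threshold,
                   oracle_threshold(fx$image$pixels[fx$mask$pixels]))
})

test_that("threshold equals the exhaustive oracle on random phantoms", {
  for (seed in 301:310) {
    frac <- c(0.1, 0.25, 0.4, 0.6)[(seed %% 4) + 1]
    ph <- generate_phantom(phantom_spec(width = 128L, height = 128L,
                                        dense_fraction = frac,
                                        noise_sd = 8, seed = seed))
    pre <- contrast_stretch(median_smooth(ph$image, ph$breast), ph$breast)
    thr <- compute_threshold(pre, ph$breast)
    expect_identical(thr$threshold,
                     oracle_threshold(pre$pixels[ph$breast$pixels]))
  }
})

test_that("dense segmentation obeys strict-threshold semantics", {
  fx <- rect_breast(c(rep(10L, 512), rep(240L, 512)))
  vals <- fx$image$pixels[fx$mask$pixels]
  expect_identical(segment_dense(fx$image, fx$mask, max(vals))$area_px, 0L)
  expect_identical(segment_dense(fx$image, fx$mask, -1)$area_px,
                   fx$mask$area_px)
  expect_identical(segment_dense(fx$image, fx$mask, 100)$area_px, 512L)
})

test_that("percent density is the dense/breast pixel ratio", {
  breast <- breast_mask(matrix(TRUE, 64, 64), check = FALSE)
  d <- matrix(FALSE, 64, 64)
  d[1:16, ] <- TRUE                   # 1024 of 4096
  meas <- measure_density(breast, dense_mask(d, breast))
  expect_equal(meas$percent_density, 25)
  full <- measure_density(breast, dense_mask(matrix(TRUE, 64, 64), breast))
  expect_equal(full$percent_density, 100)
})

test_that("the full pipeline recovers designed density on clean phantoms", {
  ph <- generate_phantom(phantom_spec(dense_fraction = 0.35, noise_sd = 5,
                                      seed = 61))
  res <- process_image(ph$image)
  expect_identical(res$status, "success")
  expect_lt(abs(res$percent_density - 100 * ph$realised_fraction), 5)
})

test_that("pipeline failures propagate from breast segmentation", {
  wide <- generate_phantom(phantom_spec(breast_semi_x = 1.3,
                                        dense_fraction = 0.2, seed = 62))
  res <- process_image(wide$image)
  expect_identical(res$status, "failure")
  expect_identical(res$reason, "FAIL_BREAST_SEGMENTATION")
})

test_that("processing is deterministic and independent of batch context", {
  ph <- generate_phantom(phantom_spec(dense_fraction = 0.25, seed = 63))
  r1 <- process_image(ph$image)
  r2 <- process_image(ph$image)
  expect_identical(unclass(r1), unclass(r2))

  # thresholds are per-image: computing others in between changes nothing
  other <- generate_phantom(phantom_spec(dense_fraction = 0.5, seed = 64))
  invisible(process_image(other$image))
  r3 <- process_image(ph$image)
  expect_identical(unclass(r1), unclass(r3))
})

test_that("an affine intensity remapping leaves the dense pixel set fixed", {
  ph <- generate_phantom(phantom_spec(dense_fraction = 0.3, noise_sd = 6,
                                      seed = 65))
  img <- ph$image
  # gain/offset change of the digitiser: the criterion scales by gain^2 at
  # every cut, so the maximising partition is unchanged
  img2 <- grey_image(4L * img$pixels + 7L, 16L, "remap")
  t1 <- compute_threshold(img, ph$breast)$threshold
  t2 <- compute_threshold(img2, ph$breast)$threshold
  d1 <- segment_dense(img, ph$breast, t1)$pixels
  d2 <- segment_dense(img2, ph$breast, t2)$pixels
  expect_identical(d1, d2)
})
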