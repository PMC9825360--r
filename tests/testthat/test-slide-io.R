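make_flat_slide <- function(h, w, rgb) {
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  slide_image(px)
}

test_that("HSV tissue mask equals per-channel Otsu intersection on a pink square", {
  sl <- make_flat_slide(40, 40, c(255, 255, 255))
  sl$pixels[11:25, 6:20, 1] <- 255
  sl$pixels[11:25, 6:20, 2] <- 105
  sl$pixels[11:25, 6:20, 3] <- 180
  mask <- compute_tissue_mask_hsv(sl)
  want <- matrix(FALSE, 40, 40); want[11:25, 6:20] <- TRUE
  expect_identical(mask, want)

  # definition: intersection of the two channel masks
  hsv <- grDevices::rgb2hsv(as.vector(sl$pixels[, , 1]),
                            as.vector(sl$pixels[, , 2]),
                            as.vector(sl$pixels[, , 3]), maxColorValue = 255)
  mh <- matrix(hsv[1, ] >= bf_otsu(hsv[1, ]), 40, 40)
  ms <- matrix(hsv[2, ] >= bf_otsu(hsv[2, ]), 40, 40)
  expect_identical(mask, mh & ms)
})

test_that("HSV tissue mask rejects constant channels", {
  expect_error(compute_tissue_mask_hsv(make_flat_slide(8, 8, c(0, 0, 0))),
               class = "lcmil_degenerate_error")
})

test_that("RGB tissue thresholds are strict and default to (235, 210, 235)", {
  sl <- make_flat_slide(2, 2, c(255, 255, 255))
  sl$pixels[1, 1, ] <- c(0, 0, 0)
  sl$pixels[1, 2, ] <- c(235, 210, 235)   # boundary: excluded
  sl$pixels[2, 1, ] <- c(234, 209, 234)   # just below: tissue
  m <- compute_tissue_mask_rgb(sl)
  expect_identical(m, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
})

test_that("patch lattice tiles exactly and drops partial patches", {
  sl <- make_flat_slide(512, 512, c(100, 100, 100))
  ps <- extract_patch_grid(sl, patch_size = 256, overlap_fraction = 0)
  expect_equal(nrow(ps), 4)
  expect_setequal(paste(ps$row, ps$col),
                  c("0 0", "0 256", "256 0", "256 256"))

  # no partial patches on a 300x300 slide
  sl2 <- make_flat_slide(300, 300, c(100, 100, 100))
  ps2 <- extract_patch_grid(sl2, patch_size = 256, overlap_fraction = 0)
  expect_equal(nrow(ps2), 1)
  expect_equal(c(ps2$row, ps2$col), c(0, 0))

  # 75% overlap of 256-px patches means a 64-px stride
  ps3 <- extract_patch_grid(sl, patch_size = 256, overlap_fraction = 0.75)
  expect_equal(attr(ps3, "stride"), 64L)

  # non-integer stride is a configuration error
  expect_error(extract_patch_grid(sl, patch_size = 256, overlap_fraction = 1 / 3),
               class = "lcmil_config_error")
})

test_that("grid completeness matches brute-force lattice enumeration", {
  set.seed(11)
  sl <- make_flat_slide(140, 170, c(100, 100, 100))
  tissue <- matrix(runif(140 * 170) > 0.4, 140, 170)
  ps <- extract_patch_grid(sl, tissue, patch_size = 32, overlap_fraction = 0.5)
  n_expected <- 0
  for (r in seq(0, 140 - 32, 16)) for (c in seq(0, 170 - 32, 16)) {
    if (tissue[r + 16 + 1, c + 16 + 1]) n_expected <- n_expected + 1
  }
  expect_equal(nrow(ps), n_expected)
  expect_true(all(tissue[cbind(ps$center_row + 1, ps$center_col + 1)]))
})

test_that("noisy labels follow the patch-center rule and partition S", {
  sl <- make_flat_slide(100, 100, c(100, 100, 100))
  ps <- extract_patch_grid(sl, patch_size = 20, overlap_fraction = 0)
  # patch at (40, 40) has center (50, 50); mask that excludes it by 1 px
  coarse <- matrix(FALSE, 100, 100)
  coarse[52:100, 1:100] <- TRUE
  ps <- assign_noisy_labels(ps, coarse)
  rec <- ps[ps$row == 40 & ps$col == 40, ]
  expect_equal(rec$label, 0L)          # center (50,50) is 1 row outside
  rec2 <- ps[ps$row == 60 & ps$col == 40, ]
  expect_equal(rec2$label, 1L)

  pools <- patch_pools(ps)
  expect_equal(length(pools$positive) + length(pools$negative), nrow(ps))
  expect_length(intersect(pools$positive, pools$negative), 0)

  # all-false mask: S_P empty
  ps0 <- assign_noisy_labels(ps, matrix(FALSE, 100, 100))
  expect_equal(sum(ps0$label), 0)

  expect_error(assign_noisy_labels(ps, matrix(FALSE, 50, 50)),
               class = "lcmil_config_error")
})

test_that("score maps hold one cell per patch position and round-trip", {
  sl <- make_flat_slide(512, 512, c(100, 100, 100))
  ps <- extract_patch_grid(sl, patch_size = 256, overlap_fraction = 0)
  ps$score <- c(0.1, 0.2, 0.3, 0.4)
  m <- assemble_score_map(ps)
  expect_equal(dim(m), c(2, 2))
  for (i in seq_len(nrow(ps))) {
    expect_equal(m[ps$row[i] / 256 + 1, ps$col[i] / 256 + 1], ps$score[i])
  }
  expect_equal(attr(m, "stride"), 256L)

  # heat-map stride for 75%-overlapping 256-px patches is 64 px per cell
  ps2 <- extract_patch_grid(sl, patch_size = 256, overlap_fraction = 0.75)
  ps2$score <- runif(nrow(ps2))
  expect_equal(attr(assemble_score_map(ps2), "downscale"), 64L)

  ps$score[2] <- NA
  expect_error(assemble_score_map(ps), "score")
})

test_that("patching and score maps are deterministic", {
  sl <- make_flat_slide(128, 128, c(90, 80, 120))
  a <- extract_patch_grid(sl, patch_size = 32, overlap_fraction = 0.5)
  b <- extract_patch_grid(sl, patch_size = 32, overlap_fraction = 0.5)
  expect_identical(a, b)
})

test_that("slides and masks survive PNG round-trips", {
  px <- array(round(runif(32 * 32 * 3) * 255), c(32, 32, 3))
  sl <- slide_image(px)
  f <- withr::local_tempfile(fileext = ".png")
  write_slide(sl, f)
  back <- read_slide(f)
  expect_equal(back$pixels, sl$pixels, tolerance = 1e-8)

  mask <- matrix(runif(32 * 32) > 0.5, 32, 32)
  fm <- withr::local_tempfile(fileext = ".png")
  write_mask(mask, fm)
  expect_identical(read_mask(fm), mask)
})

test_that("score maps survive the 16-bit TIFF + sidecar round-trip", {
  fx <- small_fixture()
  ps <- fx$pset
  ps$score <- round(runif(nrow(ps)) * 65535) / 65535
  m <- assemble_score_map(ps)
  f <- withr::local_tempfile(fileext = ".tif")
  write_score_map(m, f)
  back <- read_score_map(f)
  m0 <- unclass(m); m0[is.na(m0)] <- 0
  expect_equal(unclass(back), m0, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(attr(back, "stride"), attr(m, "stride"))
})
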