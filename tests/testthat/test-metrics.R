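test_that("relative-change image follows the ASTM definition", {
  ref <- matrix(100, 4, 4)
  to <- matrix(100, 4, 4)
  to[2, 2] <- 69; to[3, 3] <- 131
  ch <- artifact_image(to, ref)
  expect_equal(ch[2, 2], -0.31)
  expect_equal(ch[3, 3], 0.31)
  expect_equal(ch[1, 1], 0)
  expect_error(artifact_image(to, matrix(100, 3, 3)), "dimension")
})

test_that("pixels below the reference floor flag as artifact", {
  ref <- matrix(100, 3, 3); ref[2, 2] <- 0
  to <- matrix(100, 3, 3)
  ch <- artifact_image(to, ref)
  expect_true(is.infinite(ch[2, 2]))
  m <- threshold_mask(ch, 0.30)
  expect_true(m[2, 2])
  expect_equal(sum(m), 1L)
})

test_that("thresholding is strict: 'more than 30%'", {
  ch <- matrix(c(-0.31, 0.29, 0.30, 0.31), 2, 2)
  m <- threshold_mask(ch, 0.30)
  expect_identical(as.vector(unclass(m)), c(TRUE, FALSE, FALSE, TRUE))
  expect_error(threshold_mask(ch, 0), "config")
  expect_error(threshold_mask(ch, 1.5), "config")
})

test_that("threshold_mask is monotone in the threshold", {
  set.seed(5)
  ch <- matrix(rnorm(400, 0, 0.4), 20, 20)
  for (i in 1:5) {
    t1 <- runif(1, 0.05, 0.5); t2 <- t1 + runif(1, 0.01, 0.4)
    m1 <- threshold_mask(ch, t1); m2 <- threshold_mask(ch, t2)
    expect_true(all(m1 | !m2))                  # raising never adds pixels
  }
})

test_that("areas count pixels and convert with the squared pixel size", {
  m <- matrix(FALSE, 256, 256)
  m[1:10, 1:10] <- TRUE
  a <- artifact_area(m, pixel_mm = 200 / 256)
  expect_equal(a$area_px, 100L)
  expect_equal(a$area_mm2, 100 * (200 / 256)^2)          # 61.04 mm^2
  expect_equal(round(a$area_mm2, 2), 61.04)
  expect_equal(artifact_area(matrix(FALSE, 4, 4), 1)$area_px, 0L)
  full <- artifact_area(matrix(TRUE, 256, 256), 200 / 256)
  expect_equal(full$area_px, 65536L)
  expect_equal(full$area_mm2, 40000)                     # recovers FOV^2
})

test_that("one-pixel bounds follow 3 x 3 morphology", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  b <- one_pixel_bounds(m)
  expect_equal(b$area_eroded_px, 0L)
  expect_equal(b$area_dilated_px, 9L)
  m2 <- matrix(FALSE, 9, 9); m2[4:6, 4:6] <- TRUE
  b2 <- one_pixel_bounds(m2)
  expect_equal(b2$area_eroded_px, 1L)
  expect_equal(b2$area_dilated_px, 25L)
  b0 <- one_pixel_bounds(matrix(FALSE, 5, 5))
  expect_equal(b0$area_eroded_px, 0L)
  expect_equal(b0$area_dilated_px, 0L)
})

test_that("eroded <= area <= dilated for random masks", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(runif(900) < 0.3, 30, 30)
    b <- one_pixel_bounds(m)
    expect_lte(b$area_eroded_px, sum(m))
    expect_gte(b$area_dilated_px, sum(m))
  }
})

test_that("morphology agrees with EBImage on interior masks", {
  set.seed(33)
  m <- matrix(FALSE, 40, 40)
  m[10:30, 10:30] <- matrix(runif(441) < 0.4, 21, 21)
  kern <- matrix(1, 3, 3)
  expect_equal(unclass(morph_mask(m, "erode")) & TRUE,
               EBImage::erode(m * 1, kern) == 1, ignore_attr = TRUE)
  expect_equal(unclass(morph_mask(m, "dilate")) & TRUE,
               EBImage::dilate(m * 1, kern) == 1, ignore_attr = TRUE)
})

test_that("centroid alignment recovers integer offsets and rounds half away", {
  a <- matrix(FALSE, 20, 20); a[8:12, 8:12] <- TRUE
  b <- matrix(FALSE, 20, 20); b[6:10, 8:12] <- TRUE     # offset (-2, 0)
  expect_identical(unclass(align_by_centroid(a, b)) & TRUE, a)
  expect_identical(unclass(align_by_centroid(a, a)) & TRUE, a)  # zero shift
  # fractional centroid difference (1.4, 0.6) rounds to a shift of (1, 1):
  # b3's five pixels have centroid (13.6, 14.4); a3's single pixel (15, 15)
  a3 <- matrix(FALSE, 30, 30); a3[15, 15] <- TRUE
  b3 <- matrix(FALSE, 30, 30)
  b3[cbind(c(13, 13, 13, 14, 15), c(14, 15, 16, 14, 13))] <- TRUE
  d <- artifactsim:::mask_centroid(a3) - artifactsim:::mask_centroid(b3)
  expect_equal(unname(d), c(1.4, 0.6))
  aligned <- align_by_centroid(a3, b3)
  got <- which(unclass(aligned) & TRUE, arr.ind = TRUE)
  want <- which(b3, arr.ind = TRUE); want[, 1] <- want[, 1] + 1L; want[, 2] <- want[, 2] + 1L
  expect_equal(got[order(got[, 1], got[, 2]), ], want[order(want[, 1], want[, 2]), ],
               ignore_attr = TRUE)
  expect_error(align_by_centroid(a, matrix(FALSE, 20, 20)), "alignment")
})

test_that("round-half-away-from-zero breaks ties deterministically", {
  expect_equal(artifactsim:::round_half_away(c(1.4, 0.6, 0.5, -0.5, -1.5, 2.5)),
               c(1, 1, 1, -1, -2, 3))
})

test_that("similarity factor is the IoU with its boundary cases", {
  a <- matrix(FALSE, 10, 10); a[3:6, 3:6] <- TRUE
  expect_equal(similarity_factor(a, a), 1)
  b <- matrix(FALSE, 10, 10); b[8:9, 8:9] <- TRUE
  expect_equal(similarity_factor(a, b, align = FALSE), 0)
  # |A & B| = 6, |A | B| = 12 -> 0.5
  a3 <- matrix(FALSE, 1, 12); a3[1, 1:9] <- TRUE
  b3 <- matrix(FALSE, 1, 12); b3[1, 4:12] <- TRUE
  expect_equal(similarity_factor(a3, b3, align = FALSE), 0.5)
  expect_error(similarity_factor(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)),
               "empty")
})

test_that("similarity factor is symmetric and 1 only for identical masks", {
  set.seed(9)
  for (i in 1:8) {
    a <- matrix(runif(400) < 0.3, 20, 20)
    b <- matrix(runif(400) < 0.3, 20, 20)
    if (!any(a) || !any(b)) next
    expect_equal(similarity_factor(a, b, align = FALSE),
                 similarity_factor(b, a, align = FALSE))
    if (!identical(a, b)) {
      expect_lt(similarity_factor(a, b, align = FALSE), 1)
    }
  }
})

test_that("overlay classes partition the union", {
  a <- matrix(FALSE, 10, 10); a[2:5, 2:5] <- TRUE
  b <- matrix(FALSE, 10, 10); b[4:7, 4:7] <- TRUE
  ov <- overlay_classes(a, b)
  cnt <- attr(ov, "counts")
  expect_equal(sum(cnt), sum(a | b))
  expect_equal(unname(cnt["both"]), sum(a & b))
  ov_same <- overlay_classes(a, a)
  expect_true(all(ov_same[a] == 1L) && all(ov_same[!a] == 0L))
  disj <- overlay_classes(a, matrix(FALSE, 10, 10))
  expect_true(all(disj %in% c(0L, 2L)))
})

test_that("translation preserves artifact area for interior masks", {
  a <- matrix(FALSE, 30, 30); a[12:18, 12:18] <- TRUE
  b <- artifactsim:::shift_mask(a, 4, -3)
  expect_equal(sum(b), sum(a))
  aligned <- align_by_centroid(a, b)
  expect_equal(sum(aligned), sum(a))
  expect_identical(unclass(aligned) & TRUE, a)
})

test_that("mask and overlay writers produce readable PNGs", {
  m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
  p1 <- tempfile(fileext = ".png"); p2 <- tempfile(fileext = ".png")
  write_mask_png(m, p1)
  back <- png::readPNG(p1)
  expect_equal(sum(back > 0.5), sum(m))
  write_overlay_png(overlay_classes(m, artifactsim:::shift_mask(m, 1, 0)), p2)
  arr <- png::readPNG(p2)
  expect_equal(dim(arr)[3], 3L)
  unlink(c(p1, p2))
})
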