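# Enhancement front end: top-hat transforms, CLAHE, cropping, resizing,
# paired augmentation.

test_that("top-hats match the brute-force morphology oracle on 9x9 rasters", {
  rasters <- make_9x9_rasters()
  for (se in list(structuring_element("disk", 2), structuring_element("square", 1))) {
    for (nm in names(rasters)) {
      img <- rasters[[nm]]
      expect_equal(white_tophat(img, se), bf_white_tophat(img, se),
                   info = paste("white", nm))
      expect_equal(black_tophat(img, se), bf_black_tophat(img, se),
                   info = paste("black", nm))
    }
  }
})

test_that("top-hat transforms behave on canonical cases", {
  se <- structuring_element("disk", 2)
  flat <- matrix(0.7, 9, 9)
  expect_equal(white_tophat(flat, se), matrix(0, 9, 9))
  expect_equal(black_tophat(flat, se), matrix(0, 9, 9))

  peak <- matrix(0, 9, 9); peak[5, 5] <- 1
  expect_equal(white_tophat(peak, se), peak)  # isolated peak survives intact

  pit <- matrix(1, 9, 9); pit[5, 5] <- 0
  expect_equal(black_tophat(pit, se), peak)   # isolated pit is highlighted

  # duality: black top-hat of img equals white top-hat of the inverted img
  img <- make_9x9_rasters()$random1
  expect_equal(black_tophat(img, se), white_tophat(1 - img, se))

  # a flat region larger than the element forces a zero somewhere
  expect_equal(min(white_tophat(img, se)), 0)
})

test_that("top-hat enhancement deepens dark vessels and preserves range", {
  se <- structuring_element("disk", 2)
  img <- matrix(0.5, 9, 9); img[5, 3:7] <- 0.3
  enh <- tophat_enhance(img, se)
  expect_lt(enh[5, 5], img[5, 5])
  expect_equal(tophat_enhance(matrix(0.42, 9, 9), se), matrix(0.42, 9, 9))
  set.seed(7)
  rnd <- matrix(runif(81), 9, 9)
  out <- tophat_enhance(rnd, se)
  expect_true(all(out >= 0 & out <= 1))
  # hand evaluation of the formula on the same raster
  expect_equal(out, pmin(pmax(rnd + bf_white_tophat(rnd, se) -
                                bf_black_tophat(rnd, se), 0), 1))
})

test_that("structuring elements validate and scale with image size", {
  expect_error(structuring_element("disk", 0), "radius")
  expect_error(white_tophat(matrix(0, 4, 4), structuring_element("disk", 9)),
               "larger than the image")
  expect_equal(scaled_se_radius(matrix(0, 300, 300)), 9L)
  expect_equal(scaled_se_radius(matrix(0, 96, 96)), 3L)
})

test_that("CLAHE maps constants to constants and stretches low contrast", {
  flat <- matrix(0.3, 64, 64)
  out <- clahe(flat)
  expect_equal(diff(range(out)), 0)

  two <- matrix(rep(c(0.4, 0.6), each = 2048), 64, 64)
  enh <- clahe(two)
  expect_gt(diff(range(enh)), diff(range(two)))
  expect_true(all(enh >= 0 & enh <= 1))
  expect_error(clahe(two, clip_limit = 0), "positive")
})

test_that("CLAHE clipped tile histograms never exceed the clip limit", {
  set.seed(12)
  img <- matrix(runif(96 * 96), 96, 96)
  hh <- angioseg:::clahe_tile_histograms(img, clip_limit = 2.0, tiles = c(8, 8))
  expect_true(all(hh$clipped <= hh$limit))
  expect_true(any(hh$raw > hh$limit))  # clipping actually engaged somewhere
  # redistribution preserves tile mass
  expect_equal(colSums(hh$redistributed, dims = 1),
               colSums(hh$raw, dims = 1), tolerance = 1e-9)
})

test_that("central crops take symmetric margins and validate bounds", {
  img <- matrix(seq_len(300 * 300), 300, 300)
  cr <- center_crop(img, c(288, 288))
  expect_equal(dim(cr), c(288L, 288L))
  expect_equal(cr[1, 1], img[7, 7])  # 6-pixel margins
  big <- matrix(0, 768, 768)
  expect_equal(dim(center_crop(big, c(576, 576))), c(576L, 576L))
  expect_identical(center_crop(img, c(300, 300)), img)
  expect_error(center_crop(img, c(301, 300)), "exceeds")
})

test_that("resize is identity at the same size, convex, and mask-safe", {
  set.seed(3)
  img <- matrix(runif(300 * 300), 300, 300)
  expect_identical(resize_image(img, c(300, 300)), img)
  small <- resize_image(img, c(288, 288), "bilinear")
  expect_true(all(small >= min(img) & small <= max(img)))

  m <- matrix(c(1, 0, 0, 1, 1, 0, 0, 1, 1, 1, 0, 0, 0, 0, 1, 1), 4, 4)
  up <- resize_image(m, c(8, 8), "nearest")
  expect_true(all(up %in% c(0, 1)))
  expect_equal(up, m[rep(1:4, each = 2), rep(1:4, each = 2)])  # 2x2 replication
})

test_that("paired augmentation is seeded, alignment-preserving and binary", {
  pairs <- make_fixture_pairs(n = 1, size = 96, seed = 21)
  s <- pairs[[1]]
  a1 <- augment_pair(s, seed = 5)
  a2 <- augment_pair(s, seed = 5)
  expect_identical(a1, a2)
  expect_true(all(a1$mask %in% c(0, 1)))
  expect_identical(dim(a1$image), dim(s$image))

  # pure horizontal flip permutes pixels: vessel count unchanged
  fl <- angioseg:::apply_pair_transform(s, angle = 0,
    crop = c(0L, 0L, nrow(s$image), ncol(s$image)), hflip = TRUE, vflip = FALSE)
  expect_equal(sum(fl$mask), sum(s$mask))
  expect_equal(fl$image, s$image[, rev(seq_len(ncol(s$image)))])

  # zero rotation with a full-size crop and no flips is the identity
  id <- angioseg:::apply_pair_transform(s, angle = 0,
    crop = c(0L, 0L, nrow(s$image), ncol(s$image)), hflip = FALSE, vflip = FALSE)
  expect_equal(id$image, s$image)
  expect_identical(id$mask, s$mask)

  # mask transforms track the image of an indicator raster
  ind <- list(image = s$mask + 0, mask = s$mask)
  ai <- augment_pair(ind, seed = 77)
  expect_gt(dice_coefficient(ai$mask, ai$image), 0.85)
})
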