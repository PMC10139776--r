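test_that("adaptive threshold equals the explicit windowed-mean rule", {
  mp <- morph_params(adaptive_block_size = 5, adaptive_offset = 0.02)

  expect_true(all(adaptive_threshold(matrix(0.5, 20, 20), mp) == 0L))

  set.seed(8)
  z <- matrix(runif(18 * 22), 18, 22)
  expected <- matrix(as.integer(z > oracle_local_mean(z, 5) + 0.02), 18, 22)
  expect_identical(adaptive_threshold(z, mp), expected)

  # a bright ridge on a dark field is marked foreground
  ridge <- matrix(0.1, 20, 20)
  ridge[, 10:11] <- 0.9
  th <- adaptive_threshold(ridge, morph_params())
  expect_true(all(th[, 10:11] == 1L))
  expect_true(all(th[, c(1:6, 15:20)] == 0L))

  # zero offset on a checkerboard marks the bright squares
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2) * 0.8 + 0.1
  mp0 <- morph_params(adaptive_block_size = 3, adaptive_offset = 0)
  th_cb <- adaptive_threshold(cb, mp0)
  oracle_cb <- matrix(as.integer(cb > oracle_local_mean(cb, 3)), 16, 16)
  expect_identical(th_cb, oracle_cb)
  expect_true(all(th_cb[cb > 0.5] == 1L))

  expect_error(morph_params(adaptive_block_size = 4), "odd")
})

test_that("hole filling matches a border flood-fill oracle", {
  # solid disk: unchanged
  disk <- matrix(0L, 15, 15)
  disk[outer(1:15, 1:15, function(i, j) (i - 8)^2 + (j - 8)^2) <= 16] <- 1L
  expect_identical(fill_external_contours(disk), disk)

  # annulus becomes a solid disk
  ann <- matrix(0L, 15, 15)
  rr <- outer(1:15, 1:15, function(i, j) (i - 8)^2 + (j - 8)^2)
  ann[rr <= 36 & rr >= 16] <- 1L
  expect_identical(fill_external_contours(ann), oracle_fill_holes(ann))
  expect_true(all(fill_external_contours(ann)[rr <= 36] == 1L))

  # two nested rings collapse to one solid disk
  nest <- matrix(0L, 21, 21)
  rr2 <- outer(1:21, 1:21, function(i, j) (i - 11)^2 + (j - 11)^2)
  nest[rr2 >= 64 & rr2 <= 81] <- 1L
  nest[rr2 >= 16 & rr2 <= 25] <- 1L
  expect_identical(fill_external_contours(nest), oracle_fill_holes(nest))

  # random masks agree with the oracle and never lose foreground
  set.seed(9)
  for (i in 1:15) {
    b <- matrix(rbinom(16 * 16, 1, 0.45), 16, 16)
    f <- fill_external_contours(b)
    expect_identical(f, oracle_fill_holes(b))
    expect_true(all(f >= b))
  }
})

test_that("opening matches brute-force erosion-then-dilation", {
  # two 5x5 squares joined by a one-pixel bridge: bridge severed, squares kept
  b <- matrix(0L, 7, 13)
  b[2:6, 2:6] <- 1L
  b[4, 7] <- 1L
  b[2:6, 8:12] <- 1L
  o <- mask_opening(b)
  expect_identical(o, oracle_opening3(b))
  expect_identical(o[4, 7], 0L)
  expect_identical(o[3, 3], 1L)
  expect_identical(o[3, 10], 1L)

  # opening-stable shape passes through; isolated pixel is removed
  sq <- matrix(0L, 10, 10); sq[3:8, 3:8] <- 1L
  expect_identical(mask_opening(sq), sq)
  px <- matrix(0L, 9, 9); px[5, 5] <- 1L
  expect_true(all(mask_opening(px) == 0L))

  set.seed(10)
  for (i in 1:15) {
    b <- matrix(rbinom(14 * 16, 1, 0.5), 14, 16)
    o <- mask_opening(b)
    expect_identical(o, oracle_opening3(b))
    # opened mask is always contained in the dilation of the original
    expect_true(all(o <= oracle_dilate3(b)))
  }
})

test_that("inversion is an involution that conserves pixel counts", {
  expect_true(all(invert_mask(matrix(1L, 5, 5)) == 0L))
  set.seed(11)
  b <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_identical(invert_mask(invert_mask(b)), b)
  expect_identical(sum(b) + sum(invert_mask(b)), 64L)
})

test_that("component labeling respects connectivity and matches 4-conn oracle", {
  diagchain <- matrix(0L, 12, 12)
  for (i in 1:10) diagchain[i, i] <- 1L
  expect_identical(max(label_components(diagchain, 8L)), 1L)
  expect_identical(max(label_components(diagchain, 4L)), 10L)

  set.seed(12)
  for (i in 1:10) {
    b <- matrix(rbinom(15 * 15, 1, 0.4), 15, 15)
    lab4 <- label_components(b, 4L)
    ref <- EBImage::bwlabel(b)
    expect_identical(max(lab4), max(ref))
    # same partition: component of each pixel has the same member set
    expect_true(all((lab4 > 0) == (ref > 0)))
    for (k in seq_len(max(ref))) {
      expect_identical(length(unique(lab4[ref == k])), 1L)
    }
  }
})

test_that("small-region removal enforces the strict area-10 rule", {
  mp <- morph_params()
  nine <- matrix(0L, 12, 12); nine[4:6, 4:6] <- 1L          # area 9
  ten <- matrix(0L, 12, 12); ten[4:5, 4:8] <- 1L            # area 10
  expect_true(all(remove_small_regions(nine, mp) == 0L))
  expect_identical(remove_small_regions(ten, mp), ten)

  both <- nine; both[9:10, 2:11] <- 1L                      # 9 + 20
  cleaned <- remove_small_regions(both, mp)
  expect_true(all(cleaned[4:6, 4:6] == 0L))
  expect_true(all(cleaned[9:10, 2:11] == 1L))

  empty <- matrix(0L, 8, 8)
  expect_identical(remove_small_regions(empty, mp), empty)

  # under 4-connectivity a diagonal chain fragments into removable singletons
  diagchain <- matrix(0L, 14, 14)
  for (i in 1:12) diagchain[i, i] <- 1L
  expect_true(all(remove_small_regions(diagchain,
                                       morph_params(connectivity = 4)) == 0L))
  expect_identical(remove_small_regions(diagchain, mp), diagchain)

  # removal never increases foreground
  set.seed(13)
  for (i in 1:10) {
    b <- matrix(rbinom(20 * 20, 1, 0.3), 20, 20)
    expect_true(all(remove_small_regions(b, mp) <= b))
  }
})

test_that("full transform recovers fixture borders and is speckle-free", {
  expect_true(all(morph_transform(matrix(0, 48, 48)) == 0L))

  lp <- generate_cell_image(synthetic_spec(image_size = 96, n_seeds = 20,
                                           border_intensity = 1,
                                           interior_intensity = 0,
                                           noise_sigma = 0, rng_seed = 7))
  w <- morph_transform(lp$image)
  expect_true(all(w %in% c(0L, 1L)))
  iou <- seg_metrics(confusion_counts(w, lp$border_mask))$iou
  expect_gte(iou, 0.8)

  # every surviving component respects the minimum area, on fixtures and on
  # arbitrary grayscale inputs
  set.seed(14)
  for (z in list(lp$image, matrix(runif(48 * 48), 48, 48))) {
    w <- morph_transform(z)
    lab <- label_components(w, 8L)
    if (max(lab) > 0) {
      expect_gte(min(tabulate(lab[lab > 0])), 10)
    }
  }

  # staged output exposes the pipeline in order
  st <- morph_transform(lp$image, stages = TRUE)
  expect_named(st, c("threshold", "cells", "filled", "opened", "inverted",
                     "cleaned"))
  expect_identical(st$cleaned, morph_transform(lp$image))
})
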