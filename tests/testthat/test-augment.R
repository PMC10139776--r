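identity_params <- function() {
  augment_params(noise_sigma_range = c(0, 0), blur_sigma_range = c(0, 0),
                 brightness_factor_range = c(1, 1),
                 blob_count_range = c(0L, 0L))
}

test_that("degenerate T1 parameters reduce to identity and pure scaling", {
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(corrupt_T1(x, identity_params()), x)

  p <- augment_params(noise_sigma_range = c(0, 0), blur_sigma_range = c(0, 0),
                      brightness_factor_range = c(0.5, 0.5))
  expect_equal(corrupt_T1(matrix(0.8, 16, 16), p), matrix(0.4, 16, 16))
})

test_that("T1 noise field has the sampled standard deviation", {
  p <- augment_params(noise_sigma_range = c(0.1, 0.1),
                      blur_sigma_range = c(0, 0),
                      brightness_factor_range = c(1, 1))
  set.seed(31)
  x <- matrix(0.5, 100, 100)
  y <- corrupt_T1(x, p)
  expect_equal(sd(y - x), 0.1, tolerance = 0.01 / 0.1)
})

test_that("T2 adds blobs with the expected peak and analytic mass", {
  x <- matrix(runif(24 * 24), 24, 24)
  p0 <- augment_params(blob_count_range = c(0L, 0L))
  expect_identical(corrupt_T2(x, p0), x)

  # single blob, amplitude 1: maximum sits at the sampled centre and equals
  # min(1, amplitude) up to sub-pixel centre offset
  p1 <- augment_params(blob_count_range = c(1L, 1L),
                       blob_sigma_range = c(2, 2),
                       blob_amplitude_range = c(1, 1))
  set.seed(7)
  y1 <- corrupt_T2(matrix(0, 32, 32), p1)
  set.seed(7)
  ctr <- c(runif(1, 1, 32), runif(1, 1, 32))
  peak <- which(y1 == max(y1), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(peak - ctr)), 1)
  expect_lte(max(y1), 1)
  expect_gte(max(y1), 0.95)

  # five blobs on a zero image: total mass matches sum(amp * 2*pi*sigma^2)
  # (seed chosen so all centres are well inside the patch)
  p5 <- augment_params(blob_count_range = c(5L, 5L),
                       blob_sigma_range = c(2, 2),
                       blob_amplitude_range = c(0.15, 0.15))
  set.seed(3)
  y5 <- corrupt_T2(matrix(0, 96, 96), p5)
  expect_equal(sum(y5), 5 * 0.15 * 2 * pi * 4, tolerance = 0.1)
})

test_that("cut-and-paste composition is exactly piecewise inside/outside R", {
  x <- matrix(runif(48 * 48), 48, 48) * 0.5 + 0.25
  p <- augment_params(swap_probability = 0)

  # identical stubbed branches: composition is the branch output
  set.seed(5)
  v_id <- augcut_view(x, p, t1_fun = function(x, p) x,
                      t2_fun = function(x, p) x)
  expect_identical(v_id$image, x)

  # distinct constant shifts: difference is +0.1 inside R, -0.1 outside
  set.seed(5)
  v <- augcut_view(x, p, t1_fun = function(x, p) x + 0.1,
                   t2_fun = function(x, p) x - 0.1)
  r <- v$rect
  inside <- matrix(FALSE, 48, 48)
  inside[(r[["row0"]] + 1):(r[["row0"]] + r[["height"]]),
         (r[["col0"]] + 1):(r[["col0"]] + r[["width"]])] <- TRUE
  expect_identical(v$image[inside], (x + 0.1)[inside])
  expect_identical(v$image[!inside], (x - 0.1)[!inside])
  expect_false(v$swapped)

  # swap exchanges which branch fills R
  ps <- augment_params(swap_probability = 1)
  set.seed(5)
  vs <- augcut_view(x, ps, t1_fun = function(x, p) x + 0.1,
                    t2_fun = function(x, p) x - 0.1)
  rs <- vs$rect
  ins <- matrix(FALSE, 48, 48)
  ins[(rs[["row0"]] + 1):(rs[["row0"]] + rs[["height"]]),
      (rs[["col0"]] + 1):(rs[["col0"]] + rs[["width"]])] <- TRUE
  expect_identical(vs$image[ins], (x - 0.1)[ins])
  expect_identical(vs$image[!ins], (x + 0.1)[!ins])
  expect_true(vs$swapped)
})

test_that("sampled rectangles are contained and sized by the area ratio", {
  p <- augment_params()
  set.seed(17)
  for (i in 1:200) {
    v <- augcut_view(matrix(0.5, 40, 56), p,
                     t1_fun = function(x, p) x, t2_fun = function(x, p) x)
    r <- v$rect
    expect_gte(r[["row0"]], 0)
    expect_gte(r[["col0"]], 0)
    expect_lte(r[["row0"]] + r[["height"]], 40)
    expect_lte(r[["col0"]] + r[["width"]], 56)
    expect_gte(r[["height"]], 1)
    expect_gte(r[["width"]], 1)
  }
})

test_that("branch swap frequency converges to the swap probability", {
  set.seed(23)
  x <- matrix(0.5, 16, 16)
  p <- identity_params()
  n <- 2000
  swaps <- vapply(seq_len(n), function(i) {
    augcut_view(x, p, t1_fun = function(x, p) x,
                t2_fun = function(x, p) x)$swapped
  }, NA)
  # 3-sigma binomial band around 0.5
  expect_lt(abs(mean(swaps) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("view pairs are seeded-deterministic, shaped, and bounded", {
  x <- generate_cell_image(synthetic_spec(image_size = 48, n_seeds = 8,
                                          rng_seed = 3))$image
  p <- augment_params()
  set.seed(41)
  vp1 <- make_view_pair(x, p)
  set.seed(41)
  vp2 <- make_view_pair(x, p)
  expect_identical(vp1, vp2)
  expect_identical(dim(vp1$x1), dim(x))
  expect_identical(dim(vp1$x2), dim(x))
  expect_false(identical(vp1$x1, vp1$x2))
  set.seed(43)
  for (i in 1:10) {
    vp <- make_view_pair(x, p)
    expect_true(all(vp$x1 >= 0 & vp$x1 <= 1))
    expect_true(all(vp$x2 >= 0 & vp$x2 <= 1))
  }
})

test_that("invalid augmentation ranges are rejected", {
  expect_error(augment_params(noise_sigma_range = c(0.2, 0.1)), "range")
  expect_error(augment_params(swap_probability = 1.5), "swap_probability")
  expect_error(augment_params(brightness_factor_range = c(0.5, 1.5)), "range")
})
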