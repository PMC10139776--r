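#' Parameters of the cut-and-paste augmentation family
#'
#' The augmentation family draws two corruption branches and mixes them inside
#' a random rectangle. Branch `T1` imitates damaged tissue regions with weak
#' or missing borders: brightness reduction, Gaussian blur, then additive
#' Gaussian noise. Branch `T2` imitates artifactually highlighted nuclei:
#' bright Gaussian-profile blobs at random locations. The composite view
#' equals `T1` inside the rectangle and `T2` outside (roles exchanged with
#' probability `swap_probability`).
#'
#' Every `*_range` is a length-2 `c(lower, upper)` interval sampled uniformly;
#' degenerate ranges (`lower == upper`) pin the value.
#'
#' @param noise_sigma_range Additive noise standard deviation, intensity units.
#' @param blur_sigma_range Gaussian blur sigma in pixels (0 disables blur).
#' @param brightness_factor_range Multiplicative brightness factor in `(0, 1]`.
#' @param blob_count_range Integer range of blob counts for `T2`.
#' @param blob_sigma_range Blob Gaussian sigma in pixels.
#' @param blob_amplitude_range Blob peak amplitude in intensity units.
#' @param rect_area_ratio_range Rectangle area as a fraction of the patch area.
#' @param rect_aspect_range Rectangle aspect ratio (height / width).
#' @param swap_probability Probability of exchanging the two branches.
#' @return An object of class `augment_params`.
#' @export
augment_params <- function(noise_sigma_range = c(0.02, 0.1),
                           blur_sigma_range = c(1, 3),
                           brightness_factor_range = c(0.3, 0.8),
                           blob_count_range = c(3L, 10L),
                           blob_sigma_range = c(1.5, 3),
                           blob_amplitude_range = c(0.3, 0.8),
                           rect_area_ratio_range = c(0.25, 0.75),
                           rect_aspect_range = c(0.5, 2),
                           swap_probability = 0.5) {
  chk <- function(r, nm, lo = -Inf, hi = Inf) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] ||
        r[1] < lo || r[2] > hi) {
      stop("`", nm, "` must be a valid c(lower, upper) range", call. = FALSE)
    }
    r
  }
  if (swap_probability < 0 || swap_probability > 1) {
    stop("`swap_probability` must lie in [0, 1]")
  }
  structure(
    list(noise_sigma_range = chk(noise_sigma_range, "noise_sigma_range", 0),
         blur_sigma_range = chk(blur_sigma_range, "blur_sigma_range", 0),
         brightness_factor_range =
           chk(brightness_factor_range, "brightness_factor_range", 0, 1),
         blob_count_range = as.integer(chk(blob_count_range,
                                           "blob_count_range", 0)),
         blob_sigma_range = chk(blob_sigma_range, "blob_sigma_range", 0),
         blob_amplitude_range = chk(blob_amplitude_range,
                                    "blob_amplitude_range", 0),
         rect_area_ratio_range = chk(rect_area_ratio_range,
                                     "rect_area_ratio_range", 0, 1),
         rect_aspect_range = chk(rect_aspect_range, "rect_aspect_range", 0),
         swap_probability = swap_probability),
    class = "augment_params"
  )
}

.runif_range <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])

.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Corruption branch T1: brightness reduction, blur, noise
#'
#' Applies, in order, multiplication by a brightness factor, Gaussian blur and
#' additive zero-mean Gaussian noise (each magnitude sampled uniformly from
#' its range in `params`), then clips to `[0, 1]`. Noise is added after the
#' blur so it is not smoothed away, matching the grainy appearance of damaged
#' tissue regions. Randomness comes from the current R random stream.
#'
#' @param x Image patch, numeric matrix in `[0, 1]`.
#' @param params An [augment_params()].
#' @return Corrupted patch, same dimensions, in `[0, 1]`.
#' @export
corrupt_T1 <- function(x, params = augment_params()) {
  stopifnot(is.matrix(x))
  f <- .runif_range(params$brightness_factor_range)
  y <- x * f
  s <- .runif_range(params$blur_sigma_range)
  if (s > 0) {
    # kernel must fit inside the patch; cap the radius for small patches
    r <- min(2L * ceiling(3 * s) + 1L, min(dim(x)) - 1L + min(dim(x)) %% 2L)
    if (r %% 2L == 0L) r <- r - 1L
    y <- EBImage::gblur(y, sigma = s, radius = r)
  }
  ns <- .runif_range(params$noise_sigma_range)
  if (ns > 0) y <- y + stats::rnorm(length(y), 0, ns)
  .clip01(matrix(y, nrow(x), ncol(x)))
}

#' Corruption branch T2: bright Gaussian blobs
#'
#' Adds `k` Gaussian-profile bright blobs (`k` uniform over
#' `blob_count_range`) at uniformly random continuous centers, each with its
#' own sigma and peak amplitude, then clips to `[0, 1]`.
#'
#' @inheritParams corrupt_T1
#' @return Corrupted patch, same dimensions, in `[0, 1]`.
#' @export
corrupt_T2 <- function(x, params = augment_params()) {
  stopifnot(is.matrix(x))
  H <- nrow(x); W <- ncol(x)
  kr <- params$blob_count_range
  k <- if (kr[1] == kr[2]) kr[1] else sample(kr[1]:kr[2], 1L)
  y <- x
  if (k > 0) {
    rr <- seq_len(H); cc <- seq_len(W)
    for (i in seq_len(k)) {
      cr <- stats::runif(1, 1, H)
      ccen <- stats::runif(1, 1, W)
      sig <- .runif_range(params$blob_sigma_range)
      amp <- .runif_range(params$blob_amplitude_range)
      y <- y + amp * exp(-(outer((rr - cr)^2, (cc - ccen)^2, "+")) / (2 * sig^2))
    }
  }
  .clip01(y)
}

# Rectangle with area ratio and aspect ratio uniform in their ranges, position
# uniform subject to containment. Returned 0-based, half-open:
# rows [row0, row0 + height), cols [col0, col0 + width).
.sample_rect <- function(H, W, params) {
  ratio <- .runif_range(params$rect_area_ratio_range)
  aspect <- .runif_range(params$rect_aspect_range)
  area <- ratio * H * W
  h <- max(1L, min(H, as.integer(round(sqrt(area * aspect)))))
  w <- max(1L, min(W, as.integer(round(sqrt(area / aspect)))))
  row0 <- sample.int(H - h + 1L, 1L) - 1L
  col0 <- sample.int(W - w + 1L, 1L) - 1L
  c(row0 = row0, col0 = col0, height = h, width = w)
}

.rect_mask <- function(H, W, rect) {
  m <- matrix(FALSE, H, W)
  m[(rect[["row0"]] + 1L):(rect[["row0"]] + rect[["height"]]),
    (rect[["col0"]] + 1L):(rect[["col0"]] + rect[["width"]])] <- TRUE
  m
}

#' Build one augmented view by rectangular cut-and-paste
#'
#' Samples a rectangle `R`, corrupts the patch with both branches, and
#' composes the view as the `T1` result inside `R` and the `T2` result
#' outside. With probability `swap_probability` the branch roles are
#' exchanged (recorded in the `swapped` flag).
#'
#' @inheritParams corrupt_T1
#' @param t1_fun,t2_fun Branch functions `(x, params) -> matrix`; the defaults
#'   are [corrupt_T1()] and [corrupt_T2()]. Replaceable for testing.
#' @return List with `image` (the composed view), `rect` (0-based half-open
#'   `row0, col0, height, width`), and `swapped` flag.
#' @export
augcut_view <- function(x, params = augment_params(),
                        t1_fun = corrupt_T1, t2_fun = corrupt_T2) {
  stopifnot(is.matrix(x))
  H <- nrow(x); W <- ncol(x)
  rect <- .sample_rect(H, W, params)
  swapped <- stats::runif(1) < params$swap_probability
  a <- t1_fun(x, params)
  b <- t2_fun(x, params)
  if (swapped) { tmp <- a; a <- b; b <- tmp }
  inside <- .rect_mask(H, W, rect)
  out <- b
  out[inside] <- a[inside]
  list(image = out, rect = rect, swapped = swapped)
}

#' Build a pair of augmented views of one patch
#'
#' Two independent draws of [augcut_view()] applied to the same input; all
#' randomness comes from the current R random stream, so seeding reproduces
#' the pair exactly.
#'
#' @inheritParams augcut_view
#' @return An object of class `view_pair`: list with `x1`, `x2`, `rect1`,
#'   `rect2`, `swapped1`, `swapped2`.
#' @export
make_view_pair <- function(x, params = augment_params(),
                           t1_fun = corrupt_T1, t2_fun = corrupt_T2) {
  v1 <- augcut_view(x, params, t1_fun, t2_fun)
  v2 <- augcut_view(x, params, t1_fun, t2_fun)
  structure(list(x1 = v1$image, x2 = v2$image,
                 rect1 = v1$rect, rect2 = v2$rect,
                 swapped1 = v1$swapped, swapped2 = v2$swapped),
            class = "view_pair")
}
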