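#' Parameters of the morphological binarization pipeline
#'
#' Controls the transform `m` that converts a grayscale decoder output into a
#' binary closed-border map: adaptive mean thresholding, hole filling,
#' 3x3 opening, inversion and small-region removal.
#'
#' @param adaptive_block_size Odd window side (pixels) of the local-mean
#'   threshold (default 15).
#' @param adaptive_offset Intensity offset added to the local mean
#'   (default 0.02); a pixel is bright-foreground iff it exceeds
#'   `local mean + offset`.
#' @param opening_size Structuring-element side of the opening; the reference
#'   pipeline fixes this at 3.
#' @param min_region_area Connected components with area strictly below this
#'   many pixels are removed in the final cleanup (reference value 10, i.e.
#'   area-10 components survive).
#' @param connectivity Pixel connectivity for component labeling, 4 or 8
#'   (default 8).
#' @return An object of class `morph_params`.
#' @export
morph_params <- function(adaptive_block_size = 15L,
                         adaptive_offset = 0.02,
                         opening_size = 3L,
                         min_region_area = 10L,
                         connectivity = 8L) {
  adaptive_block_size <- as.integer(adaptive_block_size)
  if (adaptive_block_size < 3L || adaptive_block_size %% 2L == 0L) {
    stop("`adaptive_block_size` must be odd and >= 3")
  }
  if (min_region_area < 1L) stop("`min_region_area` must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  if (opening_size < 1L || opening_size %% 2L == 0L) {
    stop("`opening_size` must be odd and >= 1")
  }
  structure(
    list(adaptive_block_size = adaptive_block_size,
         adaptive_offset = adaptive_offset,
         opening_size = as.integer(opening_size),
         min_region_area = as.integer(min_region_area),
         connectivity = as.integer(connectivity)),
    class = "morph_params"
  )
}

.as_binary <- function(b) {
  stopifnot(is.matrix(b))
  matrix(as.integer(b > 0.5), nrow(b), ncol(b))
}

# Local mean over the intersection of the centered b x b window with the
# image, via a summed-area table (exact, no padding bias at the edges).
.local_mean <- function(x, b) {
  H <- nrow(x); W <- ncol(x)
  r <- (b - 1L) %/% 2L
  ii <- matrix(0, H + 1L, W + 1L)
  ii[-1L, -1L] <- x
  ii <- apply(ii, 2L, cumsum)
  ii <- t(apply(ii, 1L, cumsum))
  r1 <- pmax(seq_len(H) - r, 1L); r2 <- pmin(seq_len(H) + r, H)
  c1 <- pmax(seq_len(W) - r, 1L); c2 <- pmin(seq_len(W) + r, W)
  sums <- ii[r2 + 1L, c2 + 1L] - ii[r1, c2 + 1L] -
    ii[r2 + 1L, c1] + ii[r1, c1]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

#' Adaptive mean thresholding
#'
#' Binarizes a grayscale patch by comparing each pixel to the mean of its
#' local `adaptive_block_size` window: foreground iff
#' `value > local mean + adaptive_offset`. Foreground marks bright structures
#' (the cell borders). Windows are cropped at the image edge.
#'
#' @param z Grayscale patch, numeric matrix in `[0, 1]`.
#' @param params A [morph_params()].
#' @return Binary 0/1 integer matrix.
#' @export
adaptive_threshold <- function(z, params = morph_params()) {
  stopifnot(is.matrix(z))
  mu <- .local_mean(z, params$adaptive_block_size)
  matrix(as.integer(z > mu + params$adaptive_offset), nrow(z), ncol(z))
}

#' Fill regions enclosed by external contours
#'
#' Every background region fully enclosed by a foreground contour (a hole)
#' becomes foreground; background connected to the image border is preserved.
#' Never decreases the foreground pixel count.
#'
#' @param b Binary mask (0/1 matrix).
#' @return Binary 0/1 integer matrix with holes filled.
#' @export
fill_external_contours <- function(b) {
  b <- .as_binary(b)
  .as_binary(EBImage::fillHull(b))
}

#' Morphological opening
#'
#' Erosion followed by dilation with a square `opening_size` box element
#' (3x3 in the reference pipeline). Removes foreground structures thinner
#' than the element -- in the border pipeline this severs one-pixel leaks
#' between cell-interior blobs, which closes gaps in the complementary border
#' network.
#'
#' @param b Binary mask (0/1 matrix).
#' @param params A [morph_params()].
#' @return Binary 0/1 integer matrix.
#' @export
mask_opening <- function(b, params = morph_params()) {
  b <- .as_binary(b)
  kern <- EBImage::makeBrush(params$opening_size, shape = "box")
  .as_binary(EBImage::opening(b, kern))
}

#' Invert a binary mask
#'
#' Exchanges foreground and background.
#'
#' @param b Binary mask (0/1 matrix).
#' @return Binary 0/1 integer matrix.
#' @export
invert_mask <- function(b) {
  b <- .as_binary(b)
  1L - b
}

#' Label connected components
#'
#' Labels foreground components under 4- or 8-connectivity. (The 8-connected
#' variant is the default throughout the pipeline.)
#'
#' @param b Binary mask (0/1 matrix).
#' @param connectivity 4 or 8.
#' @return Integer matrix: 0 for background, `1..n` component labels.
#' @export
label_components <- function(b, connectivity = 8L) {
  b <- .as_binary(b)
  H <- nrow(b); W <- ncol(b)
  idx <- which(b > 0L)
  lab <- matrix(0L, H, W)
  if (length(idx) == 0L) return(lab)
  vid <- integer(H * W)
  vid[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  r <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  edges <- lapply(offs, function(o) {
    ok <- r + o[1] >= 1L & r + o[1] <= H & cc + o[2] <= W
    ni <- idx[ok] + o[1] + o[2] * H
    keep <- vid[ni] > 0L
    cbind(vid[idx[ok]][keep], vid[ni][keep])
  })
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

#' Remove small connected components
#'
#' Foreground components with area strictly below `min_region_area` pixels
#' are set to background; components at or above the threshold are kept
#' unchanged. Never increases the foreground pixel count.
#'
#' @param b Binary mask (0/1 matrix).
#' @param params A [morph_params()].
#' @return Binary 0/1 integer matrix.
#' @export
remove_small_regions <- function(b, params = morph_params()) {
  b <- .as_binary(b)
  lab <- label_components(b, params$connectivity)
  n <- max(lab)
  if (n == 0L) return(b)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  small <- which(areas < params$min_region_area)
  if (length(small)) b[lab %in% small] <- 0L
  b
}

#' Morphological transformation to a binary border map
#'
#' The full transform `m` converting a grayscale decoder output `z` into a
#' binary map `w` whose foreground is the closed cell-border network:
#'
#' 1. [adaptive_threshold()] marks bright border pixels;
#' 2. the complement gives candidate cell-interior blobs;
#' 3. [fill_external_contours()] makes each blob solid (removes holes left by
#'    bright nucleus artifacts and threshold speckle);
#' 4. [mask_opening()] severs thin leaks connecting neighboring blobs through
#'    broken borders -- equivalently, it closes the gaps in the border
#'    network;
#' 5. the complement of the opened blobs is the border network;
#' 6. [remove_small_regions()] deletes foreground speckle below
#'    `min_region_area` pixels.
#'
#' @param z Grayscale patch, numeric matrix in `[0, 1]`.
#' @param params A [morph_params()].
#' @param stages If `TRUE`, also return the intermediate masks of each stage.
#' @return Binary 0/1 integer matrix (list of stages if `stages = TRUE`).
#' @export
morph_transform <- function(z, params = morph_params(), stages = FALSE) {
  stopifnot(is.matrix(z))
  borders <- adaptive_threshold(z, params)
  cells <- invert_mask(borders)
  filled <- fill_external_contours(cells)
  opened <- mask_opening(filled, params)
  network <- invert_mask(opened)
  w <- remove_small_regions(network, params)
  if (stages) {
    return(list(threshold = borders, cells = cells, filled = filled,
                opened = opened, inverted = network, cleaned = w))
  }
  w
}
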