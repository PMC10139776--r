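#' Read a grayscale image, normalized to [0, 1]
#'
#' Reads 8- or 16-bit grayscale PNG or TIFF; multi-channel images are reduced
#' to their first channel. Values are returned on the `[0, 1]` scale.
#'
#' @param path Image file (`.png`, `.tif`, `.tiff`).
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask Binary 0/1 matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(.as_binary(mask) + 0, path)
  invisible(path)
}

#' Segment a whole image by tiled inference
#'
#' Tiles the image into non-overlapping `patch_size` squares, forwards each
#' tile through the trained encoder--decoder (no augmentation at inference),
#' binarizes every reconstructed tile with [morph_transform()], and stitches
#' the tile masks back at their recorded origins. Remainder margins narrower
#' than a tile are left as background. With `overlap_stride` smaller than
#' `patch_size`, overlapping tiles are averaged in the grayscale
#' reconstruction before a single whole-image morphological transform, which
#' trades the no-cross-tile-interaction guarantee for fewer seam artifacts.
#'
#' @param image Numeric matrix in `[0, 1]`, at least `patch_size` in both
#'   dimensions.
#' @param net A trained `seg_network` (or a checkpoint path).
#' @param morph_par A [morph_params()].
#' @param patch_size Tile side (default 96); must be divisible by 8.
#' @param overlap_stride Optional stride `< patch_size` enabling the
#'   overlapping mode (default `NULL`: non-overlapping tiles).
#' @return Binary 0/1 integer matrix with the dimensions of `image`.
#' @export
segment_image <- function(image, net, morph_par = morph_params(),
                          patch_size = 96L, overlap_stride = NULL) {
  if (is.character(net)) net <- load_checkpoint(net)
  stopifnot(inherits(net, "seg_network"), is.matrix(image))
  patch_size <- as.integer(patch_size)
  if (patch_size %% 8L != 0L) stop("`patch_size` must be divisible by 8")
  d <- dim(image)
  if (d[1] < patch_size || d[2] < patch_size) {
    stop("image (", d[1], "x", d[2], ") is smaller than patch_size (",
         patch_size, ")", call. = FALSE)
  }
  if (is.null(overlap_stride)) {
    tl <- tile_image(image, patch_size)
    out <- matrix(0L, d[1], d[2])
    for (i in seq_along(tl$patches)) {
      z <- decode(net, encode(net, tl$patches[[i]]))
      w <- morph_transform(z, morph_par)
      r0 <- tl$origins$row0[i]
      c0 <- tl$origins$col0[i]
      out[(r0 + 1L):(r0 + patch_size), (c0 + 1L):(c0 + patch_size)] <- w
    }
    return(out)
  }
  stride <- as.integer(overlap_stride)
  if (stride < 1L || stride >= patch_size) {
    stop("`overlap_stride` must lie in [1, patch_size)")
  }
  starts <- function(total) {
    s <- seq(0L, total - patch_size, by = stride)
    if (s[length(s)] != total - patch_size) s <- c(s, total - patch_size)
    s
  }
  accum <- matrix(0, d[1], d[2])
  count <- matrix(0, d[1], d[2])
  for (r0 in starts(d[1])) {
    for (c0 in starts(d[2])) {
      tile <- image[(r0 + 1L):(r0 + patch_size), (c0 + 1L):(c0 + patch_size)]
      z <- decode(net, encode(net, tile))
      accum[(r0 + 1L):(r0 + patch_size), (c0 + 1L):(c0 + patch_size)] <-
        accum[(r0 + 1L):(r0 + patch_size), (c0 + 1L):(c0 + patch_size)] + z
      count[(r0 + 1L):(r0 + patch_size), (c0 + 1L):(c0 + patch_size)] <-
        count[(r0 + 1L):(r0 + patch_size), (c0 + 1L):(c0 + patch_size)] + 1
    }
  }
  morph_transform(accum / pmax(count, 1), morph_par)
}
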