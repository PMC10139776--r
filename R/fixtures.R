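#' Specification of a synthetic flatmount-like patch
#'
#' Parameters of the Voronoi-tessellation generator used to emulate a
#' fluorescently labeled cell monolayer: bright closed cell borders around
#' darker polygonal interiors, with additive Gaussian noise. Ground-truth
#' border masks accompany every generated patch, so the whole pipeline can be
#' evaluated without any real microscopy data.
#'
#' @param image_size Patch side length in pixels (square patch, >= 32).
#' @param n_seeds Number of tessellation sites ("cells"), >= 2.
#' @param border_width Border thickness in pixels (>= 1).
#' @param border_intensity Intensity of border pixels in `[0, 1]`.
#' @param interior_intensity Intensity of cell interiors, strictly less than
#'   `border_intensity`.
#' @param noise_sigma Standard deviation of additive Gaussian intensity noise
#'   applied to the image (never to the mask).
#' @param rng_seed Integer seed making generation fully deterministic.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = 96L,
                           n_seeds = 20L,
                           border_width = 2,
                           border_intensity = 0.85,
                           interior_intensity = 0.15,
                           noise_sigma = 0.03,
                           rng_seed = 1L) {
  image_size <- as.integer(image_size)
  n_seeds <- as.integer(n_seeds)
  if (is.na(image_size) || image_size < 32L) {
    stop("`image_size` must be an integer >= 32")
  }
  if (is.na(n_seeds) || n_seeds < 2L) stop("`n_seeds` must be >= 2")
  if (border_width < 1) stop("`border_width` must be >= 1")
  if (border_intensity <= interior_intensity) {
    stop("`border_intensity` must exceed `interior_intensity`")
  }
  if (border_intensity > 1 || interior_intensity < 0) {
    stop("intensities must lie in [0, 1]")
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  structure(
    list(image_size = image_size, n_seeds = n_seeds,
         border_width = border_width, border_intensity = border_intensity,
         interior_intensity = interior_intensity, noise_sigma = noise_sigma,
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_spec"
  )
}

# Sites drawn uniformly with a minimum-distance rejection rule so no two cells
# collapse into a sliver; min distance = image_size / (2 sqrt(n_seeds)).
.sample_sites <- function(S, n) {
  dmin <- S / (2 * sqrt(n))
  for (restart in 1:100) {
    pts <- matrix(NA_real_, n, 2)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:200) {
        cand <- stats::runif(2, 1, S)
        if (i == 1L ||
            min(sqrt(colSums((t(pts[seq_len(i - 1L), , drop = FALSE]) - cand)^2))) >= dmin) {
          pts[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pts)
  }
  stop("could not place ", n, " sites at minimum distance ", signif(dmin, 3),
       " in a ", S, "x", S, " patch")
}

#' Generate a synthetic cell-border patch with ground truth
#'
#' Draws `n_seeds` tessellation sites (uniform, with a minimum-distance
#' rejection rule), labels every pixel by its nearest site, and rasterizes the
#' borders as the band of pixels within `border_width / 2` of a Voronoi edge,
#' i.e. pixels where `(d2 - d1) / 2 <= border_width / 2` for the distances
#' `d1 <= d2` to the two nearest sites. The image is
#' `interior_intensity` inside cells and `border_intensity` on the border,
#' plus additive Gaussian noise (clipped to `[0, 1]`); the returned mask is the
#' exact noise-free border band.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `labeled_patch`: list with `image` (matrix in
#'   `[0, 1]`), `border_mask` (0/1 integer matrix), `sites` (n x 2 matrix of
#'   site coordinates, row/col), and `spec`.
#' @export
generate_cell_image <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("`spec` must be a synthetic_spec")
  withr::with_seed(spec$rng_seed, {
    S <- spec$image_size
    sites <- .sample_sites(S, spec$n_seeds)
    px <- cbind(rep(seq_len(S), S), rep(seq_len(S), each = S))
    d2 <- outer(px[, 1], sites[, 1], "-")^2 + outer(px[, 2], sites[, 2], "-")^2
    # two smallest distances per pixel
    ord <- apply(d2, 1, function(r) sqrt(sort.int(r, partial = 1:2)[1:2]))
    edge_dist <- (ord[2, ] - ord[1, ]) / 2
    mask <- matrix(as.integer(edge_dist <= spec$border_width / 2), S, S)
    img <- spec$interior_intensity +
      (spec$border_intensity - spec$interior_intensity) * mask
    if (spec$noise_sigma > 0) {
      img <- img + stats::rnorm(S * S, 0, spec$noise_sigma)
      img <- pmin(pmax(img, 0), 1)
    }
    structure(list(image = matrix(img, S, S), border_mask = mask,
                   sites = sites, spec = spec),
              class = "labeled_patch")
  })
}

#' Generate a deterministic set of labeled patches
#'
#' Convenience wrapper producing `n` patches from consecutive seeds
#' `base_seed, base_seed + 1, ...` with otherwise identical parameters.
#'
#' @param n Number of patches.
#' @param spec Template [synthetic_spec()]; its `rng_seed` is ignored.
#' @param base_seed First seed.
#' @return List of `labeled_patch` objects.
#' @export
generate_dataset <- function(n, spec = synthetic_spec(), base_seed = 1L) {
  lapply(seq_len(n), function(i) {
    sp <- spec
    sp$rng_seed <- as.integer(base_seed + i - 1L)
    generate_cell_image(sp)
  })
}

#' Tile an image into non-overlapping square patches
#'
#' Cuts row-major, non-overlapping `patch_size x patch_size` tiles starting at
#' the top-left corner; a trailing remainder smaller than `patch_size` in
#' either dimension is dropped. Tile origins (0-based, top-left) are recorded
#' so segmented tiles can be stitched back.
#'
#' @param image Numeric matrix at least `patch_size` in both dimensions.
#' @param patch_size Tile side length in pixels.
#' @return An object of class `patch_tiles`: list with `patches` (list of
#'   matrices), `origins` (data.frame of 0-based `row0`, `col0`),
#'   `patch_size`, and `image_dim`.
#' @export
tile_image <- function(image, patch_size = 96L) {
  stopifnot(is.matrix(image))
  patch_size <- as.integer(patch_size)
  d <- dim(image)
  if (d[1] < patch_size || d[2] < patch_size) {
    stop("image (", d[1], "x", d[2], ") is smaller than patch_size (",
         patch_size, ")", call. = FALSE)
  }
  nr <- d[1] %/% patch_size
  nc <- d[2] %/% patch_size
  origins <- expand.grid(col0 = (seq_len(nc) - 1L) * patch_size,
                         row0 = (seq_len(nr) - 1L) * patch_size)
  origins <- origins[, c("row0", "col0")]  # row-major order
  patches <- lapply(seq_len(nrow(origins)), function(i) {
    r0 <- origins$row0[i]
    c0 <- origins$col0[i]
    image[(r0 + 1L):(r0 + patch_size), (c0 + 1L):(c0 + patch_size)]
  })
  structure(list(patches = patches, origins = origins,
                 patch_size = patch_size, image_dim = d),
            class = "patch_tiles")
}

#' Write a labeled patch (and optional dataset manifest) to PNG
#'
#' Writes 8-bit grayscale PNGs for the image and its mask. `save_dataset()`
#' writes a whole list of patches plus a CSV manifest recording the file
#' paths, seeds and generator parameters.
#'
#' @param patch A `labeled_patch`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, the written image path(s).
#' @export
write_labeled_patch <- function(patch, dir, prefix = "patch") {
  stopifnot(inherits(patch, "labeled_patch"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(prefix, ".png"))
  mask_path <- file.path(dir, paste0(prefix, "_mask.png"))
  png::writePNG(pmin(pmax(patch$image, 0), 1), img_path)
  png::writePNG(patch$border_mask + 0, mask_path)
  invisible(c(image = img_path, mask = mask_path))
}

#' @rdname write_labeled_patch
#' @param patches List of `labeled_patch` objects.
#' @export
save_dataset <- function(patches, dir, prefix = "patch") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    paths <- write_labeled_patch(p, dir, sprintf("%s_%04d", prefix, i))
    data.frame(path = paths[["image"]], mask = paths[["mask"]],
               seed = p$spec$rng_seed, image_size = p$spec$image_size,
               n_seeds = p$spec$n_seeds, border_width = p$spec$border_width,
               border_intensity = p$spec$border_intensity,
               interior_intensity = p$spec$interior_intensity,
               noise_sigma = p$spec$noise_sigma)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
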