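#' Network architecture configuration
#'
#' Describes the convolutional encoder--decoder and the two MLP heads used for
#' self-supervised training. The encoder has an input convolution at full
#' resolution followed by three stride-2 downsampling convolutions (so the
#' bottleneck feature map is at 1/8 of the input resolution) and a stack of
#' residual blocks at the lowest level. The decoder mirrors it with three
#' stride-1/2 transposed convolutions and a sigmoid output layer. The
#' projection head `g` (two hidden layers) and prediction head `h` (one hidden
#' layer) map globally pooled bottleneck features to representation vectors.
#'
#' @param channels_per_level Integer vector of exactly four filter counts, from
#'   full resolution down to the 1/8-resolution bottleneck. Default
#'   `c(64, 128, 256, 512)`.
#' @param n_residual_blocks Number of residual blocks at the bottleneck
#'   (default 6).
#' @param head_hidden_width Width of the hidden layers in both MLP heads
#'   (default 512).
#' @param representation_dim Length of the projection/prediction vectors
#'   (default 2048).
#' @param input_channels Number of image channels (default 1, grayscale).
#' @return An object of class `network_config`.
#' @export
network_config <- function(channels_per_level = c(64L, 128L, 256L, 512L),
                           n_residual_blocks = 6L,
                           head_hidden_width = 512L,
                           representation_dim = 2048L,
                           input_channels = 1L) {
  channels_per_level <- as.integer(channels_per_level)
  if (length(channels_per_level) != 4L || any(channels_per_level < 1L)) {
    stop("`channels_per_level` must be four positive filter counts")
  }
  if (representation_dim < 1L) stop("`representation_dim` must be positive")
  if (n_residual_blocks < 0L) stop("`n_residual_blocks` must be >= 0")
  structure(
    list(channels_per_level = channels_per_level,
         n_residual_blocks = as.integer(n_residual_blocks),
         head_hidden_width = as.integer(head_hidden_width),
         representation_dim = as.integer(representation_dim),
         input_channels = as.integer(input_channels)),
    class = "network_config"
  )
}

#' Build a randomly initialized network
#'
#' Instantiates the encoder `f`, decoder `d`, projection head `g` and
#' prediction head `h` described by a [network_config()]. Weights use He
#' initialization from the current R random stream, so `set.seed()` before
#' calling makes construction reproducible.
#'
#' @param cfg A [network_config()].
#' @return An object of class `seg_network`: a list with elements `enc`, `dec`,
#'   `g`, `h` (layer stacks), `cfg`, and `layers` (flat list of all
#'   parameterized layers, used by the optimizer).
#' @export
build_network <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  ch <- cfg$channels_per_level
  enc <- list(
    layer_conv(cfg$input_channels, ch[1]), layer_cnorm(ch[1]), layer_relu(),
    layer_conv(ch[1], ch[2], stride = 2L), layer_cnorm(ch[2]), layer_relu(),
    layer_conv(ch[2], ch[3], stride = 2L), layer_cnorm(ch[3]), layer_relu(),
    layer_conv(ch[3], ch[4], stride = 2L), layer_cnorm(ch[4]), layer_relu()
  )
  for (i in seq_len(cfg$n_residual_blocks)) enc <- c(enc, list(layer_res(ch[4])))
  dec <- list(
    layer_convt2(ch[4], ch[3]), layer_cnorm(ch[3]), layer_relu(),
    layer_convt2(ch[3], ch[2]), layer_cnorm(ch[2]), layer_relu(),
    layer_convt2(ch[2], ch[1]), layer_cnorm(ch[1]), layer_relu(),
    layer_conv(ch[1], cfg$input_channels), layer_sigmoid()
  )
  g <- list(
    layer_gap(),
    layer_dense(ch[4], cfg$head_hidden_width), layer_relu(),
    layer_dense(cfg$head_hidden_width, cfg$head_hidden_width), layer_relu(),
    layer_dense(cfg$head_hidden_width, cfg$representation_dim)
  )
  h <- list(
    layer_dense(cfg$representation_dim, cfg$head_hidden_width), layer_relu(),
    layer_dense(cfg$head_hidden_width, cfg$representation_dim)
  )
  net <- list(enc = enc, dec = dec, g = g, h = h, cfg = cfg)
  net$layers <- .flatten_layers(c(enc, dec, g, h))
  class(net) <- "seg_network"
  net
}

#' @export
print.seg_network <- function(x, ...) {
  cat("<seg_network> channels", paste(x$cfg$channels_per_level, collapse = "-"),
      "|", x$cfg$n_residual_blocks, "residual blocks | representation dim",
      x$cfg$representation_dim, "|", format(n_parameters(x$layers), big.mark = ","),
      "parameters\n")
  invisible(x)
}

.as_patch_array <- function(x, channels = 1L) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (length(d) != 3L || d[3] != channels) {
    stop("expected a single-channel image patch")
  }
  x
}

.check_divisible <- function(x) {
  d <- dim(x)
  if (d[1] %% 8L != 0L || d[2] %% 8L != 0L) {
    stop("patch dimensions must be divisible by 8, got ",
         d[1], "x", d[2], call. = FALSE)
  }
  invisible(NULL)
}

#' Encode a patch into bottleneck features
#'
#' Runs the encoder `f`: full-resolution input convolution, three stride-2
#' downsampling blocks and the residual stack, producing a feature map at 1/8
#' of the input resolution with the deepest channel count.
#'
#' @param net A `seg_network` from [build_network()].
#' @param x Image patch: numeric matrix (or `H x W x 1` array) in `[0, 1]`,
#'   both dimensions divisible by 8.
#' @return Feature map array of dim `c(H/8, W/8, channels_per_level[4])`.
#' @export
encode <- function(net, x) {
  x <- .as_patch_array(x, net$cfg$input_channels)
  .check_divisible(x)
  chain_forward(net$enc, x)$out
}

#' Decode bottleneck features into a reconstruction
#'
#' Runs the decoder `d`: three stride-1/2 transposed-convolution upsampling
#' blocks and a sigmoid output layer, restoring the full input resolution with
#' values in `[0, 1]`.
#'
#' @param net A `seg_network`.
#' @param y Feature map as returned by [encode()].
#' @return Numeric matrix in `[0, 1]` at 8 times the spatial size of `y`.
#' @export
decode <- function(net, y) {
  d <- dim(y)
  if (length(d) != 3L || d[3] != net$cfg$channels_per_level[4]) {
    stop("feature map channel count does not match the network bottleneck")
  }
  out <- chain_forward(net$dec, y)$out
  matrix(out, dim(out)[1], dim(out)[2])
}

#' Project bottleneck features to a representation vector
#'
#' Global average pooling over the feature map followed by the two-hidden-layer
#' MLP projection head `g`.
#'
#' @param net A `seg_network`.
#' @param y Feature map as returned by [encode()].
#' @return Numeric vector of length `representation_dim`.
#' @export
project <- function(net, y) {
  d <- dim(y)
  if (length(d) != 3L || d[3] != net$cfg$channels_per_level[4]) {
    stop("feature map channel count does not match the network bottleneck")
  }
  chain_forward(net$g, y)$out
}

#' Map a projection vector through the prediction head
#'
#' The one-hidden-layer MLP `h` used on one branch of the Siamese pair so that
#' `h(p)` of one view can be matched against the stop-gradient projection of
#' the other view.
#'
#' @param net A `seg_network`.
#' @param p Numeric vector of length `representation_dim`.
#' @return Numeric vector of the same length.
#' @export
predict_latent <- function(net, p) {
  if (length(p) != net$cfg$representation_dim) {
    stop("expected a vector of length ", net$cfg$representation_dim,
         ", got ", length(p))
  }
  chain_forward(net$h, p)$out
}

# -- checkpoints --------------------------------------------------------------

.get_weights <- function(net) {
  lapply(net$layers, function(l) l$par)
}

.set_weights <- function(net, weights) {
  stopifnot(length(weights) == length(net$layers))
  for (i in seq_along(weights)) {
    stopifnot(identical(names(weights[[i]]), names(net$layers[[i]]$par)))
    net$layers[[i]]$par <- weights[[i]]
  }
  invisible(net)
}

#' Save / load a network checkpoint
#'
#' A checkpoint stores the layer weights, the [network_config()] and the
#' training epoch, and can be reloaded into a freshly built network.
#'
#' @param net A `seg_network`.
#' @param path File path for the checkpoint.
#' @param epoch Training epoch to record (default `NA`).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns a `seg_network` with the stored weights and an `epoch` attribute.
#' @export
save_checkpoint <- function(net, path, epoch = NA_integer_) {
  saveRDS(list(cfg = net$cfg, weights = .get_weights(net), epoch = epoch),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$cfg) || is.null(ck$weights)) {
    stop("not a valid checkpoint file: ", path)
  }
  net <- build_network(ck$cfg)
  .set_weights(net, ck$weights)
  attr(net, "epoch") <- ck$epoch
  net
}
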