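#' Training configuration
#'
#' Hyperparameters of the self-supervised training loop. The dynamic weight
#' schedules default to the reference two-stage settings (see
#' [default_schedules()]): a pretraining stage driven by the pairwise and
#' input-reconstruction terms, then a transition over epochs 40--70 that
#' activates the morphology term and relaxes the input-reconstruction blend.
#'
#' @param epochs Number of training epochs (default 110, covering the longest
#'   transition schedule studied).
#' @param batch_size Patches per optimizer step (default 16).
#' @param learning_rate Adam step size (default 1e-4).
#' @param optimizer_name `"adam"` or `"sgd"`.
#' @param rng_seed Integer seed; fixes view sampling, shuffling and weight
#'   initialization, making training fully reproducible on CPU.
#' @param schedules Named list of [schedule_config()]s for `lambda1`,
#'   `lambda2`, `lambda3`.
#' @param checkpoint_every Write a checkpoint every this many epochs when an
#'   output directory is given (0 = final checkpoint only).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 110L,
                         batch_size = 16L,
                         learning_rate = 1e-4,
                         optimizer_name = c("adam", "sgd"),
                         rng_seed = 1L,
                         schedules = default_schedules(),
                         checkpoint_every = 0L) {
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  if (epochs < 1L) stop("`epochs` must be >= 1")
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  optimizer_name <- match.arg(optimizer_name)
  stopifnot(all(c("lambda1", "lambda2", "lambda3") %in% names(schedules)))
  structure(
    list(epochs = epochs, batch_size = batch_size,
         learning_rate = learning_rate, optimizer_name = optimizer_name,
         rng_seed = as.integer(rng_seed), schedules = schedules,
         checkpoint_every = as.integer(checkpoint_every)),
    class = "train_config"
  )
}

# Full forward pass of one view: encoder features, decoder output, projection
# and prediction vectors, with all caches needed for backprop.
.forward_view <- function(net, x) {
  xa <- .as_patch_array(x, net$cfg$input_channels)
  fe <- chain_forward(net$enc, xa)
  fd <- chain_forward(net$dec, fe$out)
  fg <- chain_forward(net$g, fe$out)
  fh <- chain_forward(net$h, fg$out)
  list(y = fe$out, z = matrix(fd$out, dim(fd$out)[1], dim(fd$out)[2]),
       p = fg$out, q = fh$out,
       ce = fe$caches, cd = fd$caches, cg = fg$caches, ch = fh$caches)
}

# Backward pass of one view given the loss gradients at z (decoder output)
# and q (prediction vector). The stop-gradient contract is enforced by
# construction: the projection p of this view receives gradient only through
# its own prediction head, never as the constant second argument of the
# cosine terms, and the morphology target w is never differentiated.
.backward_view <- function(net, fw, dz, dq) {
  d <- dim(fw$y)
  dza <- array(dz, c(nrow(dz), ncol(dz), net$cfg$input_channels))
  dp <- chain_backward(net$h, fw$ch, dq)
  dy <- chain_backward(net$dec, fw$cd, dza) +
    chain_backward(net$g, fw$cg, dp)
  chain_backward(net$enc, fw$ce, dy)
  invisible(NULL)
}

# One training step on a single patch: build the view pair, run both Siamese
# passes, compute the loss breakdown at the current epoch's weights, and
# accumulate parameter gradients. Returns the loss_breakdown.
.train_step <- function(net, x, epoch, schedules, aug_params, morph_par) {
  vp <- make_view_pair(x, aug_params)
  f1 <- .forward_view(net, vp$x1)
  f2 <- .forward_view(net, vp$x2)
  w1 <- morph_transform(f1$z, morph_par)
  w2 <- morph_transform(f2$z, morph_par)

  L_PR <- pairwise_loss(f1$q, f2$p, f2$q, f1$p)
  rec <- reconstruction_loss(x, f1$z, f2$z,
                             schedule_factor(epoch, schedules$lambda1))
  L_Mor <- morphology_loss(f1$z, f2$z, w1, w2)
  bd <- total_loss(L_PR, rec$L_Rec_i, rec$L_Rec_o, L_Mor, epoch, schedules)

  n <- length(x)
  l1 <- bd$lambda1; l2 <- bd$lambda2; l3 <- bd$lambda3
  dz1 <- (l2 * l1 * 0.5 * sign(f1$z - x) +
          l2 * (1 - l1) * sign(f1$z - f2$z) +
          l3 * 0.5 * sign(f1$z - w1)) / n
  dz2 <- (l2 * l1 * 0.5 * sign(f2$z - x) -
          l2 * (1 - l1) * sign(f1$z - f2$z) +
          l3 * 0.5 * sign(f2$z - w2)) / n
  dq1 <- -0.5 * .cosine_grad_q(f1$q, f2$p)
  dq2 <- -0.5 * .cosine_grad_q(f2$q, f1$p)
  .backward_view(net, f1, dz1, dq1)
  .backward_view(net, f2, dz2, dq2)
  bd
}

#' Train the segmentation network without labels
#'
#' Runs the self-supervised loop: for every patch, two corrupted views are
#' drawn with [make_view_pair()], passed through the shared encoder, decoder
#' and MLP heads, and the total loss (pairwise + reconstruction + morphology,
#' at the current epoch's dynamic weights) is minimized. The reconstruction
#' target is the clean pre-augmentation patch, so the encoder--decoder learns
#' to denoise; morphology targets are recomputed from the current decoder
#' outputs each step and treated as constants.
#'
#' @param patches List of clean training patches: numeric matrices in
#'   `[0, 1]`, dimensions divisible by 8. `labeled_patch` objects are
#'   accepted (their `$image` is used).
#' @param net_cfg A [network_config()].
#' @param cfg A [train_config()].
#' @param aug_params An [augment_params()].
#' @param morph_par A [morph_params()].
#' @param net Optional pre-built `seg_network` to continue training.
#' @param out_dir Optional run directory; receives `losses.csv`, a resolved
#'   config snapshot (`config.yaml`) and checkpoint files.
#' @param verbose Print per-epoch losses.
#' @return An object of class `selfseg_fit`: list with `net`, `log` (one row
#'   per epoch with all loss components and weight factors), `net_cfg`, `cfg`.
#' @export
train_network <- function(patches,
                          net_cfg = network_config(),
                          cfg = train_config(),
                          aug_params = augment_params(),
                          morph_par = morph_params(),
                          net = NULL,
                          out_dir = NULL,
                          verbose = FALSE) {
  patches <- lapply(patches, function(p) {
    if (inherits(p, "labeled_patch")) p$image else p
  })
  if (!length(patches)) stop("empty training dataset")
  for (p in patches) {
    stopifnot(is.matrix(p))
    .check_divisible(array(p, c(dim(p), 1L)))
  }
  withr::with_seed(cfg$rng_seed, {
    if (is.null(net)) net <- build_network(net_cfg)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      yaml::write_yaml(list(train = unclass(cfg)[c("epochs", "batch_size",
                                                   "learning_rate",
                                                   "optimizer_name",
                                                   "rng_seed")],
                            schedules = lapply(cfg$schedules, unclass),
                            network = unclass(net$cfg)),
                       file.path(out_dir, "config.yaml"))
    }
    n <- length(patches)
    log_rows <- vector("list", cfg$epochs)
    step_t <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batch_starts <- seq(1L, n, by = cfg$batch_size)
      acc <- NULL
      for (bs in batch_starts) {
        ids <- ord[bs:min(bs + cfg$batch_size - 1L, n)]
        zero_grads(net$layers)
        for (i in ids) {
          bd <- .train_step(net, patches[[i]], epoch, cfg$schedules,
                            aug_params, morph_par)
          if (!is.finite(bd$total)) {
            stop("non-finite loss at epoch ", epoch, " (total = ", bd$total,
                 "); aborting", call. = FALSE)
          }
          acc <- if (is.null(acc)) list(bd) else c(acc, list(bd))
        }
        step_t <- step_t + 1L
        if (cfg$optimizer_name == "adam") {
          adam_step(net$layers, cfg$learning_rate, step_t,
                    grad_scale = 1 / length(ids))
        } else {
          sgd_step(net$layers, cfg$learning_rate, grad_scale = 1 / length(ids))
        }
      }
      m <- function(f) mean(vapply(acc, `[[`, 0, f))
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, L_PR = m("L_PR"), L_Rec_i = m("L_Rec_i"),
        L_Rec_o = m("L_Rec_o"), L_Rec = m("L_Rec"), L_Mor = m("L_Mor"),
        total = m("total"),
        lambda1 = schedule_factor(epoch, cfg$schedules$lambda1),
        lambda2 = schedule_factor(epoch, cfg$schedules$lambda2),
        lambda3 = schedule_factor(epoch, cfg$schedules$lambda3))
      if (verbose) {
        message(sprintf(
          "epoch %3d  total %.4f  PR %.4f  Rec %.4f  Mor %.4f",
          epoch, m("total"), m("L_PR"), m("L_Rec"), m("L_Mor")))
      }
      if (!is.null(out_dir) && cfg$checkpoint_every > 0L &&
          epoch %% cfg$checkpoint_every == 0L) {
        save_checkpoint(net, file.path(out_dir,
                                       sprintf("checkpoint_%04d.rds", epoch)),
                        epoch = epoch)
      }
    }
    log <- do.call(rbind, log_rows)
    if (!is.null(out_dir)) {
      utils::write.csv(log, file.path(out_dir, "losses.csv"),
                       row.names = FALSE)
      save_checkpoint(net, file.path(out_dir, "checkpoint_final.rds"),
                      epoch = cfg$epochs)
    }
    structure(list(net = net, log = log, net_cfg = net$cfg, cfg = cfg),
              class = "selfseg_fit")
  })
}

#' Verify the two-stage behavior of a training log
#'
#' Checks that the recorded weight-factor traces follow their schedules: the
#' morphology weight contributed exactly 0 before its first transition cutoff,
#' every logged factor equals its schedule replay, and `lambda1` decreased
#' from its start to its end value across the transition window.
#'
#' @param log Training log data.frame from [train_network()].
#' @param schedules The schedules the run was configured with.
#' @return List report with logical fields `morphology_inactive_pretraining`,
#'   `lambda_traces_match`, `lambda1_transition_monotone`, and the epoch
#'   ranges checked.
#' @export
pretrain_stage_check <- function(log, schedules = default_schedules()) {
  need <- c("epoch", "lambda1", "lambda2", "lambda3")
  if (!is.data.frame(log) || !all(need %in% names(log))) {
    stop("malformed training log: need columns ", paste(need, collapse = ", "))
  }
  t1 <- schedules$lambda3$t1
  pre <- log$epoch <= t1
  replay_ok <- all(
    log$lambda1 == schedule_factor(log$epoch, schedules$lambda1),
    log$lambda2 == schedule_factor(log$epoch, schedules$lambda2),
    log$lambda3 == schedule_factor(log$epoch, schedules$lambda3))
  lam1 <- log$lambda1
  trans <- log$epoch >= schedules$lambda1$t1 & log$epoch <= schedules$lambda1$t2
  mono <- all(diff(lam1[trans]) <= 0) || schedules$lambda1$s <= schedules$lambda1$e
  list(morphology_inactive_pretraining =
         !any(pre) || all(log$lambda3[pre] == schedules$lambda3$s),
       lambda_traces_match = replay_ok,
       lambda1_transition_monotone = mono,
       pretraining_epochs = sum(pre),
       epochs = nrow(log))
}
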