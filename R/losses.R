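#' Cosine similarity between two vectors
#'
#' `a . b / (||a|| ||b||)`, the similarity used to compare prediction and
#' projection vectors of the two Siamese branches.
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("cosine similarity is undefined for a zero vector")
  sum(a * b) / (na * nb)
}

# Gradient of D(q, p) with respect to q (p treated as a constant).
.cosine_grad_q <- function(q, p) {
  nq <- sqrt(sum(q * q))
  np <- sqrt(sum(p * p))
  d <- sum(q * p) / (nq * np)
  (p / np - d * q / nq) / nq
}

#' Symmetric stop-gradient pairwise representation loss
#'
#' `-D(q1, sg(p2))/2 - D(q2, sg(p1))/2` where `D` is [cosine_similarity()] and
#' `sg` is the stop-gradient: during optimization no update flows through the
#' second argument of either term. This function computes the value; the
#' training loop enforces the stop-gradient contract by backpropagating only
#' through `q1` and `q2`.
#'
#' @param q1,q2 Prediction vectors of the two views.
#' @param p1,p2 Projection vectors of the two views (stop-gradient targets).
#' @return Scalar in `[-1, 1]`; `-1` at perfect alignment.
#' @export
pairwise_loss <- function(q1, p2, q2, p1) {
  -0.5 * cosine_similarity(q1, p2) - 0.5 * cosine_similarity(q2, p1)
}

.mean_l1 <- function(a, b) mean(abs(a - b))

#' Reconstruction loss of the denoising encoder--decoder
#'
#' Compares both decoder outputs with the clean, un-augmented input
#' (`L_Rec_i`) and with each other (`L_Rec_o`), and blends them:
#' \deqn{L_{Rec,i} = \tfrac12 \|x - z_1\|_1 + \tfrac12 \|x - z_2\|_1, \quad
#'       L_{Rec,o} = \|z_1 - z_2\|_1, \quad
#'       L_{Rec} = \lambda_1 L_{Rec,i} + (1 - \lambda_1) L_{Rec,o}.}
#' The L1 norm is taken as the per-pixel mean so values are
#' resolution-invariant.
#'
#' @param x Clean input patch (matrix).
#' @param z1,z2 Decoder outputs for the two augmented views, same dimensions.
#' @param lambda1 Blend weight in `[0, 1]` (dynamic during training).
#' @return List with `L_Rec_i`, `L_Rec_o`, `L_Rec`.
#' @export
reconstruction_loss <- function(x, z1, z2, lambda1) {
  if (!all(dim(x) == dim(z1)) || !all(dim(x) == dim(z2))) {
    stop("`x`, `z1`, `z2` must have identical dimensions")
  }
  if (lambda1 < 0 || lambda1 > 1) stop("`lambda1` must lie in [0, 1]")
  li <- 0.5 * .mean_l1(x, z1) + 0.5 * .mean_l1(x, z2)
  lo <- .mean_l1(z1, z2)
  list(L_Rec_i = li, L_Rec_o = lo, L_Rec = lambda1 * li + (1 - lambda1) * lo)
}

#' Morphology loss
#'
#' Mean-L1 distance between each decoder output and its own binarized
#' morphological transform, `(||w1 - z1||_1 + ||w2 - z2||_1) / 2`. The binary
#' targets `w = m(z)` are computed by [morph_transform()] and treated as
#' constants (no gradient flows through the non-differentiable transform), so
#' minimizing this term pulls the decoder toward binary closed-border maps.
#'
#' @param z1,z2 Decoder outputs (matrices in `[0, 1]`).
#' @param w1,w2 Their binarized transforms, same dimensions.
#' @return Scalar loss, `>= 0`.
#' @export
morphology_loss <- function(z1, z2, w1, w2) {
  if (!all(dim(z1) == dim(w1)) || !all(dim(z2) == dim(w2)) ||
      !all(dim(z1) == dim(z2))) {
    stop("all inputs must have identical dimensions")
  }
  0.5 * .mean_l1(w1, z1) + 0.5 * .mean_l1(w2, z2)
}

#' Dynamic loss-weight schedule
#'
#' Piecewise-linear weight as a function of the training epoch `t`: constant
#' `s` up to `t1`, linear transition to `e` over `(t1, t2)`, constant `e` from
#' `t2` on. The degenerate case `t1 == t2` is a step function (value `s` for
#' `t <= t1`, `e` after), which reproduces fixed-weight training when both
#' cutoffs are 0.
#'
#' @param s,e Start and end values.
#' @param t1,t2 Transition epoch cutoffs, `t1 <= t2`.
#' @return `schedule_config()` returns an object of class `schedule_config`;
#'   `schedule_factor()` returns the scalar weight at epoch `t`.
#' @export
schedule_config <- function(s, e, t1, t2) {
  if (t1 > t2) stop("`t1` must not exceed `t2`")
  structure(list(s = s, e = e, t1 = t1, t2 = t2), class = "schedule_config")
}

#' @rdname schedule_config
#' @param t Epoch (scalar or vector, `>= 0`).
#' @param cfg A `schedule_config`.
#' @export
schedule_factor <- function(t, cfg) {
  stopifnot(inherits(cfg, "schedule_config"))
  if (any(t < 0)) stop("`t` must be >= 0")
  if (cfg$t1 == cfg$t2) {
    return(ifelse(t <= cfg$t1, cfg$s, cfg$e))
  }
  ifelse(t <= cfg$t1, cfg$s,
         ifelse(t >= cfg$t2, cfg$e,
                cfg$s - (cfg$s - cfg$e) * (t - cfg$t1) / (cfg$t2 - cfg$t1)))
}

#' Default weight schedules
#'
#' The reference settings: `lambda1` (input-vs-output reconstruction blend)
#' transitions 1 to 0.5 over epochs 40--70, `lambda2` (reconstruction weight)
#' is constant 0.5, and `lambda3` (morphology weight) transitions 0 to 1 over
#' epochs 40--70, so the morphology term is inactive during pretraining.
#'
#' @return Named list of three `schedule_config` objects
#'   (`lambda1`, `lambda2`, `lambda3`).
#' @export
default_schedules <- function() {
  list(lambda1 = schedule_config(1, 0.5, 40, 70),
       lambda2 = schedule_config(0.5, 0.5, 0, 0),
       lambda3 = schedule_config(0, 1, 40, 70))
}

#' Assemble the total training loss
#'
#' Combines the component losses at the weights given by the schedules at
#' epoch `t`:
#' \deqn{L = L_{PR} + \lambda_2 L_{Rec} + \lambda_3 L_{Mor}, \qquad
#'       L_{Rec} = \lambda_1 L_{Rec,i} + (1 - \lambda_1) L_{Rec,o}.}
#'
#' @param L_PR Pairwise representation loss.
#' @param L_Rec_i,L_Rec_o Reconstruction loss components.
#' @param L_Mor Morphology loss.
#' @param epoch Current epoch `t`.
#' @param schedules Named list of `schedule_config`s as from
#'   [default_schedules()].
#' @return An object of class `loss_breakdown`: list with `L_PR`, `L_Rec_i`,
#'   `L_Rec_o`, `L_Rec`, `L_Mor`, `total`, `lambda1`, `lambda2`, `lambda3`.
#' @export
total_loss <- function(L_PR, L_Rec_i, L_Rec_o, L_Mor, epoch,
                       schedules = default_schedules()) {
  l1 <- schedule_factor(epoch, schedules$lambda1)
  l2 <- schedule_factor(epoch, schedules$lambda2)
  l3 <- schedule_factor(epoch, schedules$lambda3)
  L_Rec <- l1 * L_Rec_i + (1 - l1) * L_Rec_o
  structure(
    list(L_PR = L_PR, L_Rec_i = L_Rec_i, L_Rec_o = L_Rec_o, L_Rec = L_Rec,
         L_Mor = L_Mor, total = L_PR + l2 * L_Rec + l3 * L_Mor,
         lambda1 = l1, lambda2 = l2, lambda3 = l3),
    class = "loss_breakdown"
  )
}
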