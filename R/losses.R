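# Compound segmentation loss: weighted focal + cross-entropy group plus Dice,
# with deep-supervision aggregation across decoder resolutions.
#
# Probability maps are (B, 2, H, W) arrays (channel 1 = background,
# channel 2 = vessel) summing to 1 per pixel; targets are {0,1} masks.

EPS_LOG <- 1e-8    # clamp inside logarithms
DICE_SMOOTH <- 1e-5

#' Loss configuration
#'
#' Scalar weights of the enhanced compound loss
#' \eqn{L = \lambda_1(\alpha L_{CE} + \beta L_{Focal}) + \lambda_2 L_{Dice}}.
#'
#' @param alpha weight of the cross-entropy term inside the CE group.
#' @param beta weight of the focal term inside the CE group.
#' @param lambda1 weight of the CE group.
#' @param lambda2 weight of the Dice term.
#' @param focal_alpha length-2 class weights `c(background, foreground)`
#'   applied inside the focal term.
#' @param gamma focusing exponent of the focal term.
#' @param ds_weights optional per-level deep-supervision weights (normalized
#'   to sum 1); default halves per coarser level.
#' @return a `loss_config` list.
#' @export
loss_config <- function(alpha = 0.5, beta = 0.5, lambda1 = 1, lambda2 = 1,
                        focal_alpha = c(0.25, 0.75), gamma = 2,
                        ds_weights = NULL) {
  stopifnot(alpha >= 0, beta >= 0, lambda1 >= 0, lambda2 >= 0, gamma >= 0,
            length(focal_alpha) == 2, all(focal_alpha >= 0),
            all(focal_alpha <= 1))
  structure(list(alpha = alpha, beta = beta, lambda1 = lambda1,
                 lambda2 = lambda2, focal_alpha = focal_alpha, gamma = gamma,
                 ds_weights = ds_weights),
            class = "loss_config")
}

# normalize probs to (B,2,H,W) and target to (B,H,W)
canon_probs <- function(probs) {
  d <- dim(probs)
  if (length(d) == 3L) dim(probs) <- c(1L, d)
  stopifnot(length(dim(probs)) == 4L, dim(probs)[2] == 2L)
  probs
}

# add a batch axis if absent; no spatial check (deep-supervision targets are
# downsampled per level)
canon_target3 <- function(target) {
  d <- dim(target)
  if (length(d) == 2L) dim(target) <- c(1L, d)
  stopifnot(length(dim(target)) == 3L, all(target %in% c(0, 1)))
  target
}

canon_target <- function(target, probs) {
  d <- dim(target)
  if (length(d) == 2L) dim(target) <- c(1L, d)
  pd <- dim(probs)
  stopifnot(all(dim(target) == pd[c(1, 3, 4)]),
            all(target %in% c(0, 1)))
  target
}

prob_true_class <- function(probs, target) {
  pfg <- probs[, 2L, , , drop = TRUE]
  dim(pfg) <- dim(probs)[c(1, 3, 4)]
  ifelse(target == 1, pfg, 1 - pfg)
}

#' Cross-entropy loss
#'
#' Mean over pixels of \eqn{-\log p_{i,y_i}}.
#'
#' @param probs probability map `(B,2,H,W)` (or `(2,H,W)`).
#' @param target binary mask `(B,H,W)` (or `(H,W)`).
#' @return non-negative scalar.
#' @export
ce_loss <- function(probs, target) {
  probs <- canon_probs(probs)
  target <- canon_target(target, probs)
  pt <- prob_true_class(probs, target)
  -mean(log(pmax(pt, EPS_LOG)))
}

#' Focal loss
#'
#' Mean over pixels of \eqn{-\alpha_t (1-p_t)^\gamma \log p_t}, where
#' \eqn{\alpha_t} is `focal_alpha[2]` for vessel pixels and `focal_alpha[1]`
#' for background pixels.
#'
#' @inheritParams ce_loss
#' @param focal_alpha class weights `c(background, foreground)`.
#' @param gamma focusing exponent.
#' @return non-negative scalar.
#' @export
focal_loss <- function(probs, target, focal_alpha = c(0.25, 0.75), gamma = 2) {
  stopifnot(gamma >= 0)
  probs <- canon_probs(probs)
  target <- canon_target(target, probs)
  pt <- prob_true_class(probs, target)
  at <- ifelse(target == 1, focal_alpha[2], focal_alpha[1])
  mean(-at * (1 - pt)^gamma * log(pmax(pt, EPS_LOG)))
}

#' Soft Dice loss
#'
#' Complement of the soft Dice coefficient on the foreground probability,
#' averaged over the batch. A small smoothing term in numerator and
#' denominator makes the empty-mask/empty-prediction case evaluate to 0.
#'
#' @inheritParams ce_loss
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(probs, target) {
  probs <- canon_probs(probs)
  target <- canon_target(target, probs)
  B <- dim(probs)[1]
  vals <- vapply(seq_len(B), function(b) {
    p <- probs[b, 2L, , ]
    y <- target[b, , ]
    1 - (2 * sum(y * p) + DICE_SMOOTH) / (sum(y) + sum(p) + DICE_SMOOTH)
  }, numeric(1))
  mean(vals)
}

#' Enhanced compound loss
#'
#' \eqn{\lambda_1(\alpha L_{CE} + \beta L_{Focal}) + \lambda_2 L_{Dice}}.
#'
#' @inheritParams ce_loss
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
enhanced_loss <- function(probs, target, cfg = loss_config()) {
  cfg$lambda1 * (cfg$alpha * ce_loss(probs, target) +
                 cfg$beta * focal_loss(probs, target, cfg$focal_alpha,
                                       cfg$gamma)) +
    cfg$lambda2 * dice_loss(probs, target)
}

#' Deep-supervision loss
#'
#' Weighted sum of [enhanced_loss()] over decoder levels; the target mask is
#' nearest-neighbor downsampled to each level's resolution. Weights default to
#' halving per coarser level and are normalized to sum 1.
#'
#' @param ds_probs non-empty list of probability maps, ordered fine to coarse.
#' @param target full-resolution binary mask.
#' @param cfg a [loss_config()]; `cfg$ds_weights` overrides the default.
#' @return scalar loss.
#' @export
deep_supervision_loss <- function(ds_probs, target, cfg = loss_config()) {
  if (length(ds_probs) == 0) stop("ds_probs must be non-empty")
  w <- cfg$ds_weights
  if (is.null(w)) w <- 2^(-(seq_along(ds_probs) - 1))
  stopifnot(length(w) == length(ds_probs))
  w <- w / sum(w)
  target <- canon_target3(target)
  total <- 0
  for (i in seq_along(ds_probs)) {
    p <- canon_probs(ds_probs[[i]])
    t_i <- downsample_target(target, dim(p)[3], dim(p)[4])
    total <- total + w[i] * enhanced_loss(p, t_i, cfg)
  }
  total
}

# nearest-neighbor downsampling of a (B,H,W) mask stack
downsample_target <- function(target, oh, ow) {
  d <- dim(target)
  if (d[2] == oh && d[3] == ow) return(target)
  out <- array(0, c(d[1], oh, ow))
  for (b in seq_len(d[1])) out[b, , ] <- nearest_resize(target[b, , ], oh, ow)
  out
}

# ---- training-time gradient (w.r.t. logits) --------------------------------
# These run on the internal layout: logits (H,W,2,B), target (H,W,B).

# nearest-neighbor downsampling of an (H,W,B) mask stack
downsample_target_hwb <- function(target, oh, ow) {
  d <- dim(target)
  if (d[1] == oh && d[2] == ow) return(target)
  out <- array(0, c(oh, ow, d[3]))
  for (b in seq_len(d[3])) out[, , b] <- nearest_resize(target[, , b], oh, ow)
  out
}

# Forward + backward of the enhanced loss from 2-channel logits.
# Returns loss components and dL/dlogits. CE/focal average over all pixels of
# the batch; Dice is computed per image then averaged.
enhanced_loss_grad <- function(logits, target, cfg = loss_config()) {
  probs <- softmax_hwcb(logits)
  d <- dim(probs)
  B <- d[4]; N <- prod(d[c(1, 2, 4)])
  stopifnot(all(dim(target) == d[c(1, 2, 4)]))
  pfg <- probs[, , 2L, ]; dim(pfg) <- d[c(1, 2, 4)]
  pbg <- 1 - pfg
  y <- target

  pt <- y * pfg + (1 - y) * pbg
  ptc <- pmax(pt, EPS_LOG)
  at <- cfg$focal_alpha[1] + y * (cfg$focal_alpha[2] - cfg$focal_alpha[1])

  l_ce <- -mean(log(ptc))
  l_focal <- mean(-at * (1 - pt)^cfg$gamma * log(ptc))

  # dL/dz_fg for the CE term: (p_fg - y)/N
  g_ce <- (pfg - y) / N
  # focal: df/dpt, then dpt/dz_fg = sign * p_fg * p_bg
  gamma <- cfg$gamma
  dfdpt <- at * (gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(ptc) -
                   (1 - pt)^gamma / ptc)
  g_focal <- dfdpt * (2 * y - 1) * pfg * pbg / N

  # Dice per image
  l_dice <- 0
  g_dice <- array(0, dim(y))
  for (b in seq_len(B)) {
    p <- pfg[, , b]; yb <- y[, , b]
    num <- 2 * sum(yb * p) + DICE_SMOOTH
    den <- sum(yb) + sum(p) + DICE_SMOOTH
    l_dice <- l_dice + (1 - num / den)
    dLdp <- -(2 * yb * den - num) / den^2
    g_dice[, , b] <- dLdp * p * (1 - p) / B
  }
  l_dice <- l_dice / B

  gfg <- cfg$lambda1 * (cfg$alpha * g_ce + cfg$beta * g_focal) +
    cfg$lambda2 * g_dice
  glogits <- array(0, d)
  glogits[, , 2L, ] <- gfg
  glogits[, , 1L, ] <- -gfg
  total <- cfg$lambda1 * (cfg$alpha * l_ce + cfg$beta * l_focal) +
    cfg$lambda2 * l_dice
  list(total = total, ce = l_ce, focal = l_focal, dice = l_dice,
       grad = glogits)
}

# Deep-supervision version: list of (H,W,2,B) logits (ordered as produced by
# the decoder), full-resolution (H,W,B) target. Returns per-level gradients.
deep_supervision_loss_grad <- function(logits_list, target, cfg = loss_config(),
                                       weights = NULL) {
  n <- length(logits_list)
  stopifnot(n >= 1)
  if (is.null(weights)) {
    # finest level gets the largest weight; levels are ordered deep -> shallow
    sizes <- vapply(logits_list, function(z) dim(z)[1], numeric(1))
    ord <- rank(-sizes, ties.method = "first")  # 1 = finest
    weights <- 2^(-(ord - 1))
  }
  weights <- weights / sum(weights)
  comps <- c(total = 0, ce = 0, focal = 0, dice = 0)
  grads <- vector("list", n)
  for (i in seq_len(n)) {
    z <- logits_list[[i]]
    t_i <- downsample_target_hwb(target, dim(z)[1], dim(z)[2])
    r <- enhanced_loss_grad(z, t_i, cfg)
    comps <- comps + weights[i] * c(r$total, r$ce, r$focal, r$dice)
    grads[[i]] <- r$grad * weights[i]
  }
  list(total = comps[["total"]], ce = comps[["ce"]], focal = comps[["focal"]],
       dice = comps[["dice"]], grads = grads)
}
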