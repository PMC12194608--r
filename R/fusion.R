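# Foundation-feature fusion path: a frozen foundation encoder (shape-contract
# interface + deterministic stub) supplies feature pyramids that are adapted
# to the backbone's stage grids (adaptive average pooling, optional 1x1
# channel doubling), enhanced by FrequencyLoRA (FFT amplitude modulation +
# low-rank bottleneck, identity at initialization), concatenated with the
# backbone stage features, projected back by a 1x1 convolution, and gated by
# a parallel channel-spatial attention gate.

#' Foundation encoder shape contract
#'
#' Declares the output shapes a foundation encoder must honor. The
#' `single_scale` default is one `(256, 64, 64)` map; `multi_scale` is three
#' maps `(256, 256, 256)`, `(256, 128, 128)`, `(256, 64, 64)`. The earliest
#' (highest-resolution) multi-scale map is accepted but never fused. Custom
#' shapes support scaled-down synthetic experiments.
#'
#' @param variant `"single_scale"` or `"multi_scale"`.
#' @param outputs optional list of `c(channels, height, width)` overriding the
#'   defaults.
#' @return a `foundation_contract` list.
#' @export
foundation_contract <- function(variant = c("multi_scale", "single_scale"),
                                outputs = NULL) {
  variant <- match.arg(variant)
  if (is.null(outputs)) {
    outputs <- if (variant == "single_scale") list(c(256L, 64L, 64L))
    else list(c(256L, 256L, 256L), c(256L, 128L, 128L), c(256L, 64L, 64L))
  }
  stopifnot(all(vapply(outputs, length, integer(1)) == 3L))
  structure(list(variant = variant, outputs = outputs),
            class = "foundation_contract")
}

#' Deterministic stub foundation encoder
#'
#' Stands in for a frozen pretrained encoder: it produces a pyramid matching
#' the contract shapes from pooled image content passed through a fixed,
#' seeded random projection, so outputs are content-dependent and
#' reproducible but carry no learned weights (the module is frozen; no
#' parameter receives gradients).
#'
#' @param image feature map `(B,C,H,W)` (channels are averaged to gray) or a
#'   2D matrix.
#' @param contract a [foundation_contract()].
#' @param seed integer seed fixing the random projection.
#' @return list with `features` (list of `(B,Cout,h,w)` arrays, one per
#'   contract output) and `contract`.
#' @export
stub_encoder <- function(image, contract, seed = 3407L) {
  r <- stub_encoder_hwcb(bchw_to_hwcb(image), contract, seed)
  r$features <- lapply(r$features, hwcb_to_bchw)
  r
}

# internal (H,W,C,B) variant used by the model forward pass
stub_encoder_hwcb <- function(x, contract, seed = 3407L) {
  stopifnot(inherits(contract, "foundation_contract"))
  d <- dim(x)
  B <- d[4]
  feats <- vector("list", length(contract$outputs))
  grays <- lapply(seq_len(B), function(b) {
    g <- x[, , 1L, b]
    if (d[3] > 1) for (c in 2:d[3]) g <- g + x[, , c, b]
    g / d[3]
  })
  for (k in seq_along(contract$outputs)) {
    co <- contract$outputs[[k]]
    C <- co[1]; h <- co[2]; w <- co[3]
    proj <- with_seed(derive_seed(seed, k),
                      matrix(stats::rnorm(C * 3, 0, 1), C, 3))
    out <- array(0, c(h, w, C, B))
    for (b in seq_len(B)) {
      g <- bilinear_resize(grays[[b]], h, w)
      gy <- rbind(g[-1, , drop = FALSE] - g[-h, , drop = FALSE], rep(0, w))
      gx <- cbind(g[, -1, drop = FALSE] - g[, -w, drop = FALSE], rep(0, h))
      base <- rbind(as.numeric(g), as.numeric(g * g),
                    as.numeric(sqrt(gy^2 + gx^2)))
      out[, , , b] <- array(t(tanh(proj %*% base)), c(h, w, C))
    }
    feats[[k]] <- out
  }
  list(features = feats, contract = contract)
}

# ---- scale adaptation -------------------------------------------------------

make_scale_adapter <- function(ci, target_c, th, tw) {
  if (target_c == ci) chan_up <- NULL
  else if (target_c == 2L * ci) chan_up <- layer_conv(ci, target_c, k = 1L)
  else stop("scale_adapt supports target channels in {C, 2C}; got ",
            ci, " -> ", target_c)
  list(chan_up = chan_up, th = th, tw = tw, ci = ci, target_c = target_c)
}

scale_adapter_fwd <- function(ad, x, train = TRUE) {
  d <- dim(x)
  y <- if (d[1] == ad$th && d[2] == ad$tw) x else adaptive_avgpool(x, ad$th, ad$tw)
  if (!is.null(ad$chan_up)) y <- ad$chan_up$fwd(y, train)
  y
}

scale_adapter_bwd <- function(ad, gy, in_h, in_w) {
  g <- if (!is.null(ad$chan_up)) ad$chan_up$bwd(gy) else gy
  if (in_h == ad$th && in_w == ad$tw) g
  else adaptive_avgpool_bwd(g, in_h, in_w)
}

#' Adapt a feature map to a target stage shape
#'
#' Spatial reduction by adaptive average pooling to the target grid; channel
#' doubling, when requested, through a learnable 1x1 convolution. Target
#' channel counts other than `C` or `2C` are rejected.
#'
#' @param x feature map `(B,C,H,W)`.
#' @param target integer `c(channels, height, width)`.
#' @param params optional adapter created by an earlier call (element
#'   `adapter`); if `NULL` a fresh adapter is initialized.
#' @return feature map with shape `(B, target[1], target[2], target[3])`;
#'   the adapter used is attached as attribute `"adapter"`.
#' @export
scale_adapt <- function(x, target, params = NULL) {
  x <- bchw_to_hwcb(x)
  d <- dim(x)
  ad <- if (is.null(params)) make_scale_adapter(d[3], target[1], target[2],
                                                target[3]) else params
  y <- hwcb_to_bchw(scale_adapter_fwd(ad, x, train = FALSE))
  attr(y, "adapter") <- ad
  y
}

# ---- FrequencyLoRA ----------------------------------------------------------

#' FrequencyLoRA configuration
#'
#' @param reduction channel reduction factor of the amplitude MLP.
#' @param mu residual weight of the amplitude enhancement.
#' @param rank bottleneck width of the low-rank adapter.
#' @return a `frequency_lora_config` list.
#' @export
frequency_lora_config <- function(reduction = 8L, mu = 0.2, rank = 4L) {
  stopifnot(reduction >= 1, rank >= 1, mu >= 0)
  structure(list(reduction = as.integer(reduction), mu = mu,
                 rank = as.integer(rank)),
            class = "frequency_lora_config")
}

#' Create FrequencyLoRA parameters
#'
#' The amplitude MLP acts per spatial frequency across channels (two 1x1
#' convolutions, reduce then restore); its restoring layer and the LoRA "up"
#' projection are zero-initialized, so the whole module is the identity at
#' initialization.
#'
#' @param channels channel count of the feature maps to adapt.
#' @param cfg a [frequency_lora_config()].
#' @return list of trainable sub-modules (`freq`, `lora`).
#' @export
frequency_lora_params <- function(channels, cfg = frequency_lora_config()) {
  if (cfg$rank > channels) stop("rank exceeds channel count")
  hidden <- max(1L, channels %/% cfg$reduction)
  list(
    freq = module_env(mlp1 = layer_conv(channels, hidden, k = 1L),
                      relu = layer_relu(),
                      mlp2 = layer_conv(hidden, channels, k = 1L,
                                        init = "zero"),
                      mu = cfg$mu),
    lora = list(down = layer_conv(channels, cfg$rank, k = 1L, bias = FALSE),
                up = layer_conv(cfg$rank, channels, k = 1L, bias = FALSE,
                                init = "zero"))
  )
}

# per-channel 2D FFT of an (H,W,C,B) tensor (slices are contiguous)
fft2_hwcb <- function(x, inverse = FALSE) {
  d <- dim(x)
  out <- array(complex(real = 0), d)
  norm <- if (inverse) d[1] * d[2] else 1
  for (b in seq_len(d[4])) for (c in seq_len(d[3])) {
    m <- x[, , c, b]
    out[, , c, b] <- stats::fft(m, inverse = inverse) / norm
  }
  out
}

freq_adapter_fwd <- function(fr, x, train = TRUE) {
  d <- dim(x)
  F_ <- fft2_hwcb(x)
  A <- Mod(F_)
  U <- F_ / pmax(A, 1e-12)
  M <- fr$mlp2$fwd(fr$relu$fwd(fr$mlp1$fwd(A, train), train), train)
  Fp <- F_ + fr$mu * M * U
  Y <- fft2_hwcb(Re(Fp), inverse = TRUE) +
    (0+1i) * fft2_hwcb(Im(Fp), inverse = TRUE)
  if (train) { fr$U_cache <- U; fr$d_cache <- d }
  res <- Re(Y)
  attr(res, "max_imag") <- max(abs(Im(Y)))
  res
}

freq_adapter_bwd <- function(fr, G) {
  U <- fr$U_cache
  H <- fft2_hwcb(G, inverse = TRUE)
  gM <- fr$mu * Re(U * H)
  gA <- fr$mlp1$bwd(fr$relu$bwd(fr$mlp2$bwd(gM)))
  Z <- H + gA * Conj(U)
  gX <- Re(fft2_hwcb(Re(Z)) + (0+1i) * fft2_hwcb(Im(Z)))
  fr$U_cache <- NULL
  gX
}

lora_fwd <- function(lo, x, train = TRUE) {
  x + lo$up$fwd(lo$down$fwd(x, train), train)
}

lora_bwd <- function(lo, gy) {
  gy + lo$down$bwd(lo$up$bwd(gy))
}

#' Frequency-domain amplitude enhancement
#'
#' Per channel, the 2D FFT amplitude spectrum `A` is modulated as
#' `A' = A + mu * MLP(A)` (phase untouched) and the map is transformed back;
#' with a zero MLP the module is the identity up to FFT round-off. The
#' imaginary residue discarded by the final real part is exposed as the
#' `"max_imag"` attribute.
#'
#' @param x real feature map `(B,C,H,W)`.
#' @param cfg a [frequency_lora_config()] (carries `mu`).
#' @param params modules from [frequency_lora_params()].
#' @return feature map of the same shape.
#' @export
frequency_adapter <- function(x, cfg = frequency_lora_config(),
                              params = frequency_lora_params(dim(as_bchw(x))[2], cfg)) {
  xi <- bchw_to_hwcb(x)
  fr <- params$freq
  fr$mu <- cfg$mu
  y <- freq_adapter_fwd(fr, xi, train = FALSE)
  out <- hwcb_to_bchw(y)
  attr(out, "max_imag") <- attr(y, "max_imag")
  out
}

#' Low-rank (LoRA) bottleneck adapter
#'
#' `x + Up(Down(x))` with 1x1 projections to `rank` channels and back, no
#' biases; `Up` is zero-initialized so the adapter is exactly the identity at
#' initialization. Learnable parameter count is `2 * C * rank`.
#'
#' @inheritParams frequency_adapter
#' @return feature map of the same shape.
#' @export
lora_adapter <- function(x, cfg = frequency_lora_config(),
                         params = frequency_lora_params(dim(as_bchw(x))[2], cfg)) {
  if (cfg$rank > dim(as_bchw(x))[2]) stop("rank exceeds channel count")
  hwcb_to_bchw(lora_fwd(params$lora, bchw_to_hwcb(x), train = FALSE))
}

#' FrequencyLoRA: frequency enhancement followed by low-rank adaptation
#'
#' Composition [lora_adapter()] of [frequency_adapter()]; the identity at
#' default initialization.
#'
#' @inheritParams frequency_adapter
#' @return feature map of the same shape.
#' @export
frequency_lora <- function(x, cfg = frequency_lora_config(),
                           params = frequency_lora_params(dim(as_bchw(x))[2], cfg)) {
  lora_adapter(frequency_adapter(x, cfg, params), cfg, params)
}

# ---- AttentionGate ----------------------------------------------------------

#' Create AttentionGate parameters
#'
#' Channel branch: global average pooling, then a two-layer MLP with layer
#' normalization between the layers. Spatial branch: 1x1 channel compression,
#' parallel 3x3 and 7x7 convolutions summed (multi-scale context), then a 1x1
#' projection to one logit map. Both final layers are zero-initialized, so
#' each sigmoid starts at 0.5.
#'
#' @param channels input channel count.
#' @param reduction hidden-width reduction factor of both branches.
#' @return list of trainable sub-modules.
#' @export
attention_gate_params <- function(channels, reduction = 8L) {
  hidden <- max(1L, channels %/% reduction)
  module_env(ch_fc1 = layer_linear(channels, hidden),
             ch_ln = layer_layernorm(hidden),
             ch_fc2 = layer_linear(hidden, channels, init = "zero"),
             sp_in = layer_conv(channels, hidden, k = 1L),
             sp_k3 = layer_conv(hidden, hidden, k = 3L),
             sp_k7 = layer_conv(hidden, hidden, k = 7L),
             sp_out = layer_conv(hidden, 1L, k = 1L, init = "zero"))
}

# gate forward on an internal (H,W,C,B) tensor
gate_fwd <- function(gt, x, train = TRUE) {
  d <- dim(x)
  HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  xm <- x
  dim(xm) <- c(HW, C * B)
  gap <- t(matrix(colMeans(xm), C, B))             # (B, C)
  h1 <- gt$ch_fc1$fwd(gap, train)
  h2 <- gt$ch_ln$fwd(h1, train)
  h3 <- h2 * (h2 > 0)
  zc <- gt$ch_fc2$fwd(h3, train)                   # (B, C)
  s0 <- gt$sp_in$fwd(x, train)
  s0r <- s0 * (s0 > 0)
  s1 <- gt$sp_k3$fwd(s0r, train) + gt$sp_k7$fwd(s0r, train)
  s1r <- s1 * (s1 > 0)
  zs <- gt$sp_out$fwd(s1r, train)                  # (H,W,1,B)
  sc <- sigmoid(zc)
  ssp <- sigmoid(zs)
  scv <- rep(as.numeric(t(sc)), each = HW)         # column (c,b) order
  sm <- matrix(ssp, HW, B)
  sfull <- sm[, rep(seq_len(B), each = C), drop = FALSE]
  y <- xm * scv * sfull
  dim(y) <- d
  if (train) {
    gt$cache <- list(xm = xm, sc = sc, scv = scv, sfull = sfull, d = d,
                     h2mask = (h2 > 0), s0mask = (s0 > 0), s1mask = (s1 > 0),
                     ssp = ssp)
  }
  attr(y, "channel_weights") <- sc
  attr(y, "spatial_weights") <- ssp
  y
}

gate_bwd <- function(gt, gy) {
  cc <- gt$cache
  d <- cc$d
  HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  gm <- gy
  dim(gm) <- c(HW, C * B)
  gx_m <- gm * cc$scv * cc$sfull
  g_sc <- t(matrix(colSums(gm * cc$xm * cc$sfull), C, B))   # (B, C)
  g_sfull <- gm * cc$xm * cc$scv                            # (HW, C*B)
  # reduce over channels: columns (c,b) -> b
  dim(g_sfull) <- c(HW * 1, C, B)  # temporarily 3D
  g_sm <- matrix(0, HW, B)
  for (c in seq_len(C)) g_sm <- g_sm + matrix(g_sfull[, c, ], HW, B)
  # channel branch
  g_zc <- g_sc * cc$sc * (1 - cc$sc)
  g_h3 <- gt$ch_fc2$bwd(g_zc)
  g_h2 <- g_h3 * cc$h2mask
  g_gap <- gt$ch_fc1$bwd(gt$ch_ln$bwd(g_h2))                # (B, C)
  gx_m <- gx_m + rep(as.numeric(t(g_gap)), each = HW) / HW
  # spatial branch
  sspm <- matrix(cc$ssp, HW, B)
  g_zs <- array(g_sm * sspm * (1 - sspm), c(d[1], d[2], 1L, B))
  g_s1r <- gt$sp_out$bwd(g_zs)
  g_s1 <- g_s1r * cc$s1mask
  g_s0r <- gt$sp_k3$bwd(g_s1) + gt$sp_k7$bwd(g_s1)
  g_s0 <- g_s0r * cc$s0mask
  gx_sp <- gt$sp_in$bwd(g_s0)
  gx <- gx_m
  dim(gx) <- d
  gx <- gx + gx_sp
  gt$cache <- NULL
  gx
}

#' Dual channel-spatial attention gate
#'
#' `O = I * sigmoid(Wc) * sigmoid(Ws)`: per-channel weights from a pooled MLP
#' and a per-pixel weight map from a multi-scale convolutional branch are
#' applied in parallel by element-wise multiplication, preserving the input
#' shape. With zero logits the output is exactly `I / 4`.
#'
#' @param x feature map `(B,C,H,W)`.
#' @param params modules from [attention_gate_params()].
#' @return gated feature map; sigmoid channel/spatial weights are attached as
#'   attributes `"channel_weights"` and `"spatial_weights"`.
#' @export
attention_gate <- function(x, params = attention_gate_params(dim(as_bchw(x))[2])) {
  y <- gate_fwd(params, bchw_to_hwcb(x), train = FALSE)
  out <- hwcb_to_bchw(y)
  attr(out, "channel_weights") <- attr(y, "channel_weights")
  sw <- attr(y, "spatial_weights")                  # (H,W,1,B)
  attr(out, "spatial_weights") <- sw
  out
}

# ---- fuse stage -------------------------------------------------------------

make_fuse_params <- function(channels) {
  list(proj = layer_conv(2L * channels, channels, k = 1L),
       gate = attention_gate_params(channels))
}

fuse_fwd <- function(fp, nn_feat, fnd_feat, train = TRUE) {
  dn <- dim(nn_feat); df <- dim(fnd_feat)
  if (!all(dn == df))
    stop("fuse_stage: shape mismatch between backbone and foundation features")
  cc <- array(0, c(dn[1], dn[2], 2L * dn[3], dn[4]))
  cc[, , seq_len(dn[3]), ] <- nn_feat
  cc[, , dn[3] + seq_len(dn[3]), ] <- fnd_feat
  pj <- fp$proj$fwd(cc, train)
  gate_fwd(fp$gate, pj, train)
}

fuse_bwd <- function(fp, gy) {
  g_pj <- gate_bwd(fp$gate, gy)
  g_cc <- fp$proj$bwd(g_pj)
  C <- dim(g_cc)[3] / 2L
  list(g_nn = g_cc[, , seq_len(C), , drop = FALSE],
       g_fnd = g_cc[, , C + seq_len(C), , drop = FALSE])
}

#' Fuse a backbone stage with adapted foundation features
#'
#' Channel-wise concatenation (2C), 1x1 convolutional projection back to C,
#' then adaptive selection by the attention gate. The result replaces the
#' encoder stage feature for both the skip connection and the next stage.
#'
#' @param nn_feat,foundation_feat feature maps sharing batch, channel and
#'   spatial dims.
#' @param params modules from an internal constructor; freshly initialized
#'   when omitted.
#' @return fused feature map with the shape of `nn_feat`.
#' @export
fuse_stage <- function(nn_feat, foundation_feat,
                       params = make_fuse_params(dim(as_bchw(nn_feat))[2])) {
  hwcb_to_bchw(fuse_fwd(params, bchw_to_hwcb(nn_feat),
                        bchw_to_hwcb(foundation_feat), train = FALSE))
}

# ---- attention heatmap export -----------------------------------------------

#' Export a spatial attention heatmap
#'
#' Bilinearly upsamples a spatial weight map to `out_size`, min-max
#' normalizes to `[0,1]`, blacks out values below `threshold`, and maps the
#' remaining values onto a red-to-orange gradient. A constant weight map has
#' no dynamic range and renders all black.
#'
#' @param spatial_weights 2D numeric matrix of attention weights.
#' @param out_size output side length in pixels (square).
#' @param threshold background-suppression threshold on the normalized map.
#' @param file optional PNG path to write.
#' @return `(out_size, out_size, 3)` RGB array in `[0,1]`, invisibly if
#'   written to file.
#' @export
export_attention_heatmap <- function(spatial_weights, out_size = 640L,
                                     threshold = 0.5, file = NULL) {
  stopifnot(is.matrix(spatial_weights), all(is.finite(spatial_weights)))
  up <- bilinear_resize(spatial_weights, out_size, out_size)
  rng <- range(up)
  img <- array(0, c(out_size, out_size, 3L))
  if (rng[2] - rng[1] > 1e-12) {
    v <- (up - rng[1]) / (rng[2] - rng[1])
    hot <- v >= threshold
    t_ <- pmin(pmax((v - threshold) / max(1 - threshold, 1e-12), 0), 1)
    r <- ifelse(hot, 1, 0)
    g <- ifelse(hot, 0.65 * t_, 0)
    img[, , 1] <- r
    img[, , 2] <- g
  }
  if (!is.null(file)) {
    png::writePNG(img, file)
    return(invisible(img))
  }
  img
}
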