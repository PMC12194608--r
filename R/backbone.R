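# nnU-Net-style 2D encoder-decoder backbone: stacked convolutional blocks
# (two ConvDropoutNormReLU modules each, instance normalization, dropout 0),
# stride-2 channel-doubling downsampling from stage E1 on (E0 is a
# full-resolution block), transposed-convolution upsampling with skip
# concatenation, and deep-supervision heads at every decoder level.

#' Backbone configuration
#'
#' With the defaults (8 stages, base 32 channels capped at 512, 640 px
#' input) the stage schedule reproduces the reference anchors: stage E3 is
#' `(B,256,80,80)` and the bottleneck E7 is `(B,512,5,5)`; final logits are
#' `(B,2,640,640)`.
#'
#' @param n_stages number of encoder stages (E0 full resolution, then one
#'   halving per stage).
#' @param base_channels channels of stage E0; doubled per stage.
#' @param max_channels channel cap.
#' @param input_channels input channels (grayscale is replicated to 3 by the
#'   pipeline).
#' @param input_size square input side; must be divisible by
#'   `2^(n_stages-1)`.
#' @param deep_supervision emit auxiliary predictions at every decoder level.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(n_stages = 8L, base_channels = 32L,
                            max_channels = 512L, input_channels = 3L,
                            input_size = 640L, deep_supervision = TRUE) {
  n_stages <- as.integer(n_stages)
  input_size <- as.integer(input_size)
  if (input_size %% 2^(n_stages - 1L) != 0L)
    stop("input_size must be divisible by 2^(n_stages-1)")
  structure(list(n_stages = n_stages,
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 input_channels = as.integer(input_channels),
                 input_size = input_size,
                 deep_supervision = isTRUE(deep_supervision)),
            class = "backbone_config")
}

#' Channel count of encoder stage k (0-based)
#' @param config a [backbone_config()].
#' @param k stage index, 0-based.
#' @return integer channel count `min(base * 2^k, max)`.
#' @export
stage_channels <- function(config, k) {
  pmin(config$base_channels * 2^k, config$max_channels)
}

#' Spatial side length of encoder stage k (0-based)
#' @inheritParams stage_channels
#' @return integer side length `input_size / 2^k` (stage 0 at full size).
#' @export
stage_size <- function(config, k) {
  as.integer(config$input_size / 2^k)
}

make_enc_stage <- function(ci, co, downsample) {
  list(conv1 = layer_conv(ci, co, k = 3L, stride = if (downsample) 2L else 1L),
       in1 = layer_instancenorm(co), relu1 = layer_relu(),
       conv2 = layer_conv(co, co, k = 3L, stride = 1L),
       in2 = layer_instancenorm(co), relu2 = layer_relu())
}

make_dec_level <- function(c_deep, c_skip) {
  list(tconv = layer_tconv(c_deep, c_skip, k = 2L, stride = 2L),
       conv1 = layer_conv(2L * c_skip, c_skip, k = 3L),
       in1 = layer_instancenorm(c_skip), relu1 = layer_relu(),
       conv2 = layer_conv(c_skip, c_skip, k = 3L),
       in2 = layer_instancenorm(c_skip), relu2 = layer_relu(),
       head = layer_conv(c_skip, 2L, k = 1L))
}

block_fwd <- function(st, x, train = TRUE) {
  st$relu2$fwd(st$in2$fwd(st$conv2$fwd(
    st$relu1$fwd(st$in1$fwd(st$conv1$fwd(x, train), train), train),
    train), train), train)
}

block_bwd <- function(st, gy) {
  st$conv1$bwd(st$in1$bwd(st$relu1$bwd(
    st$conv2$bwd(st$in2$bwd(st$relu2$bwd(gy))))))
}

#' Build the encoder-decoder backbone
#'
#' Encoder stage `k >= 1` begins with a stride-2, channel-doubling (capped)
#' 3x3 convolution; every block is conv-dropout-norm-ReLU twice (dropout
#' probability 0, instance normalization). The decoder mirrors the encoder
#' with 2x2 transposed convolutions halving channels and doubling spatial
#' size, skip concatenation, and a 1x1 two-channel prediction head per
#' level.
#'
#' @param config a [backbone_config()].
#' @return a `backbone` model handle (list of layer environments).
#' @export
build_backbone <- function(config) {
  stopifnot(inherits(config, "backbone_config"))
  n <- config$n_stages
  enc <- vector("list", n)
  for (k in 0:(n - 1L)) {
    ci <- if (k == 0L) config$input_channels else stage_channels(config, k - 1L)
    enc[[k + 1L]] <- make_enc_stage(ci, stage_channels(config, k), k > 0L)
  }
  dec <- vector("list", n - 1L)
  # dec[[i]] upsamples from 0-based stage (n-i) to stage (n-1-i)
  for (i in seq_len(n - 1L)) {
    dec[[i]] <- make_dec_level(stage_channels(config, n - i),
                               stage_channels(config, n - i - 1L))
  }
  structure(list(config = config, enc = enc, dec = dec), class = "backbone")
}

#' Run the encoder
#'
#' @param model a `backbone` from [build_backbone()] (or a fused model; the
#'   fusion path is applied at its planned stages).
#' @param batch input feature map `(B, input_channels, input_size,
#'   input_size)`.
#' @param train keep backward caches.
#' @return list of stage features: each element
#'   `list(stage_index, feature)`, shallow to deep.
#' @export
encode <- function(model, batch, train = FALSE) {
  batch <- as_bchw(batch)
  cfg <- model$config
  d <- dim(batch)
  if (d[3] != cfg$input_size || d[4] != cfg$input_size ||
      d[2] != cfg$input_channels)
    stop("input shape (", paste(d, collapse = ","),
         ") does not match config (", cfg$input_channels, ",",
         cfg$input_size, ",", cfg$input_size, ")")
  feats <- encode_internal(model, bchw_to_hwcb(batch), train = train)
  lapply(seq_along(feats), function(i)
    list(stage_index = i - 1L, feature = hwcb_to_bchw(feats[[i]])))
}

# internal: plain list of (H,W,C,B) stage features, fusion applied if the
# model carries a fusion path
encode_internal <- function(model, batch, train = TRUE) {
  n <- model$config$n_stages
  feats <- vector("list", n)
  cur <- batch
  pyramid <- NULL
  if (!is.null(model$fusion)) {
    pyramid <- model$fusion$encoder_fn(batch)$features
  }
  for (k in 0:(n - 1L)) {
    cur <- block_fwd(model$enc[[k + 1L]], cur, train)
    if (!is.null(model$fusion)) {
      fs <- model$fusion$by_stage[[as.character(k)]]
      if (!is.null(fs)) {
        f_raw <- pyramid[[fs$pyramid_index]]
        a <- scale_adapter_fwd(fs$adapter, f_raw, train)
        a2 <- freq_adapter_fwd(fs$flp$freq, a, train)
        a3 <- lora_fwd(fs$flp$lora, a2, train)
        cur <- fuse_fwd(fs$fuse, cur, a3, train)
      }
    }
    feats[[k + 1L]] <- cur
  }
  feats
}

#' Run the decoder
#'
#' @param model a `backbone`.
#' @param stages stage features as returned by [encode()] (possibly with
#'   fused replacements).
#' @param train keep backward caches.
#' @return list with `final_logits` (`(B,2,H,W)` at input resolution) and
#'   `ds_outputs` (deep-supervision logits per decoder level, ordered deep to
#'   shallow, empty when deep supervision is off; the last entry equals
#'   `final_logits`).
#' @export
decode <- function(model, stages, train = FALSE) {
  if (length(stages) && is.list(stages[[1]]) &&
      !is.null(stages[[1]]$feature))
    stages <- lapply(stages, `[[`, "feature")
  n <- model$config$n_stages
  if (length(stages) != n)
    stop("expected ", n, " stage features, got ", length(stages))
  r <- decode_internal(model, lapply(stages, bchw_to_hwcb), train = train)
  logits <- lapply(r$logits, hwcb_to_bchw)
  list(final_logits = logits[[n - 1L]],
       ds_outputs = if (model$config$deep_supervision) logits else list())
}

decode_internal <- function(model, feats, train = TRUE) {
  n <- model$config$n_stages
  logits <- vector("list", n - 1L)
  d <- feats[[n]]
  for (i in seq_len(n - 1L)) {
    lvl <- model$dec[[i]]
    u <- lvl$tconv$fwd(d, train)
    skip <- feats[[n - i]]
    du <- dim(u)
    cc <- array(0, c(du[1], du[2], 2L * du[3], du[4]))
    cc[, , seq_len(du[3]), ] <- u
    cc[, , du[3] + seq_len(du[3]), ] <- skip
    d <- block_fwd(lvl, cc, train)
    logits[[i]] <- lvl$head$fwd(d, train)
  }
  list(logits = logits, last = d)
}

# Full backward pass through decoder, fusion and encoder given per-level
# logit gradients (ordered as decode_internal's logits). Accumulates
# parameter gradients in the layer environments.
model_backward <- function(model, glogits) {
  n <- model$config$n_stages
  gskip <- vector("list", n)            # gradients flowing into stage feats
  g_d <- NULL
  for (i in rev(seq_len(n - 1L))) {
    lvl <- model$dec[[i]]
    g <- lvl$head$bwd(glogits[[i]])
    if (!is.null(g_d)) g <- g + g_d
    gcc <- block_bwd(lvl, g)
    C <- dim(gcc)[3] / 2L
    gu <- gcc[, , seq_len(C), , drop = FALSE]
    gs <- gcc[, , C + seq_len(C), , drop = FALSE]
    gskip[[n - i]] <- if (is.null(gskip[[n - i]])) gs else gskip[[n - i]] + gs
    g_d <- lvl$tconv$bwd(gu)
  }
  gskip[[n]] <- g_d
  # encoder backward, deep to shallow
  g_next <- NULL
  for (k in (n - 1L):0L) {
    g <- gskip[[k + 1L]]
    if (is.null(g)) g <- 0
    if (!is.null(g_next)) g <- g + g_next
    if (!is.null(model$fusion)) {
      fs <- model$fusion$by_stage[[as.character(k)]]
      if (!is.null(fs)) {
        sp <- fuse_bwd(fs$fuse, g)
        g <- sp$g_nn
        gf <- lora_bwd(fs$flp$lora, sp$g_fnd)
        gf <- freq_adapter_bwd(fs$flp$freq, gf)
        # scale adapter: channel-up conv accumulates its weight gradient;
        # the gradient stops at the frozen foundation encoder
        scale_adapter_bwd(fs$adapter, gf, fs$in_hw[1], fs$in_hw[2])
      }
    }
    g_next <- block_bwd(model$enc[[k + 1L]], g)
  }
  invisible(g_next)
}
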