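# Assembly of the full segmentation model: backbone + optional foundation
# fusion path. The fusion plan maps foundation pyramid outputs onto backbone
# encoder stages: with the default 8-stage/640 px backbone and the default
# multi-scale contract, the (256,128,128) map fuses at stage E3 (as
# (256,80,80)) and the (256,64,64) map, channel-doubled, at the E7
# bottleneck (as (512,5,5)); the single-scale contract fuses at E7 only. The
# earliest high-resolution map is never fused (no early fusion).

is_default_anchor_backbone <- function(cfg) {
  cfg$n_stages == 8L && cfg$base_channels == 32L && cfg$max_channels == 512L &&
    cfg$input_size == 640L
}

fusion_mid_stage <- function(n_stages) {
  deepest <- n_stages - 1L
  if (n_stages - 5L >= 1L) n_stages - 5L else max(1L, deepest - 2L)
}

#' Synthetic foundation contract scaled to a backbone
#'
#' For scaled-down experiments where the default contract shapes do not match
#' the backbone's stage schedule, builds a synthetic (stand-in) contract
#' whose fusable outputs align with the backbone's fusion stages, keeping the
#' same structure as the defaults: the last output feeds the bottleneck
#' through channel doubling, the second-to-last feeds the mid fusion stage at
#' equal channels, and the earliest map is present but never fused.
#'
#' @param config a [backbone_config()].
#' @param variant `"multi_scale"` or `"single_scale"`.
#' @return a [foundation_contract()].
#' @export
scaled_contract <- function(config, variant = c("multi_scale", "single_scale")) {
  variant <- match.arg(variant)
  n <- config$n_stages
  deepest <- n - 1L
  mid <- fusion_mid_stage(n)
  s <- config$input_size
  deep_c <- stage_channels(config, deepest)
  if (deep_c %% 2L != 0L) stop("deepest stage channels must be even")
  if (variant == "single_scale") {
    foundation_contract("single_scale",
                        list(c(deep_c %/% 2L, s %/% 8L, s %/% 8L)))
  } else {
    mid_c <- stage_channels(config, mid)
    foundation_contract("multi_scale",
                        list(c(mid_c, s %/% 2L, s %/% 2L),
                             c(mid_c, s %/% 4L, s %/% 4L),
                             c(deep_c %/% 2L, s %/% 8L, s %/% 8L)))
  }
}

#' Fusion plan: which pyramid output fuses into which encoder stage
#'
#' @param config a [backbone_config()].
#' @param contract a [foundation_contract()].
#' @return list of `list(stage, pyramid_index, target)` entries, where
#'   `target = c(channels, height, width)` is the backbone stage shape.
#' @export
fusion_plan <- function(config, contract) {
  n <- config$n_stages
  deepest <- n - 1L
  np <- length(contract$outputs)
  entry <- function(stage, pidx) {
    tc <- stage_channels(config, stage)
    fc <- contract$outputs[[pidx]][1]
    if (!(tc == fc || tc == 2L * fc))
      stop("contract output ", pidx, " (", fc, " ch) cannot adapt to stage ",
           stage, " (", tc, " ch): channel ratio must be 1 or 2")
    list(stage = stage, pyramid_index = pidx,
         target = c(tc, stage_size(config, stage), stage_size(config, stage)))
  }
  if (contract$variant == "single_scale") {
    list(entry(deepest, np))
  } else {
    if (np < 2L) stop("multi_scale contract needs at least two outputs")
    mid <- fusion_mid_stage(n)
    list(entry(mid, np - 1L), entry(deepest, np))
  }
}

#' Build the full segmentation model
#'
#' @param config a [backbone_config()].
#' @param variant `"baseline"` (no fusion path at all),
#'   `"single_scale_fusion"` or `"multi_scale_fusion"`.
#' @param contract foundation contract; defaults to the standard contract
#'   for the default backbone and to [scaled_contract()] otherwise.
#' @param fl_cfg a [frequency_lora_config()].
#' @param foundation_encoder optional callable `function(batch)` honoring the
#'   contract (returns `list(features = ...)`); defaults to the frozen
#'   deterministic [stub_encoder()].
#' @param stub_seed seed of the stub encoder's fixed projection.
#' @return a `backbone` model handle, with a `fusion` component unless
#'   `variant = "baseline"`.
#' @export
build_seg_model <- function(config,
                            variant = c("multi_scale_fusion",
                                        "single_scale_fusion", "baseline"),
                            contract = NULL,
                            fl_cfg = frequency_lora_config(),
                            foundation_encoder = NULL,
                            stub_seed = 3407L) {
  variant <- match.arg(variant)
  model <- build_backbone(config)
  model$variant <- variant
  if (variant == "baseline") return(model)
  cvar <- if (variant == "single_scale_fusion") "single_scale" else "multi_scale"
  if (is.null(contract)) {
    contract <- if (is_default_anchor_backbone(config))
      foundation_contract(cvar) else scaled_contract(config, cvar)
  }
  stopifnot(contract$variant == cvar)
  plan <- fusion_plan(config, contract)
  by_stage <- list()
  for (p in plan) {
    co <- contract$outputs[[p$pyramid_index]]
    by_stage[[as.character(p$stage)]] <- list(
      pyramid_index = p$pyramid_index,
      in_hw = co[2:3],
      adapter = make_scale_adapter(co[1], p$target[1], p$target[2],
                                   p$target[3]),
      flp = frequency_lora_params(p$target[1], fl_cfg),
      fuse = make_fuse_params(p$target[1]))
  }
  # encoder_fn runs on the internal (H,W,C,B) layout; external plug-ins see
  # the public (B,C,H,W) convention
  encoder_fn <- if (is.null(foundation_encoder)) {
    force(contract); force(stub_seed)
    function(batch) stub_encoder_hwcb(batch, contract, stub_seed)
  } else {
    function(batch) {
      r <- foundation_encoder(hwcb_to_bchw(batch))
      r$features <- lapply(r$features, bchw_to_hwcb)
      r
    }
  }
  model$fusion <- list(contract = contract, plan = plan, by_stage = by_stage,
                       encoder_fn = encoder_fn, fl_cfg = fl_cfg)
  model
}

# all trainable layer environments of a model
model_layers <- function(model) {
  collect_layers(list(model$enc, model$dec,
                      if (!is.null(model$fusion)) model$fusion$by_stage))
}

# forward pass to per-level logits; batch is internal (H,W,C,B)
model_forward <- function(model, batch, train = TRUE) {
  feats <- encode_internal(model, batch, train = train)
  decode_internal(model, feats, train = train)
}

# internal: (H,W,C,B) batch -> (H,W,B) foreground probability
predict_proba_hwcb <- function(model, batch) {
  r <- model_forward(model, batch, train = FALSE)
  p <- softmax_hwcb(r$logits[[length(r$logits)]])
  d <- dim(p)
  out <- p[, , 2L, ]
  dim(out) <- d[c(1, 2, 4)]
  out
}

#' Predict segmentation probabilities for a batch
#'
#' @param model a model from [build_seg_model()].
#' @param batch input `(B, input_channels, H, W)` array.
#' @return foreground probability array `(B, H, W)`.
#' @export
predict_proba <- function(model, batch) {
  p <- predict_proba_hwcb(model, bchw_to_hwcb(batch))
  aperm(p, c(3L, 1L, 2L))
}

# ---- checkpointing ----------------------------------------------------------

#' Save a model checkpoint
#'
#' Serializes all layer parameters with the architecture configuration
#' embedded so the model can be rebuilt on load.
#'
#' @param model a model from [build_seg_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  layers <- model_layers(model)
  obj <- list(config = model$config, variant = model$variant,
              contract = if (!is.null(model$fusion)) model$fusion$contract,
              fl_cfg = if (!is.null(model$fusion)) model$fusion$fl_cfg,
              state = get_state(layers))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return the rebuilt model with restored parameters.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- build_seg_model(obj$config, obj$variant, contract = obj$contract,
                           fl_cfg = if (is.null(obj$fl_cfg))
                             frequency_lora_config() else obj$fl_cfg)
  set_state(model_layers(model), obj$state)
  model
}
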