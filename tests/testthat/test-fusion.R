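test_that("foundation contracts declare the documented shapes", {
  ss <- foundation_contract("single_scale")
  expect_equal(ss$outputs, list(c(256L, 64L, 64L)))
  ms <- foundation_contract("multi_scale")
  expect_equal(ms$outputs, list(c(256L, 256L, 256L), c(256L, 128L, 128L),
                                c(256L, 64L, 64L)))
})

test_that("the stub encoder honors the contract and is deterministic", {
  set.seed(30)
  img <- array(runif(1 * 3 * 64 * 64), c(1, 3, 64, 64))
  ct <- foundation_contract("multi_scale",
                            list(c(8L, 32L, 32L), c(8L, 16L, 16L)))
  a <- stub_encoder(img, ct, seed = 99L)
  expect_length(a$features, 2)
  expect_equal(dim(a$features[[1]]), c(1, 8, 32, 32))
  expect_equal(dim(a$features[[2]]), c(1, 8, 16, 16))
  b <- stub_encoder(img, ct, seed = 99L)
  expect_identical(a$features, b$features)
  # content-dependent: a different image yields different features
  img2 <- array(runif(1 * 3 * 64 * 64), c(1, 3, 64, 64))
  c_ <- stub_encoder(img2, ct, seed = 99L)
  expect_gt(max(abs(a$features[[1]] - c_$features[[1]])), 1e-6)
})

test_that("scale adaptation pools to the target grid and can double channels", {
  set.seed(31)
  x <- array(rnorm(1 * 8 * 16 * 16), c(1, 8, 16, 16))
  y <- scale_adapt(x, c(8L, 10L, 10L))
  expect_equal(dim(y), c(1, 8, 10, 10))
  y2 <- scale_adapt(x, c(16L, 4L, 4L))
  expect_equal(dim(y2), c(1, 16, 4, 4))
  # identity when the target equals the input shape
  y3 <- scale_adapt(x, c(8L, 16L, 16L))
  expect_equal(y3, x, ignore_attr = TRUE)
  expect_error(scale_adapt(x, c(24L, 4L, 4L)), "channel")
  # averaging cannot extend the input's range
  expect_gte(min(y), min(x)); expect_lte(max(y), max(x))
})

test_that("FrequencyLoRA is the identity at initialization", {
  set.seed(32)
  cfg <- frequency_lora_config()   # reduction 8, mu 0.2, rank 4
  expect_equal(cfg$reduction, 8L)
  expect_equal(cfg$mu, 0.2)
  expect_equal(cfg$rank, 4L)
  x <- array(rnorm(1 * 16 * 12 * 12), c(1, 16, 12, 12))
  prm <- frequency_lora_params(16, cfg)
  expect_lt(max(abs(frequency_adapter(x, cfg, prm) - x)), 1e-5)
  expect_lt(max(abs(lora_adapter(x, cfg, prm) - x)), 1e-10)
  expect_lt(max(abs(frequency_lora(x, cfg, prm) - x)), 1e-5)
})

test_that("the frequency adapter reconstructs real signals with negligible imaginary residue", {
  set.seed(33)
  x <- array(rnorm(1 * 4 * 10 * 10), c(1, 4, 10, 10))
  cfg <- frequency_lora_config(reduction = 2)
  prm <- frequency_lora_params(4, cfg)
  # perturb the amplitude MLP so the spectrum actually changes
  prm$freq$mlp2$W <- array(rnorm(length(prm$freq$mlp2$W), 0, 0.1),
                           dim(prm$freq$mlp2$W))
  y <- frequency_adapter(x, cfg, prm)
  expect_lt(attr(y, "max_imag"), 1e-6)
  expect_gt(max(abs(y - x)), 1e-6)   # enhancement is active
  # mu = 0 removes the enhancement entirely
  y0 <- frequency_adapter(x, frequency_lora_config(reduction = 2, mu = 0), prm)
  expect_lt(max(abs(y0 - x)), 1e-5)
})

test_that("the frequency adapter commutes with circular translation", {
  set.seed(34)
  h <- 16
  base <- outer(sin(2 * pi * (1:h) / h), cos(2 * pi * 3 * (1:h) / h))
  x <- array(base, c(1, 1, h, h))
  cfg <- frequency_lora_config(reduction = 1, rank = 1)
  prm <- frequency_lora_params(1, cfg)
  prm$freq$mlp2$W <- array(0.3, dim(prm$freq$mlp2$W))
  shift <- function(m, s) m[c((s + 1):h, 1:s), ]
  y <- frequency_adapter(x, cfg, prm)[1, 1, , ]
  xs <- array(shift(base, 5), c(1, 1, h, h))
  ys <- frequency_adapter(xs, cfg, prm)[1, 1, , ]
  expect_equal(ys, shift(y, 5), tolerance = 1e-8)
})

test_that("LoRA adapter has the stated parameter count and rank guard", {
  cfg <- frequency_lora_config(rank = 4)
  prm <- frequency_lora_params(32, cfg)
  n_lora <- length(prm$lora$down$W) + length(prm$lora$up$W)
  expect_equal(n_lora, 2 * 32 * 4)
  expect_null(prm$lora$down$b)
  expect_error(frequency_lora_params(2, cfg), "rank")
})

test_that("the attention gate scales by exactly 1/4 at zero logits and is bounded", {
  set.seed(35)
  x <- array(rnorm(2 * 16 * 8 * 8), c(2, 16, 8, 8))
  prm <- attention_gate_params(16)
  y <- attention_gate(x, prm)
  expect_equal(y, x / 4, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(dim(y), dim(x))
  # randomize the branch heads: the gate ratio stays inside (0, 1)
  prm$ch_fc2$W <- matrix(rnorm(length(prm$ch_fc2$W)), nrow(prm$ch_fc2$W))
  prm$sp_out$W <- array(rnorm(length(prm$sp_out$W)), dim(prm$sp_out$W))
  y2 <- attention_gate(x, prm)
  ratio <- y2[abs(x) > 1e-8] / x[abs(x) > 1e-8]
  expect_true(all(ratio > 0 & ratio < 1))
  # saturated-high logits pass the input through
  prm$ch_fc2$b <- rep(50, length(prm$ch_fc2$b))
  prm$ch_fc2$W <- matrix(0, nrow(prm$ch_fc2$W), ncol(prm$ch_fc2$W))
  prm$sp_out$b <- rep(50, length(prm$sp_out$b))
  prm$sp_out$W <- array(0, dim(prm$sp_out$W))
  y3 <- attention_gate(x, prm)
  expect_equal(y3, x, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("fuse_stage concatenates, projects back and preserves the stage shape", {
  set.seed(36)
  a <- array(rnorm(1 * 16 * 6 * 6), c(1, 16, 6, 6))
  b <- array(rnorm(1 * 16 * 6 * 6), c(1, 16, 6, 6))
  y <- fuse_stage(a, b)
  expect_equal(dim(y), c(1, 16, 6, 6))
  expect_true(all(is.finite(y)))
  bad <- array(rnorm(1 * 8 * 6 * 6), c(1, 8, 6, 6))
  expect_error(fuse_stage(a, bad), "mismatch")
})

test_that("a fused model reproduces the unfused backbone when the fusion path is silenced", {
  set.seed(37)
  cfg <- tiny_backbone(n_stages = 4, base = 4, input = 32)
  set.seed(101)
  fused <- build_seg_model(cfg, "multi_scale_fusion",
                           foundation_encoder = function(batch) {
                             ct <- scaled_contract(cfg, "multi_scale")
                             list(features = lapply(ct$outputs, function(o)
                               array(0, c(dim(batch)[1], o[1], o[2], o[3]))))
                           })
  set.seed(101)
  plain <- build_seg_model(cfg, "baseline")
  # silence the fusion path: the 1x1 projection passes only backbone
  # channels, the gate is saturated open
  for (fs in fused$fusion$by_stage) {
    C <- dim(fs$fuse$proj$W)[1]
    W <- array(0, dim(fs$fuse$proj$W))
    for (c in seq_len(C)) W[c, c, 1, 1] <- 1
    fs$fuse$proj$W <- W
    fs$fuse$proj$b <- rep(0, C)
    fs$fuse$gate$ch_fc2$b <- rep(50, length(fs$fuse$gate$ch_fc2$b))
    fs$fuse$gate$sp_out$b <- rep(50, length(fs$fuse$gate$sp_out$b))
  }
  x <- array(rnorm(1 * 3 * 32 * 32), c(1, 3, 32, 32))
  rf <- decode(fused, encode(fused, x))
  rp <- decode(plain, encode(plain, x))
  expect_equal(rf$final_logits, rp$final_logits, tolerance = 1e-6)
})

test_that("attention heatmaps threshold, normalize and upsample as specified", {
  w <- matrix(c(0.1, 0.9, 0.4, 0.6), 2, 2)
  img <- export_attention_heatmap(w, out_size = 64, threshold = 0.5)
  expect_equal(dim(img), c(64, 64, 3))
  # the minimum-value corner is black, the maximum is pure red-to-orange
  expect_equal(img[1, 1, ], c(0, 0, 0))
  mx <- which(bilinear_resize(w, 64, 64) == max(bilinear_resize(w, 64, 64)),
              arr.ind = TRUE)[1, ]
  expect_equal(img[mx[1], mx[2], 1], 1)
  expect_equal(img[mx[1], mx[2], 2], 0.65, tolerance = 1e-9)
  # a normalized value just below the threshold renders black
  wv <- matrix(c(0, 1, 0.4, 0.2), 2, 2)
  up <- bilinear_resize(wv, 8, 8)
  hm <- export_attention_heatmap(wv, out_size = 8, threshold = 0.5)
  below <- up < 0.5
  expect_true(all(hm[, , 1][below] == 0))
  # constant map: defined fallback, all black
  hc <- export_attention_heatmap(matrix(0.7, 3, 3), out_size = 16)
  expect_true(all(hc == 0))
})
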