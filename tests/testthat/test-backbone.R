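test_that("the channel and spatial schedules match the stage arithmetic", {
  cfg <- backbone_config()   # defaults: 8 stages, base 32, cap 512, 640 px
  expect_equal(stage_channels(cfg, 0:7),
               c(32, 64, 128, 256, 512, 512, 512, 512))
  expect_equal(stage_size(cfg, 0:7), c(640, 320, 160, 80, 40, 20, 10, 5))
  # anchors: E3 is 256 channels at 80x80; E7 is 512 channels at 5x5
  expect_equal(c(stage_channels(cfg, 3), stage_size(cfg, 3)), c(256, 80))
  expect_equal(c(stage_channels(cfg, 7), stage_size(cfg, 7)), c(512, 5))
  tiny <- backbone_config(n_stages = 4, base_channels = 8, max_channels = 64,
                          input_size = 64)
  expect_equal(stage_channels(tiny, 3), 64)
  expect_equal(stage_size(tiny, 3), 8)
})

test_that("indivisible input sizes are rejected at construction", {
  expect_error(backbone_config(n_stages = 5, input_size = 100),
               "divisible")
})

test_that("encode produces one feature per stage with the scheduled shapes", {
  set.seed(20)
  cfg <- tiny_backbone(n_stages = 4, base = 4, input = 32)
  model <- build_backbone(cfg)
  x <- array(rnorm(2 * 3 * 32 * 32), c(2, 3, 32, 32))
  stages <- encode(model, x)
  expect_length(stages, 4)
  expect_equal(stages[[1]]$stage_index, 0)
  for (k in 0:3) {
    f <- stages[[k + 1]]$feature
    expect_equal(dim(f), c(2, stage_channels(cfg, k), stage_size(cfg, k),
                           stage_size(cfg, k)))
  }
  expect_error(encode(model, array(0, c(1, 3, 16, 16))), "shape")
})

test_that("decode inverts the encoder schedule and emits deep supervision", {
  set.seed(21)
  cfg <- tiny_backbone(n_stages = 4, base = 4, input = 32)
  model <- build_backbone(cfg)
  x <- array(rnorm(1 * 3 * 32 * 32), c(1, 3, 32, 32))
  r <- decode(model, encode(model, x))
  expect_equal(dim(r$final_logits), c(1, 2, 32, 32))
  expect_length(r$ds_outputs, 3)          # one per decoder level
  # the last ds output is the full-resolution head
  expect_equal(dim(r$ds_outputs[[3]]), c(1, 2, 32, 32))
  expect_true(all(is.finite(r$final_logits)))
  # deep supervision off: no auxiliary outputs
  cfg2 <- backbone_config(n_stages = 4, base_channels = 4, max_channels = 64,
                          input_size = 32, deep_supervision = FALSE)
  model2 <- build_backbone(cfg2)
  r2 <- decode(model2, encode(model2, x))
  expect_length(r2$ds_outputs, 0)
  expect_error(decode(model, list()), "expected")
})

test_that("round-trip shape contract holds over random tiny configurations", {
  set.seed(22)
  grid <- list(c(3, 2, 16), c(4, 4, 32), c(5, 2, 32))
  for (g in grid) {
    cfg <- backbone_config(n_stages = g[1], base_channels = g[2],
                           max_channels = 32, input_size = g[3])
    model <- build_backbone(cfg)
    B <- sample(1:2, 1)
    x <- array(rnorm(B * 3 * g[3]^2), c(B, 3, g[3], g[3]))
    r <- decode(model, encode(model, x))
    expect_equal(dim(r$final_logits), c(B, 2, g[3], g[3]))
    expect_true(all(is.finite(r$final_logits)))
  }
})
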