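# Shared fixtures: random binary masks, brute-force metric oracles, and tiny
# model configurations. Everything is generated in code at test time.

random_mask <- function(h = 32, w = h, p = 0.15, min_pixels = 1) {
  repeat {
    m <- matrix(rbinom(h * w, 1, p), h, w)
    if (sum(m) >= min_pixels) return(m)
  }
}

# O(n^2) oracles computed by direct enumeration, independent of the package's
# distance-transform fast path
oracle_counts <- function(pred, gt) {
  tp <- fp <- fn <- inter <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j]; g <- gt[i, j]
    if (p == 1 && g == 1) { tp <- tp + 1; inter <- inter + 1 }
    if (p == 1 && g == 0) fp <- fp + 1
    if (p == 0 && g == 1) fn <- fn + 1
  }
  list(tp = tp, fp = fp, fn = fn, inter = inter,
       np = sum(pred), ng = sum(gt))
}

tiny_backbone <- function(n_stages = 4L, base = 4L, input = 32L,
                          max_channels = 64L) {
  backbone_config(n_stages = n_stages, base_channels = base,
                  max_channels = max_channels, input_channels = 3L,
                  input_size = input, deep_supervision = TRUE)
}

tiny_synth <- function(seed = 11L, image_size = 64L) {
  rmax <- max(2, image_size %/% 12)
  synth_config(image_size = image_size, n_vessels = c(2L, 5L),
               radius_range = c(1, rmax), intensity_fg = 0.9,
               intensity_bg = 0.1, noise_sigma = 0.03,
               max_fg_fraction = 0.05, seed = seed)
}
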