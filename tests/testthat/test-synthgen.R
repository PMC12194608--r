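test_that("generated slices respect the foreground-fraction cap", {
  cfg <- tiny_synth(seed = 5L)
  for (s in 1:8) {
    pair <- generate_slice(cfg, seed = s)
    expect_lte(mean(pair$mask), cfg$max_fg_fraction)
    expect_true(all(pair$mask %in% c(0, 1)))
    expect_equal(dim(pair$image), dim(pair$mask))
  }
})

test_that("vessels are bright: mean intensity inside mask exceeds outside", {
  cfg <- tiny_synth(seed = 7L)
  for (s in 1:5) {
    pair <- generate_slice(cfg, seed = s)
    if (sum(pair$mask) == 0) next
    expect_gt(mean(pair$image[pair$mask == 1]),
              mean(pair$image[pair$mask == 0]))
  }
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- tiny_synth(seed = 3L)
  a <- generate_slice(cfg, seed = 42L)
  b <- generate_slice(cfg, seed = 42L)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  d1 <- generate_dataset(3, 2, cfg)
  d2 <- generate_dataset(3, 2, cfg)
  expect_identical(lapply(d1, `[[`, "image"), lapply(d2, `[[`, "image"))
})

test_that("zero vessels give an empty mask over a noisy background", {
  cfg <- synth_config(image_size = 64, n_vessels = c(0L, 0L),
                      radius_range = c(2, 4), seed = 1L)
  pair <- generate_slice(cfg, seed = 9L)
  expect_equal(sum(pair$mask), 0)
  expect_gt(stats::sd(pair$image), 0)   # noise present
})

test_that("infeasible configurations are rejected", {
  cfg <- synth_config(image_size = 64, n_vessels = c(60L, 80L),
                      radius_range = c(8, 12), max_fg_fraction = 0.02,
                      seed = 1L)
  expect_error(generate_slice(cfg, seed = 1L), "infeasible")
})

test_that("datasets are case-structured with correct counts", {
  cfg <- tiny_synth(seed = 2L)
  ds <- generate_dataset(8, 2, cfg)
  expect_length(ds, 16)
  ids <- vapply(ds, `[[`, character(1), "case_id")
  expect_length(unique(ids), 8)
  expect_true(all(table(ids) == 2))
  one <- generate_dataset(1, 3, cfg)
  expect_length(unique(vapply(one, `[[`, character(1), "case_id")), 1)
})

test_that("PNG writer/reader round-trips images, masks and the manifest", {
  cfg <- tiny_synth(seed = 4L)
  ds <- generate_dataset(2, 2, cfg)
  dir <- withr::local_tempdir()
  manifest <- write_slice_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), 4)
  back <- read_slice_dataset(dir)
  expect_length(back, 4)
  expect_identical(back[[1]]$mask, ds[[1]]$mask)   # masks survive exactly
  # 8-bit quantization: images agree to 1/255
  expect_lt(max(abs(back[[1]]$image - ds[[1]]$image)), 1 / 254)
  expect_equal(back[[3]]$case_id, ds[[3]]$case_id)
})
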