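make_pair <- function(image, mask = NULL, spacing = 1) {
  if (is.null(mask)) mask <- (image > 0.5) * 1
  structure(list(image = image, mask = mask, spacing_mm = spacing,
                 case_id = "case_001", slice_index = 0L),
            class = "slice_pair")
}

test_that("crop_nonzero finds the tight bounding box", {
  img <- matrix(0, 10, 10)
  img[3:6, 4:8] <- 0.7          # rows 3..6, cols 4..8 (1-based)
  pair <- make_pair(img)
  r <- crop_nonzero(pair)
  expect_equal(dim(r$pair$image), c(4, 5))
  expect_equal(unname(r$bbox), c(3, 6, 4, 8))
  expect_equal(dim(r$pair$mask), dim(r$pair$image))
})

test_that("crop_nonzero is the identity on fully non-zero images and idempotent", {
  img <- matrix(runif(36, 0.1, 1), 6, 6)
  pair <- make_pair(img)
  r <- crop_nonzero(pair)
  expect_identical(r$pair$image, img)
  img2 <- matrix(0, 8, 8); img2[2:5, 3:7] <- runif(20, 0.2, 1)
  once <- crop_nonzero(make_pair(img2))
  twice <- crop_nonzero(once$pair)
  expect_identical(once$pair$image, twice$pair$image)
})

test_that("crop_nonzero rejects all-zero images", {
  expect_error(crop_nonzero(make_pair(matrix(0, 5, 5))), "all-zero")
})

test_that("resample scales dimensions by the spacing ratio", {
  set.seed(1)
  img <- matrix(runif(100 * 100), 100, 100)
  pair <- make_pair(img, spacing = 0.6)
  out <- resample(pair, 0.3)
  expect_equal(dim(out$image), c(200, 200))
  expect_equal(out$spacing_mm, 0.3)
  expect_true(all(out$mask %in% c(0, 1)))
})

test_that("resample at the source spacing is the identity", {
  set.seed(2)
  img <- matrix(runif(40 * 30), 40, 30)
  mask <- matrix(rbinom(40 * 30, 1, 0.2), 40, 30)
  pair <- make_pair(img, mask, spacing = 0.7)
  out <- resample(pair, 0.7)
  expect_identical(out$image, img)
  expect_identical(out$mask, mask)
})

test_that("resampled masks stay binary and roughly preserve foreground", {
  set.seed(3)
  mask <- matrix(0, 50, 50); mask[20:30, 15:35] <- 1
  pair <- make_pair(matrix(runif(2500, 0.2, 1), 50, 50), mask, spacing = 1)
  out <- resample(pair, 0.5)
  expect_true(all(out$mask %in% c(0, 1)))
  expect_lt(abs(mean(out$mask) - mean(mask)) / mean(mask), 0.1)
})

test_that("z-score normalization matches its closed forms", {
  img <- matrix(c(0, 2, 0, 2), 2, 2)
  expect_equal(zscore_normalize(img), matrix(c(-1, 1, -1, 1), 2, 2))
  expect_equal(zscore_normalize(matrix(3.7, 4, 4)), matrix(0, 4, 4))
  set.seed(4)
  z <- zscore_normalize(matrix(rnorm(400, 5, 3), 20, 20))
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-6)
})

test_that("augmentation with zero probabilities is the identity", {
  set.seed(5)
  pair <- make_pair(matrix(runif(64), 8, 8))
  aug <- aug_config(p_rotation = 0, p_scale = 0, p_elastic = 0, p_mirror = 0)
  out <- augment(pair, aug, seed = 1L)
  expect_identical(out$image, pair$image)
  expect_identical(out$mask, pair$mask)
})

test_that("mirror flips are exact involutions and preserve foreground", {
  set.seed(6)
  img <- matrix(runif(15 * 15), 15, 15)
  mask <- matrix(rbinom(225, 1, 0.2), 15, 15)
  pair <- make_pair(img, mask)
  aug <- aug_config(p_rotation = 0, p_scale = 0, p_elastic = 0, p_mirror = 1)
  once <- augment(pair, aug, seed = 7L)
  twice <- augment(once, aug, seed = 7L)    # same draws, same flips
  expect_identical(twice$image, pair$image)
  expect_identical(twice$mask, pair$mask)
  expect_equal(sum(once$mask), sum(mask))   # flips preserve pixel counts
  # flips keep mask-conditioned mean intensity unchanged
  if (sum(once$mask) > 0)
    expect_equal(mean(once$image[once$mask == 1]),
                 mean(img[mask == 1]))
})

test_that("rotation and scaling approximately preserve foreground area", {
  set.seed(7)
  mask <- matrix(0, 40, 40); mask[15:25, 12:30] <- 1
  pair <- make_pair(matrix(runif(1600, 0.3, 1), 40, 40), mask)
  aug <- aug_config(p_rotation = 1, p_scale = 1, p_elastic = 0, p_mirror = 0,
                    rotation_deg_range = c(-15, 15),
                    scale_range = c(0.95, 1.05))
  for (s in 1:4) {
    out <- augment(pair, aug, seed = s)
    expect_lt(abs(sum(out$mask) - sum(mask)) / sum(mask), 0.2)
    expect_true(all(out$mask %in% c(0, 1)))
  }
})

test_that("augmentation is deterministic given the seed", {
  set.seed(8)
  pair <- make_pair(matrix(runif(100), 10, 10))
  aug <- aug_config(p_rotation = 1, p_scale = 1, p_elastic = 1, p_mirror = 1)
  a <- augment(pair, aug, seed = 33L)
  b <- augment(pair, aug, seed = 33L)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
})
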