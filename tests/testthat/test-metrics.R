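test_that("dice_iou matches direct pixel enumeration", {
  pred <- matrix(0, 4, 4); pred[1, 1:4] <- 1            # |P| = 4
  gt <- matrix(0, 4, 4); gt[1, 3:4] <- 1; gt[2, 1:2] <- 1  # |G| = 4, overlap 2
  r <- dice_iou(pred, gt)
  expect_equal(r[["dice_pct"]], 50)
  expect_equal(r[["iou_pct"]], 100 / 3, tolerance = 1e-9)
  m <- random_mask(8, 8, 0.3)
  expect_equal(unname(dice_iou(m, m)), c(100, 100))
  a <- matrix(0, 4, 4); a[1, 1] <- 1
  b <- matrix(0, 4, 4); b[4, 4] <- 1
  expect_equal(unname(dice_iou(a, b)), c(0, 0))
  z <- matrix(0, 4, 4)
  expect_equal(unname(dice_iou(z, z)), c(100, 100))
})

test_that("precision/recall/F1 match direct TP/FP/FN counting", {
  gt <- matrix(0, 4, 4); gt[2, 1:4] <- 1
  pred <- matrix(0, 4, 4); pred[2, 1:2] <- 1   # 2 correct of 4 true
  r <- precision_recall_f1(pred, gt)
  expect_equal(r[["precision_pct"]], 100)
  expect_equal(r[["recall_pct"]], 50)
  expect_equal(r[["f1_pct"]], 200 / 3, tolerance = 1e-9)
  m <- random_mask(6, 6, 0.4)
  expect_equal(unname(precision_recall_f1(m, m)), c(100, 100, 100))
  # degenerate empty prediction flagged
  z <- matrix(0, 4, 4)
  rz <- precision_recall_f1(z, gt)
  expect_equal(rz[["precision_pct"]], 0)
  expect_true("precision" %in% attr(rz, "degenerate"))
})

test_that("F1 is numerically identical to Dice on random mask pairs", {
  set.seed(10)
  for (i in 1:200) {
    p <- random_mask(12, 12, runif(1, 0.05, 0.6), min_pixels = 0)
    g <- random_mask(12, 12, runif(1, 0.05, 0.6), min_pixels = 0)
    expect_equal(precision_recall_f1(p, g)[["f1_pct"]],
                 dice_iou(p, g)[["dice_pct"]], tolerance = 1e-9)
  }
})

test_that("Dice dominates IoU with equality only at 0 or 100", {
  set.seed(11)
  for (i in 1:50) {
    p <- random_mask(10, 10, runif(1, 0.1, 0.5))
    g <- random_mask(10, 10, runif(1, 0.1, 0.5))
    r <- dice_iou(p, g)
    expect_gte(r[["dice_pct"]], r[["iou_pct"]] - 1e-12)
    if (abs(r[["dice_pct"]] - r[["iou_pct"]]) < 1e-12)
      expect_true(r[["dice_pct"]] %in% c(0, 100))
  }
})

test_that("surface distances match the Pythagorean single-pixel case", {
  a <- matrix(0, 8, 8); a[1, 1] <- 1
  b <- matrix(0, 8, 8); b[4, 5] <- 1        # offset (3, 4): distance 5
  sd_ <- surface_distances(a, b, spacing_mm = 1)
  expect_equal(sd_$pred_to_gt, 5)
  expect_equal(sd_$gt_to_pred, 5)
  expect_equal(hd95(a, b), 5)
  expect_equal(asd(a, b), 5)
  # linear in spacing
  expect_equal(asd(a, b, spacing_mm = 0.5), 2.5)
  expect_equal(hd95(a, b, spacing_mm = 0.5), 2.5)
})

test_that("identical masks have zero surface distances", {
  m <- random_mask(16, 16, 0.2)
  expect_equal(hd95(m, m), 0)
  expect_equal(asd(m, m), 0)
})

test_that("surface distances are undefined for empty masks", {
  m <- random_mask(8, 8, 0.3)
  z <- matrix(0, 8, 8)
  expect_error(surface_distances(m, z), "empty")
  expect_error(hd95(z, m), "empty")
})

test_that("EDT fast path equals the brute-force oracle", {
  set.seed(12)
  for (i in 1:25) {
    p <- random_mask(24, 24, runif(1, 0.05, 0.4))
    g <- random_mask(24, 24, runif(1, 0.05, 0.4))
    fast <- surface_distances(p, g, method = "edt")
    slow <- surface_distances(p, g, method = "bruteforce")
    expect_equal(sort(fast$pred_to_gt), sort(slow$pred_to_gt),
                 tolerance = 1e-9)
    expect_equal(sort(fast$gt_to_pred), sort(slow$gt_to_pred),
                 tolerance = 1e-9)
  }
})

test_that("pooled HD95 is symmetric; ASD and HD95 are bounded by the exact Hausdorff", {
  set.seed(13)
  for (i in 1:20) {
    p <- random_mask(16, 16, 0.2)
    g <- random_mask(16, 16, 0.2)
    expect_equal(hd95(p, g), hd95(g, p), tolerance = 1e-12)
    hmax <- vesselfuse:::hausdorff_exact(p, g)
    expect_lte(hd95(p, g), hmax + 1e-12)
    expect_lte(asd(p, g), hmax + 1e-12)
  }
  # the directed-percentile convention is also available
  p <- random_mask(16, 16, 0.2); g <- random_mask(16, 16, 0.2)
  expect_true(is.finite(hd95(p, g,
                             convention = "max_of_directed_percentiles")))
})

test_that("metric_report applies the empty-mask policy", {
  m <- random_mask(8, 8, 0.3)
  z <- matrix(0, 8, 8)
  r <- metric_report(z, m)
  expect_equal(r$dice_pct, 0)
  expect_true(is.na(r$hd95_mm))
  expect_true(is.na(r$asd_mm))
  r2 <- metric_report(z, z)
  expect_equal(r2$dice_pct, 100)
})

test_that("macro aggregation uses unweighted means and sample sd", {
  m <- random_mask(8, 8, 0.3)
  r1 <- metric_report(m, m, id = "a")
  s1 <- macro_aggregate(r1)
  expect_equal(s1$mean[s1$metric == "dice_pct"], 100)
  expect_equal(s1$sd[s1$metric == "dice_pct"], 0)
  # two images with Dice 80 and 90: mean 85, sample sd 7.0711
  fake <- rbind(r1, r1)
  fake$dice_pct <- c(80, 90)
  s2 <- macro_aggregate(fake)
  expect_equal(s2$mean[s2$metric == "dice_pct"], 85)
  expect_equal(s2$sd[s2$metric == "dice_pct"], sqrt(50), tolerance = 1e-9)
  # permutation invariance
  s3 <- macro_aggregate(fake[2:1, ])
  expect_equal(s2$mean, s3$mean)
  # undefined surface metrics excluded and counted
  fake$hd95_mm <- c(3, NA)
  s4 <- macro_aggregate(fake)
  expect_equal(s4$mean[s4$metric == "hd95_mm"], 3)
  expect_equal(s4$n_missing[s4$metric == "hd95_mm"], 1)
  expect_error(macro_aggregate(fake[0, ]), "no reports")
})

test_that("boundary extraction marks exactly the 4-connected rim", {
  m <- matrix(0, 7, 7); m[2:6, 2:6] <- 1
  b <- mask_boundary(m)
  expect_equal(sum(b), 16)            # 5x5 block rim
  expect_equal(b[4, 4], 0)            # interior not boundary
  # single pixels are their own boundary
  s <- matrix(0, 5, 5); s[3, 3] <- 1
  expect_equal(mask_boundary(s), s)
  # edge-touching pixels are boundary
  e <- matrix(1, 3, 3)
  expect_equal(sum(mask_boundary(e)), 8)
})
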