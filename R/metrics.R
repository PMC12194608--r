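# Evaluation metrics for binary 2D segmentations: overlap (Dice, IoU),
# pixel-level precision/recall/F1, and surface distances (HD95, ASD) with an
# exact-EDT fast path plus an O(n^2) brute-force oracle, and macro-averaging
# across images.

check_mask_pair <- function(pred, gt) {
  stopifnot(is.matrix(pred), is.matrix(gt), all(dim(pred) == dim(gt)),
            all(pred %in% c(0, 1)), all(gt %in% c(0, 1)))
}

#' Dice and IoU overlap (percent)
#'
#' `Dice = 2|P∩G| / (|P|+|G|) * 100`, `IoU = |P∩G| / |P∪G| * 100`.
#' Two empty masks agree perfectly and score 100/100.
#'
#' @param pred,gt binary matrices of identical shape.
#' @return named numeric vector `c(dice_pct, iou_pct)`.
#' @export
dice_iou <- function(pred, gt) {
  check_mask_pair(pred, gt)
  np <- sum(pred); ng <- sum(gt)
  if (np == 0 && ng == 0) return(c(dice_pct = 100, iou_pct = 100))
  inter <- sum(pred * gt)
  uni <- np + ng - inter
  c(dice_pct = 200 * inter / (np + ng), iou_pct = 100 * inter / uni)
}

#' Pixel-level precision, recall and F1 (percent)
#'
#' Counts TP/FP/FN pixel-wise. A zero denominator yields 0 by convention,
#' flagged in the `"degenerate"` attribute.
#'
#' @inheritParams dice_iou
#' @return named numeric vector `c(precision_pct, recall_pct, f1_pct)`.
#' @export
precision_recall_f1 <- function(pred, gt) {
  check_mask_pair(pred, gt)
  tp <- sum(pred * gt)
  fp <- sum(pred * (1 - gt))
  fn <- sum((1 - pred) * gt)
  degenerate <- character()
  if (tp + fp == 0) degenerate <- c(degenerate, "precision")
  if (tp + fn == 0) degenerate <- c(degenerate, "recall")
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  out <- c(precision_pct = 100 * prec, recall_pct = 100 * rec,
           f1_pct = 100 * f1)
  if (length(degenerate)) attr(out, "degenerate") <- degenerate
  out
}

#' Boundary pixels of a binary mask
#'
#' A mask pixel is a boundary pixel when at least one of its 4-neighbors is
#' background; pixels on the image edge count their outside neighbors as
#' background.
#'
#' @param mask binary matrix.
#' @return binary matrix of the same shape marking boundary pixels.
#' @export
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  core <- pad[2:(h + 1), 2:(w + 1)]
  eroded <- core * pad[1:h, 2:(w + 1)] * pad[3:(h + 2), 2:(w + 1)] *
    pad[2:(h + 1), 1:w] * pad[2:(h + 1), 3:(w + 2)]
  core - eroded
}

#' Directed surface distances between two mask contours
#'
#' For every boundary pixel of each contour, the minimum Euclidean distance
#' (pixel centers, scaled by `spacing_mm`) to the other contour.
#'
#' @inheritParams dice_iou
#' @param spacing_mm isotropic pixel spacing in millimetres.
#' @param method `"edt"` (exact Euclidean distance transform) or
#'   `"bruteforce"` (all-pairs oracle).
#' @return list with numeric vectors `pred_to_gt` and `gt_to_pred` (mm).
#' @export
surface_distances <- function(pred, gt, spacing_mm = 1,
                              method = c("edt", "bruteforce")) {
  method <- match.arg(method)
  check_mask_pair(pred, gt)
  stopifnot(spacing_mm > 0)
  if (sum(pred) == 0 || sum(gt) == 0)
    stop("surface distances are undefined for an empty mask")
  bp <- mask_boundary(pred)
  bg <- mask_boundary(gt)
  pp <- which(bp == 1, arr.ind = TRUE)
  pg <- which(bg == 1, arr.ind = TRUE)
  if (method == "edt") {
    dg <- sqrt(cpp_edt_sq(bg))
    dp <- sqrt(cpp_edt_sq(bp))
    list(pred_to_gt = dg[pp] * spacing_mm,
         gt_to_pred = dp[pg] * spacing_mm)
  } else {
    d_one <- function(a, b) {
      vapply(seq_len(nrow(a)), function(i) {
        sqrt(min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2))
      }, numeric(1))
    }
    list(pred_to_gt = d_one(pp, pg) * spacing_mm,
         gt_to_pred = d_one(pg, pp) * spacing_mm)
  }
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' By default the 95th percentile (linear interpolation, R quantile type 7) of
#' the pooled union of both directed distance multisets — a symmetric
#' convention. `"max_of_directed_percentiles"` takes the maximum of the two
#' directed 95th percentiles instead.
#'
#' @inheritParams surface_distances
#' @param convention `"pooled"` or `"max_of_directed_percentiles"`.
#' @return distance in mm.
#' @export
hd95 <- function(pred, gt, spacing_mm = 1,
                 convention = c("pooled", "max_of_directed_percentiles"),
                 method = c("edt", "bruteforce")) {
  convention <- match.arg(convention)
  sd_ <- surface_distances(pred, gt, spacing_mm, match.arg(method))
  if (convention == "pooled") {
    unname(stats::quantile(c(sd_$pred_to_gt, sd_$gt_to_pred), 0.95, type = 7))
  } else {
    max(stats::quantile(sd_$pred_to_gt, 0.95, type = 7),
        stats::quantile(sd_$gt_to_pred, 0.95, type = 7))
  }
}

#' Average symmetric surface distance (mm)
#'
#' `(sum of directed minima from both contours) / (|∂P| + |∂G|)`.
#'
#' @inheritParams surface_distances
#' @return distance in mm.
#' @export
asd <- function(pred, gt, spacing_mm = 1, method = c("edt", "bruteforce")) {
  sd_ <- surface_distances(pred, gt, spacing_mm, match.arg(method))
  (sum(sd_$pred_to_gt) + sum(sd_$gt_to_pred)) /
    (length(sd_$pred_to_gt) + length(sd_$gt_to_pred))
}

# exact (100th percentile) Hausdorff distance; used in property tests
hausdorff_exact <- function(pred, gt, spacing_mm = 1) {
  sd_ <- surface_distances(pred, gt, spacing_mm)
  max(sd_$pred_to_gt, sd_$gt_to_pred)
}

#' Per-image metric report
#'
#' Computes all evaluation metrics for one prediction/ground-truth pair.
#' When exactly one mask is empty the surface metrics are undefined and
#' reported as `NA`; overlap metrics remain defined.
#'
#' @inheritParams surface_distances
#' @param id optional image identifier carried into the report.
#' @return one-row `data.frame` with columns `id`, `dice_pct`, `iou_pct`,
#'   `hd95_mm`, `asd_mm`, `precision_pct`, `recall_pct`, `f1_pct`.
#' @export
metric_report <- function(pred, gt, spacing_mm = 1, id = NA_character_) {
  di <- dice_iou(pred, gt)
  pr <- precision_recall_f1(pred, gt)
  if (sum(pred) > 0 && sum(gt) > 0) {
    h <- hd95(pred, gt, spacing_mm)
    a <- asd(pred, gt, spacing_mm)
  } else {
    h <- NA_real_; a <- NA_real_
  }
  data.frame(id = id, dice_pct = di[["dice_pct"]], iou_pct = di[["iou_pct"]],
             hd95_mm = h, asd_mm = a,
             precision_pct = pr[["precision_pct"]],
             recall_pct = pr[["recall_pct"]], f1_pct = pr[["f1_pct"]],
             stringsAsFactors = FALSE)
}

#' Macro-average a set of per-image metric reports
#'
#' Unweighted mean and sample standard deviation (n-1) of each metric across
#' images; images whose surface metrics are undefined are excluded from those
#' metrics' aggregation and counted in `n_missing`.
#'
#' @param reports `data.frame` of rows from [metric_report()] (row-bound).
#' @return `data.frame` with one row per metric: `metric`, `mean`, `sd`,
#'   `n`, `n_missing`.
#' @export
macro_aggregate <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  if (NROW(reports) == 0) stop("no reports to aggregate")
  cols <- c("dice_pct", "iou_pct", "hd95_mm", "asd_mm", "precision_pct",
            "recall_pct", "f1_pct")
  out <- lapply(cols, function(cl) {
    v <- reports[[cl]]
    ok <- !is.na(v)
    data.frame(metric = cl,
               mean = mean(v[ok]),
               sd = if (sum(ok) > 1) stats::sd(v[ok]) else 0,
               n = sum(ok), n_missing = sum(!ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
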