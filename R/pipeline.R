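# Training / inference / evaluation orchestration: case-level k-fold CV, SGD
# with Nesterov momentum under a polynomial LR schedule, deep-supervision
# training of the selected variant, ensemble prediction by probability
# averaging, and macro-averaged evaluation.

#' Training configuration
#'
#' @param max_epochs maximum training epochs.
#' @param lr0 initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param nesterov use Nesterov acceleration.
#' @param poly_exponent exponent of the polynomial LR schedule.
#' @param seed global seed (default 3407).
#' @param fold_count number of CV folds.
#' @param variant `"baseline"`, `"single_scale_fusion"` or
#'   `"multi_scale_fusion"`.
#' @param loss a [loss_config()].
#' @param backbone a [backbone_config()].
#' @param batch_size minibatch size.
#' @param aug optional [aug_config()] applied to training slices each epoch;
#'   `NULL` disables augmentation.
#' @return a `train_config` list.
#' @export
train_config <- function(max_epochs = 250L, lr0 = 0.01, momentum = 0.99,
                         weight_decay = 3e-5, nesterov = TRUE,
                         poly_exponent = 0.9, seed = 3407L, fold_count = 5L,
                         variant = c("multi_scale_fusion",
                                     "single_scale_fusion", "baseline"),
                         loss = loss_config(), backbone = backbone_config(),
                         batch_size = 8L, aug = NULL) {
  variant <- match.arg(variant)
  stopifnot(lr0 > 0, momentum >= 0, momentum < 1, fold_count >= 2,
            max_epochs >= 1, batch_size >= 1)
  structure(list(max_epochs = as.integer(max_epochs), lr0 = lr0,
                 momentum = momentum, weight_decay = weight_decay,
                 nesterov = isTRUE(nesterov), poly_exponent = poly_exponent,
                 seed = as.integer(seed), fold_count = as.integer(fold_count),
                 variant = variant, loss = loss, backbone = backbone,
                 batch_size = as.integer(batch_size), aug = aug),
            class = "train_config")
}

#' Load a training configuration from a YAML file
#'
#' The file may contain top-level blocks `train`, `backbone`, `loss`, `aug`
#' and `synth`; each block's entries are passed to the corresponding
#' constructor ([train_config()], [backbone_config()], [loss_config()],
#' [aug_config()], [synth_config()]) on top of its defaults.
#'
#' @param path YAML file path.
#' @return list with elements `train` (a `train_config`) and, when a
#'   `synth` block is present, `synth` (a `synth_config`).
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(block) if (is.null(y[[block]])) list() else y[[block]]
  backbone <- do.call(backbone_config, pick("backbone"))
  loss_args <- pick("loss")
  if (!is.null(loss_args$focal_alpha))
    loss_args$focal_alpha <- as.numeric(loss_args$focal_alpha)
  loss <- do.call(loss_config, loss_args)
  aug <- if (is.null(y$aug)) NULL else do.call(aug_config, y$aug)
  train_args <- pick("train")
  train_args$backbone <- backbone
  train_args$loss <- loss
  train_args$aug <- aug
  out <- list(train = do.call(train_config, train_args))
  if (!is.null(y$synth)) {
    sa <- y$synth
    for (nm in c("n_vessels", "radius_range"))
      if (!is.null(sa[[nm]])) sa[[nm]] <- as.numeric(sa[[nm]])
    out$synth <- do.call(synth_config, sa)
  }
  out
}

#' Case-level k-fold cross-validation splits
#'
#' Folds are defined over case identifiers, never over slices, so slices of
#' one case can never span training and validation. Fold sizes differ by at
#' most one; the split is deterministic given `seed`.
#'
#' @param case_ids character vector of unique case identifiers.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `fold_split` lists: `fold_index`, `train_case_ids`,
#'   `val_case_ids`.
#' @export
make_cv_splits <- function(case_ids, k, seed = 3407L) {
  case_ids <- unique(case_ids)
  if (k > length(case_ids))
    stop("cannot make ", k, " folds from ", length(case_ids), " cases")
  shuffled <- with_seed(seed, sample(case_ids))
  fold_of <- rep(seq_len(k), length.out = length(shuffled))
  lapply(seq_len(k), function(f) {
    structure(list(fold_index = f,
                   train_case_ids = shuffled[fold_of != f],
                   val_case_ids = shuffled[fold_of == f]),
              class = "fold_split")
  })
}

#' Polynomial learning-rate schedule
#'
#' `lr0 * (1 - epoch / max_epochs)^exponent`.
#'
#' @param epoch 0-based epoch, `0 <= epoch <= max_epochs`.
#' @param max_epochs total epochs.
#' @param lr0 initial learning rate.
#' @param exponent polynomial exponent.
#' @return learning rate for the epoch.
#' @export
poly_lr <- function(epoch, max_epochs, lr0, exponent = 0.9) {
  if (epoch < 0 || epoch > max_epochs) stop("epoch out of range")
  lr0 * (1 - epoch / max_epochs)^exponent
}

# slice -> internal (H,W,C,1) network input (z-scored, replicated channels)
slice_to_input <- function(pair, input_channels) {
  img <- zscore_normalize(pair$image)
  x <- array(0, c(nrow(img), ncol(img), input_channels, 1L))
  for (c in seq_len(input_channels)) x[, , c, 1] <- img
  x
}

# internal (H,W,C,B) batch + (H,W,B) targets
make_batch <- function(slices, idx, input_channels) {
  h <- nrow(slices[[idx[1]]]$image); w <- ncol(slices[[idx[1]]]$image)
  B <- length(idx)
  x <- array(0, c(h, w, input_channels, B))
  y <- array(0, c(h, w, B))
  for (i in seq_along(idx)) {
    s <- slices[[idx[i]]]
    x[, , , i] <- slice_to_input(s, input_channels)[, , , 1]
    y[, , i] <- s$mask
  }
  list(x = x, y = y)
}

soft_dice <- function(p, y) {
  (2 * sum(p * y) + DICE_SMOOTH) / (sum(p) + sum(y) + DICE_SMOOTH)
}

#' Train one cross-validation fold
#'
#' Trains the configured variant on the slices of the training cases,
#' validating on the held-out cases once per epoch. The foundation encoder
#' (stub or plug-in) is frozen throughout. Deterministic given `cfg$seed`.
#'
#' @param slices list of `slice_pair` objects (all cases).
#' @param split a `fold_split` from [make_cv_splits()].
#' @param cfg a [train_config()].
#' @param run_dir optional directory for the checkpoint and CSV log.
#' @param contract optional foundation contract override.
#' @param verbose print one line per epoch.
#' @return list with `model`, `log` (per-epoch data.frame), and
#'   `checkpoint` path (or `NA`).
#' @export
train_fold <- function(slices, split, cfg, run_dir = NULL, contract = NULL,
                       verbose = FALSE) {
  case_ids <- vapply(slices, `[[`, character(1), "case_id")
  tr_idx <- which(case_ids %in% split$train_case_ids)
  va_idx <- which(case_ids %in% split$val_case_ids)
  if (length(tr_idx) == 0) stop("empty training split")
  set.seed(derive_seed(cfg$seed, split$fold_index))
  model <- build_seg_model(cfg$backbone, cfg$variant, contract = contract)
  layers <- model_layers(model)
  nc <- cfg$backbone$input_channels
  log_rows <- vector("list", cfg$max_epochs)
  for (epoch in 0:(cfg$max_epochs - 1L)) {
    lr <- poly_lr(epoch, cfg$max_epochs, cfg$lr0, cfg$poly_exponent)
    ord <- sample(tr_idx)
    comp <- c(total = 0, ce = 0, focal = 0, dice = 0)
    nb <- 0L
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      use <- slices[idx]
      if (!is.null(cfg$aug)) {
        use <- lapply(seq_along(use), function(i)
          augment(use[[i]], cfg$aug,
                  seed = derive_seed(cfg$seed, epoch * 100000L + idx[i])))
      }
      batch <- make_batch(use, seq_along(use), nc)
      zero_grads(layers)
      fw <- model_forward(model, batch$x, train = TRUE)
      lg <- deep_supervision_loss_grad(fw$logits, batch$y, cfg$loss)
      model_backward(model, lg$grads)
      sgd_step(layers, lr, cfg$momentum, cfg$weight_decay, cfg$nesterov)
      comp <- comp + c(lg$total, lg$ce, lg$focal, lg$dice)
      nb <- nb + 1L
    }
    comp <- comp / nb
    # per-epoch validation
    vs <- vh <- numeric(0)
    if (length(va_idx)) {
      vs <- vh <- numeric(length(va_idx))
      for (i in seq_along(va_idx)) {
        s <- slices[[va_idx[i]]]
        p <- predict_proba_hwcb(model, slice_to_input(s, nc))[, , 1]
        vs[i] <- soft_dice(p, s$mask)
        vh[i] <- dice_iou((p >= 0.5) * 1, s$mask)[["dice_pct"]]
      }
    }
    log_rows[[epoch + 1L]] <- data.frame(
      epoch = epoch, lr = lr, loss_total = comp[["total"]],
      loss_ce = comp[["ce"]], loss_focal = comp[["focal"]],
      loss_dice = comp[["dice"]],
      val_soft_dice = if (length(vs)) mean(vs) else NA_real_,
      val_dice_pct = if (length(vh)) mean(vh) else NA_real_)
    if (verbose)
      message(sprintf("epoch %3d lr %.5f loss %.4f val_dice %.1f%%",
                      epoch, lr, comp[["total"]],
                      log_rows[[epoch + 1L]]$val_dice_pct))
  }
  log <- do.call(rbind, log_rows)
  ckpt <- NA_character_
  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt <- file.path(run_dir, sprintf("fold_%d.rds", split$fold_index))
    save_checkpoint(model, ckpt)
    utils::write.csv(log, file.path(run_dir,
                                    sprintf("fold_%d_log.csv",
                                            split$fold_index)),
                     row.names = FALSE)
  }
  list(model = model, log = log, checkpoint = ckpt)
}

#' Ensemble prediction by probability averaging
#'
#' Averages the per-pixel foreground probabilities of several trained models
#' (the five fold models, in the full protocol) and thresholds at 0.5.
#'
#' @param checkpoints list of models and/or checkpoint file paths.
#' @param image a `slice_pair`, a 2D matrix, or a prepared input array.
#' @return list with `proba` (matrix) and `mask` (binary matrix).
#' @export
ensemble_predict <- function(checkpoints, image) {
  if (length(checkpoints) == 0) stop("need at least one checkpoint")
  models <- lapply(checkpoints, function(m) {
    if (is.character(m)) load_checkpoint(m) else m
  })
  nc <- models[[1]]$config$input_channels
  x <- if (inherits(image, "slice_pair")) slice_to_input(image, nc)
  else if (is.matrix(image))
    slice_to_input(list(image = image), nc)
  else bchw_to_hwcb(image)
  probs <- lapply(models, function(m) {
    if (m$config$input_channels != nc ||
        !all(dim(x)[1:2] == c(m$config$input_size, m$config$input_size)))
      stop("incompatible checkpoint for this input")
    predict_proba_hwcb(m, x)[, , 1]
  })
  p <- Reduce(`+`, probs) / length(probs)
  list(proba = p, mask = (p >= 0.5) * 1)
}

#' Evaluate predicted masks against ground truth
#'
#' Computes the per-image metric reports and their macro-aggregated summary
#' (mean +/- sd across images).
#'
#' @param pred_masks,gt_masks lists of paired binary matrices; names are
#'   used for pairing when present on both.
#' @param spacing_mm isotropic spacing in mm.
#' @param out_csv optional path; writes per-image rows plus a summary block.
#' @return list with `per_image` and `summary` data.frames.
#' @export
evaluate_run <- function(pred_masks, gt_masks, spacing_mm = 1,
                         out_csv = NULL) {
  if (!is.null(names(pred_masks)) && !is.null(names(gt_masks))) {
    missing_p <- setdiff(names(gt_masks), names(pred_masks))
    missing_g <- setdiff(names(pred_masks), names(gt_masks))
    if (length(missing_p) || length(missing_g))
      stop("unpaired masks: ",
           paste(c(missing_p, missing_g), collapse = ", "))
    pred_masks <- pred_masks[names(gt_masks)]
  }
  if (length(pred_masks) != length(gt_masks))
    stop("prediction and ground-truth counts differ")
  ids <- names(gt_masks)
  if (is.null(ids)) ids <- sprintf("img_%04d", seq_along(gt_masks))
  per <- do.call(rbind, lapply(seq_along(gt_masks), function(i)
    metric_report(pred_masks[[i]], gt_masks[[i]], spacing_mm, id = ids[i])))
  summ <- macro_aggregate(per)
  if (!is.null(out_csv)) {
    utils::write.csv(per, out_csv, row.names = FALSE)
    sfile <- sub("\\.csv$", "_summary.csv", out_csv)
    pretty <- data.frame(metric = summ$metric,
                         mean_sd = sprintf("%.2f ± %.2f", summ$mean,
                                           summ$sd),
                         n = summ$n, n_missing = summ$n_missing)
    utils::write.csv(pretty, sfile, row.names = FALSE)
  }
  list(per_image = per, summary = summ)
}
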