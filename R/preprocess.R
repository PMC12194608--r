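# Preprocessing chain: non-zero ROI crop, spacing resample (cubic spline for
# images, nearest neighbor for masks), per-image z-score normalization, and
# training-time augmentation (rotation, scaling, elastic deformation, mirror
# flips) applying the identical spatial transform to image and mask.

#' Augmentation configuration
#'
#' @param rotation_deg_range rotation angle range in degrees.
#' @param scale_range isotropic zoom range.
#' @param elastic_alpha displacement amplitude (pixels) of the elastic field.
#' @param elastic_sigma Gaussian smoothing sigma (pixels) of the field.
#' @param mirror_axes logical `c(vertical, horizontal)`: which axes may flip.
#' @param p_rotation,p_scale,p_elastic,p_mirror per-transform probabilities.
#' @return an `aug_config` list.
#' @export
aug_config <- function(rotation_deg_range = c(-15, 15),
                       scale_range = c(0.85, 1.15),
                       elastic_alpha = 10, elastic_sigma = 4,
                       mirror_axes = c(TRUE, TRUE),
                       p_rotation = 0.5, p_scale = 0.5, p_elastic = 0.2,
                       p_mirror = 0.5) {
  p <- c(p_rotation, p_scale, p_elastic, p_mirror)
  stopifnot(all(p >= 0), all(p <= 1), length(mirror_axes) == 2)
  structure(list(rotation_deg_range = rotation_deg_range,
                 scale_range = scale_range, elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma, mirror_axes = mirror_axes,
                 p_rotation = p_rotation, p_scale = p_scale,
                 p_elastic = p_elastic, p_mirror = p_mirror),
            class = "aug_config")
}

#' Preprocessing configuration
#'
#' @param target_spacing_mm resampling target; `NULL` keeps the dataset
#'   median spacing (computed by the caller).
#' @param spline_order_image interpolation order for images (3 = cubic).
#' @param do_crop crop to the non-zero region first.
#' @param aug an [aug_config()].
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing_mm = NULL,
                              spline_order_image = 3L, do_crop = TRUE,
                              aug = aug_config()) {
  stopifnot(is.null(target_spacing_mm) || target_spacing_mm > 0)
  structure(list(target_spacing_mm = target_spacing_mm,
                 spline_order_image = as.integer(spline_order_image),
                 do_crop = do_crop, aug = aug),
            class = "preprocess_config")
}

#' Crop a slice to its non-zero bounding box
#'
#' The tight bounding box of strictly non-zero image pixels; the mask is
#' cropped identically and the box is returned for traceability.
#'
#' @param pair a `slice_pair`.
#' @return list with elements `pair` (cropped) and `bbox`
#'   (`c(row_min, row_max, col_min, col_max)`).
#' @export
crop_nonzero <- function(pair) {
  img <- pair$image
  nz <- which(img != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) stop("all-zero image: non-zero ROI is undefined")
  bbox <- c(row_min = min(nz[, 1]), row_max = max(nz[, 1]),
            col_min = min(nz[, 2]), col_max = max(nz[, 2]))
  pair$image <- img[bbox[1]:bbox[2], bbox[3]:bbox[4], drop = FALSE]
  pair$mask <- pair$mask[bbox[1]:bbox[2], bbox[3]:bbox[4], drop = FALSE]
  list(pair = pair, bbox = bbox)
}

# separable natural-cubic-spline sampling of a matrix at fractional positions
spline_resize <- function(img, oh, ow) {
  h <- nrow(img); w <- ncol(img)
  # half-pixel-center mapping, clamped to the grid
  ys <- pmin(pmax((seq_len(oh) - 0.5) * h / oh + 0.5, 1), h)
  xs <- pmin(pmax((seq_len(ow) - 0.5) * w / ow + 0.5, 1), w)
  tmp <- matrix(0, h, ow)
  for (i in seq_len(h)) {
    tmp[i, ] <- stats::splinefun(seq_len(w), img[i, ], method = "natural")(xs)
  }
  out <- matrix(0, oh, ow)
  for (j in seq_len(ow)) {
    out[, j] <- stats::splinefun(seq_len(h), tmp[, j], method = "natural")(ys)
  }
  out
}

nearest_resize_coords <- function(n_in, n_out) {
  pmin(pmax(round((seq_len(n_out) - 0.5) * n_in / n_out + 0.5), 1), n_in)
}

#' Resample a slice to a target pixel spacing
#'
#' Output dimensions are `round(dims * spacing / target)`. The image is
#' interpolated with a cubic spline (separable, natural boundary), the mask
#' with nearest neighbor so it stays binary; the spacing field is updated.
#'
#' @param pair a `slice_pair`.
#' @param target_spacing_mm positive target spacing.
#' @return resampled `slice_pair`.
#' @export
resample <- function(pair, target_spacing_mm) {
  stopifnot(target_spacing_mm > 0, pair$spacing_mm > 0)
  ratio <- pair$spacing_mm / target_spacing_mm
  oh <- max(1L, as.integer(round(nrow(pair$image) * ratio)))
  ow <- max(1L, as.integer(round(ncol(pair$image) * ratio)))
  if (oh == nrow(pair$image) && ow == ncol(pair$image)) {
    pair$spacing_mm <- target_spacing_mm
    return(pair)
  }
  pair$image <- spline_resize(pair$image, oh, ow)
  ri <- nearest_resize_coords(nrow(pair$mask), oh)
  ci <- nearest_resize_coords(ncol(pair$mask), ow)
  pair$mask <- pair$mask[ri, ci, drop = FALSE]
  pair$spacing_mm <- target_spacing_mm
  pair
}

#' Z-score normalize an image
#'
#' Subtracts the mean and divides by the (population) standard deviation over
#' all pixels; constant images map to all zeros.
#'
#' @param image numeric matrix.
#' @return normalized matrix with mean ~0 and sd ~1.
#' @export
zscore_normalize <- function(image) {
  m <- mean(image)
  s <- sqrt(mean((image - m)^2))
  if (s < 1e-12) return(image * 0)
  (image - m) / s
}

# separable Gaussian smoothing with reflected edges
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, min(ceiling(3 * sigma), min(dim(m)) - 1L))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_reflect <- function(v, r) c(rev(v[seq_len(r)]), v,
                                  rev(v[(length(v) - r + 1):length(v)]))
  conv1 <- function(v) {
    p <- pad_reflect(v, r)
    stats::filter(p, k, sides = 2)[(r + 1):(r + length(v))]
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

# inverse-warp sampling: out(i,j) = img(src_y(i,j), src_x(i,j))
warp_sample <- function(img, src_y, src_x, mode = c("bilinear", "nearest"),
                        fill = 0) {
  mode <- match.arg(mode)
  h <- nrow(img); w <- ncol(img)
  if (mode == "nearest") {
    yi <- round(src_y); xi <- round(src_x)
    ok <- yi >= 1 & yi <= h & xi >= 1 & xi <= w
    out <- matrix(fill, nrow(src_y), ncol(src_y))
    out[ok] <- img[cbind(yi[ok], xi[ok])]
    return(out)
  }
  y0 <- floor(src_y); x0 <- floor(src_x)
  wy <- src_y - y0; wx <- src_x - x0
  gv <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    v <- matrix(fill, nrow(yy), ncol(yy))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  gv(y0, x0) * (1 - wy) * (1 - wx) + gv(y0, x0 + 1) * (1 - wy) * wx +
    gv(y0 + 1, x0) * wy * (1 - wx) + gv(y0 + 1, x0 + 1) * wy * wx
}

#' Randomly augment a slice
#'
#' Applies (with configured probabilities) random rotation, isotropic
#' scaling, elastic deformation and mirror flips. Image and mask receive the
#' identical spatial transform; the image is sampled bilinearly, the mask
#' with nearest neighbor so it stays binary. Pure mirror flips are exact
#' array reversals (an involution). Deterministic given `seed`.
#'
#' @param pair a `slice_pair`.
#' @param aug an [aug_config()].
#' @param seed integer seed.
#' @return augmented `slice_pair`.
#' @export
augment <- function(pair, aug = aug_config(), seed = 1L) {
  stopifnot(inherits(aug, "aug_config"))
  with_seed(seed, {
    h <- nrow(pair$image); w <- ncol(pair$image)
    theta <- 0; zoom <- 1; elastic <- FALSE
    if (stats::runif(1) < aug$p_rotation)
      theta <- stats::runif(1, aug$rotation_deg_range[1],
                            aug$rotation_deg_range[2]) * pi / 180
    if (stats::runif(1) < aug$p_scale)
      zoom <- stats::runif(1, aug$scale_range[1], aug$scale_range[2])
    if (stats::runif(1) < aug$p_elastic) elastic <- TRUE
    flips <- c(FALSE, FALSE)
    if (stats::runif(1) < aug$p_mirror)
      flips <- aug$mirror_axes & (stats::runif(2) < 0.5)

    if (theta != 0 || zoom != 1 || elastic) {
      cy <- (h + 1) / 2; cx <- (w + 1) / 2
      gy <- matrix(seq_len(h), h, w) - cy
      gx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
      # inverse map: rotate by -theta, scale by 1/zoom
      src_y <- (cos(theta) * gy - sin(theta) * gx) / zoom + cy
      src_x <- (sin(theta) * gy + cos(theta) * gx) / zoom + cx
      if (elastic) {
        dy <- gaussian_smooth(matrix(stats::rnorm(h * w), h, w),
                              aug$elastic_sigma) * aug$elastic_alpha
        dx <- gaussian_smooth(matrix(stats::rnorm(h * w), h, w),
                              aug$elastic_sigma) * aug$elastic_alpha
        src_y <- src_y + dy; src_x <- src_x + dx
      }
      pair$image <- warp_sample(pair$image, src_y, src_x, "bilinear")
      pair$mask <- warp_sample(pair$mask, src_y, src_x, "nearest")
    }
    if (flips[1]) {
      pair$image <- pair$image[rev(seq_len(h)), , drop = FALSE]
      pair$mask <- pair$mask[rev(seq_len(h)), , drop = FALSE]
    }
    if (flips[2]) {
      pair$image <- pair$image[, rev(seq_len(w)), drop = FALSE]
      pair$mask <- pair$mask[, rev(seq_len(w)), drop = FALSE]
    }
    pair
  })
}

# ---- PNG corpus I/O ---------------------------------------------------------

#' Write a slice dataset as paired PNG files plus a manifest
#'
#' Emits `image_XXXX.png` / `mask_XXXX.png` (8-bit grayscale, mask in
#' \{0, 255\}) and `manifest.csv` with columns `index`, `case_id`,
#' `slice_index`, `spacing_mm`.
#'
#' @param slices list of `slice_pair` objects.
#' @param dir output directory (created if needed).
#' @return the manifest `data.frame`, invisibly.
#' @export
write_slice_dataset <- function(slices, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    png::writePNG(pmin(pmax(s$image, 0), 1),
                  file.path(dir, sprintf("image_%04d.png", i)))
    png::writePNG(s$mask, file.path(dir, sprintf("mask_%04d.png", i)))
    rows[[i]] <- data.frame(index = i, case_id = s$case_id,
                            slice_index = s$slice_index,
                            spacing_mm = s$spacing_mm,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a slice dataset written by [write_slice_dataset()]
#'
#' @param dir dataset directory containing PNGs and `manifest.csv`.
#' @return list of `slice_pair` objects.
#' @export
read_slice_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    img <- png::readPNG(file.path(dir, sprintf("image_%04d.png", r$index)))
    msk <- png::readPNG(file.path(dir, sprintf("mask_%04d.png", r$index)))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    new_slice_pair(img, (msk > 0.5) * 1, r$spacing_mm, r$case_id,
                   r$slice_index)
  })
}
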