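# Synthetic TOF-MRA-like slice generator. Axial TOF-MRA slices show flowing
# blood as small bright quasi-elliptical vessel cross-sections scattered on a
# dark noisy background, with vessels occupying only a few percent of pixels —
# the class-imbalance regime the segmentation method targets. Slices are
# organized into cases (patients) so the case-level CV protocol is testable.

#' Synthetic slice generator configuration
#'
#' @param image_size pixels per side of the square slice.
#' @param n_vessels integer range `c(min, max)` of vessel cross-sections per
#'   slice.
#' @param radius_range range of ellipse semi-axis lengths in pixels.
#' @param intensity_fg,intensity_bg mean vessel / background grayscale in
#'   `[0,1]`.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param max_fg_fraction upper bound on the vessel-pixel proportion.
#' @param spacing_mm isotropic pixel spacing (default 1, so distance metrics
#'   read in pixels unless overridden).
#' @param seed integer seed making the generator deterministic.
#' @return a `synth_config` list.
#' @export
synth_config <- function(image_size = 640L, n_vessels = c(3L, 12L),
                         radius_range = c(2, 12), intensity_fg = 0.85,
                         intensity_bg = 0.12, noise_sigma = 0.04,
                         max_fg_fraction = 0.05, spacing_mm = 1.0,
                         seed = 1L) {
  if (length(n_vessels) == 1L) n_vessels <- rep(n_vessels, 2L)
  stopifnot(image_size >= 16, max_fg_fraction > 0, max_fg_fraction < 1,
            all(radius_range > 0), radius_range[2] < image_size / 4,
            n_vessels[1] >= 0, n_vessels[2] >= n_vessels[1],
            intensity_fg > intensity_bg, noise_sigma >= 0, spacing_mm > 0)
  structure(list(image_size = as.integer(image_size),
                 n_vessels = as.integer(n_vessels),
                 radius_range = radius_range, intensity_fg = intensity_fg,
                 intensity_bg = intensity_bg, noise_sigma = noise_sigma,
                 max_fg_fraction = max_fg_fraction, spacing_mm = spacing_mm,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a slice-specific seed below 2^31
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) * 1000003 + i * 10007 + j * 101) %% 2147483629)
}

new_slice_pair <- function(image, mask, spacing_mm, case_id, slice_index) {
  stopifnot(all(dim(image) == dim(mask)), all(mask %in% c(0, 1)))
  structure(list(image = image, mask = mask, spacing_mm = spacing_mm,
                 case_id = case_id, slice_index = as.integer(slice_index)),
            class = "slice_pair")
}

# subpixel occupancy of one ellipse on a 2x supersampled grid (logical),
# restricted to its bounding box; `occ` is modified by reference semantics of
# the caller (returned).
draw_ellipse_ss <- function(occ, cx, cy, a, b, theta, ss = 2L) {
  n <- nrow(occ)
  rmax <- max(a, b) + 1
  # supersample coordinates are (k - 0.5)/ss in pixel units (1-based pixels)
  lo_r <- max(1L, floor((cy - rmax) * ss)); hi_r <- min(n, ceiling((cy + rmax) * ss))
  lo_c <- max(1L, floor((cx - rmax) * ss)); hi_c <- min(n, ceiling((cx + rmax) * ss))
  if (lo_r > hi_r || lo_c > hi_c) return(occ)
  ys <- ((lo_r:hi_r) - 0.5) / ss
  xs <- ((lo_c:hi_c) - 0.5) / ss
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  occ[lo_r:hi_r, lo_c:hi_c] <- occ[lo_r:hi_r, lo_c:hi_c] | (u * u + v * v <= 1)
  occ
}

# average 2x2 supersample blocks down to per-pixel coverage in [0,1]
coverage_from_ss <- function(occ, ss = 2L) {
  n <- nrow(occ) / ss
  o <- matrix(as.numeric(occ), nrow(occ), ncol(occ))
  idx <- rep(seq_len(n), each = ss)
  cov <- t(rowsum(t(rowsum(o, idx)), idx)) / (ss * ss)
  dimnames(cov) <- NULL
  cov
}

#' Generate one synthetic TOF-MRA-like slice
#'
#' Draws bright anti-aliased elliptical vessel cross-sections (random
#' eccentricity and orientation) on a dark background with additive Gaussian
#' noise clipped to `[0,1]`. The mask marks pixels with blob coverage of at
#' least 0.5. The foreground fraction never exceeds
#' `config$max_fg_fraction`; a configuration whose minimum vessel count
#' cannot fit under that bound is rejected.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; identical seeds give bit-identical slices.
#' @param case_id,slice_index identifiers carried on the slice.
#' @param case_params optional per-case parameter list (see
#'   [generate_dataset()]).
#' @return a `slice_pair`: list with `image`, `mask`, `spacing_mm`,
#'   `case_id`, `slice_index`.
#' @export
generate_slice <- function(config, seed = config$seed, case_id = "case_001",
                           slice_index = 0L, case_params = NULL) {
  stopifnot(inherits(config, "synth_config"))
  S <- config$image_size
  min_area <- config$n_vessels[1] * pi * config$radius_range[1]^2
  if (min_area / S^2 > config$max_fg_fraction)
    stop("infeasible config: minimum vessel count cannot fit under ",
         "max_fg_fraction")
  if (is.null(case_params)) {
    case_params <- list(intensity_fg = config$intensity_fg,
                        intensity_bg = config$intensity_bg,
                        radius_range = config$radius_range,
                        n_vessels = config$n_vessels)
  }
  with_seed(seed, {
    ss <- 2L
    occ <- matrix(FALSE, S * ss, S * ss)
    nv <- if (case_params$n_vessels[2] > case_params$n_vessels[1])
      sample(case_params$n_vessels[1]:case_params$n_vessels[2], 1L)
    else case_params$n_vessels[1]
    budget <- config$max_fg_fraction * S^2
    if (nv > 0) {
      for (v in seq_len(nv)) {
        a <- stats::runif(1, case_params$radius_range[1],
                          case_params$radius_range[2])
        ecc <- stats::runif(1, 0.5, 1)         # semi-axis ratio b/a
        b <- max(a * ecc, case_params$radius_range[1])
        theta <- stats::runif(1, 0, pi)
        margin <- max(a, b) + 1
        cx <- stats::runif(1, margin, S - margin)
        cy <- stats::runif(1, margin, S - margin)
        cand <- draw_ellipse_ss(occ, cx, cy, a, b, theta, ss)
        # enforce the cap on actual mask pixels (coverage >= 0.5), not on
        # subpixel area, so the bound holds exactly
        if (sum(coverage_from_ss(cand, ss) >= 0.5) <= budget) occ <- cand
        else break
      }
    }
    cov <- coverage_from_ss(occ, ss)
    mask <- (cov >= 0.5) * 1
    image <- case_params$intensity_bg +
      (case_params$intensity_fg - case_params$intensity_bg) * cov +
      stats::rnorm(S * S, 0, config$noise_sigma)
    image <- matrix(pmin(pmax(image, 0), 1), S, S)
    new_slice_pair(image, mask, config$spacing_mm, case_id, slice_index)
  })
}

#' Generate a case-structured synthetic dataset
#'
#' Produces `n_cases * slices_per_case` slices. Slices of one case share
#' per-case appearance parameters (intensity and vessel-size jitter drawn
#' once per case), emulating the within-patient correlation of real slice
#' stacks.
#'
#' @param n_cases number of cases (>= 1).
#' @param slices_per_case slices per case (>= 1).
#' @param config a [synth_config()]; `config$seed` fixes the whole dataset.
#' @return list of `slice_pair` objects.
#' @export
generate_dataset <- function(n_cases, slices_per_case, config) {
  stopifnot(n_cases >= 1, slices_per_case >= 1)
  out <- vector("list", n_cases * slices_per_case)
  idx <- 1L
  for (ci in seq_len(n_cases)) {
    case_id <- sprintf("case_%03d", ci)
    cp <- with_seed(derive_seed(config$seed, ci), {
      jitter_fg <- stats::runif(1, -0.05, 0.05)
      jitter_bg <- stats::runif(1, -0.03, 0.03)
      rr <- sort(stats::runif(2, config$radius_range[1],
                              config$radius_range[2]))
      if (diff(rr) < 0.5) rr[2] <- min(rr[1] + 0.5, config$radius_range[2])
      list(intensity_fg = min(max(config$intensity_fg + jitter_fg, 0.5), 1),
           intensity_bg = max(min(config$intensity_bg + jitter_bg, 0.4), 0),
           radius_range = rr,
           n_vessels = config$n_vessels)
    })
    for (si in seq_len(slices_per_case)) {
      out[[idx]] <- generate_slice(config,
                                   seed = derive_seed(config$seed, ci, si),
                                   case_id = case_id, slice_index = si - 1L,
                                   case_params = cp)
      idx <- idx + 1L
    }
  }
  out
}
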