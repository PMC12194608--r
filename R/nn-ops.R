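# Low-level tensor ops and trainable layers.
#
# Public feature maps follow the field convention (B, C, H, W). Internally
# all network code uses the spatial-first layout (H, W, C, B) — column-major
# R then stores each channel plane contiguously, which the C++ convolution
# kernels in src/ops.cpp rely on. Layers are mutable environments exposing
# fwd(x) / bwd(gy); each caches what its backward pass needs when
# `train = TRUE`. Narrow convolutions run direct shift-and-accumulate C++
# kernels; wide ones go through im2col + BLAS GEMM; 1x1 convolutions are
# plain per-sample GEMMs.

as_bchw <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array")
  if (length(d) == 2L) dim(x) <- c(1L, 1L, d[1], d[2])
  else if (length(d) == 3L) dim(x) <- c(1L, d[1], d[2], d[3])
  else if (length(d) != 4L) stop("feature map must have 2-4 dims")
  x
}

# public (B,C,H,W) <-> internal (H,W,C,B)
bchw_to_hwcb <- function(x) aperm(as_bchw(x), c(3L, 4L, 2L, 1L))
hwcb_to_bchw <- function(x) aperm(x, c(4L, 3L, 1L, 2L))

conv_out_dim <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

# ---- layer constructors -----------------------------------------------------

new_layer <- function(params = character()) {
  e <- new.env(parent = emptyenv())
  e$param_names <- params
  e$frozen <- FALSE
  e
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

layer_conv <- function(ci, co, k = 3L, stride = 1L, pad = NULL,
                       bias = TRUE, init = c("he", "zero")) {
  init <- match.arg(init)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  l <- new_layer(if (bias) c("W", "b") else "W")
  l$ci <- ci; l$co <- co; l$k <- as.integer(k)
  l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  fan_in <- ci * k * k
  l$W <- if (init == "zero") array(0, c(co, ci, k, k)) else
    he_init(c(co, ci, k, k), fan_in)
  if (bias) l$b <- numeric(co)
  one_by_one <- (k == 1L && stride == 1L && pad == 0L)
  direct <- !one_by_one && (ci * co <= 1024L)
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    stopifnot(d[3] == l$ci)
    OH <- conv_out_dim(d[1], l$k, l$stride, l$pad)
    OW <- conv_out_dim(d[2], l$k, l$stride, l$pad)
    if (one_by_one) {
      Wm <- matrix(l$W, l$co, l$ci)
      HW <- d[1] * d[2]
      y <- array(0, c(d[1], d[2], l$co, d[4]))
      for (b in seq_len(d[4])) {
        xb <- x[, , , b]
        dim(xb) <- c(HW, l$ci)
        yb <- xb %*% t(Wm)
        if (!is.null(l$b)) yb <- yb + rep(l$b, each = HW)
        y[, , , b] <- yb
      }
      if (train) { l$x <- x; l$xdim <- d } else l$x <- NULL
      return(y)
    }
    if (direct) {
      y <- cpp_conv2d_fwd(x, l$W, if (is.null(l$b)) numeric(0) else l$b,
                          d[1], d[2], d[3], d[4], l$co, l$k, l$stride, l$pad)
      dim(y) <- c(OH, OW, l$co, d[4])
      if (train) { l$x <- x; l$xdim <- d } else l$x <- NULL
      return(y)
    }
    cols <- cpp_im2col(x, d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
    Wm <- matrix(aperm(l$W, c(3L, 4L, 2L, 1L)), l$ci * l$k * l$k, l$co)
    y <- cols %*% Wm
    if (!is.null(l$b)) y <- y + rep(l$b, each = OH * OW * d[4])
    dim(y) <- c(OH, OW, d[4], l$co)
    if (train) { l$cols <- cols; l$xdim <- d } else l$cols <- NULL
    aperm(y, c(1L, 2L, 4L, 3L))
  }
  l$bwd <- function(gy) {
    d <- l$xdim
    dy <- dim(gy)
    if (one_by_one) {
      Wm <- matrix(l$W, l$co, l$ci)
      HW <- d[1] * d[2]
      gx <- array(0, d)
      gW <- matrix(0, l$co, l$ci)
      gb <- numeric(l$co)
      for (b in seq_len(d[4])) {
        gb_m <- gy[, , , b]; dim(gb_m) <- c(HW, l$co)
        xb <- l$x[, , , b]; dim(xb) <- c(HW, l$ci)
        gW <- gW + crossprod(gb_m, xb)
        if (!is.null(l$b)) gb <- gb + colSums(gb_m)
        gx[, , , b] <- gb_m %*% Wm
      }
      l$gW <- array(gW, dim(l$W))
      if (!is.null(l$b)) l$gb <- gb
      l$x <- NULL
      return(gx)
    }
    if (direct) {
      r <- cpp_conv2d_bwd(l$x, l$W, gy, d[1], d[2], d[3], d[4], l$co, l$k,
                          l$stride, l$pad, !is.null(l$b))
      l$gW <- array(r$gw, dim(l$W))
      if (!is.null(l$b)) l$gb <- r$gb
      gx <- r$gx
      dim(gx) <- d
      l$x <- NULL
      return(gx)
    }
    G <- aperm(gy, c(1L, 2L, 4L, 3L))
    dim(G) <- c(dy[1] * dy[2] * dy[4], dy[3])
    gWm <- crossprod(l$cols, G)                       # (CKK, Co)
    dim(gWm) <- c(l$k, l$k, l$ci, l$co)
    l$gW <- aperm(gWm, c(4L, 3L, 1L, 2L))
    if (!is.null(l$b)) l$gb <- colSums(G)
    Wm <- matrix(aperm(l$W, c(3L, 4L, 2L, 1L)), l$ci * l$k * l$k, l$co)
    gcols <- tcrossprod(G, Wm)
    gx <- cpp_col2im(gcols, d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
    dim(gx) <- d
    l$cols <- NULL
    gx
  }
  l
}

# Transposed convolution with kernel == stride (decoder upsampling): doubles
# the spatial size and (in the backbone) halves the channel count.
layer_tconv <- function(ci, co, k = 2L, stride = 2L) {
  stopifnot(k == stride)
  l <- new_layer(c("W", "b"))
  l$ci <- ci; l$co <- co; l$k <- as.integer(k)
  l$W <- he_init(c(ci, co, k, k), ci)
  l$b <- numeric(co)
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    stopifnot(d[3] == l$ci)
    y <- cpp_tconv2d_fwd(x, l$W, l$b, d[1], d[2], d[3], d[4], l$co, l$k)
    dim(y) <- c(d[1] * l$k, d[2] * l$k, l$co, d[4])
    if (train) { l$x <- x; l$xdim <- d } else l$x <- NULL
    y
  }
  l$bwd <- function(gy) {
    d <- l$xdim
    r <- cpp_tconv2d_bwd(l$x, l$W, gy, d[1], d[2], d[3], d[4], l$co, l$k)
    l$gW <- array(r$gw, dim(l$W))
    l$gb <- r$gb
    gx <- r$gx
    dim(gx) <- d
    l$x <- NULL
    gx
  }
  l
}

layer_instancenorm <- function(C, eps = 1e-5) {
  l <- new_layer(c("g", "be"))
  l$C <- C; l$eps <- eps
  l$g <- rep(1, C); l$be <- rep(0, C)
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    HW <- d[1] * d[2]
    m <- x
    dim(m) <- c(HW, d[3] * d[4])
    mu <- colMeans(m)
    xc <- m - rep(mu, each = HW)
    istd <- 1 / sqrt(colMeans(xc * xc) + l$eps)
    xhat <- xc * rep(istd, each = HW)
    y <- xhat * rep(rep(l$g, times = d[4]), each = HW) +
      rep(rep(l$be, times = d[4]), each = HW)
    if (train) { l$xhat <- xhat; l$istd <- istd; l$d <- d }
    dim(y) <- d
    y
  }
  l$bwd <- function(gy) {
    d <- l$d
    HW <- d[1] * d[2]
    gm <- gy
    dim(gm) <- c(HW, d[3] * d[4])
    l$gg <- rowSums(matrix(colSums(gm * l$xhat), d[3], d[4]))
    l$gbe <- rowSums(matrix(colSums(gm), d[3], d[4]))
    gxhat <- gm * rep(rep(l$g, times = d[4]), each = HW)
    gx <- rep(l$istd, each = HW) *
      (gxhat - rep(colMeans(gxhat), each = HW) -
         l$xhat * rep(colMeans(gxhat * l$xhat), each = HW))
    dim(gx) <- d
    l$xhat <- NULL
    gx
  }
  l$grad_name <- c(g = "gg", be = "gbe")
  l
}

layer_relu <- function() {
  l <- new_layer()
  l$fwd <- function(x, train = TRUE) {
    y <- x * (x > 0)
    if (train) l$mask <- (x > 0)
    y
  }
  l$bwd <- function(gy) { gx <- gy * l$mask; l$mask <- NULL; gx }
  l
}

# Dense layer on (B, F) matrices (channel-attention MLP).
layer_linear <- function(fi, fo, bias = TRUE, init = c("he", "zero")) {
  init <- match.arg(init)
  l <- new_layer(if (bias) c("W", "b") else "W")
  l$W <- if (init == "zero") matrix(0, fo, fi) else
    matrix(stats::rnorm(fo * fi, 0, sqrt(2 / fi)), fo, fi)
  if (bias) l$b <- numeric(fo)
  l$fwd <- function(x, train = TRUE) {
    y <- tcrossprod(x, l$W)
    if (!is.null(l$b)) y <- sweep(y, 2L, l$b, "+")
    if (train) l$x <- x
    y
  }
  l$bwd <- function(gy) {
    l$gW <- crossprod(gy, l$x)
    if (!is.null(l$b)) l$gb <- colSums(gy)
    gx <- gy %*% l$W
    l$x <- NULL
    gx
  }
  l
}

# LayerNorm over the feature axis of a (B, F) matrix.
layer_layernorm <- function(F_, eps = 1e-5) {
  l <- new_layer(c("g", "be"))
  l$g <- rep(1, F_); l$be <- rep(0, F_); l$eps <- eps
  l$fwd <- function(x, train = TRUE) {
    mu <- rowMeans(x)
    xc <- x - mu
    istd <- 1 / sqrt(rowMeans(xc * xc) + l$eps)
    xhat <- xc * istd
    if (train) { l$xhat <- xhat; l$istd <- istd }
    sweep(sweep(xhat, 2L, l$g, "*"), 2L, l$be, "+")
  }
  l$bwd <- function(gy) {
    gxhat <- sweep(gy, 2L, l$g, "*")
    l$gg <- colSums(gy * l$xhat)
    l$gbe <- colSums(gy)
    gx <- l$istd * (gxhat - rowMeans(gxhat) - l$xhat * rowMeans(gxhat * l$xhat))
    l$xhat <- NULL
    gx
  }
  l$grad_name <- c(g = "gg", be = "gbe")
  l
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# softmax over the channel axis of an internal (H,W,C,B) tensor
softmax_hwcb <- function(logits) {
  d <- dim(logits)
  if (d[3] == 2L) {
    z0 <- logits[, , 1L, , drop = FALSE]
    z1 <- logits[, , 2L, , drop = FALSE]
    p1 <- 1 / (1 + exp(z0 - z1))
    out <- array(0, d)
    out[, , 1L, ] <- 1 - p1
    out[, , 2L, ] <- p1
    return(out)
  }
  m <- array(-Inf, d[c(1, 2, 4)])
  for (c in seq_len(d[3])) {
    xc <- logits[, , c, , drop = FALSE]; dim(xc) <- d[c(1, 2, 4)]
    m <- pmax(m, xc)
  }
  s <- array(0, d[c(1, 2, 4)])
  z <- array(0, d)
  for (c in seq_len(d[3])) {
    xc <- logits[, , c, , drop = FALSE]; dim(xc) <- d[c(1, 2, 4)]
    e <- exp(xc - m)
    z[, , c, ] <- e
    s <- s + e
  }
  for (c in seq_len(d[3])) z[, , c, ] <- z[, , c, ] / as.numeric(s)
  z
}

# softmax over the channel axis of a public (B,C,H,W) map
softmax_channels <- function(logits) {
  hwcb_to_bchw(softmax_hwcb(bchw_to_hwcb(logits)))
}

# ---- adaptive average pooling ----------------------------------------------

adaptive_bins <- function(n_in, n_out) {
  lo <- floor((0:(n_out - 1)) * n_in / n_out) + 1L
  hi <- ceiling((1:n_out) * n_in / n_out)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

# (n_out x n_in) bin-averaging operator; pooling is a pair of GEMMs and its
# adjoint the transposed pair
pool_operator <- function(n_in, n_out) {
  b <- adaptive_bins(n_in, n_out)
  L <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    idx <- b$lo[i]:b$hi[i]
    L[i, idx] <- 1 / length(idx)
  }
  L
}

# apply operators over the H and W axes of an (H,W,C,B) tensor
apply_sep_ops <- function(x, Lh, Lw) {
  d <- dim(x)
  oh <- nrow(Lh); ow <- nrow(Lw)
  m <- x
  dim(m) <- c(d[1], d[2] * d[3] * d[4])
  m <- Lh %*% m
  dim(m) <- c(oh, d[2], d[3], d[4])
  m <- aperm(m, c(2L, 1L, 3L, 4L))
  dim(m) <- c(d[2], oh * d[3] * d[4])
  m <- Lw %*% m
  dim(m) <- c(ow, oh, d[3], d[4])
  aperm(m, c(2L, 1L, 3L, 4L))
}

adaptive_avgpool <- function(x, oh, ow) {
  d <- dim(x)
  apply_sep_ops(x, pool_operator(d[1], oh), pool_operator(d[2], ow))
}

adaptive_avgpool_bwd <- function(gy, in_h, in_w) {
  d <- dim(gy)
  apply_sep_ops(gy, t(pool_operator(in_h, d[1])), t(pool_operator(in_w, d[2])))
}

# ---- resizing ---------------------------------------------------------------

#' Bilinear resize of a 2D matrix
#'
#' Half-pixel-center convention (`align_corners = FALSE`), matching the usual
#' image-resampling behavior of imaging toolkits.
#'
#' @param img numeric matrix.
#' @param oh,ow output height and width.
#' @return `oh x ow` numeric matrix.
#' @export
bilinear_resize <- function(img, oh, ow) {
  h <- nrow(img); w <- ncol(img)
  ys <- pmin(pmax(((seq_len(oh) - 0.5) * h / oh) - 0.5, 0), h - 1)
  xs <- pmin(pmax(((seq_len(ow) - 0.5) * w / ow) - 0.5, 0), w - 1)
  y0 <- pmin(floor(ys), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(floor(xs), w - 1); x1 <- pmin(x0 + 1, w - 1)
  wy <- ys - y0; wx <- xs - x0
  a <- img[y0 + 1, x0 + 1, drop = FALSE]; b <- img[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- img[y1 + 1, x0 + 1, drop = FALSE]; d <- img[y1 + 1, x1 + 1, drop = FALSE]
  wxm <- matrix(wx, oh, ow, byrow = TRUE)
  top <- a * (1 - wxm) + b * wxm
  bot <- c_ * (1 - wxm) + d * wxm
  top * (1 - matrix(wy, oh, ow)) + bot * matrix(wy, oh, ow)
}

nearest_resize <- function(img, oh, ow) {
  h <- nrow(img); w <- ncol(img)
  yi <- pmin(pmax(floor((seq_len(oh) - 0.5) * h / oh) + 1, 1), h)
  xi <- pmin(pmax(floor((seq_len(ow) - 0.5) * w / ow) + 1, 1), w)
  img[yi, xi, drop = FALSE]
}

# ---- parameter plumbing -----------------------------------------------------

is_layer <- function(x) is.environment(x) && !is.null(x$param_names)

# container environment for composite modules that must cache state by
# reference (lists would lose writes to copy semantics)
module_env <- function(...) list2env(list(...), parent = emptyenv())

# Recursively collect layer environments from nested lists / module envs.
collect_layers <- function(x) {
  if (is_layer(x)) return(list(x))
  if (is.environment(x)) x <- as.list(x)
  if (is.list(x)) return(unlist(lapply(x, collect_layers), recursive = FALSE))
  list()
}

n_params <- function(layers) {
  sum(vapply(layers, function(l) {
    if (l$frozen) return(0)
    sum(vapply(l$param_names, function(nm) length(l[[nm]]), numeric(1)))
  }, numeric(1)))
}

zero_grads <- function(layers) {
  for (l in layers) {
    for (nm in l$param_names) {
      gnm <- if (!is.null(l$grad_name)) l$grad_name[[nm]] else paste0("g", nm)
      l[[gnm]] <- NULL
    }
  }
  invisible(NULL)
}

# SGD with Nesterov momentum: v <- m*v + (g + wd*w); step <- (g + wd*w) + m*v.
sgd_step <- function(layers, lr, momentum = 0.99, weight_decay = 3e-5,
                     nesterov = TRUE) {
  for (l in layers) {
    if (l$frozen) next
    for (nm in l$param_names) {
      gnm <- if (!is.null(l$grad_name)) l$grad_name[[nm]] else paste0("g", nm)
      g <- l[[gnm]]
      if (is.null(g)) next
      d <- g + weight_decay * l[[nm]]
      vnm <- paste0("v", nm)
      v <- l[[vnm]]
      if (is.null(v)) v <- d * 0
      v <- momentum * v + d
      l[[vnm]] <- v
      step <- if (nesterov) d + momentum * v else v
      l[[nm]] <- l[[nm]] - lr * step
    }
  }
  invisible(NULL)
}

get_state <- function(layers) {
  lapply(layers, function(l) mget(l$param_names, envir = l))
}

set_state <- function(layers, state) {
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    for (nm in layers[[i]]$param_names) layers[[i]][[nm]] <- state[[i]][[nm]]
  }
  invisible(NULL)
}

#' @useDynLib vesselfuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
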