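# Rank-3 feature tensors (C x H x W) and the elementary forward
# primitives the pooling/attention blocks are built from: SiLU, zero-
# padded "same" 2-d convolution, and stride-1 max pooling with -Inf
# padding.  All operations are deterministic given weights.

stop_shape <- function(msg) {
  stop(errorCondition(msg, class = c("isdiou_shape_error", "isdiou_error", "error")))
}

#' Validate a feature tensor
#'
#' A feature tensor is a plain numeric array with `dim = c(C, H, W)`
#' (channels, rows, columns) and finite entries.
#'
#' @param values Numeric array.
#' @return The validated array (invisibly unchanged).
#' @export
feature_tensor <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_shape("a feature tensor must be a rank-3 array (C x H x W)")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_shape("feature tensor entries must be finite numbers")
  values
}

#' Sigmoid Linear Unit activation
#'
#' `silu(x) = x * sigmoid(x)`, the activation used after every
#' convolution in the SPPMC block.
#'
#' @param x Numeric.
#' @return Numeric of the same shape.
#' @export
silu <- function(x) x * stats::plogis(x)

sigmoid <- function(x) stats::plogis(x)

relu <- function(x) pmax(x, 0)

#' Stride-1 max pooling with shape-preserving padding
#'
#' Sliding-window maximum over each channel with stride 1 and symmetric
#' half-window padding, so the output shape equals the input shape.
#' Padding behaves as `-Inf`: padded positions never win, hence
#' `kernel = 1` is the identity and the output dominates the input
#' elementwise.
#'
#' @param x A feature tensor (C x H x W array).
#' @param kernel Odd window size, >= 1.
#' @return An array of the same shape as `x`.
#' @export
max_pool_same <- function(x, kernel) {
  x <- feature_tensor(x)
  if (!is.numeric(kernel) || length(kernel) != 1L || kernel < 1 ||
      kernel != as.integer(kernel) || kernel %% 2 == 0)
    stop_usage("'kernel' must be an odd positive integer")
  kernel <- as.integer(kernel)
  if (kernel == 1L) return(x)
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  p <- (kernel - 1L) %/% 2L
  xp <- array(-Inf, c(C, H + 2L * p, W + 2L * p))
  xp[, p + seq_len(H), p + seq_len(W)] <- x
  out <- array(-Inf, d)
  for (i in seq_len(kernel)) {
    for (j in seq_len(kernel)) {
      out <- pmax(out, xp[, (i - 1L) + seq_len(H), (j - 1L) + seq_len(W), drop = FALSE])
    }
  }
  array(out, d)
}

#' Zero-padded "same" 2-d convolution
#'
#' Cross-correlation of a `C x H x W` tensor with a weight array of
#' shape `(out_channels, in_channels, kh, kw)` (odd `kh`, `kw`) and an
#' optional bias, using symmetric zero padding so spatial dimensions are
#' preserved.
#'
#' @param x A feature tensor.
#' @param w Weight array `(O, C, kh, kw)`.
#' @param b Optional bias vector of length `O`.
#' @return An `O x H x W` array.
#' @export
conv2d_same <- function(x, w, b = NULL) {
  x <- feature_tensor(x)
  if (!is.array(w) || length(dim(w)) != 4L)
    stop_shape("conv weights must be a rank-4 array (O x C x kh x kw)")
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  dw <- dim(w); O <- dw[1]
  if (dw[2] != C)
    stop_shape(sprintf("conv expects %d input channels, got %d", dw[2], C))
  kh <- dw[3]; kw <- dw[4]
  if (kh %% 2 == 0 || kw %% 2 == 0)
    stop_usage("conv kernel extents must be odd")
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(C, H + 2L * ph, W + 2L * pw))
  xp[, ph + seq_len(H), pw + seq_len(W)] <- x
  out <- array(0, c(O, H, W))
  for (o in seq_len(O)) {
    acc <- matrix(if (is.null(b)) 0 else b[o], H, W)
    for (ci in seq_len(C)) {
      for (i in seq_len(kh)) {
        for (j in seq_len(kw)) {
          wv <- w[o, ci, i, j]
          if (wv != 0)
            acc <- acc + wv * xp[ci, (i - 1L) + seq_len(H), (j - 1L) + seq_len(W)]
        }
      }
    }
    out[o, , ] <- acc
  }
  out
}

# Concatenate feature tensors along the channel axis.
cat_channels <- function(tensors) {
  dims <- lapply(tensors, dim)
  H <- dims[[1]][2]; W <- dims[[1]][3]
  for (d in dims) if (d[2] != H || d[3] != W)
    stop_shape("cannot concatenate tensors with differing spatial shapes")
  C <- sum(vapply(dims, `[`, integer(1), 1L))
  out <- array(0, c(C, H, W))
  at <- 0L
  for (t in tensors) {
    ct <- dim(t)[1]
    out[at + seq_len(ct), , ] <- t
    at <- at + ct
  }
  out
}

# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
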