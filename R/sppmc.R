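# Forward semantics of the multi-channel spatial-pyramid-pooling block
# (SPPMC).  Six parallel branches feed the fusion stage:
#
#   shortcut : 1x1 conv                          receptive field  1
#   local    : 1x1 -> 3x3 -> 3x3 convs           receptive field  5
#   pool(k)  : stem 1x1 -> 3x3 -> 1x1, then a    receptive field  k + 2
#              stride-1 max pool of kernel k       (7, 11, 15, 19)
#
# for k in the arithmetic kernel ladder 5, 9, 13, 17.  The local and
# pooled branch outputs are concatenated on the channel axis, fused by
# 1x1 -> 3x3 convolutions, re-concatenated with the shortcut, and
# projected back to the input channel count by a final 1x1 conv.  SiLU
# follows every convolution; all spatial operations are stride-1/same,
# so the output spatial shape equals the input's.

#' Structural specification of an SPPMC block
#'
#' @param in_channels Input (and output) channel count.
#' @param hidden_channels Channel count of the internal branches;
#'   defaults to half the input channels.
#' @param pool_kernels Strictly increasing odd pooling kernels.  The
#'   default `c(5, 9, 13, 17)` is an arithmetic ladder of common
#'   difference 4, which yields evenly spaced receptive fields.
#' @return A list of class `"sppmc_spec"`.
#' @export
sppmc_spec <- function(in_channels, hidden_channels = max(1L, in_channels %/% 2L),
                       pool_kernels = c(5L, 9L, 13L, 17L)) {
  in_channels <- as.integer(in_channels)
  hidden_channels <- as.integer(hidden_channels)
  pool_kernels <- as.integer(pool_kernels)
  if (in_channels < 1L || hidden_channels < 1L)
    stop_config("channel counts must be positive")
  if (length(pool_kernels) < 1L || any(pool_kernels %% 2L == 0L))
    stop_config("pool kernels must be odd")
  if (any(diff(pool_kernels) <= 0L))
    stop_config("pool kernels must be strictly increasing")
  structure(list(in_channels = in_channels, hidden_channels = hidden_channels,
                 pool_kernels = pool_kernels),
            class = "sppmc_spec")
}

#' Layer stacks of the SPPMC branches
#'
#' Returns one [layer_stack()] per pre-fusion branch (shortcut, local,
#' and one per pooling kernel), suitable for [receptive_field()].
#'
#' @param spec An [sppmc_spec()].
#' @return Named list of layer stacks.
#' @export
sppmc_branch_layers <- function(spec = sppmc_spec(64L)) {
  stopifnot(inherits(spec, "sppmc_spec"))
  out <- list(shortcut = layer_stack(1L),
              local = layer_stack(c(1L, 3L, 3L)))
  for (k in spec$pool_kernels)
    out[[paste0("pool", k)]] <- layer_stack(c(1L, 3L, 1L, k))
  out
}

#' Per-branch receptive fields of an SPPMC block
#'
#' Folds each branch's layer stack through the receptive-field
#' recurrence.  With the default kernel ladder the result is
#' `{1, 5, 7, 11, 15, 19}`.
#'
#' @inheritParams sppmc_branch_layers
#' @return Named integer vector of receptive fields.
#' @export
sppmc_receptive_fields <- function(spec = sppmc_spec(64L)) {
  vapply(sppmc_branch_layers(spec), receptive_field, integer(1))
}

# One conv's parameters.
conv_param <- function(out_c, in_c, k, init, gen) {
  if (init == "passthrough") {
    w <- array(0, c(out_c, in_c, k, k))
    mid <- (k + 1L) %/% 2L
    for (o in seq_len(out_c)) w[o, ((o - 1L) %% in_c) + 1L, mid, mid] <- 1
    list(w = w, b = rep(0, out_c))
  } else {
    sd <- sqrt(1 / (in_c * k * k))
    list(w = array(gen(out_c * in_c * k * k) * sd, c(out_c, in_c, k, k)),
         b = rep(0, out_c))
  }
}

#' Weights for an SPPMC block
#'
#' `init = "seeded"` draws deterministic uniform weights from `seed`
#' (inference-only; the package trains nothing).  `init =
#' "passthrough"` builds identity-like convolutions (center-tap
#' weight 1) with linear activation, which makes the pooled branches
#' reproduce plain [max_pool_same()] outputs — used to verify the block
#' wiring.
#'
#' @param spec An [sppmc_spec()].
#' @param init `"seeded"` or `"passthrough"`.
#' @param seed Integer seed for the `"seeded"` init.
#' @return A list of class `"sppmc_params"` with one `w`/`b` pair per
#'   convolution and an `activation` field (`"silu"` or `"linear"`).
#' @export
sppmc_params <- function(spec, init = c("seeded", "passthrough"), seed = 1L) {
  stopifnot(inherits(spec, "sppmc_spec"))
  init <- match.arg(init)
  ci <- spec$in_channels
  ch <- if (init == "passthrough") ci else spec$hidden_channels
  np <- length(spec$pool_kernels)
  gen <- NULL
  build <- function() {
    list(
      cv_short = conv_param(ch, ci, 1L, init, gen),
      cv_local1 = conv_param(ch, ci, 1L, init, gen),
      cv_local2 = conv_param(ch, ch, 3L, init, gen),
      cv_local3 = conv_param(ch, ch, 3L, init, gen),
      cv_stem1 = conv_param(ch, ci, 1L, init, gen),
      cv_stem2 = conv_param(ch, ch, 3L, init, gen),
      cv_stem3 = conv_param(ch, ch, 1L, init, gen),
      cv_fuse1 = conv_param(ch, (1L + np) * ch, 1L, init, gen),
      cv_fuse2 = conv_param(ch, ch, 3L, init, gen),
      cv_out = conv_param(ci, 2L * ch, 1L, init, gen),
      hidden = ch,
      activation = if (init == "passthrough") "linear" else "silu"
    )
  }
  params <- if (init == "seeded") {
    gen <- function(n) stats::runif(n, -1, 1)
    with_local_seed(seed, build())
  } else build()
  structure(params, class = "sppmc_params")
}

#' Forward pass of the SPPMC block
#'
#' @param x A feature tensor with `spec$in_channels` channels.
#' @param spec An [sppmc_spec()].
#' @param params An [sppmc_params()] for `spec`.
#' @param return_branches If `TRUE`, also return the six pre-fusion
#'   branch outputs (shortcut, local, one per pool kernel).
#' @return The output tensor (same shape as `x`), or — with
#'   `return_branches = TRUE` — a list with elements `output` and
#'   `branches`.
#' @export
sppmc_forward <- function(x, spec, params, return_branches = FALSE) {
  stopifnot(inherits(spec, "sppmc_spec"), inherits(params, "sppmc_params"))
  x <- feature_tensor(x)
  if (dim(x)[1] != spec$in_channels)
    stop_shape(sprintf("SPPMC expects %d input channels, got %d",
                       spec$in_channels, dim(x)[1]))
  act <- if (identical(params$activation, "linear")) identity else silu
  cv <- function(p, t) act(conv2d_same(t, p$w, p$b))
  shortcut <- cv(params$cv_short, x)
  local <- cv(params$cv_local3, cv(params$cv_local2, cv(params$cv_local1, x)))
  stem <- cv(params$cv_stem3, cv(params$cv_stem2, cv(params$cv_stem1, x)))
  pooled <- lapply(spec$pool_kernels, function(k) max_pool_same(stem, k))
  names(pooled) <- paste0("pool", spec$pool_kernels)
  fused <- cv(params$cv_fuse2,
              cv(params$cv_fuse1, cat_channels(c(list(local), pooled))))
  out <- cv(params$cv_out, cat_channels(list(fused, shortcut)))
  if (return_branches)
    list(output = out, branches = c(list(shortcut = shortcut, local = local), pooled))
  else out
}
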