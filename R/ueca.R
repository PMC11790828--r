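# Forward semantics of the UECA joint attention block: a
# squeeze-excitation (SE) channel branch and a coordinate-attention
# (CA) directional branch run in parallel; the input is gated by each
# branch and the two gated copies are summed.
#
#   SE: z_c  = mean over (i,j) of x_c(i,j)
#       s1   = sigmoid(M1 %*% relu(M2 %*% z))            (C gates)
#   CA: z^h  = row means,  z^w = column means (per channel)
#       v    = relu(F1 [z^h, z^w])  (1x1 channel mixing, C -> C/r_ca)
#       g^h  = sigmoid(Fh v^h),  g^w = sigmoid(Fw v^w)   (C x H, C x W)
#       s2   = g^h (x) g^w   (broadcast product, C x H x W)
#   out: Y  = X (.) s1 + X (.) s2

#' Weights for a UECA block
#'
#' The SE branch squeezes `C -> C / r_se -> C` through `M2` then `M1`;
#' the CA branch reduces `C -> C / r_ca` through the shared 1x1 mixing
#' `F1` and restores `C` through `Fh` / `Fw`.  Both reduction ratios
#' must divide the channel count.  The ReLU nonlinearity sits between
#' the two mixings in each branch; the gates are sigmoids, hence all
#' attention entries lie strictly in (0, 1).
#'
#' @param channels Channel count `C` of the inputs the block will see.
#' @param r_se Reduction ratio of the SE branch (default 16).
#' @param r_ca Reduction ratio of the CA branch (default 32).
#' @param init `"seeded"` (deterministic uniform weights from `seed`)
#'   or `"zero"` (all-zero mixings, so every gate is sigmoid(0) = 1/2).
#' @param seed Integer seed for the `"seeded"` init.
#' @return A list of class `"ueca_params"`.
#' @export
ueca_params <- function(channels, r_se = 16L, r_ca = 32L,
                        init = c("seeded", "zero"), seed = 1L) {
  init <- match.arg(init)
  channels <- as.integer(channels)
  r_se <- as.integer(r_se); r_ca <- as.integer(r_ca)
  if (channels < 1L) stop_config("'channels' must be positive")
  if (r_se < 1L || channels %% r_se != 0L)
    stop_config(sprintf("SE reduction ratio %d must divide the channel count %d",
                        r_se, channels))
  if (r_ca < 1L || channels %% r_ca != 0L)
    stop_config(sprintf("CA reduction ratio %d must divide the channel count %d",
                        r_ca, channels))
  cse <- channels %/% r_se
  cca <- channels %/% r_ca
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc)
    else matrix(stats::runif(nr * nc, -1, 1) * sqrt(1 / nc), nr, nc)
  }
  params <- if (init == "seeded") {
    with_local_seed(seed, list(
      M2 = mk(cse, channels), M1 = mk(channels, cse),
      F1 = mk(cca, channels), Fh = mk(channels, cca), Fw = mk(channels, cca)))
  } else {
    list(M2 = mk(cse, channels), M1 = mk(channels, cse),
         F1 = mk(cca, channels), Fh = mk(channels, cca), Fw = mk(channels, cca))
  }
  params$channels <- channels
  params$r_se <- r_se
  params$r_ca <- r_ca
  structure(params, class = "ueca_params")
}

#' Attention maps of the UECA block
#'
#' Computes the SE channel gates `s1`, the directional coordinate gates
#' `gh` (per channel and row) and `gw` (per channel and column), and
#' their broadcast product `s2`.
#'
#' @param x A feature tensor whose channel count matches `params`.
#' @param params A [ueca_params()].
#' @return A list with elements `z` (per-channel means), `zh`, `zw`
#'   (directional means, `C x H` and `C x W`), `s1` (length-`C` gate
#'   vector), `gh` (`C x H`), `gw` (`C x W`), and `s2` (`C x H x W`).
#' @export
ueca_gates <- function(x, params) {
  stopifnot(inherits(params, "ueca_params"))
  x <- feature_tensor(x)
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  if (C != params$channels)
    stop_shape(sprintf("UECA expects %d channels, got %d", params$channels, C))
  # SE branch: global average pool then two channel mixings
  z <- apply(x, 1L, mean)
  s1 <- as.vector(sigmoid(params$M1 %*% relu(params$M2 %*% z)))
  # CA branch: directional means, shared mixing, directional gates
  zh <- apply(x, c(1L, 2L), mean)           # C x H (row means)
  zw <- apply(x, c(1L, 3L), mean)           # C x W (column means)
  v <- relu(params$F1 %*% cbind(zh, zw))    # (C/r_ca) x (H + W)
  vh <- v[, seq_len(H), drop = FALSE]
  vw <- v[, H + seq_len(W), drop = FALSE]
  gh <- sigmoid(params$Fh %*% vh)           # C x H
  gw <- sigmoid(params$Fw %*% vw)           # C x W
  s2 <- array(0, d)
  for (ci in seq_len(C)) s2[ci, , ] <- outer(gh[ci, ], gw[ci, ])
  list(z = z, zh = zh, zw = zw, s1 = s1,
       gh = unname(as.matrix(gh)), gw = unname(as.matrix(gw)), s2 = s2)
}

#' Combine an input with UECA attention maps
#'
#' `combine = "sum"` (the default attention-gated reading) returns
#' `X (.) s1 + X (.) s2`; `combine = "product"` returns the literal
#' nested form `X (.) (X (.) s1 + X (.) s2)`.
#'
#' @param x A feature tensor.
#' @param s1 Length-`C` channel gate vector.
#' @param s2 `C x H x W` spatial gate array.
#' @param combine `"sum"` or `"product"`.
#' @return A tensor of the same shape as `x`.
#' @export
ueca_combine <- function(x, s1, s2, combine = c("sum", "product")) {
  combine <- match.arg(combine)
  x <- feature_tensor(x)
  d <- dim(x)
  gated <- array(x * as.vector(s1), d) + x * s2   # s1 broadcasts over (H, W)
  if (combine == "sum") gated else x * gated
}

#' Forward pass of the UECA block
#'
#' @inheritParams ueca_gates
#' @param combine `"sum"` (default) or `"product"`, see
#'   [ueca_combine()].
#' @return A tensor of the same shape as `x`.  Under `"sum"` the output
#'   magnitude is bounded by `2 * max(abs(x))` since every gate lies in
#'   (0, 1).
#' @export
ueca_forward <- function(x, params, combine = c("sum", "product")) {
  g <- ueca_gates(x, params)
  ueca_combine(x, g$s1, g$s2, combine)
}
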