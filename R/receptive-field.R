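# Receptive-field arithmetic for stacks of convolution/pooling layers.

#' Describe a stack of layers by kernel and stride
#'
#' @param kernel Integer vector of (odd, positive) kernel extents.
#' @param stride Integer vector of strides (recycled).
#' @return A data frame with columns `kernel`, `stride`.
#' @export
layer_stack <- function(kernel, stride = 1L) {
  if (length(kernel) == 0L) stop_usage("layer stack must not be empty")
  df <- data.frame(kernel = as.integer(kernel), stride = as.integer(stride))
  if (any(df$kernel < 1L) || any(df$stride < 1L))
    stop_usage("kernels and strides must be positive integers")
  df
}

# Parse a CLI-style layer string: "k,s k,s ..." (stride defaults to 1).
parse_layers <- function(text) {
  parts <- strsplit(trimws(text), "[[:space:];]+")[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop_usage("no layers given")
  ks <- lapply(parts, function(p) {
    v <- suppressWarnings(as.integer(strsplit(p, ",")[[1]]))
    if (length(v) < 1L || length(v) > 2L || any(is.na(v)))
      stop_usage(sprintf("cannot parse layer '%s' (expected 'kernel,stride')", p))
    c(v, 1L)[1:2]
  })
  layer_stack(vapply(ks, `[`, integer(1), 1L), vapply(ks, `[`, integer(1), 2L))
}

#' Receptive field of a layer stack
#'
#' Folds the standard recurrence `R_1 = k_1`,
#' `R_n = R_(n-1) + (k_n - 1) * prod(s_1, ..., s_(n-1))` over the
#' layers.  For stride-1 stacks the recurrence degenerates to a sum, so
#' the result is independent of layer order.
#'
#' @param layers A [layer_stack()] (or a data frame/list coercible to
#'   one, or a string like `"1,1 3,1 1,1 17,1"`).
#' @return The receptive field in pixels (a positive integer).
#' @examples
#' receptive_field(layer_stack(c(1, 3, 1, 17)))  # 19
#' @export
receptive_field <- function(layers) {
  if (is.character(layers)) layers <- parse_layers(layers)
  if (is.list(layers) && !is.data.frame(layers))
    layers <- layer_stack(vapply(layers, `[`, numeric(1), 1L),
                          vapply(layers, `[`, numeric(1), 2L))
  if (!is.data.frame(layers) || nrow(layers) == 0L)
    stop_usage("layer stack must not be empty")
  layers <- layer_stack(layers$kernel, layers$stride)
  r <- layers$kernel[1L]
  sp <- 1L
  n <- nrow(layers)
  if (n >= 2L) {
    for (i in 2:n) {
      sp <- sp * layers$stride[i - 1L]
      r <- r + (layers$kernel[i] - 1L) * sp
    }
  }
  as.integer(r)
}
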