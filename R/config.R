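# Run configuration: defaults, YAML loading, flag merging, and range
# validation shared by the command-line interface.

#' Package default configuration
#'
#' A nested list of every tunable parameter with its documented
#' default: the loss hyperparameters (`ratio = 1`, `k = 0.5`,
#' `theta = 4`, `s = 1`, crossed shape-weight pairing), the block
#' settings (pool kernel ladder 5/9/13/17, SE/CA reduction ratios 16
#' and 32, `"sum"` attention combination), the simulator settings, the
#' phantom settings, and the evaluation confidence cut (0.55).
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    loss = list(ratio = 1.0, k = 0.5, theta = 4, s = 1.0,
                shape_weight_pairing = "crossed"),
    blocks = list(pool_kernels = c(5L, 9L, 13L, 17L),
                  r_se = 16L, r_ca = 32L, ueca_combine = "sum"),
    sim = list(n_targets = 49L, n_anchors_per_target = 9L,
               anchor_scatter_radius = 1.5,
               aspect_ratios = c(0.5, 1, 2), scales = c(0.5, 1, 2),
               steps = 200L, step_size = 0.05,
               loss_names = c("iou", "diou", "ciou", "isd")),
    phantoms = list(image_size = 64L, n_images = 10L, max_ellipses = 3L,
                    noise_sd = 0.05),
    eval = list(score_threshold = 0.55)
  )
}

# Recursively merge `over` onto `base`.
merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Validate and normalize a raw configuration mapping
#'
#' Merges the mapping (e.g. parsed from a YAML file) onto
#' [default_config()] and range-checks every bounded parameter: `ratio`
#' in \[0.5, 1.5\], `k` in (0, 1\], `theta` in \[2, 6\], `s >= 0`,
#' strictly increasing odd pool kernels, positive steps/step size.
#' Each violated bound is reported with the offending key and its
#' admissible range, as a config error.
#'
#' @param raw A (possibly partial, possibly empty) named list.
#' @return The fully resolved configuration list, with the loss section
#'   replaced by a validated [isd_config()].
#' @export
validate_config <- function(raw = list()) {
  if (!is.list(raw)) stop_config("configuration must be a mapping")
  cfg <- merge_config(default_config(), raw)
  cfg$loss <- isd_config(ratio = cfg$loss$ratio, k = cfg$loss$k,
                         theta = cfg$loss$theta, s = cfg$loss$s,
                         shape_weight_pairing = cfg$loss$shape_weight_pairing)
  if (!cfg$blocks$ueca_combine %in% c("sum", "product"))
    stop_config("'ueca_combine' must be \"sum\" or \"product\"")
  pk <- cfg$blocks$pool_kernels
  if (any(pk %% 2 == 0) || any(diff(pk) <= 0))
    stop_config("'pool_kernels' must be strictly increasing odd integers")
  cfg$sim <- unclass(sim_config(
    n_targets = cfg$sim$n_targets,
    n_anchors_per_target = cfg$sim$n_anchors_per_target,
    anchor_scatter_radius = cfg$sim$anchor_scatter_radius,
    aspect_ratios = cfg$sim$aspect_ratios, scales = cfg$sim$scales,
    steps = cfg$sim$steps, step_size = cfg$sim$step_size,
    loss_names = cfg$sim$loss_names, isd = cfg$loss, seed = cfg$seed))
  if (cfg$eval$score_threshold < 0 || cfg$eval$score_threshold > 1)
    stop_config("'score_threshold' must lie in [0, 1]")
  cfg
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  raw
}

write_resolved_config <- function(cfg, path) {
  ser <- cfg
  ser$loss <- unclass(ser$loss)
  ser$sim$isd <- NULL
  yaml::write_yaml(ser, path)
  invisible(path)
}
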