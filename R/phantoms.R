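# Synthetic fixtures: procedurally generated grayscale "cardiac MRI"
# phantom images with labeled boxes, plus a detection perturbation
# model.  The phantoms stand in for real cardiac MRI data so that the
# detection metrics are testable without any download; they emulate
# bright elliptical structures on a dark noisy background, with class-
# dependent eccentricity and wall thickness, and make no claim to MRI
# physics.

PHANTOM_CLASSES <- c("NOR", "MINF", "HCM", "DCM", "ARV")

#' Phantom image specification
#'
#' @param image_size Square image side length in pixels.
#' @param n_images Number of images to generate.
#' @param classes Class label vocabulary (default: the five cardiac
#'   diagnosis groups NOR, MINF, HCM, DCM, ARV).
#' @param max_ellipses Each image carries 1 to `max_ellipses` bright
#'   ellipses, each emitting one ground-truth box.
#' @param intensity_range Ellipse brightness range (image background is
#'   0.1).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(image_size = 64L, n_images = 10L,
                         classes = PHANTOM_CLASSES, max_ellipses = 3L,
                         intensity_range = c(0.6, 0.9), noise_sd = 0.05,
                         seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 16L) stop_config("'image_size' must be at least 16 pixels")
  if (n_images < 1L) stop_config("'n_images' must be positive")
  if (max_ellipses < 1L || max_ellipses > 3L)
    stop_config("'max_ellipses' must be in 1..3")
  structure(list(image_size = image_size, n_images = as.integer(n_images),
                 classes = classes, max_ellipses = as.integer(max_ellipses),
                 intensity_range = intensity_range, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Class-conditional ellipse geometry (semi-axes in pixels, relative to
# a 64-px image; scaled with image size).  Classes differ in size,
# eccentricity and wall thickness so they are statistically
# distinguishable:
#   NOR  : medium, near-circular, solid
#   MINF : medium, moderately eccentric, solid
#   HCM  : medium, near-circular, thick bright wall (small dark core)
#   DCM  : large, near-circular, thin wall (large dark core = dilation)
#   ARV  : small, strongly elongated, solid
class_geometry <- function(class, scale) {
  p <- switch(class,
    NOR = list(a = c(6, 9), ecc = c(0.85, 1.00), core = 0),
    MINF = list(a = c(6, 9), ecc = c(0.55, 0.75), core = 0),
    HCM = list(a = c(7, 10), ecc = c(0.85, 1.00), core = 0.35),
    DCM = list(a = c(10, 14), ecc = c(0.85, 1.00), core = 0.75),
    ARV = list(a = c(4, 6), ecc = c(0.40, 0.60), core = 0),
    list(a = c(5, 9), ecc = c(0.6, 1.0), core = 0))
  a <- stats::runif(1, p$a[1], p$a[2]) * scale
  b <- a * stats::runif(1, p$ecc[1], p$ecc[2])
  list(a = a, b = b, core = p$core)
}

#' Generate phantom images with labeled ground-truth boxes
#'
#' Each image is a dark background plus additive Gaussian noise and 1-3
#' bright (possibly hollow) ellipses; the tight axis-aligned box of
#' each ellipse is emitted as a ground-truth record with a class drawn
#' from the five-label vocabulary.  Ellipses whose box would leave the
#' image are resampled, never clipped, so every emitted box lies fully
#' inside the image.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `images` (a list of `image_size x image_size`
#'   matrices with values in \[0, 1\]) and `gts` (ground-truth records;
#'   see [ground_truth_records()]).
#' @export
generate_phantoms <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, {
    sz <- spec$image_size
    scale <- sz / 64
    xs <- matrix(rep(seq_len(sz), each = sz), sz, sz)   # column index
    ys <- matrix(rep(seq_len(sz), times = sz), sz, sz)  # row index
    images <- vector("list", spec$n_images)
    recs <- list()
    for (im in seq_len(spec$n_images)) {
      img <- matrix(0.1, sz, sz) + matrix(stats::rnorm(sz * sz, 0, spec$noise_sd), sz, sz)
      n_ell <- sample.int(spec$max_ellipses, 1L)
      for (e in seq_len(n_ell)) {
        cls <- sample(spec$classes, 1L)
        repeat {
          geom <- class_geometry(cls, scale)
          ang <- stats::runif(1, 0, pi)
          # tight half-extents of the rotated ellipse
          hw <- sqrt((geom$a * cos(ang))^2 + (geom$b * sin(ang))^2)
          hh <- sqrt((geom$a * sin(ang))^2 + (geom$b * cos(ang))^2)
          cx <- stats::runif(1, 1, sz)
          cy <- stats::runif(1, 1, sz)
          if (cx - hw >= 0 && cx + hw <= sz && cy - hh >= 0 && cy + hh <= sz)
            break
        }
        u <- (xs - cx) * cos(ang) + (ys - cy) * sin(ang)
        v <- -(xs - cx) * sin(ang) + (ys - cy) * cos(ang)
        q <- (u / geom$a)^2 + (v / geom$b)^2
        inside <- q <= 1
        if (geom$core > 0) inside <- inside & (q >= geom$core^2)
        img[inside] <- img[inside] +
          stats::runif(1, spec$intensity_range[1], spec$intensity_range[2])
        recs[[length(recs) + 1L]] <- data.frame(
          image_id = sprintf("img%03d", im), class_id = cls,
          cx = cx, cy = cy, w = 2 * hw, h = 2 * hh,
          stringsAsFactors = FALSE)
      }
      images[[im]] <- pmin(pmax(img, 0), 1)
    }
    gts <- do.call(rbind, c(recs, make.row.names = FALSE))
    list(images = images,
         gts = ground_truth_records(gts$image_id, gts$class_id,
                                    gts$cx, gts$cy, gts$w, gts$h))
  })
}

#' Perturb ground truth into scored detections
#'
#' Jitters ground-truth boxes (Gaussian center jitter of sd
#' `sigma_center` pixels; log-normal size jitter of sd `sigma_size`),
#' drops each with probability `drop_rate`, and injects spurious
#' low-score detections at rate `spurious_rate` per ground-truth box.
#' Scores decay with the realized jitter magnitude, so unjittered
#' detections score highest; with all rates and sigmas zero the output
#' is a perfect detector (every detection a TP with score 1).
#'
#' @param gts Ground-truth records.
#' @param sigma_center,sigma_size Jitter standard deviations (>= 0).
#' @param drop_rate,spurious_rate Rates in \[0, 1\].
#' @param image_size Image side length, used to place spurious boxes.
#' @param seed Integer seed.
#' @return Detection records (see [detection_records()]).
#' @export
perturb_detections <- function(gts, sigma_center = 0, sigma_size = 0,
                               drop_rate = 0, spurious_rate = 0,
                               image_size = 64L, seed = 1L) {
  if (sigma_center < 0 || sigma_size < 0)
    stop_config("jitter sigmas must be >= 0")
  if (drop_rate < 0 || drop_rate > 1 || spurious_rate < 0 || spurious_rate > 1)
    stop_config("rates must lie in [0, 1]")
  with_local_seed(seed, {
    n <- nrow(gts)
    keep <- stats::runif(n) >= drop_rate
    out <- list()
    if (any(keep)) {
      g <- gts[keep, , drop = FALSE]
      m <- nrow(g)
      dcx <- stats::rnorm(m, 0, sigma_center)
      dcy <- stats::rnorm(m, 0, sigma_center)
      lw <- stats::rnorm(m, 0, sigma_size)
      lh <- stats::rnorm(m, 0, sigma_size)
      jit <- sqrt(dcx^2 + dcy^2) / pmax(g$w, g$h) + (abs(lw) + abs(lh)) / 2
      out$jittered <- detection_records(
        g$image_id, g$class_id, score = pmin(1, exp(-jit)),
        cx = g$cx + dcx, cy = g$cy + dcy,
        w = g$w * exp(lw), h = g$h * exp(lh))
    }
    n_spur <- stats::rbinom(1L, n, spurious_rate)
    if (n_spur > 0) {
      cls <- sample(unique(gts$class_id), n_spur, replace = TRUE)
      imgs <- sample(unique(gts$image_id), n_spur, replace = TRUE)
      w <- stats::runif(n_spur, 0.1, 0.3) * image_size
      h <- stats::runif(n_spur, 0.1, 0.3) * image_size
      out$spurious <- detection_records(
        imgs, cls, score = stats::runif(n_spur, 0.05, 0.3),
        cx = stats::runif(n_spur, image_size * 0.25, image_size * 0.75),
        cy = stats::runif(n_spur, image_size * 0.25, image_size * 0.75),
        w = w, h = h)
    }
    if (length(out) == 0L)
      return(detection_records(character(0), character(0), numeric(0),
                               numeric(0), numeric(0), numeric(0), numeric(0)))
    do.call(rbind, c(unname(out), make.row.names = FALSE))
  })
}
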