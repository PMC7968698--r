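#' Augmentation configuration
#'
#' Label-preserving transforms applied to training images only: rotation,
#' width/height shifts, multiplicative brightness, horizontal/vertical
#' flips, additive Gaussian noise, and (optionally) feature-wise
#' centering / std normalization fitted on the training split. Defaults
#' are mild (rotation within 15 degrees, shifts within 10% of the tile,
#' brightness in [0.8, 1.2], both flips, noise sd 0.02) and every value is
#' overridable. The default multiplier of 32 expands a training split by
#' roughly the ratio seen in annotated-trap practice (3,078 originals to
#' ~1e5 augmented images).
#'
#' @param rotation_range max absolute rotation in degrees.
#' @param width_shift,height_shift max absolute shift as a fraction of the
#'   tile side.
#' @param brightness_range multiplicative brightness interval.
#' @param horizontal_flip,vertical_flip allow random flips.
#' @param noise_sigma additive Gaussian noise sd.
#' @param featurewise_center,featurewise_std_normalization flags consumed
#'   by the training loop via [fit_feature_stats()].
#' @param multiplier integer >= 1: output images per input image.
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation_range = 15,
                                width_shift = 0.1,
                                height_shift = 0.1,
                                brightness_range = c(0.8, 1.2),
                                horizontal_flip = TRUE,
                                vertical_flip = TRUE,
                                noise_sigma = 0.02,
                                featurewise_center = FALSE,
                                featurewise_std_normalization = FALSE,
                                multiplier = 32L) {
  if (multiplier < 1) stop("multiplier must be >= 1")
  if (rotation_range < 0 || width_shift < 0 || height_shift < 0 || noise_sigma < 0) {
    stop("augmentation ranges must be nonnegative")
  }
  structure(list(rotation_range = rotation_range, width_shift = width_shift,
                 height_shift = height_shift, brightness_range = brightness_range,
                 horizontal_flip = horizontal_flip, vertical_flip = vertical_flip,
                 noise_sigma = noise_sigma, featurewise_center = featurewise_center,
                 featurewise_std_normalization = featurewise_std_normalization,
                 multiplier = as.integer(multiplier)),
            class = "augmentation_config")
}

#' Affine transform of a single tile
#'
#' Rotation about the tile center plus translation, sampled by inverse
#' mapping with bilinear interpolation; exposed borders are filled by edge
#' replication (coordinates clamp to the image), avoiding artificial dark
#' corners. Zero angle and zero shift reproduce the input exactly.
#'
#' @param img numeric matrix.
#' @param angle rotation in degrees (counter-clockwise).
#' @param dy,dx translation in pixels (rows, cols).
#' @param flip_h,flip_v mirror columns / rows (applied before rotation).
#' @return Transformed matrix of the same size.
#' @export
affine_transform <- function(img, angle = 0, dy = 0, dx = 0,
                             flip_h = FALSE, flip_v = FALSE) {
  if (flip_h) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  if (flip_v) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  if (angle == 0 && dy == 0 && dx == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  cy <- (n + 1) / 2; cx <- (m + 1) / 2
  th <- angle * pi / 180
  r <- matrix(rep(seq_len(n), m), n, m) - cy
  c_ <- matrix(rep(seq_len(m), each = n), n, m) - cx
  # inverse map: rotate by -th, then undo the shift
  sy <- cos(th) * r + sin(th) * c_ + cy - dy
  sx <- -sin(th) * r + cos(th) * c_ + cx - dx
  sy <- pmin(pmax(sy, 1), n)
  sx <- pmin(pmax(sx, 1), m)
  y0 <- pmin(floor(sy), n - 1); x0 <- pmin(floor(sx), m - 1)
  fy <- sy - y0; fx <- sx - x0
  at <- function(yy, xx) img[cbind(as.vector(yy), as.vector(xx))]
  v <- (1 - fy) * (1 - fx) * at(y0, x0) +
       (1 - fy) * fx       * at(y0, x0 + 1) +
       fy       * (1 - fx) * at(y0 + 1, x0) +
       fy       * fx       * at(y0 + 1, x0 + 1)
  matrix(v, n, m)
}

#' Augment a training dataset
#'
#' Draws `multiplier` seeded random transforms per input image. Labels are
#' copied unchanged; outputs are clipped to `[0,1]`; identical
#' `(input, cfg, seed)` yields identical output. Only the training split
#' may be augmented: any validation/test image in the input is an error.
#'
#' @param ds a `trap_dataset` whose images all belong to the train split.
#' @param cfg an [augmentation_config()].
#' @param seed integer seed.
#' @return A `trap_dataset` of size `multiplier * dataset_size(ds)` whose
#'   provenance records the source image index.
#' @export
augment_dataset <- function(ds, cfg = augmentation_config(), seed = 1L) {
  stopifnot(inherits(ds, "trap_dataset"), inherits(cfg, "augmentation_config"))
  if (any(ds$split != "train")) {
    stop("augmentation is restricted to the training split")
  }
  n <- dataset_size(ds)
  m <- cfg$multiplier
  out <- array(0, c(TILE, TILE, n * m))
  src <- integer(n * m)
  with_seed(seed, {
    k <- 0L
    for (i in seq_len(n)) {
      img <- ds$images[, , i]
      for (r in seq_len(m)) {
        k <- k + 1L
        a <- if (cfg$rotation_range > 0) stats::runif(1, -cfg$rotation_range, cfg$rotation_range) else 0
        dy <- if (cfg$height_shift > 0) stats::runif(1, -cfg$height_shift, cfg$height_shift) * TILE else 0
        dx <- if (cfg$width_shift > 0) stats::runif(1, -cfg$width_shift, cfg$width_shift) * TILE else 0
        fh <- cfg$horizontal_flip && stats::runif(1) < 0.5
        fv <- cfg$vertical_flip && stats::runif(1) < 0.5
        x <- affine_transform(img, a, dy, dx, fh, fv)
        br <- cfg$brightness_range
        if (!(br[1] == 1 && br[2] == 1)) x <- x * stats::runif(1, br[1], br[2])
        if (cfg$noise_sigma > 0) {
          x <- x + matrix(stats::rnorm(TILE * TILE, 0, cfg$noise_sigma), TILE, TILE)
        }
        out[, , k] <- pmin(pmax(x, 0), 1)
        src[k] <- i
      }
    }
  })
  new_trap_dataset(out, rep(ds$labels, each = m), rep("train", n * m),
                   provenance = data.frame(source = src), params = ds$params)
}

#' Feature-wise centering / standardization statistics
#'
#' `fit_feature_stats` computes the per-pixel mean and standard deviation
#' over a training set; `apply_feature_norm` subtracts the mean and, where
#' the per-pixel sd is positive, divides by it (std-zero pixels are only
#' centered). Statistics must be fitted on the training split alone and
#' then applied unchanged to validation/test images — fitting is the only
#' place data is read.
#'
#' @param ds a `trap_dataset` or a 60 x 60 x n image array.
#' @param x an image matrix or array to normalize.
#' @param stats a fitted object from `fit_feature_stats`.
#' @return `fit_feature_stats`: list of class `feature_stats` with `mean`
#'   and `sd` images; `apply_feature_norm`: normalized image(s).
#' @export
fit_feature_stats <- function(ds) {
  imgs <- if (inherits(ds, "trap_dataset")) ds$images else ds
  stopifnot(length(dim(imgs)) == 3)
  mu <- apply(imgs, c(1, 2), mean)
  sd_ <- apply(imgs, c(1, 2), stats::sd)
  if (dim(imgs)[3] < 2) sd_ <- matrix(0, nrow(mu), ncol(mu))
  structure(list(mean = mu, sd = sd_, fitted = TRUE), class = "feature_stats")
}

#' @rdname fit_feature_stats
#' @export
apply_feature_norm <- function(x, stats) {
  if (!inherits(stats, "feature_stats") || !isTRUE(stats$fitted)) {
    stop("feature statistics have not been fitted")
  }
  denom <- ifelse(stats$sd > 0, stats$sd, 1)
  if (length(dim(x)) == 3) {
    for (i in seq_len(dim(x)[3])) x[, , i] <- (x[, , i] - stats$mean) / denom
    x
  } else {
    (x - stats$mean) / denom
  }
}
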