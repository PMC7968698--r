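#' Scene parameters for the synthetic trap-image generator
#'
#' The generator emulates bright-field sub-images of a single microfluidic
#' yeast-aging trap: a pocket with a wider inlet at the top and a narrower
#' outlet at the bottom, holding a mother cell against the medium flow.
#' Geometry follows the device (inlet 6 um, outlet 3 um, trap height 5 um)
#' rendered at 6 px/um so the trap occupies the central ~2/3 of the 60x60
#' tile. Nuisance structure mimics real acquisitions: Gaussian blur,
#' background brightness variation, oblique shadows, additive noise, and
#' occasional near-transparent cells.
#'
#' @param hard logical; the "hard mode" preset shrinks the daughter offset
#'   and raises blur/noise/shadow levels so trained classifiers are
#'   imperfect and model comparisons are meaningful. Default `FALSE`
#'   ("easy mode": clean, nearly separable images).
#' @param px_per_um pixel pitch of the rendering, default 6.
#' @param mother_radius_range,daughter_radius_range cell radii in pixels;
#'   the daughter upper bound must stay strictly below the mother lower
#'   bound.
#' @param extra_cell_count_range integer range of cells beyond the mother
#'   for crowded (`exC`) scenes; at least 2.
#' @param blur_sigma_range Gaussian blur sigma range in pixels.
#' @param background_level_range background intensity range in `[0,1]`.
#' @param noise_sigma additive Gaussian noise sd (intensity units).
#' @param shadow_probability probability of an oblique shadow field.
#' @param transparent_cell_probability probability that a cell is rendered
#'   near-transparent (weak rim), as seen in real low-contrast frames.
#' @param daughter_gap_scale multiplier (< 1 squeezes) on the
#'   mother-daughter center distance; hard mode lowers it.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(hard = FALSE,
                         px_per_um = 6,
                         mother_radius_range = c(8, 11),
                         daughter_radius_range = c(4, 6),
                         extra_cell_count_range = c(2, 4),
                         blur_sigma_range = if (hard) c(0.6, 1.3) else c(0.3, 0.7),
                         background_level_range = if (hard) c(0.5, 0.78) else c(0.62, 0.7),
                         noise_sigma = if (hard) 0.04 else 0.015,
                         shadow_probability = if (hard) 0.45 else 0.1,
                         transparent_cell_probability = if (hard) 0.1 else 0,
                         daughter_gap_scale = if (hard) 0.95 else 1.1) {
  p <- list(
    hard = hard,
    px_per_um = px_per_um,
    trap_inlet_width = 6 * px_per_um,
    trap_outlet_width = 3 * px_per_um,
    trap_height = 5 * px_per_um,
    mother_radius_range = mother_radius_range,
    daughter_radius_range = daughter_radius_range,
    extra_cell_count_range = extra_cell_count_range,
    blur_sigma_range = blur_sigma_range,
    background_level_range = background_level_range,
    noise_sigma = noise_sigma,
    shadow_probability = shadow_probability,
    transparent_cell_probability = transparent_cell_probability,
    daughter_gap_scale = daughter_gap_scale
  )
  validate_scene_params(p)
  class(p) <- "scene_params"
  p
}

validate_scene_params <- function(p) {
  rng_ok <- function(r) length(r) == 2 && is.finite(r[1]) && is.finite(r[2]) && r[1] <= r[2]
  if (!rng_ok(p$mother_radius_range) || !rng_ok(p$daughter_radius_range) ||
      !rng_ok(p$extra_cell_count_range) || !rng_ok(p$blur_sigma_range) ||
      !rng_ok(p$background_level_range)) {
    stop("degenerate scene parameters: every range needs low <= high")
  }
  if (p$daughter_radius_range[2] >= p$mother_radius_range[1]) {
    stop("daughter radius upper bound must be strictly below mother radius lower bound")
  }
  if (p$extra_cell_count_range[1] < 2) {
    stop("crowded scenes need at least 2 extra cells")
  }
  for (f in c("noise_sigma", "shadow_probability", "transparent_cell_probability")) {
    v <- p[[f]]
    if (!is.finite(v) || v < 0 || v > 1) stop("intensity parameter out of [0,1]: ", f)
  }
  if (any(p$background_level_range < 0) || any(p$background_level_range > 1)) {
    stop("background_level_range must lie within [0,1]")
  }
  invisible(p)
}

# Run expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

TILE <- 60L

# --- low-level rendering -------------------------------------------------

# squared-distance field from each pixel to a segment (r1,c1)-(r2,c2)
segment_dist <- function(rr, cc, r1, c1, r2, c2) {
  vr <- r2 - r1; vc <- c2 - c1
  L2 <- vr * vr + vc * vc
  t <- ((rr - r1) * vr + (cc - c1) * vc) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((rr - (r1 + t * vr))^2 + (cc - (c1 + t * vc))^2)
}

render_trap_walls <- function(p) {
  rr <- matrix(rep(seq_len(TILE), TILE), TILE, TILE)
  cc <- matrix(rep(seq_len(TILE), each = TILE), TILE, TILE)
  mid <- (TILE + 1) / 2
  top <- mid - p$trap_height / 2
  bot <- mid + p$trap_height / 2
  wall <- matrix(0, TILE, TILE)
  for (s in c(-1, 1)) {
    d <- segment_dist(rr, cc,
                      top, mid + s * p$trap_inlet_width / 2,
                      bot, mid + s * p$trap_outlet_width / 2)
    wall <- pmax(wall, pmax(0, 1 - d / 1.8))  # ~2 px soft wall
  }
  wall
}

# anti-aliased ellipse; returns list(shade = additive intensity field,
# mask = logical eroded footprint used for ground truth)
render_cell <- function(cy, cx, r, aspect, theta, transparent) {
  rr <- matrix(rep(seq_len(TILE), TILE), TILE, TILE) - cy
  cc <- matrix(rep(seq_len(TILE), each = TILE), TILE, TILE) - cx
  u <- (cos(theta) * rr + sin(theta) * cc) / r
  v <- (-sin(theta) * rr + cos(theta) * cc) / (r * aspect)
  d <- sqrt(u * u + v * v)              # normalized radial coordinate
  rim_strength <- if (transparent) 0.08 else 0.35
  interior <- if (transparent) 0.02 else 0.08
  rim <- rim_strength * exp(-((d - 1)^2) / (2 * 0.12^2))
  inside <- pmax(0, pmin(1, (1 - d) / 0.15))
  shade <- interior * inside - rim
  list(shade = shade, mask = d < 0.8)
}

gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(img)
  # replicate-pad then 1D convolve along rows and columns
  pad <- function(m) m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
  conv1 <- function(m) {
    mp <- pad(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

# --- scene composition ---------------------------------------------------

draw_range <- function(r) stats::runif(1, r[1], r[2])

# place daughter relative to mother; dir = -1 above (mduC), +1 below (mddC)
place_daughter <- function(my, mx, rm, rd, dir, gap_scale) {
  theta <- stats::runif(1, -0.5, 0.5)             # radians off vertical
  d <- gap_scale * (rm + rd)
  dy <- dir * d * cos(theta)
  if (abs(dy) < rd * 0.6) dy <- dir * rd * 0.6    # keep ordering unambiguous
  c(my + dy, mx + d * sin(theta))
}

#' Generate one labeled synthetic trap scene
#'
#' Renders a 60x60 single-channel image whose cell configuration matches
#' the requested category exactly: `nC` no cells, `mC` a central mother,
#' `mduC`/`mddC` mother plus one daughter strictly above/below her, `exC`
#' mother plus at least two extra cells. Identical `(label, params, seed)`
#' always yields a bit-identical image.
#'
#' @param label one of `category5_levels()`.
#' @param params a [scene_params()] object.
#' @param seed integer seed for this scene.
#' @return A list of class `labeled_image` with fields `image` (60x60
#'   matrix in `[0,1]`), `label`, `mask` (pre-noise logical cell mask used
#'   for ground-truth checks), `cells` (data frame of centers/radii), and
#'   `seed`.
#' @export
generate_scene <- function(label, params = scene_params(), seed = 1L) {
  assert_category5(label)
  if (length(label) != 1) stop("generate_scene draws one scene at a time")
  validate_scene_params(params)
  with_seed(seed, {
    bg <- draw_range(params$background_level_range)
    img <- matrix(bg, TILE, TILE)
    # mild background field (illumination ramp)
    ramp <- stats::runif(1, -0.05, 0.05)
    img <- img + ramp * outer(seq(-1, 1, length.out = TILE),
                              seq(-1, 1, length.out = TILE), function(a, b) (a + b) / 2)
    img <- img - 0.45 * render_trap_walls(params)

    mid <- (TILE + 1) / 2
    cells <- data.frame(y = numeric(0), x = numeric(0), r = numeric(0))
    if (label != "nC") {
      rm_ <- draw_range(params$mother_radius_range)
      my <- mid + stats::runif(1, -2, 2)
      mx <- mid + stats::runif(1, -2, 2)
      cells <- rbind(cells, data.frame(y = my, x = mx, r = rm_))
      if (label %in% c("mduC", "mddC")) {
        rd <- draw_range(params$daughter_radius_range)
        pos <- place_daughter(my, mx, rm_, rd,
                              dir = if (label == "mddC") 1 else -1,
                              gap_scale = params$daughter_gap_scale)
        cells <- rbind(cells, data.frame(y = pos[1], x = pos[2], r = rd))
      } else if (label == "exC") {
        n_extra <- sample(params$extra_cell_count_range[1]:params$extra_cell_count_range[2], 1)
        for (k in seq_len(n_extra)) {
          r <- draw_range(params$daughter_radius_range)
          for (try in 1:200) {
            y <- stats::runif(1, r + 2, TILE - r - 2)
            x <- stats::runif(1, r + 2, TILE - r - 2)
            dist <- sqrt((cells$y - y)^2 + (cells$x - x)^2)
            if (all(dist >= 0.95 * (cells$r + r))) break
          }
          cells <- rbind(cells, data.frame(y = y, x = x, r = r))
        }
      }
    }

    mask <- matrix(FALSE, TILE, TILE)
    for (i in seq_len(nrow(cells))) {
      cell <- render_cell(cells$y[i], cells$x[i], cells$r[i],
                          aspect = stats::runif(1, 0.85, 1.0),
                          theta = stats::runif(1, 0, pi),
                          transparent = stats::runif(1) < params$transparent_cell_probability)
      img <- img + cell$shade
      mask <- mask | cell$mask
    }

    if (stats::runif(1) < params$shadow_probability) {
      ang <- stats::runif(1, 0, 2 * pi)
      strength <- stats::runif(1, 0.05, 0.18)
      grad <- outer(seq(-1, 1, length.out = TILE), seq(-1, 1, length.out = TILE),
                    function(a, b) a * cos(ang) + b * sin(ang))
      img <- img * (1 - strength * (grad + 1) / 2)
    }

    img <- gauss_blur(img, draw_range(params$blur_sigma_range))
    if (params$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(TILE * TILE, 0, params$noise_sigma), TILE, TILE)
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, label = label, mask = mask,
                   cells = cells, seed = as.integer(seed)),
              class = "labeled_image")
  })
}

# largest-remainder-free stratified split sizes: boundaries rounded so each
# split count is within 1 of the exact proportion
split_sizes <- function(n, fractions) {
  b <- round(cumsum(fractions) * n)
  diff(c(0, b))
}

#' Generate a labeled synthetic dataset with train/val/test splits
#'
#' Draws `per_class_counts[cat]` scenes per category under `params`, then
#' assigns them to disjoint, exhaustive, per-category stratified splits.
#' The defaults mirror the real dataset's size: 1,000 images per category
#' and a 3078/1026/896 train/validation/test partition (fractions
#' 0.6156/0.2052/0.1792 of 5,000).
#'
#' @param per_class_counts named integer vector over `category5_levels()`;
#'   a single unnamed number is recycled to all five categories.
#' @param params a [scene_params()] object.
#' @param split_fractions numeric length-3 `(train, val, test)`,
#'   nonnegative, summing to 1 within 1e-6.
#' @param seed master seed; each scene receives a derived sub-seed so the
#'   whole dataset is reproducible.
#' @param keep_masks retain pre-noise ground-truth masks (for invariant
#'   checks); default `TRUE`.
#' @return A `trap_dataset`: list with `images` (60 x 60 x N array),
#'   `labels` (character), `split` (character in train/val/test), `masks`
#'   (logical array or `NULL`), and `provenance` (data frame with the
#'   per-scene seed and draw index).
#' @export
generate_dataset <- function(per_class_counts = 1000,
                             params = scene_params(),
                             split_fractions = c(3078, 1026, 896) / 5000,
                             seed = 1L,
                             keep_masks = TRUE) {
  lv <- category5_levels()
  if (length(per_class_counts) == 1 && is.null(names(per_class_counts))) {
    per_class_counts <- stats::setNames(rep(per_class_counts, 5), lv)
  }
  if (!all(names(per_class_counts) %in% lv)) stop("unknown category in counts")
  counts <- stats::setNames(rep(0L, 5), lv)
  counts[names(per_class_counts)] <- as.integer(per_class_counts)
  if (any(counts < 0)) stop("per-class counts must be >= 0")
  if (length(split_fractions) != 3 || any(split_fractions < 0) ||
      abs(sum(split_fractions) - 1) > 1e-6) {
    stop("split fractions must be nonnegative and sum to 1")
  }
  n <- sum(counts)
  images <- array(0, c(TILE, TILE, n))
  masks <- if (keep_masks) array(FALSE, c(TILE, TILE, n)) else NULL
  labels <- character(n)
  split <- character(n)
  prov <- data.frame(seed = integer(n), draw = integer(n))
  idx <- 0L
  with_seed(seed, {
    for (cat in lv) {
      nc <- counts[[cat]]
      if (nc == 0L) next
      sub_seeds <- sample.int(.Machine$integer.max - 1L, nc)
      sizes <- split_sizes(nc, split_fractions)
      assign_order <- sample.int(nc)  # shuffle before stratified assignment
      split_of <- rep(c("train", "val", "test"), times = sizes)[order(assign_order)]
      for (k in seq_len(nc)) {
        sc <- generate_scene(cat, params, sub_seeds[k])
        idx <- idx + 1L
        images[, , idx] <- sc$image
        if (keep_masks) masks[, , idx] <- sc$mask
        labels[idx] <- cat
        split[idx] <- split_of[k]
        prov$seed[idx] <- sub_seeds[k]
        prov$draw[idx] <- k
      }
    }
  })
  new_trap_dataset(images, labels, split, masks, prov, params)
}

new_trap_dataset <- function(images, labels, split, masks = NULL,
                             provenance = NULL, params = NULL) {
  stopifnot(dim(images)[1] == TILE, dim(images)[2] == TILE,
            dim(images)[3] == length(labels), length(split) == length(labels))
  assert_category5(labels)
  structure(list(images = images, labels = labels, split = split,
                 masks = masks, provenance = provenance, params = params),
            class = "trap_dataset")
}

#' @export
print.trap_dataset <- function(x, ...) {
  cat("trap_dataset:", length(x$labels), "images (60x60)\n")
  print(table(label = x$labels, split = x$split))
  invisible(x)
}

#' Subset a trap dataset by split or index
#'
#' @param ds a `trap_dataset`.
#' @param split one of "train", "val", "test", or `NULL` with `idx`.
#' @param idx integer indices (used when `split` is `NULL`).
#' @return The subset as a `trap_dataset`.
#' @export
dataset_subset <- function(ds, split = NULL, idx = NULL) {
  stopifnot(inherits(ds, "trap_dataset"))
  if (!is.null(split)) idx <- which(ds$split %in% split)
  if (length(idx) == 0) {
    return(new_trap_dataset(array(0, c(TILE, TILE, 0)), character(0), character(0)))
  }
  new_trap_dataset(ds$images[, , idx, drop = FALSE], ds$labels[idx], ds$split[idx],
                   if (!is.null(ds$masks)) ds$masks[, , idx, drop = FALSE] else NULL,
                   if (!is.null(ds$provenance)) ds$provenance[idx, , drop = FALSE] else NULL,
                   ds$params)
}

#' Number of images in a dataset
#' @param ds a `trap_dataset`.
#' @export
dataset_size <- function(ds) length(ds$labels)
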