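# Augmentation operators: random brightness, flipping, random masking
# (1 to 20 rectangles of varying sizes), Gaussian noise, random rotation.
# Each variant samples an independent subset of the five operators; the
# emitted variant set includes the unmodified original as element 1, so a
# policy with variants_per_original = 6 turns 796 originals into 4,776
# images.

#' Augmentation policy
#'
#' @param brightness_delta Maximum relative brightness change (multiplier
#'   sampled in `[1 - delta, 1 + delta]`).
#' @param flip_modes Subset of `c("horizontal", "vertical")`.
#' @param mask_count_range Integer interval within `[1, 20]`: number of
#'   filled rectangles per masked variant.
#' @param mask_size_range Rectangle side as a fraction of the image side.
#' @param noise_sigma Gaussian noise standard deviation on the 0-255 scale.
#' @param rotation_range Maximum absolute rotation in degrees.
#' @param variants_per_original Number of output images per original,
#'   original included (>= 1).
#' @return An `augmentation_policy` object.
#' @export
augmentation_policy <- function(brightness_delta = 0.3,
                                flip_modes = c("horizontal", "vertical"),
                                mask_count_range = c(1L, 20L),
                                mask_size_range = c(0.02, 0.2),
                                noise_sigma = 10,
                                rotation_range = 30,
                                variants_per_original = 6L) {
  if (variants_per_original < 1L) stopf("variants_per_original must be >= 1")
  if (mask_count_range[1] < 1L || mask_count_range[2] > 20L ||
      mask_count_range[1] > mask_count_range[2])
    stopf("mask_count_range must be within [1, 20]")
  if (!all(flip_modes %in% c("horizontal", "vertical")))
    stopf("flip_modes must be a subset of horizontal/vertical")
  structure(list(brightness_delta = brightness_delta,
                 flip_modes = flip_modes,
                 mask_count_range = as.integer(mask_count_range),
                 mask_size_range = mask_size_range,
                 noise_sigma = noise_sigma,
                 rotation_range = rotation_range,
                 variants_per_original = as.integer(variants_per_original)),
            class = "augmentation_policy")
}

#' Image-space augmentation primitives
#'
#' Deterministic single-operator transforms on `H x W x 3` arrays in
#' `[0, 1]`: brightness scaling, mirror flips, nearest-neighbour rotation
#' about the centre (zero fill), rectangle masking, and additive Gaussian
#' noise (sigma on the 0-255 scale; supply the noise seed).
#'
#' @param img `H x W x 3` numeric array in `[0, 1]`.
#' @param factor Brightness multiplier.
#' @param mode `"horizontal"` or `"vertical"`.
#' @param angle Rotation angle in degrees (counter-clockwise).
#' @param rects Data frame of rectangles (`x`, `y`, `w`, `h` in pixels).
#' @param sigma,seed Noise level (0-255 scale) and seed.
#' @name augment-primitives
NULL

#' @rdname augment-primitives
#' @export
adjust_brightness <- function(img, factor) clamp(img * factor, 0, 1)

#' @rdname augment-primitives
#' @export
flip_image <- function(img, mode) {
  switch(mode,
         horizontal = img[, rev(seq_len(dim(img)[2])), , drop = FALSE],
         vertical = img[rev(seq_len(dim(img)[1])), , , drop = FALSE],
         stopf("unknown flip mode '%s'", mode))
}

#' @rdname augment-primitives
#' @export
rotate_image <- function(img, angle) {
  h <- dim(img)[1]; w <- dim(img)[2]
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(rep(seq_len(h), w), h); xx <- t(matrix(rep(seq_len(w), h), w))
  # inverse mapping: source = R(-theta) (target - c) + c
  sx <- cos(th) * (xx - cx) + sin(th) * (yy - cy) + cx
  sy <- -sin(th) * (xx - cx) + cos(th) * (yy - cy) + cy
  si <- round(sy); sj <- round(sx)
  ok <- si >= 1 & si <= h & sj >= 1 & sj <= w
  out <- array(0, dim = dim(img))
  idx_ok <- which(ok)
  src <- cbind(si[idx_ok], sj[idx_ok])
  for (c in 1:3) {
    ch <- img[, , c]
    plane <- matrix(0, h, w)
    plane[idx_ok] <- ch[src]
    out[, , c] <- plane
  }
  out
}

#' @rdname augment-primitives
#' @export
mask_image <- function(img, rects, fill = 0) {
  for (i in seq_len(nrow(rects))) {
    r <- rects[i, ]
    ys <- max(1, r$y):min(dim(img)[1], r$y + r$h - 1)
    xs <- max(1, r$x):min(dim(img)[2], r$x + r$w - 1)
    img[ys, xs, ] <- fill
  }
  img
}

#' @rdname augment-primitives
#' @export
add_gaussian_noise <- function(img, sigma, seed) {
  with_seed(seed, clamp(img + stats::rnorm(length(img), sd = sigma / 255), 0, 1))
}

# Sample one variant's operator subset and parameters.
sample_variant_params <- function(policy, img_dim, seed) {
  with_seed(seed, {
    use <- stats::runif(5) < 0.5
    p <- list()
    if (use[1]) p$brightness <- stats::runif(1, 1 - policy$brightness_delta,
                                             1 + policy$brightness_delta)
    if (use[2] && length(policy$flip_modes))
      p$flip <- sample(policy$flip_modes, 1)
    if (use[3]) p$rotation <- stats::runif(1, -policy$rotation_range,
                                           policy$rotation_range)
    if (use[4]) {
      nm <- sample(policy$mask_count_range[1]:policy$mask_count_range[2], 1)
      side <- min(img_dim[1:2])
      p$masks <- data.frame(
        x = sample.int(img_dim[2], nm, replace = TRUE),
        y = sample.int(img_dim[1], nm, replace = TRUE),
        w = pmax(1L, round(stats::runif(nm, policy$mask_size_range[1],
                                        policy$mask_size_range[2]) * side)),
        h = pmax(1L, round(stats::runif(nm, policy$mask_size_range[1],
                                        policy$mask_size_range[2]) * side)))
    }
    if (use[5]) p$noise_seed <- derive_seed(seed, "noise")
    p
  })
}

apply_variant <- function(img, p, policy) {
  if (!is.null(p$brightness)) img <- adjust_brightness(img, p$brightness)
  if (!is.null(p$flip)) img <- flip_image(img, p$flip)
  if (!is.null(p$rotation)) img <- rotate_image(img, p$rotation)
  if (!is.null(p$masks)) img <- mask_image(img, p$masks)
  if (!is.null(p$noise_seed)) img <- add_gaussian_noise(img, policy$noise_sigma,
                                                        p$noise_seed)
  round(clamp(img, 0, 1) * 255) / 255
}

#' Augment one image
#'
#' Returns exactly `policy$variants_per_original` images; element 1 is the
#' unmodified original, and each further variant applies an independently
#' sampled subset of the five operators (brightness, flip, rotation,
#' masking, noise, in that order). The sampled parameters of variant i are
#' attached as `attr(out[[i]], "params")`.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param policy An [augmentation_policy()].
#' @param seed Integer seed; identical seeds give identical variants.
#' @return List of image arrays.
#' @export
augment_image <- function(img, policy, seed) {
  if (length(dim(img)) != 3L || any(dim(img)[1:2] < 1))
    stopf("augment_image: empty image")
  v <- policy$variants_per_original
  out <- vector("list", v)
  out[[1]] <- img
  attr(out[[1]], "params") <- list()
  if (v > 1) for (j in 2:v) {
    p <- sample_variant_params(policy, dim(img), derive_seed(seed, "variant", j))
    out[[j]] <- apply_variant(img, p, policy)
    attr(out[[j]], "params") <- p
  }
  out
}

#' Augment every field-collected sample of a manifest
#'
#' Reads each `source == "field"` image, writes
#' `variants_per_original` files per original (the original re-emitted as
#' variant 0), and returns a manifest of the outputs, all tagged
#' `source = "augmented"`. Output count is exactly
#' `variants_per_original x input count`.
#'
#' @param manifest A `dataset_manifest` (only field samples are used).
#' @param policy An [augmentation_policy()].
#' @param seed Integer seed.
#' @param out_dir Directory for augmented images (class subdirectories).
#' @return A `dataset_manifest` of the augmented samples.
#' @export
augment_dataset <- function(manifest, policy, seed, out_dir) {
  df <- manifest$samples[manifest$samples$source == "field", , drop = FALSE]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(df))
  if (nrow(df) > 0) for (i in seq_len(nrow(df))) {
    img <- read_image(df$path[i])
    vs <- augment_image(img, policy, derive_seed(seed, df$path[i]))
    cdir <- file.path(out_dir, df$label[i])
    dir.create(cdir, showWarnings = FALSE)
    stem <- tools::file_path_sans_ext(basename(df$path[i]))
    paths <- character(length(vs))
    for (j in seq_along(vs)) {
      paths[j] <- file.path(cdir, sprintf("%s_aug%d.png", stem, j - 1L))
      png::writePNG(vs[[j]], paths[j])
    }
    rows[[i]] <- data.frame(path = paths, label = df$label[i],
                            source = "augmented", split = df$split[i],
                            stringsAsFactors = FALSE)
  }
  samples <- if (length(rows)) do.call(rbind, rows) else NULL
  dataset_manifest(samples, classes = manifest$classes, seed = seed)
}
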