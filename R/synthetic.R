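# Synthetic leaf-image corpus.
#
# Each class renders an elliptical leaf on a textured soil-like background;
# class identity is encoded in the visual signature: lesion count range,
# lesion colour (hue/saturation/value), lesion size, leaf hue shift, and
# texture noise. The class structure and per-class totals mirror an 11-class
# imbalanced cotton disease/pest corpus. Images are 8-bit RGB, deterministic
# for a fixed seed.

#' Class specification for the synthetic renderer
#'
#' @param name Class name (directory name in the image folder layout).
#' @param n_images Number of images to render (>= 0).
#' @param visual_signature Named list of renderer parameters; see
#'   [default_class_specs()] for the fields and bounds.
#' @return A `class_spec` object.
#' @export
class_spec <- function(name, n_images, visual_signature) {
  if (n_images < 0) stopf("n_images must be >= 0 (class %s)", name)
  sig <- visual_signature
  defaults <- list(lesion_count = c(0L, 0L), lesion_hue = 0.1,
                   lesion_sat = 0.8, lesion_val = 0.45,
                   lesion_size = c(0.03, 0.08),
                   leaf_hue = 0.33, texture_sigma = 0.02, bg_hue = 0.09)
  sig <- utils::modifyList(defaults, sig)
  if (any(sig$lesion_count < 0)) stopf("lesion_count must be >= 0")
  if (sig$texture_sigma < 0 || sig$texture_sigma > 0.25)
    stopf("texture_sigma outside renderer bounds [0, 0.25]")
  structure(list(name = name, n_images = as.integer(n_images),
                 visual_signature = sig), class = "class_spec")
}

#' Default 11-class specification table
#'
#' Eleven classes (ten disease/pest signatures plus healthy) with the
#' imbalanced per-class totals of the emulated cotton corpus, optionally
#' scaled.
#'
#' @param scale Multiplier applied to every per-class total (counts are
#'   rounded); `1/20` gives a desk-scale corpus.
#' @param n_per_class Optional fixed per-class count overriding the table.
#' @return List of [class_spec()] objects.
#' @export
default_class_specs <- function(scale = 1, n_per_class = NULL) {
  tab <- list(
    #                      total  lesions   hue   sat   val   size        leaf_hue sigma
    healthy            = list(6444, c(0, 0),  0.33, 0.0,  0.5,  c(0.03, 0.05), 0.33, 0.02),
    aphids             = list(1582, c(8, 16), 0.14, 0.75, 0.65, c(0.02, 0.04), 0.33, 0.02),
    army_worm          = list(1360, c(2, 5),  0.07, 0.85, 0.30, c(0.08, 0.14), 0.32, 0.03),
    bacterial_blight   = list(2477, c(3, 8),  0.10, 0.80, 0.40, c(0.04, 0.08), 0.33, 0.02),
    cotton_curl_virus  = list(2530, c(1, 3),  0.22, 0.60, 0.55, c(0.05, 0.10), 0.28, 0.08),
    fusarium_wilt      = list(881,  c(1, 3),  0.16, 0.70, 0.50, c(0.06, 0.12), 0.19, 0.03),
    herbicide_growth_damage =
                         list(280,  c(2, 6),  0.24, 0.45, 0.70, c(0.05, 0.10), 0.30, 0.02),
    leaf_redding       = list(578,  c(1, 4),  0.98, 0.80, 0.45, c(0.08, 0.15), 0.36, 0.02),
    leaf_variegation   = list(116,  c(4, 10), 0.30, 0.10, 0.90, c(0.04, 0.09), 0.33, 0.02),
    powdery_mildew     = list(1350, c(10, 20), 0.0, 0.03, 0.95, c(0.015, 0.035), 0.33, 0.02),
    target_spot        = list(1355, c(3, 7),  0.05, 0.90, 0.25, c(0.05, 0.09), 0.33, 0.02)
  )
  lapply(names(tab), function(nm) {
    e <- tab[[nm]]
    n <- if (!is.null(n_per_class)) n_per_class else round(e[[1]] * scale)
    class_spec(nm, n, list(lesion_count = e[[2]], lesion_hue = e[[3]],
                           lesion_sat = e[[4]], lesion_val = e[[5]],
                           lesion_size = e[[6]], leaf_hue = e[[7]],
                           texture_sigma = e[[8]]))
  })
}

# Smooth random field in [-1, 1]-ish range via bilinear upscaling of a
# coarse Gaussian grid.
smooth_noise <- function(size, coarse = 6L) {
  g <- matrix(stats::rnorm((coarse + 1)^2), coarse + 1)
  pos <- seq(1, coarse + 1, length.out = size)
  i0 <- pmin(floor(pos), coarse); fr <- pos - i0
  A <- matrix(0, size, coarse + 1)
  A[cbind(seq_len(size), i0)] <- 1 - fr
  A[cbind(seq_len(size), i0 + 1)] <- fr
  A %*% g %*% t(A)
}

#' Render one synthetic leaf image
#'
#' @param size Image side in pixels (>= 32).
#' @param signature Visual signature list (see [class_spec()]).
#' @param seed Integer seed; identical seeds give byte-identical images.
#' @return `size x size x 3` array on the 8-bit grid in `[0, 1]`.
#' @export
render_leaf_image <- function(size, signature, seed) {
  if (size < 32) stopf("image size must be >= 32")
  sig <- signature
  with_seed(seed, {
    s <- size
    yy <- matrix(rep(seq_len(s), s), s)          # row coordinate
    xx <- t(yy)
    # background: soil-toned, low-frequency value variation
    bgv <- 0.32 + 0.10 * smooth_noise(s)
    bgh <- (sig$bg_hue %||% 0.09) + 0.02 * smooth_noise(s)
    bg <- hsv_to_rgb(bgh, 0.45, clamp(bgv, 0.05, 0.8))
    # leaf ellipse
    cx <- s / 2 + stats::runif(1, -0.05, 0.05) * s
    cy <- s / 2 + stats::runif(1, -0.05, 0.05) * s
    a <- stats::runif(1, 0.30, 0.40) * s
    b <- stats::runif(1, 0.24, 0.36) * s
    th <- stats::runif(1, 0, pi)
    xr <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
    yr <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
    leaf <- (xr / a)^2 + (yr / b)^2 <= 1
    lh <- sig$leaf_hue + 0.02 * smooth_noise(s)
    lv <- 0.42 + 0.16 * smooth_noise(s, 8L)
    lc <- hsv_to_rgb(lh, 0.60, clamp(lv, 0.1, 0.85))
    r <- ifelse(leaf, lc$r, bg$r)
    g <- ifelse(leaf, lc$g, bg$g)
    bl <- ifelse(leaf, lc$b, bg$b)
    # lesions: disks inside the leaf with the class colour
    nl <- if (sig$lesion_count[2] > 0)
      sample(sig$lesion_count[1]:sig$lesion_count[2], 1) else 0L
    if (nl > 0) {
      for (i in seq_len(nl)) {
        u <- sqrt(stats::runif(1)); ang <- stats::runif(1, 0, 2 * pi)
        lx <- cx + 0.85 * u * a * cos(ang) * cos(th) - 0.85 * u * b * sin(ang) * sin(th)
        ly <- cy + 0.85 * u * a * cos(ang) * sin(th) + 0.85 * u * b * sin(ang) * cos(th)
        rad <- stats::runif(1, sig$lesion_size[1], sig$lesion_size[2]) * s
        disk <- leaf & ((xx - lx)^2 + (yy - ly)^2 <= rad^2)
        hue <- sig$lesion_hue + stats::runif(1, -0.015, 0.015)
        val <- clamp(sig$lesion_val + stats::runif(1, -0.08, 0.08), 0.05, 1)
        col <- hsv_to_rgb(hue, sig$lesion_sat, val)
        r[disk] <- col$r; g[disk] <- col$g; bl[disk] <- col$b
      }
    }
    img <- array(c(r, g, bl), dim = c(s, s, 3))
    img <- img + stats::rnorm(length(img), sd = sig$texture_sigma)
    round(clamp(img, 0, 1) * 255) / 255
  })
}

#' Generate a synthetic image corpus
#'
#' Renders `n_images` RGB images per class into one directory per class
#' (`out_dir/<class>/<class>_<i>.png`) and returns the manifest.
#' Deterministic for a fixed seed: the same call produces byte-identical
#' files.
#'
#' @param class_specs List of [class_spec()] objects (unique names).
#' @param out_dir Output directory (created if needed; must be writable).
#' @param image_size Square image side in pixels (>= 32).
#' @param seed Integer master seed.
#' @param source Provenance tag recorded in the manifest (default
#'   `"synthetic"`; use `"field"` when emulating field-collected originals).
#' @return A `dataset_manifest` with `split = "unassigned"`.
#' @export
generate_synthetic_dataset <- function(class_specs, out_dir, image_size = 64L,
                                       seed = 1L, source = "synthetic") {
  nms <- vapply(class_specs, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stopf("duplicate class names: %s",
                                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (image_size < 32) stopf("image_size must be >= 32")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
    stopf("output directory not writable: %s", out_dir)
  rows <- vector("list", length(class_specs))
  for (ci in seq_along(class_specs)) {
    cs <- class_specs[[ci]]
    cdir <- file.path(out_dir, cs$name)
    dir.create(cdir, showWarnings = FALSE)
    paths <- character(cs$n_images)
    for (i in seq_len(cs$n_images)) {
      img <- render_leaf_image(image_size, cs$visual_signature,
                               derive_seed(seed, cs$name, i))
      paths[i] <- file.path(cdir, sprintf("%s_%05d.png", cs$name, i))
      png::writePNG(img, paths[i])
    }
    rows[[ci]] <- if (cs$n_images > 0)
      data.frame(path = paths, label = cs$name, source = source,
                 split = "unassigned", stringsAsFactors = FALSE)
    else NULL
  }
  rows <- Filter(Negate(is.null), rows)
  samples <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
             else NULL
  dataset_manifest(samples, classes = nms, seed = seed)
}

#' Read an image file as a numeric array
#'
#' @param path PNG file path.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Load a manifest's images into a batch array
#'
#' @param manifest A `dataset_manifest`.
#' @param split Optional split filter (`"train"`, `"test"`).
#' @return List with `x` (`H x W x 3 x N` array), `y` (integer labels in
#'   class-list order), and `classes`.
#' @export
load_dataset <- function(manifest, split = NULL) {
  df <- manifest$samples
  if (!is.null(split)) df <- df[df$split == split, , drop = FALSE]
  if (nrow(df) == 0) stopf("no samples%s", if (is.null(split)) "" else
    sprintf(" in split '%s'", split))
  first <- read_image(df$path[1])
  x <- array(0, dim = c(dim(first), nrow(df)))
  x[, , , 1] <- first
  if (nrow(df) > 1) for (i in 2:nrow(df)) x[, , , i] <- read_image(df$path[i])
  y <- match(df$label, manifest$classes)
  list(x = x, y = y, classes = manifest$classes)
}
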