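# Dataset manifests: CSV with header exactly `path,label,source,split`,
# per-class count accounting, and the stratified 8:2 splitter whose per-class
# rule is train = floor(train_fraction * n), remainder to test.

MANIFEST_SOURCES <- c("online", "field", "augmented", "synthetic")
MANIFEST_SPLITS <- c("train", "test", "unassigned")

#' Construct a dataset manifest
#'
#' @param samples Data frame with columns `path`, `label`, `source`
#'   (online/field/augmented/synthetic), `split` (train/test/unassigned).
#' @param classes Class-name vector fixing label order (default: sorted
#'   unique labels).
#' @param seed Integer seed recorded for provenance.
#' @return A `dataset_manifest` with per-class `(train, test, total)`
#'   counts.
#' @export
dataset_manifest <- function(samples, classes = NULL, seed = NA_integer_) {
  if (is.null(samples))
    samples <- data.frame(path = character(), label = character(),
                          source = character(), split = character(),
                          stringsAsFactors = FALSE)
  need <- c("path", "label", "source", "split")
  if (!all(need %in% names(samples)))
    stopf("manifest needs columns %s", paste(need, collapse = ","))
  samples <- samples[, need]
  bad <- which(!samples$source %in% MANIFEST_SOURCES)
  if (length(bad)) stopf("row %d: unknown source '%s'", bad[1], samples$source[bad[1]])
  bad <- which(!samples$split %in% MANIFEST_SPLITS)
  if (length(bad)) stopf("row %d: unknown split '%s'", bad[1], samples$split[bad[1]])
  classes <- classes %||% sort(unique(samples$label))
  bad <- which(!samples$label %in% classes)
  if (length(bad)) stopf("row %d: label '%s' not in class list", bad[1],
                         samples$label[bad[1]])
  counts <- t(vapply(classes, function(cl) {
    s <- samples$split[samples$label == cl]
    c(train = sum(s == "train"), test = sum(s == "test"), total = length(s))
  }, numeric(3)))
  structure(list(samples = samples, classes = classes,
                 class_counts = as.data.frame(counts), seed = seed),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("dataset_manifest: %d samples, %d classes (train %d / test %d)\n",
              nrow(x$samples), length(x$classes),
              sum(x$class_counts$train), sum(x$class_counts$test)))
  invisible(x)
}

#' Write / read a manifest CSV
#'
#' The file is UTF-8 CSV with header exactly `path,label,source,split`.
#' Reading validates every row (enums, class membership) and reports the
#' first offending row number.
#'
#' @param manifest A `dataset_manifest`.
#' @param path CSV file path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest$samples, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_manifest
#' @param classes Optional class list to validate labels against.
#' @export
read_manifest <- function(path, classes = NULL) {
  if (!file.exists(path)) stopf("manifest file not found: %s", path)
  hdr <- readLines(path, n = 1L, encoding = "UTF-8")
  if (!identical(hdr, "path,label,source,split"))
    stopf("malformed manifest header: expected 'path,label,source,split'")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  nf <- which(vapply(seq_len(nrow(df)), function(i)
    anyNA(df[i, ]) || any(df[i, ] == ""), logical(1)))
  if (length(nf)) stopf("row %d: malformed (empty field)", nf[1])
  # preserve first-appearance class order so write/read round-trips
  dataset_manifest(df, classes = classes %||% unique(df$label))
}

#' Merge manifests
#'
#' @param ... `dataset_manifest` objects.
#' @param classes Optional combined class list.
#' @export
merge_manifests <- function(..., classes = NULL) {
  ms <- list(...)
  samples <- do.call(rbind, lapply(ms, function(m) m$samples))
  classes <- classes %||% Reduce(union, lapply(ms, function(m) m$classes))
  dataset_manifest(samples, classes = classes, seed = ms[[1]]$seed)
}

# Family key: an augmented variant written as <stem>_aug<k> belongs to its
# original's family, so a family never straddles the split boundary.
family_key <- function(path, source) {
  stem <- tools::file_path_sans_ext(basename(path))
  ifelse(source == "augmented", sub("_aug[0-9]+$", "", stem), stem)
}

#' Stratified train/test split
#'
#' Per class of size n, the training set receives
#' `floor(train_fraction * n)` samples and the test set the remainder;
#' membership is chosen by a seeded shuffle within the class. When
#' `group_families = TRUE`, an original and its augmented variants are kept
#' in the same split (stricter than plain stratification; with families
#' present the per-class train count may fall short of the floor target by
#' at most one family).
#'
#' @param manifest A `dataset_manifest`.
#' @param train_fraction Fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @param group_families Keep augmentation families un-split.
#' @return A new `dataset_manifest` with `split` assigned.
#' @export
stratified_split <- function(manifest, train_fraction = 0.8, seed = 1L,
                             group_families = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  df <- manifest$samples
  df$split <- "unassigned"
  for (cl in manifest$classes) {
    idx <- which(df$label == cl)
    n <- length(idx)
    if (n == 0) next
    target <- floor(train_fraction * n)
    fam <- if (group_families) family_key(df$path[idx], df$source[idx])
           else as.character(seq_along(idx))
    units <- split(idx, fam)
    ord <- with_seed(derive_seed(seed, "split", cl),
                     sample.int(length(units)))
    assigned <- 0L
    for (ui in ord) {
      u <- units[[ui]]
      if (assigned + length(u) <= target) {
        df$split[u] <- "train"
        assigned <- assigned + length(u)
      } else df$split[u] <- "test"
    }
  }
  dataset_manifest(df, classes = manifest$classes, seed = seed)
}

#' Split counts implied by the per-class floor rule
#'
#' Pure accounting: for each class total n, train = floor(frac * n),
#' test = n - train.
#'
#' @param totals Named or unnamed vector of per-class totals.
#' @param train_fraction Fraction in (0, 1).
#' @return Data frame with columns `total`, `train`, `test`.
#' @export
split_counts <- function(totals, train_fraction = 0.8) {
  train <- floor(train_fraction * totals)
  data.frame(total = totals, train = train, test = totals - train)
}
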