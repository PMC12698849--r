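# Labeled image sets: the synthetic generator that emulates a 4-class brain
# MRI folder (no-tumour background plus three lesion classes differing in
# position, extent and intensity), an on-disk folder reader, min-max
# preprocessing to [-1, 1], and IID partitioning across clients.

new_labeled_image_set <- function(images, labels, class_names, value_range) {
  stopifnot(length(dim(images)) == 3L, dim(images)[3] == length(labels))
  structure(list(images = images, labels = as.integer(labels),
                 class_names = class_names,
                 value_range = as.numeric(value_range)),
            class = "labeled_image_set")
}

#' Number of samples in a labeled image set
#' @param data a `labeled_image_set`
#' @return integer count
#' @export
n_images <- function(data) dim(data$images)[3]

#' @export
print.labeled_image_set <- function(x, ...) {
  d <- dim(x$images)
  cat("Labeled image set:", d[3], "images of", d[1], "x", d[2],
      "|", length(x$class_names), "classes\n")
  print(table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                     labels = x$class_names)))
  invisible(x)
}

#' Subset a labeled image set
#' @param x a `labeled_image_set`
#' @param i integer index vector of samples to keep
#' @param ... unused
#' @return a `labeled_image_set` with the selected samples
#' @export
`[.labeled_image_set` <- function(x, i, ...) {
  new_labeled_image_set(x$images[, , i, drop = FALSE], x$labels[i],
                        x$class_names, x$value_range)
}

#' Generate a synthetic multi-class grayscale image set
#'
#' Stand-in for a class-per-folder medical imaging dataset: class 0 is pure
#' background noise ("no lesion"); every class `c >= 1` carries an elliptical
#' bright lesion whose centre position, radius and intensity are
#' class-specific (small/bright near the top-left through large/dim near the
#' bottom-right), with per-image jitter and additive pixel noise. The classes
#' are separable enough that a small CNN exceeds 0.9 held-out accuracy.
#' Output is bitwise-deterministic given the arguments.
#'
#' @param n_per_class images per class (>= 1)
#' @param n_classes number of classes (>= 2); class 0 is background-only
#' @param image_size square image side length in pixels (>= 8)
#' @param seed integer seed
#' @return a `labeled_image_set` with raw intensities in `[0, 255]`
#' @examples
#' d <- generate_synthetic_images(10, 4, 32, seed = 0)
#' table(d$labels)
#' @export
generate_synthetic_images <- function(n_per_class, n_classes = 4L,
                                      image_size = 32L, seed = 0L) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (image_size < 8L) stop("image_size must be >= 8")
  n_per_class <- as.integer(n_per_class)
  n_classes <- as.integer(n_classes)
  H <- as.integer(image_size)
  n <- n_per_class * n_classes
  labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  # normalized pixel-centre coordinates
  gx <- (seq_len(H) - 0.5) / H
  grid_x <- matrix(gx, H, H, byrow = TRUE)   # column coordinate
  grid_y <- matrix(gx, H, H)                 # row coordinate
  imgs <- withr::with_seed(as.integer(seed), {
    out <- array(0, dim = c(H, H, n))
    for (i in seq_len(n)) {
      cls <- labels[i]
      img <- matrix(stats::rnorm(H * H, mean = 40, sd = 12), H, H)
      if (cls >= 1L) {
        # class signature: position along the diagonal, growing radius,
        # fading intensity
        frac <- (cls - 1L) / max(1L, n_classes - 2L)
        cx <- 0.28 + 0.44 * frac + stats::rnorm(1, 0, 0.04)
        cy <- 0.28 + 0.44 * frac + stats::rnorm(1, 0, 0.04)
        rx <- (0.10 + 0.16 * frac) * stats::runif(1, 0.85, 1.15)
        ry <- rx * stats::runif(1, 0.65, 1.0)
        amp <- (215 - 95 * frac) * stats::runif(1, 0.9, 1.1)
        m <- ((grid_x - cx) / rx)^2 + ((grid_y - cy) / ry)^2
        img <- img + amp * exp(-pmax(m - 1, 0) * 6)
      }
      out[, , i] <- pmin(pmax(img + stats::rnorm(H * H, 0, 8), 0), 255)
    }
    out
  })
  class_names <- c("class0_background",
                   paste0("class", seq_len(n_classes - 1L), "_lesion"))
  new_labeled_image_set(imgs, labels, class_names, c(0, 255))
}

#' Read a class-per-subdirectory image folder
#'
#' Each subdirectory of `path` is one class; labels 0, 1, ... are assigned in
#' sorted subdirectory-name order. PNG/JPEG/TIFF images are read, converted
#' to grayscale and resized to `image_size` x `image_size`.
#'
#' @param path directory containing one subdirectory per class
#' @param image_size target square side length in pixels
#' @return a `labeled_image_set` with intensities in `[0, 1]`
#' @export
load_image_folder <- function(path, image_size = 32L) {
  if (!dir.exists(path)) stop("image folder does not exist: ", path)
  dirs <- sort(list.dirs(path, recursive = FALSE))
  if (length(dirs) == 0L) stop("no class subdirectories in: ", path)
  imgs <- list()
  labels <- integer(0)
  for (ci in seq_along(dirs)) {
    files <- sort(list.files(dirs[ci], full.names = TRUE,
                             pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                             ignore.case = TRUE))
    if (length(files) == 0L) stop("no readable images in: ", dirs[ci])
    for (f in files) {
      img <- EBImage::readImage(f)
      if (length(dim(img)) == 3L) img <- EBImage::channel(img, "luminance")
      img <- EBImage::resize(img, w = image_size, h = image_size)
      imgs[[length(imgs) + 1L]] <- EBImage::imageData(img)
      labels <- c(labels, ci - 1L)
    }
  }
  arr <- array(unlist(imgs), dim = c(image_size, image_size, length(imgs)))
  new_labeled_image_set(arr, labels, basename(dirs), c(0, 1))
}

#' Write a labeled image set as a class-per-subdirectory PNG folder
#'
#' Inverse of [load_image_folder()] (used for round-trip checks and to
#' export synthetic fixtures).
#'
#' @param data a `labeled_image_set`
#' @param path output directory (created if needed)
#' @return `path`, invisibly
#' @export
write_image_folder <- function(data, path) {
  lo <- data$value_range[1]; hi <- data$value_range[2]
  for (ci in seq_along(data$class_names)) {
    dir.create(file.path(path, data$class_names[ci]), recursive = TRUE,
               showWarnings = FALSE)
  }
  counter <- integer(length(data$class_names))
  for (i in seq_len(n_images(data))) {
    ci <- data$labels[i] + 1L
    counter[ci] <- counter[ci] + 1L
    img <- (data$images[, , i] - lo) / max(hi - lo, .Machine$double.eps)
    png::writePNG(img, file.path(path, data$class_names[ci],
                                 sprintf("img_%04d.png", counter[ci])))
  }
  invisible(path)
}

#' Resize and min-max normalize images to [-1, 1]
#'
#' Images are resized to `target_size` x `target_size` (bilinear, via
#' EBImage) and each image is independently mapped by
#' `x' = 2 (x - min) / (max - min) - 1`, so its minimum becomes -1 and its
#' maximum +1. A constant image (max == min) maps to all zeros, the midpoint
#' of the range. Already-normalized data passes through unchanged up to
#' floating tolerance (idempotence).
#'
#' @param data a `labeled_image_set`
#' @param target_size output side length in pixels (default: keep size)
#' @return a `labeled_image_set` with `value_range = c(-1, 1)`
#' @export
preprocess <- function(data, target_size = NULL) {
  if (n_images(data) == 0L) stop("empty image set")
  d <- dim(data$images)
  target_size <- as.integer(target_size %||% d[1])
  imgs <- data$images
  if (target_size != d[1] || d[1] != d[2]) {
    resized <- array(0, dim = c(target_size, target_size, d[3]))
    for (i in seq_len(d[3])) {
      resized[, , i] <- EBImage::imageData(
        EBImage::resize(EBImage::Image(imgs[, , i]),
                        w = target_size, h = target_size))
    }
    imgs <- resized
  }
  for (i in seq_len(d[3])) {
    x <- imgs[, , i]
    mn <- min(x); mx <- max(x)
    imgs[, , i] <- if (mx > mn) 2 * (x - mn) / (mx - mn) - 1 else x * 0
  }
  new_labeled_image_set(imgs, data$labels, data$class_names, c(-1, 1))
}

#' Partition a dataset into disjoint client shards
#'
#' IID uniform split: indices are shuffled under `seed` and dealt into `k`
#' shards whose sizes differ by at most one. Shards are pairwise disjoint
#' and jointly cover the dataset; shard `i` is the local dataset of client
#' `i` with size `n_i`.
#'
#' @param data a `labeled_image_set`
#' @param k number of clients (1 <= k <= number of samples)
#' @param seed integer seed
#' @return an object of class `partition_plan` with `k`, `shard_indices`
#'   (list of integer vectors) and `shard_sizes`
#' @export
partition <- function(data, k, seed = 1L) {
  n <- n_images(data)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds dataset size ", n)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  shard_of <- rep_len(seq_len(k), n)
  shard_indices <- split(perm, shard_of)
  names(shard_indices) <- NULL
  shard_indices <- lapply(shard_indices, sort)
  structure(list(k = k, shard_indices = shard_indices,
                 shard_sizes = lengths(shard_indices)),
            class = "partition_plan")
}

#' Split a dataset into train and test subsets
#'
#' @param data a `labeled_image_set`
#' @param test_fraction fraction of samples held out (default 0.2)
#' @param seed integer seed
#' @return list with `train` and `test` labeled image sets
#' @export
split_train_test <- function(data, test_fraction = 0.2, seed = 1L) {
  n <- n_images(data)
  n_test <- max(1L, round(n * test_fraction))
  if (n_test >= n) stop("test_fraction leaves no training data")
  test_idx <- withr::with_seed(as.integer(seed), sort(sample.int(n, n_test)))
  list(train = data[setdiff(seq_len(n), test_idx)], test = data[test_idx])
}
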