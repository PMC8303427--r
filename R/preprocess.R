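# Preprocessing: frame extraction, image standardization, subject-wise split.

#' Extract frames from a sequence at a fixed interval
#'
#' Keeps every `interval`-th frame starting at the first one (0-based
#' indices 0, interval, 2*interval, ...). The interval-of-5 convention used
#' for echo video is a fixed sampling stride, not a frame rate.
#'
#' @param frames a list of frames, or an array whose last dimension indexes
#'   frames.
#' @param interval positive integer stride.
#' @return the retained frames, same container type as the input.
#' @export
extract_frames <- function(frames, interval) {
  if (length(interval) != 1L || !is.finite(interval) || interval < 1 ||
      interval != round(interval))
    stop("interval must be a positive integer")
  if (is.list(frames)) {
    if (length(frames) == 0L) stop("frame sequence is empty")
    return(frames[seq(1L, length(frames), by = interval)])
  }
  d <- dim(frames)
  if (is.null(d) || length(d) < 2L) stop("frames must be a list or an array")
  n <- d[length(d)]
  if (n == 0L) stop("frame sequence is empty")
  keep <- seq(1L, n, by = interval)
  idx <- c(lapply(d[-length(d)], seq_len), list(keep))
  do.call(`[`, c(list(frames), idx, list(drop = FALSE)))
}

#' Standardize an image for the network
#'
#' Crops fixed margins, rescales intensities to `[0, 1]` (8-bit inputs are
#' divided by 255), resizes bilinearly to `out_size` x `out_size`, and
#' replicates grayscale to three channels. Idempotent on already-standardized
#' input.
#'
#' @param image 2-D matrix or H x W x 3 array.
#' @param out_size output side in pixels.
#' @param crop_margins integer margins `c(top, bottom, left, right)` removed
#'   before resizing (burned-in annotations on clinical exports; zero for
#'   synthetic data).
#' @return an `out_size` x `out_size` x 3 array in `[0, 1]`.
#' @export
standardize_image <- function(image, out_size = 512L, crop_margins = c(0L, 0L, 0L, 0L)) {
  d <- dim(image)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
    stop("image must be a 2-D matrix or an H x W x 3 array")
  if (length(crop_margins) != 4L || any(crop_margins < 0))
    stop("crop_margins must be c(top, bottom, left, right), nonnegative")
  h <- d[1]; w <- d[2]
  if (crop_margins[1] + crop_margins[2] >= h ||
      crop_margins[3] + crop_margins[4] >= w)
    stop("crop margins remove the whole image")
  rows <- (crop_margins[1] + 1L):(h - crop_margins[2])
  cols <- (crop_margins[3] + 1L):(w - crop_margins[4])
  image <- if (length(d) == 2L) image[rows, cols, drop = FALSE]
           else image[rows, cols, , drop = FALSE]
  image[!is.finite(image)] <- 0
  mx <- max(image)
  if (mx > 1) image <- image / 255
  image <- pmin(pmax(image, 0), 1)
  chans <- if (length(dim(image)) == 2L) list(image)
           else lapply(1:3, function(c) image[, , c])
  out <- array(0, c(out_size, out_size, 3L))
  for (c in 1:3) {
    src <- chans[[min(c, length(chans))]]
    out[, , c] <- if (nrow(src) == out_size && ncol(src) == out_size) src
                  else bilinear_resize(src, out_size, out_size)
  }
  out
}

#' Assign subjects to train / validation / test partitions
#'
#' Subjects are assigned whole (no subject ever spans two partitions) by a
#' seeded shuffle followed by a greedy rule: each subject goes to the
#' partition whose image-count deficit against the target ratio is largest.
#' When the manifest carries view labels the deficit is accumulated per
#' view class, so each class approaches the target ratio individually and no
#' partition is starved of a class; for subjects with identical class
#' composition this reduces to the plain image-count rule. With subjects of
#' comparable size the achieved image fractions land within a few
#' percentage points of the target.
#'
#' @param manifest data frame with `subject_id` (one row per image).
#' @param ratio three nonnegative numbers, train:validation:test (default
#'   `c(7, 1, 2)`).
#' @param seed integer shuffle seed.
#' @return a data frame of class `"split_assignment"` with columns
#'   `subject_id` and `split`; the target ratio is attached as attribute
#'   `"ratio"`.
#' @export
split_by_subject <- function(manifest, ratio = c(7, 1, 2), seed = 1L) {
  if (!is.data.frame(manifest) || !"subject_id" %in% names(manifest))
    stop("manifest must be a data frame with a subject_id column")
  if (length(ratio) != 3L || any(!is.finite(ratio)) || any(ratio < 0) ||
      sum(ratio) == 0)
    stop("ratio must be three nonnegative numbers with a positive sum")
  counts <- table(manifest$subject_id)
  subjects <- names(counts)
  parts <- c("train", "validation", "test")
  if (length(subjects) < sum(ratio > 0))
    stop(sprintf("need at least %d subjects for %d non-empty partitions",
                 sum(ratio > 0), sum(ratio > 0)))
  frac <- ratio / sum(ratio)
  order_s <- with_local_seed(seed, sample(subjects))
  has_labels <- "view_label" %in% names(manifest)
  strata <- if (has_labels) sort(unique(manifest$view_label)) else "all"
  # per-stratum image counts: strata x subjects
  cnt <- if (has_labels)
    unclass(table(factor(manifest$view_label, levels = strata),
                  manifest$subject_id))
  else matrix(as.integer(counts), 1, dimnames = list("all", subjects))
  assigned <- matrix(0, length(strata), 3)
  split <- character(length(order_s))
  for (i in seq_along(order_s)) {
    n_i <- cnt[, order_s[i]]
    sel <- n_i > 0                   # judge only the classes this subject has
    deficit <- colSums((outer(rowSums(assigned) + n_i, frac) -
                          assigned)[sel, , drop = FALSE])
    deficit[frac == 0] <- -Inf
    p <- which.max(deficit)          # ties favor train > validation > test
    split[i] <- parts[p]
    assigned[, p] <- assigned[, p] + n_i
  }
  out <- data.frame(subject_id = order_s, split = split,
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ratio") <- ratio
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Add a split column to a manifest
#'
#' @param manifest image manifest data frame.
#' @param assignment a [split_by_subject()] result.
#' @return the manifest with a `split` column.
#' @export
add_split <- function(manifest, assignment) {
  idx <- match(manifest$subject_id, assignment$subject_id)
  if (anyNA(idx))
    stop("assignment is missing subjects present in the manifest")
  manifest$split <- assignment$split[idx]
  manifest
}
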