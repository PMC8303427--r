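#' Standard echocardiographic view vocabulary
#'
#' The nine standard transthoracic views used as the default label set:
#' parasternal long-axis (PSLA), parasternal short-axis at the great vessels
#' (SB) and at the papillary muscles (SM), apical four-/five-/two-/three-
#' chamber (A4C, A5C, A2C, A3C), subcostal four-chamber (SUB4C) and
#' suprasternal aortic arch (SUPAO).
#'
#' @export
echo_views <- function() {
  c("PSLA", "SB", "SM", "A4C", "A5C", "A2C", "A3C", "SUB4C", "SUPAO")
}

#' Configuration for the synthetic echo-like image generator
#'
#' Describes a desk-scale dataset that reproduces the statistical structure
#' the graph-constrained classifier relies on: view classes distinguished by
#' spatial layout, per-subject morphological variation, periodic affine
#' deformation across the frames of a "cardiac cycle", and multiplicative
#' speckle noise. Same seed and config give bit-identical images.
#'
#' @param n_classes number of view classes (>= 2); labels are taken from
#'   [echo_views()] in order.
#' @param n_subjects_per_class subjects generated per class.
#' @param frames_per_cycle frames in one deformation cycle (>= 1).
#' @param n_cycles cycles recorded per subject.
#' @param image_size square image side in pixels (>= 16).
#' @param speckle_strength standard deviation of the unit-mean multiplicative
#'   speckle factor; 0 disables speckle.
#' @param deformation_amplitude maximal fractional affine perturbation over a
#'   cycle; 0 freezes the heart.
#' @param seed integer seed driving all randomness.
#' @return a list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_classes = 9L, n_subjects_per_class = 5L,
                             frames_per_cycle = 8L, n_cycles = 2L,
                             image_size = 128L, speckle_strength = 0.1,
                             deformation_amplitude = 0.05, seed = 1L) {
  chk_count <- function(x, nm, min) {
    if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
      stop(sprintf("invalid field '%s': must be an integer >= %d", nm, min))
  }
  chk_count(n_classes, "n_classes", 2)
  if (n_classes > length(echo_views()))
    stop(sprintf("invalid field 'n_classes': at most %d views available",
                 length(echo_views())))
  chk_count(n_subjects_per_class, "n_subjects_per_class", 1)
  chk_count(frames_per_cycle, "frames_per_cycle", 1)
  chk_count(n_cycles, "n_cycles", 1)
  chk_count(image_size, "image_size", 16)
  if (!is.finite(speckle_strength) || speckle_strength < 0)
    stop("invalid field 'speckle_strength': must be a nonnegative scalar")
  if (!is.finite(deformation_amplitude) || deformation_amplitude < 0)
    stop("invalid field 'deformation_amplitude': must be a nonnegative scalar")
  chk_count(seed, "seed", -2^31)
  structure(list(n_classes = as.integer(n_classes),
                 n_subjects_per_class = as.integer(n_subjects_per_class),
                 frames_per_cycle = as.integer(frames_per_cycle),
                 n_cycles = as.integer(n_cycles),
                 image_size = as.integer(image_size),
                 speckle_strength = speckle_strength,
                 deformation_amplitude = deformation_amplitude,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Run expr with a private RNG stream, restoring the caller's stream after.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Class-specific layout: centers/radii/orientations of dark elliptical
# "chambers" inside a bright scan sector. Deterministic per class index,
# independent of the dataset seed.
class_layout <- function(k) {
  with_local_seed(97000L + k, {
    n_ell <- 2L + (k - 1L) %% 4L
    # spread first-chamber position systematically so layouts never collide
    ang0 <- 2 * pi * (k - 1) / 9
    data.frame(
      cx = pmin(pmax(0.5 + 0.22 * cos(ang0) + runif(n_ell, -0.12, 0.12), 0.22), 0.78),
      cy = pmin(pmax(0.52 + 0.18 * sin(ang0) + runif(n_ell, -0.15, 0.15), 0.28), 0.82),
      rx = runif(n_ell, 0.07, 0.15),
      ry = runif(n_ell, 0.07, 0.15),
      phi = runif(n_ell, 0, pi)
    )
  })
}

# Render a layout onto a size x size canvas: bright ultrasound-like sector
# with a mild radial gradient, dark soft-edged chambers.
render_template <- function(layout, size) {
  g <- (seq_len(size) - 0.5) / size
  X <- matrix(g, size, size, byrow = TRUE)   # column coordinate in [0,1]
  Y <- matrix(g, size, size)                 # row coordinate in [0,1]
  dx <- X - 0.5; dy <- Y - 0.06
  rad <- sqrt(dx^2 + dy^2)
  ang <- atan2(dx, dy)
  sector <- (dy > 0) & (abs(ang) < 0.72) & (rad < 0.92)
  canvas <- matrix(0.02, size, size)
  canvas[sector] <- 0.55 + 0.12 * (1 - rad[sector])
  for (e in seq_len(nrow(layout))) {
    co <- cos(layout$phi[e]); si <- sin(layout$phi[e])
    xr <- (X - layout$cx[e]) * co + (Y - layout$cy[e]) * si
    yr <- -(X - layout$cx[e]) * si + (Y - layout$cy[e]) * co
    m <- (xr / layout$rx[e])^2 + (yr / layout$ry[e])^2
    w <- pmin(pmax((1.25 - m) / 0.5, 0), 1)
    canvas <- canvas * (1 - w * sector) + 0.10 * w * sector
  }
  canvas
}

# Sinusoidal affine deformation for a frame phase in [0, 2*pi); amplitude is
# the maximal fractional perturbation of the affine coefficients.
cycle_affine <- function(phase, amplitude) {
  s1 <- sin(phase); s2 <- sin(phase + pi / 2); s3 <- sin(phase + pi / 4)
  c(1 + amplitude * s1,        0.5 * amplitude * s3, 0.3 * amplitude * s2,
    0.5 * amplitude * s2, 1 + amplitude * s2,        0.3 * amplitude * s1)
}

#' Generate a synthetic echo-like labeled image dataset
#'
#' For each class a deterministic base template (dark elliptical chambers on
#' a bright speckle-bearing sector) is perturbed once per subject, deformed
#' per frame by an affine map whose parameters vary sinusoidally with period
#' `frames_per_cycle`, and finally multiplied by unit-mean gamma speckle.
#' Images of the same class and cycle phase therefore share high mutual
#' information, which is the structure the similarity graph exploits.
#'
#' @param config a [synthetic_config()].
#' @return a list with `records` (list of image records, each holding
#'   `image_id`, `subject_id`, `view_label`, `frame_index` and `pixel_data`,
#'   a matrix in `[0, 1]`) and `manifest` (a data frame of the metadata).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be created by synthetic_config()")
  labels <- echo_views()[seq_len(config$n_classes)]
  n_frames <- config$frames_per_cycle * config$n_cycles
  records <- vector("list",
                    config$n_classes * config$n_subjects_per_class * n_frames)
  i <- 0L
  with_local_seed(config$seed, {
    for (k in seq_len(config$n_classes)) {
      layout <- class_layout(k)
      for (s in seq_len(config$n_subjects_per_class)) {
        lay <- layout
        lay$cx <- lay$cx + runif(nrow(lay), -0.02, 0.02)
        lay$cy <- lay$cy + runif(nrow(lay), -0.02, 0.02)
        lay$rx <- lay$rx * runif(nrow(lay), 0.9, 1.1)
        lay$ry <- lay$ry * runif(nrow(lay), 0.9, 1.1)
        base <- render_template(lay, config$image_size)
        subject_id <- sprintf("%s_s%02d", labels[k], s)
        for (t in seq_len(n_frames) - 1L) {
          phase <- 2 * pi * (t %% config$frames_per_cycle) /
            config$frames_per_cycle
          img <- if (config$deformation_amplitude > 0) {
            th <- matrix(cycle_affine(phase, config$deformation_amplitude),
                         nrow = 1)
            b <- base; dim(b) <- c(dim(base), 1L, 1L)
            w <- cpp_affine_warp(b, th)
            dim(w) <- dim(base)
            w
          } else base
          if (config$speckle_strength > 0) {
            sh <- 1 / config$speckle_strength^2
            img <- img * matrix(stats::rgamma(length(img), shape = sh,
                                              rate = sh), nrow(img))
          }
          img <- pmin(pmax(img, 0), 1)
          i <- i + 1L
          records[[i]] <- list(
            image_id = sprintf("%s_f%03d", subject_id, t),
            subject_id = subject_id, view_label = labels[k],
            frame_index = t, pixel_data = img)
        }
      }
    }
  })
  manifest <- data.frame(
    image_id = vapply(records, `[[`, "", "image_id"),
    image_path = NA_character_,
    subject_id = vapply(records, `[[`, "", "subject_id"),
    view_label = vapply(records, `[[`, "", "view_label"),
    frame_index = vapply(records, function(r) as.integer(r$frame_index), 0L),
    stringsAsFactors = FALSE)
  list(records = records, manifest = manifest)
}

#' Write a dataset to disk as PNG images plus a CSV manifest
#'
#' @param records list of image records from [generate_dataset()].
#' @param dir output directory; images go under `dir/images/`.
#' @return invisibly, the manifest path (`dir/manifest.csv`).
#' @export
write_manifest <- function(records, dir) {
  if (length(records) == 0L) stop("records must be non-empty")
  img_dir <- file.path(dir, "images")
  if (!dir.exists(img_dir) &&
      !dir.create(img_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", img_dir))
  rel <- character(length(records))
  for (i in seq_along(records)) {
    rel[i] <- file.path("images", paste0(records[[i]]$image_id, ".png"))
    png::writePNG(records[[i]]$pixel_data, file.path(dir, rel[i]))
  }
  manifest <- data.frame(
    image_id = vapply(records, `[[`, "", "image_id"),
    image_path = rel,
    subject_id = vapply(records, `[[`, "", "subject_id"),
    view_label = vapply(records, `[[`, "", "view_label"),
    frame_index = vapply(records, function(r) as.integer(r$frame_index), 0L),
    stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV manifest written by [write_manifest()]
#'
#' Image paths are interpreted relative to the manifest location; the
#' directory is attached as attribute `"dir"` so downstream loaders can
#' resolve them.
#'
#' @param path manifest CSV path.
#' @return a data frame with columns image_id, image_path, subject_id,
#'   view_label, frame_index (plus split, if present).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest '%s' does not exist", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "image_path", "subject_id", "view_label", "frame_index")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop(sprintf("manifest is missing columns: %s", paste(miss, collapse = ", ")))
  attr(m, "dir") <- dirname(normalizePath(path))
  m
}

# Load one grayscale image matrix for a manifest row.
load_image <- function(path, dir = NULL) {
  p <- if (!is.null(dir) && !grepl("^(/|[A-Za-z]:)", path))
    file.path(dir, path) else path
  if (!file.exists(p)) return(NULL)
  img <- png::readPNG(p)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}
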