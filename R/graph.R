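# Mutual-information similarity graph over training images.
#
# Edge weights are histogram mutual information between image intensity
# fields. The estimator is a convention (the weight scale has no canonical
# definition): grayscale, min-max normalization, optional downsampling,
# 32 equal-width bins, MI in bits with 0*log(0) = 0. The default threshold
# 0.2 and per-node cap of 10 neighbors are calibrated to that scale.

# Equal-width bin index in 1..n_bins for values already in [0, 1].
mi_bin <- function(v, n_bins) pmin(floor(v * n_bins) + 1L, n_bins)

# Grayscale + min-max normalize; constant images map to all zeros.
mi_normalize <- function(img) {
  if (length(dim(img)) == 3L)
    img <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  r <- range(img)
  if (!all(is.finite(r))) stop("image contains non-finite values")
  if (r[2] > r[1]) (img - r[1]) / (r[2] - r[1]) else img * 0
}

# MI in bits from two binned index vectors of equal length.
mi_from_binned <- function(ba, bb, n_bins) {
  joint <- tabulate((ba - 1L) * n_bins + bb, nbins = n_bins * n_bins)
  n <- length(ba)
  p <- joint / n
  pa <- colSums(matrix(p, n_bins, n_bins))   # marginal of ba
  pb <- rowSums(matrix(p, n_bins, n_bins))   # marginal of bb
  nz <- p > 0
  pp <- outer(pb, pa)                        # matches joint's (bb, ba) layout
  sum(p[nz] * log2(p[nz] / pp[nz]))
}

#' Histogram mutual information between two images
#'
#' Estimates I(A;B) in bits from the joint histogram of paired pixel
#' intensities after grayscale conversion and per-image min-max
#' normalization. Symmetric and nonnegative; a non-constant image with
#' itself gives its marginal entropy, constant images give 0.
#'
#' @param image_a,image_b images of identical spatial size (matrix or
#'   H x W x 3 array).
#' @param n_bins number of equal-width intensity bins (>= 2; default 32).
#' @return mutual information in bits.
#' @export
mutual_information <- function(image_a, image_b, n_bins = 32L) {
  if (length(n_bins) != 1L || n_bins < 2 || n_bins != round(n_bins))
    stop("n_bins must be an integer >= 2")
  a <- mi_normalize(image_a); b <- mi_normalize(image_b)
  if (!identical(dim(a), dim(b)))
    stop(sprintf("image size mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  mi_from_binned(mi_bin(as.vector(a), as.integer(n_bins)),
                 mi_bin(as.vector(b), as.integer(n_bins)),
                 as.integer(n_bins))
}

# Resolve images for manifest rows: from a named list/env keyed by image_id
# if given, else from disk. Errors list every missing image.
resolve_images <- function(manifest, images = NULL) {
  dir <- attr(manifest, "dir")
  out <- vector("list", nrow(manifest))
  names(out) <- manifest$image_id
  missing <- character(0)
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$image_id[i]
    img <- if (!is.null(images) && !is.null(images[[id]])) images[[id]]
           else if (!is.na(manifest$image_path[i]))
             load_image(manifest$image_path[i], dir)
    if (is.null(img)) missing <- c(missing, id) else out[[id]] <- img
  }
  if (length(missing))
    stop(sprintf("missing image files for: %s", paste(missing, collapse = ", ")))
  out
}

#' Build the intra-class mutual-information similarity graph
#'
#' Every training image is a node. For each node, all other images with the
#' same view label are candidates; candidates whose MI exceeds `threshold`
#' are kept, and only the `max_neighbors` highest-MI candidates are retained
#' (ties broken by image id, so construction is deterministic). Pairwise MI
#' is computed once per unordered pair; adjacency lists are directed
#' (per-node top-k) while weights are symmetric. If the manifest carries a
#' `split` column, only `"train"` rows enter the graph, so validation and
#' test images can never leak into the regularizer.
#'
#' @param manifest image manifest (see [read_manifest()]).
#' @param threshold minimal MI (exclusive) for an edge; default 0.2.
#' @param max_neighbors per-node neighbor cap; default 10.
#' @param n_bins histogram bins for the MI estimate; default 32.
#' @param mi_resize side to which images are downsampled before MI (default
#'   64); `NULL` keeps native resolution.
#' @param images optional named list of in-memory image matrices keyed by
#'   image_id (skips disk reads).
#' @param same_subject_only restrict candidates to the node's own subject
#'   (default `FALSE`: candidates span subjects within a class).
#' @return an object of class `"similarity_graph"`.
#' @export
build_graph <- function(manifest, threshold = 0.2, max_neighbors = 10L,
                        n_bins = 32L, mi_resize = 64L, images = NULL,
                        same_subject_only = FALSE) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("manifest must be a non-empty data frame")
  if (threshold < 0) stop("threshold must be >= 0")
  if (max_neighbors < 1) stop("max_neighbors must be >= 1")
  if ("split" %in% names(manifest))
    manifest <- manifest[manifest$split == "train", , drop = FALSE]
  if (nrow(manifest) == 0L) stop("manifest has no training rows")
  imgs <- resolve_images(manifest, images)
  binned <- lapply(imgs, function(img) {
    v <- mi_normalize(img)
    if (!is.null(mi_resize) && (nrow(v) != mi_resize || ncol(v) != mi_resize))
      v <- pmin(pmax(bilinear_resize(v, mi_resize, mi_resize), 0), 1)
    mi_bin(as.vector(v), as.integer(n_bins))
  })
  ids <- manifest$image_id
  labels <- stats::setNames(manifest$view_label, ids)
  subjects <- stats::setNames(manifest$subject_id, ids)
  adjacency <- stats::setNames(vector("list", length(ids)), ids)
  for (lab in unique(manifest$view_label)) {
    members <- ids[labels[ids] == lab]
    nm <- length(members)
    W <- matrix(0, nm, nm, dimnames = list(members, members))
    if (nm >= 2L) {
      for (i in seq_len(nm - 1L)) for (j in (i + 1L):nm) {
        w <- mi_from_binned(binned[[members[i]]], binned[[members[j]]],
                            as.integer(n_bins))
        W[i, j] <- w; W[j, i] <- w
      }
    }
    for (i in seq_len(nm)) {
      u <- members[i]
      cand <- members[-i]
      if (same_subject_only) cand <- cand[subjects[cand] == subjects[u]]
      w <- W[u, cand]
      keep <- w > threshold
      cand <- cand[keep]; w <- w[keep]
      if (length(cand)) {
        o <- order(-w, cand, method = "radix")
        o <- o[seq_len(min(length(o), max_neighbors))]
        adjacency[[u]] <- data.frame(v = cand[o], w = unname(w[o]),
                                     stringsAsFactors = FALSE)
      } else {
        adjacency[[u]] <- data.frame(v = character(0), w = numeric(0))
      }
    }
  }
  structure(list(nodes = ids, labels = labels, adjacency = adjacency,
                 threshold = threshold,
                 max_neighbors = as.integer(max_neighbors),
                 n_bins = as.integer(n_bins),
                 mi_resize = if (is.null(mi_resize)) NA_integer_
                             else as.integer(mi_resize)),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  deg <- vapply(x$adjacency, nrow, 0L)
  cat(sprintf(paste0("Mutual-information similarity graph: %d nodes, ",
                     "%d directed edges\n"), length(x$nodes), sum(deg)))
  cat(sprintf("  threshold > %g, per-node cap %d, degree range %d-%d\n",
              x$threshold, x$max_neighbors, min(deg), max(deg)))
  invisible(x)
}

#' Save a similarity graph as a text edge list
#'
#' One JSON header line (threshold, cap, bins, node ids and labels) followed
#' by tab-separated `u v weight` lines with weights at 12 significant
#' digits; round-trips losslessly through [load_graph()].
#'
#' @param graph a `"similarity_graph"`.
#' @param path output file.
#' @export
save_graph <- function(graph, path) {
  stopifnot(inherits(graph, "similarity_graph"))
  header <- jsonlite::toJSON(list(
    threshold = graph$threshold, max_neighbors = graph$max_neighbors,
    n_bins = graph$n_bins, mi_resize = graph$mi_resize,
    nodes = graph$nodes, labels = as.list(graph$labels)), auto_unbox = TRUE,
    digits = NA)
  lines <- character(0)
  for (u in graph$nodes) {
    adj <- graph$adjacency[[u]]
    if (nrow(adj))
      lines <- c(lines, sprintf("%s\t%s\t%.12g", u, adj$v, adj$w))
  }
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

#' Load a similarity graph saved by [save_graph()]
#'
#' Validates the stored invariants: every weight must exceed the stored
#' threshold, neighbor lists must respect the per-node cap and intra-class
#' constraint, and weights must be symmetric where both directions exist.
#'
#' @param path graph file path.
#' @return a `"similarity_graph"`.
#' @export
load_graph <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty graph file")
  header <- tryCatch(jsonlite::fromJSON(lines[1]),
                     error = function(e) stop("line 1: malformed JSON header"))
  nodes <- as.character(header$nodes)
  labels <- stats::setNames(as.character(unlist(header$labels)),
                            names(header$labels))
  adjacency <- stats::setNames(
    rep(list(data.frame(v = character(0), w = numeric(0))), length(nodes)),
    nodes)
  wmap <- new.env(parent = emptyenv())
  if (length(lines) > 1L) for (ln in 2:length(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L) stop(sprintf("line %d: expected 'u\\tv\\tweight'", ln))
    w <- suppressWarnings(as.numeric(f[3]))
    if (is.na(w)) stop(sprintf("line %d: non-numeric weight '%s'", ln, f[3]))
    if (w <= header$threshold)
      stop(sprintf("line %d: weight %g is not above threshold %g",
                   ln, w, header$threshold))
    if (!(f[1] %in% nodes) || !(f[2] %in% nodes))
      stop(sprintf("line %d: unknown node id", ln))
    if (!identical(labels[[f[1]]], labels[[f[2]]]))
      stop(sprintf("line %d: edge crosses view labels", ln))
    key <- paste(sort(f[1:2]), collapse = "\r")
    prev <- wmap[[key]]
    if (!is.null(prev) && abs(prev - w) > 1e-9)
      stop(sprintf("line %d: asymmetric weight for pair %s-%s", ln, f[1], f[2]))
    wmap[[key]] <- w
    adjacency[[f[1]]] <- rbind(adjacency[[f[1]]],
                               data.frame(v = f[2], w = w,
                                          stringsAsFactors = FALSE))
  }
  for (u in nodes) {
    if (nrow(adjacency[[u]]) > header$max_neighbors)
      stop(sprintf("node %s exceeds the neighbor cap %d", u,
                   header$max_neighbors))
    rownames(adjacency[[u]]) <- NULL
  }
  structure(list(nodes = nodes, labels = labels, adjacency = adjacency,
                 threshold = header$threshold,
                 max_neighbors = as.integer(header$max_neighbors),
                 n_bins = as.integer(header$n_bins),
                 mi_resize = as.integer(header$mi_resize)),
            class = "similarity_graph")
}
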