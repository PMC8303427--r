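# Shared fixtures, built in code and memoized for the test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- make()
  .fixture_cache[[name]]
}

# Small labeled dataset with split column and in-memory image store.
tiny_dataset <- function() {
  fixture("tiny_dataset", function() {
    cfg <- synthetic_config(n_classes = 3, n_subjects_per_class = 6,
                            frames_per_cycle = 4, n_cycles = 1,
                            image_size = 64, seed = 31)
    ds <- generate_dataset(cfg)
    man <- add_split(ds$manifest, split_by_subject(ds$manifest, seed = 4))
    imgs <- stats::setNames(lapply(ds$records, `[[`, "pixel_data"),
                            man$image_id)
    list(config = cfg, manifest = man, images = imgs, records = ds$records)
  })
}

# A similarity graph over the tiny dataset's training split.
tiny_graph <- function() {
  fixture("tiny_graph", function() {
    d <- tiny_dataset()
    build_graph(d$manifest, images = d$images)
  })
}

# A small untrained network on 64-px inputs (all unit tests use this size).
tiny_net <- function(n_classes = 3, seed = 11, ...) {
  init_network(network_config(backbone = "tiny", n_classes = n_classes,
                              input_size = 64, ...), seed = seed)
}

# Standardize a grayscale matrix to a given network input size.
std64 <- function(img) standardize_image(img, out_size = 64)

# Independent brute-force graph oracle: full pairwise MI matrix at the
# module's documented preprocessing, threshold, then per-node top-k with
# lexicographic tie-break. Mirrors the spec of the construction, not its
# code path.
brute_force_graph <- function(manifest, images, threshold = 0.2,
                              max_neighbors = 10, n_bins = 32,
                              mi_resize = 64) {
  prep <- lapply(images[manifest$image_id], function(img) {
    v <- img
    if (length(dim(v)) == 3L) v <- (v[, , 1] + v[, , 2] + v[, , 3]) / 3
    r <- range(v); v <- if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else v * 0
    if (nrow(v) != mi_resize)
      v <- pmin(pmax(echograph:::bilinear_resize(v, mi_resize, mi_resize), 0), 1)
    v
  })
  ids <- manifest$image_id
  lab <- stats::setNames(manifest$view_label, ids)
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    w <- mutual_information(prep[[ids[i]]], prep[[ids[j]]], n_bins)
    M[i, j] <- w; M[j, i] <- w
  }
  adj <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    cand <- ids[lab[ids] == lab[ids[i]] & ids != ids[i]]
    w <- M[ids[i], cand]
    keep <- w > threshold
    cand <- cand[keep]; w <- w[keep]
    o <- order(-w, cand, method = "radix")
    o <- o[seq_len(min(length(o), max_neighbors))]
    adj[[ids[i]]] <- data.frame(v = cand[o], w = unname(w[o]),
                                stringsAsFactors = FALSE)
  }
  adj
}
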