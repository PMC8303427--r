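# Training: neighbor-aware batch composition, the composite loss
#   total = supervised cross-entropy + alpha * sum_(u,v) w_uv * d(phi_u, phi_v)
# with d the mean squared error between embeddings, hand-derived backprop
# through the shared network, Adam, and early stopping on validation
# accuracy.

#' Training configuration
#'
#' Default protocol: Adam at learning rate 1e-4, 500
#' epochs of 100 steps, early stop after 5 stagnant epochs, alpha 0.4, 8
#' input images with 4 sampled neighbors each (40 images loaded per step),
#' no augmentation in graph mode. Desk-scale runs shrink epochs/steps, not
#' the loss.
#'
#' @param learning_rate Adam step size.
#' @param epochs maximal epochs.
#' @param steps_per_epoch optimizer steps per epoch.
#' @param patience epochs without validation improvement before stopping.
#' @param min_epochs epochs to run before early stopping may trigger
#'   (default 1, i.e. no burn-in). Short-budget runs trained from random
#'   initialization should allow a few burn-in epochs: before learning
#'   onset, validation accuracy on a small split is chance-level noise, and
#'   a lucky early epoch would otherwise freeze the model.
#' @param alpha weight of the graph regularizer.
#' @param n_inputs labeled images per step.
#' @param n_neighbors neighbors sampled per input (graph mode).
#' @param seed seed for all stochastic choices (init, batch draw, neighbor
#'   sampling, dropout, augmentation).
#' @param augmentation random affine jitter of training images; off by
#'   default (graph mode never augments, since graph weights are computed on
#'   the unaugmented images).
#' @return a list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 500L,
                         steps_per_epoch = 100L, patience = 5L,
                         min_epochs = 1L, alpha = 0.4,
                         n_inputs = 8L, n_neighbors = 4L, seed = 1L,
                         augmentation = FALSE) {
  chk <- function(x, nm) if (length(x) != 1L || !is.finite(x) || x < 1 ||
                             x != round(x))
    stop(sprintf("'%s' must be a positive integer", nm))
  chk(epochs, "epochs"); chk(steps_per_epoch, "steps_per_epoch")
  chk(patience, "patience"); chk(min_epochs, "min_epochs")
  chk(n_inputs, "n_inputs")
  if (n_neighbors < 0 || n_neighbors != round(n_neighbors))
    stop("'n_neighbors' must be a nonnegative integer")
  if (patience > epochs) stop("'patience' must not exceed 'epochs'")
  if (!is.finite(learning_rate) || learning_rate <= 0)
    stop("'learning_rate' must be positive")
  if (!is.finite(alpha) || alpha < 0) stop("'alpha' must be nonnegative")
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs), alpha = alpha,
                 n_inputs = as.integer(n_inputs),
                 n_neighbors = as.integer(n_neighbors),
                 seed = as.integer(seed), augmentation = isTRUE(augmentation)),
            class = "train_config")
}

#' Compose a neighbor-aware training batch
#'
#' Draws `n_inputs` labeled training images without replacement, and for
#' each, `min(n_neighbors, degree)` distinct neighbors uniformly without
#' replacement from its adjacency list. Isolated nodes yield empty neighbor
#' sets and contribute only to the supervised loss. Uses R's ambient RNG
#' stream (seeded by [fit_gcnn()]).
#'
#' @param graph a `"similarity_graph"` over the training split.
#' @param manifest the training-split manifest rows.
#' @param config a [train_config()].
#' @return a list of class `"training_batch"`: `inputs` (manifest rows) and
#'   `neighbor_sets` (one `data.frame(v, w)` per input).
#' @export
compose_batch <- function(graph, manifest, config) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("training split is empty")
  n <- min(config$n_inputs, nrow(manifest))
  rows <- sample.int(nrow(manifest), n)
  inputs <- manifest[rows, , drop = FALSE]
  neighbor_sets <- lapply(inputs$image_id, function(id) {
    adj <- if (!is.null(graph)) graph$adjacency[[id]] else NULL
    if (is.null(adj) || nrow(adj) == 0L || config$n_neighbors == 0L)
      return(data.frame(v = character(0), w = numeric(0)))
    take <- min(config$n_neighbors, nrow(adj))
    adj[sample.int(nrow(adj), take), , drop = FALSE]
  })
  structure(list(inputs = inputs, neighbor_sets = neighbor_sets),
            class = "training_batch")
}

#' Graph regularizer on embedding pairs
#'
#' `sum_p w_p * mean((u_p - v_p)^2)` over aligned rows of the two embedding
#' matrices: the similarity-weighted mean squared error between the
#' embeddings of each input and its sampled neighbor. Zero when there are no
#' pairs.
#'
#' @param input_embeddings,neighbor_embeddings P x D matrices, row p holding
#'   the embeddings of the two ends of pair p.
#' @param weights length-P edge weights.
#' @return a nonnegative scalar.
#' @export
graph_regularizer <- function(input_embeddings, neighbor_embeddings, weights) {
  u <- as.matrix(input_embeddings); v <- as.matrix(neighbor_embeddings)
  if (!all(dim(u) == dim(v)))
    stop(sprintf("embedding dimension mismatch: %s vs %s",
                 paste(dim(u), collapse = "x"), paste(dim(v), collapse = "x")))
  if (nrow(u) == 0L) return(0)
  if (length(weights) != nrow(u))
    stop("one weight required per embedding pair")
  sum(weights * rowMeans((u - v)^2))
}

# Stack standardized images for ids from a store (list keyed by image_id).
stack_images <- function(ids, store, input_size) {
  x <- array(0, c(input_size, input_size, 3L, length(ids)))
  for (i in seq_along(ids)) {
    img <- store[[ids[i]]]
    if (is.null(img)) stop(sprintf("no image available for id '%s'", ids[i]))
    x[, , , i] <- img
  }
  x
}

# Map a batch to tensors: inputs first, then neighbor images (duplicates
# kept), plus the pair index (u row, v row, weight).
batch_tensors <- function(batch, store, input_size) {
  n_in <- nrow(batch$inputs)
  nb_ids <- unlist(lapply(batch$neighbor_sets, `[[`, "v"))
  ids <- c(batch$inputs$image_id, nb_ids)
  x <- stack_images(ids, store, input_size)
  ui <- rep(seq_len(n_in), vapply(batch$neighbor_sets, nrow, 0L))
  pairs <- list(ui = ui,
                vi = if (length(nb_ids)) n_in + seq_along(nb_ids) else integer(0),
                w = unlist(lapply(batch$neighbor_sets, `[[`, "w"),
                           use.names = FALSE))
  list(x = x, n_in = n_in, pairs = pairs)
}

#' Evaluate the composite loss on a batch
#'
#' Recomputes, in evaluation mode (no dropout), the supervised cross-entropy
#' of the labeled inputs, the graph regularizer over the batch's sampled
#' neighbor pairs, and their weighted sum. The report satisfies
#' `total = supervised + alpha * graph` to machine precision.
#'
#' @param batch a [compose_batch()] result.
#' @param net a `"gcnn_net"` or fitted model.
#' @param images named list of standardized image arrays keyed by image_id
#'   (covering inputs and neighbors).
#' @param alpha graph-term weight.
#' @param classes class vocabulary defining label indices (defaults to the
#'   sorted labels present).
#' @return a list of class `"loss_report"`: `supervised`, `graph`, `alpha`,
#'   `total`.
#' @export
total_loss <- function(batch, net, images, alpha = 0.4, classes = NULL) {
  net <- as_net(net)
  if (is.null(classes)) classes <- sort(unique(batch$inputs$view_label))
  y <- match(batch$inputs$view_label, classes)
  if (anyNA(y))
    stop(sprintf("label outside vocabulary: %s",
                 paste(setdiff(batch$inputs$view_label, classes), collapse = ", ")))
  bt <- batch_tensors(batch, images, net$config$input_size)
  fw <- nn_forward(net, bt$x)
  sup <- cross_entropy(fw$probs[seq_len(bt$n_in), , drop = FALSE], y)
  gr <- graph_regularizer(fw$embedding[bt$pairs$ui, , drop = FALSE],
                          fw$embedding[bt$pairs$vi, , drop = FALSE],
                          bt$pairs$w)
  structure(list(supervised = sup, graph = gr, alpha = alpha,
                 total = sup + alpha * gr), class = "loss_report")
}

# Full forward + backward for one step. x holds inputs first (n_in rows of
# the 4th dimension), then neighbor images; pairs index rows of x.
loss_and_grads <- function(net, x, y, n_in, pairs, alpha, train = TRUE) {
  cfg <- net$config; p <- net$params
  M <- dim(x)[4]; C <- cfg$embedding_channels
  mask <- if (train && cfg$dropout_rate > 0)
    matrix((stats::runif(M * C) >= cfg$dropout_rate) / (1 - cfg$dropout_rate),
           M, C)
  else NULL
  fw <- nn_forward(net, x, mask)
  probs_in <- fw$probs[seq_len(n_in), , drop = FALSE]
  sup <- cross_entropy(probs_in, y)
  dlogits <- matrix(0, M, cfg$n_classes)
  dlogits[seq_len(n_in), ] <- cross_entropy_dlogits(probs_in, y)
  E <- fw$embedding
  gval <- 0
  demb_extra <- matrix(0, M, C)
  P <- length(pairs$ui)
  if (P > 0L && alpha > 0) {
    diff <- E[pairs$ui, , drop = FALSE] - E[pairs$vi, , drop = FALSE]
    gval <- sum(pairs$w * rowMeans(diff^2))
    gd <- diff * (2 * alpha * pairs$w / C)
    for (k in seq_len(P)) {
      demb_extra[pairs$ui[k], ] <- demb_extra[pairs$ui[k], ] + gd[k, ]
      demb_extra[pairs$vi[k], ] <- demb_extra[pairs$vi[k], ] - gd[k, ]
    }
  } else if (P > 0L) {
    diff <- E[pairs$ui, , drop = FALSE] - E[pairs$vi, , drop = FALSE]
    gval <- sum(pairs$w * rowMeans(diff^2))
  }
  grads <- nn_backward(net, fw, dlogits, demb_extra, mask)
  list(report = list(supervised = sup, graph = gval, alpha = alpha,
                     total = sup + alpha * gval),
       grads = grads)
}

nn_backward <- function(net, fw, dlogits, demb_extra, mask) {
  cfg <- net$config; p <- net$params
  g <- list()
  hb <- fc_bwd(fw$dropped, p$head_W, dlogits)
  g$head_W <- hb$dW; g$head_b <- hb$db
  demb <- if (is.null(mask)) hb$dX else hb$dX * mask
  demb <- demb + demb_extra                 # graph term bypasses dropout
  dm <- dim(if (cfg$use_se) fw$se$out else fw$bb$maps)
  dmaps <- gap_bwd(demb, dm[1], dm[2])
  if (cfg$use_se) {
    se <- fw$se
    dF1 <- dmaps * se$gf
    m <- matrix(dmaps * fw$bb$maps, nrow = dm[1] * dm[2])
    dgate <- t(matrix(colSums(m), nrow = dm[3]))
    dz2 <- dgate * se$g * (1 - se$g)
    f2 <- fc_bwd(se$a1, p$se_fc2_W, dz2)
    g$se_fc2_W <- f2$dW; g$se_fc2_b <- f2$db
    dz1 <- relu_bwd(f2$dX, se$a1)
    f1 <- fc_bwd(se$s, p$se_fc1_W, dz1)
    g$se_fc1_W <- f1$dW; g$se_fc1_b <- f1$db
    dmaps <- dF1 + gap_bwd(f1$dX, dm[1], dm[2])
  }
  for (i in 3:1) {
    cc <- fw$bb$caches[[i]]
    dact <- relu_bwd(dmaps, cc$act)
    want <- i > 1L || cfg$use_stm
    cb <- conv_bwd(cc$conv, p[[sprintf("conv%d_W", i)]], dact, want_dx = want)
    g[[sprintf("conv%d_W", i)]] <- cb$dW
    g[[sprintf("conv%d_b", i)]] <- cb$db
    dmaps <- cb$dX
  }
  if (cfg$use_stm) {
    dtheta <- cpp_warp_pool_dtheta(fw$x, fw$loc$theta, dmaps, fw$pool_s)
    lf <- fc_bwd(fw$loc$g, p$loc_fc_W, dtheta)
    g$loc_fc_W <- lf$dW; g$loc_fc_b <- lf$db
    da <- dim(fw$loc$act)
    dact <- relu_bwd(gap_bwd(lf$dX, da[1], da[2]), fw$loc$act)
    cb <- conv_bwd(fw$loc$conv, p$loc_conv_W, dact, want_dx = FALSE)
    g$loc_conv_W <- cb$dW; g$loc_conv_b <- cb$db
  }
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(a) a * 0),
       v = lapply(params, function(a) a * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Random affine jitter (small rotation, isotropic scale, translation) used
# only when augmentation is on (never in graph mode).
augment_batch <- function(x) {
  n <- dim(x)[4]
  ang <- stats::runif(n, -0.12, 0.12)
  sc <- stats::runif(n, 0.95, 1.05)
  th <- cbind(sc * cos(ang), -sc * sin(ang), stats::runif(n, -0.08, 0.08),
              sc * sin(ang), sc * cos(ang), stats::runif(n, -0.08, 0.08))
  cpp_affine_warp(x, th)
}

# Build a standardized image store for manifest rows.
image_store <- function(manifest, images, input_size) {
  raw <- resolve_images(manifest, images)
  lapply(raw, function(img) standardize_image(img, out_size = input_size))
}

predict_probs <- function(net, x, chunk = 64L) {
  n <- dim(x)[4]
  out <- matrix(0, n, net$config$n_classes)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out[s:e, ] <- nn_forward(net, x[, , , s:e, drop = FALSE])$probs
  }
  out
}

#' Fit the graph-constrained view classifier
#'
#' Trains the network by Adam on batches of labeled images plus their
#' sampled graph neighbors, minimizing cross-entropy plus
#' `alpha * sum w_uv * d(phi_u, phi_v)`; the inputs and their neighbors
#' share one set of network weights, and gradients flow through both sides
#' of `d`. Validation accuracy is evaluated every epoch; training stops when
#' it has not improved for `patience` epochs and the weights of the best
#' epoch (ties favoring the earlier one) are returned. Without a graph this
#' reduces to standard supervised training.
#'
#' @param manifest manifest with `split` column (`train` and `validation`
#'   rows required; see [split_by_subject()]).
#' @param graph a `"similarity_graph"` built on the training split, or
#'   `NULL` for plain supervised training.
#' @param net_config a [network_config()].
#' @param config a [train_config()].
#' @param images optional named list of raw image matrices keyed by
#'   image_id (skips disk reads).
#' @return an object of class `"echo_gcnn"`: the trained network, the class
#'   vocabulary, per-epoch history (supervised, graph, total losses and
#'   validation accuracy), the best epoch, and the training subjects.
#' @export
fit_gcnn <- function(manifest, graph = NULL,
                     net_config = network_config(),
                     config = train_config(), images = NULL) {
  if (!all(c("split", "view_label", "subject_id", "image_id") %in% names(manifest)))
    stop("manifest needs image_id, subject_id, view_label and split columns")
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  va <- manifest[manifest$split == "validation", , drop = FALSE]
  if (nrow(tr) == 0L) stop("training split is empty")
  if (nrow(va) == 0L) stop("validation split is empty")
  overlap <- intersect(unique(tr$subject_id), unique(va$subject_id))
  if (length(overlap))
    stop(sprintf("subjects appear in both train and validation: %s",
                 paste(overlap, collapse = ", ")))
  classes <- intersect(echo_views(), unique(manifest$view_label))
  if (length(classes) == 0L) classes <- sort(unique(manifest$view_label))
  if (length(classes) != net_config$n_classes)
    stop(sprintf("network expects %d classes but manifest has %d",
                 net_config$n_classes, length(classes)))
  if (!is.null(graph)) {
    extra <- setdiff(names(graph$adjacency)[vapply(graph$adjacency, nrow, 0L) > 0],
                     tr$image_id)
    if (length(extra))
      stop("graph contains non-training nodes with edges; rebuild it on the training split")
  }
  attr_dir <- attr(manifest, "dir")
  attr(tr, "dir") <- attr_dir; attr(va, "dir") <- attr_dir
  store_tr <- image_store(tr, images, net_config$input_size)
  x_va <- stack_images(va$image_id,
                       image_store(va, images, net_config$input_size),
                       net_config$input_size)
  y_va <- match(va$view_label, classes)
  augment <- config$augmentation && is.null(graph)
  with_local_seed(config$seed, {
    net <- init_network(net_config, seed = config$seed)
    opt <- adam_init(net$params)
    history <- data.frame(epoch = integer(0), supervised = numeric(0),
                          graph = numeric(0), total = numeric(0),
                          val_accuracy = numeric(0))
    best_acc <- -Inf; best_epoch <- 0L; best_params <- net$params
    stagnant <- 0L
    for (epoch in seq_len(config$epochs)) {
      acc_sup <- acc_gr <- acc_tot <- 0
      for (step in seq_len(config$steps_per_epoch)) {
        batch <- compose_batch(graph, tr, config)
        bt <- batch_tensors(batch, store_tr, net_config$input_size)
        if (augment) bt$x <- augment_batch(bt$x)
        y <- match(batch$inputs$view_label, classes)
        lg <- loss_and_grads(net, bt$x, y, bt$n_in, bt$pairs,
                             if (is.null(graph)) 0 else config$alpha)
        upd <- adam_step(net$params, lg$grads, opt, config$learning_rate)
        net$params <- upd$params; opt <- upd$state
        acc_sup <- acc_sup + lg$report$supervised
        acc_gr <- acc_gr + lg$report$graph
        acc_tot <- acc_tot + lg$report$total
      }
      pv <- predict_probs(net, x_va)
      val_acc <- mean(max.col(pv, ties.method = "first") == y_va)
      ns <- config$steps_per_epoch
      history <- rbind(history, data.frame(
        epoch = epoch, supervised = acc_sup / ns, graph = acc_gr / ns,
        total = acc_tot / ns, val_accuracy = val_acc))
      if (val_acc > best_acc) {
        best_acc <- val_acc; best_epoch <- epoch
        best_params <- net$params
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (epoch > config$min_epochs && stagnant >= config$patience) break
      }
    }
    net$params <- best_params
    structure(list(net = net, classes = classes, history = history,
                   best_epoch = best_epoch,
                   train_subjects = unique(tr$subject_id),
                   train_config = config), class = "echo_gcnn")
  })
}

#' Ablation study over the four architecture variants
#'
#' Trains, with identical splits and seeds, the plain backbone, backbone+SE,
#' STM+backbone+SE, and the full graph+STM+backbone+SE model, and reports
#' overall test accuracy per variant. Non-graph variants train with random
#' affine augmentation; the graph variant trains without augmentation, as
#' the similarity graph is computed on the original images.
#'
#' @param manifest manifest with train/validation/test splits.
#' @param graph similarity graph over the training split (for the full
#'   variant).
#' @param net_config base [network_config()]; ablation switches are applied
#'   on top.
#' @param config base [train_config()] used by the graph variant; non-graph
#'   variants use `n_inputs = plain_batch` supervised images per step.
#' @param seeds seeds replicated per variant.
#' @param images optional in-memory image store.
#' @param plain_batch supervised batch size for non-graph variants
#'   (default 32).
#' @return a list of class `"gcnn_ablation"`: `runs` (variant x seed
#'   accuracies) and `table` (mean overall accuracy per variant, in the
#'   order backbone, +SE, +STM+SE, graph+STM+SE).
#' @export
run_ablation <- function(manifest, graph, net_config = network_config(),
                         config = train_config(), seeds = c(1L, 2L, 3L),
                         images = NULL, plain_batch = 32L) {
  variants <- data.frame(
    name = c("backbone", "backbone+SE", "STM+backbone+SE",
             "graph+STM+backbone+SE"),
    use_stm = c(FALSE, FALSE, TRUE, TRUE),
    use_se = c(FALSE, TRUE, TRUE, TRUE),
    use_graph = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  runs <- expand.grid(variant = variants$name, seed = seeds,
                      stringsAsFactors = FALSE)
  runs$accuracy <- NA_real_
  for (r in seq_len(nrow(runs))) {
    v <- variants[variants$name == runs$variant[r], ]
    ncfg <- net_config
    ncfg$use_stm <- v$use_stm; ncfg$use_se <- v$use_se
    tcfg <- config
    tcfg$seed <- as.integer(runs$seed[r])
    if (!v$use_graph) {
      tcfg$n_inputs <- as.integer(plain_batch)
      tcfg$n_neighbors <- 0L
      tcfg$augmentation <- TRUE
    }
    fit <- fit_gcnn(manifest, graph = if (v$use_graph) graph else NULL,
                    net_config = ncfg, config = tcfg, images = images)
    ev <- evaluate_model(fit, manifest, split = "test", images = images)
    runs$accuracy[r] <- ev$overall_accuracy
  }
  tab <- aggregate(accuracy ~ variant, data = runs, FUN = mean)
  tab <- tab[match(variants$name, tab$variant), , drop = FALSE]
  names(tab) <- c("variant", "mean_test_accuracy")
  rownames(tab) <- NULL
  structure(list(runs = runs, table = tab), class = "gcnn_ablation")
}

#' @export
print.gcnn_ablation <- function(x, ...) {
  cat("Ablation over architecture variants (overall test accuracy)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("Loss: total %.6f = supervised %.6f + %.2f * graph %.6f\n",
              x$total, x$supervised, x$alpha, x$graph))
  invisible(x)
}
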