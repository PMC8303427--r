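make_graph_stub <- function(adj, labels) {
  structure(list(nodes = names(adj), labels = labels, adjacency = adj,
                 threshold = 0.2, max_neighbors = 10L, n_bins = 32L,
                 mi_resize = 64L), class = "similarity_graph")
}

test_that("batch composition samples the documented neighbor counts", {
  man <- data.frame(image_id = sprintf("n%02d", 1:13),
                    subject_id = "s1", view_label = "A4C",
                    frame_index = 0, stringsAsFactors = FALSE)
  adj <- list(
    n01 = data.frame(v = sprintf("n%02d", 2:11), w = seq(3, 2.1, by = -0.1)),
    n02 = data.frame(v = c("n01", "n03"), w = c(2.5, 2.4)),
    n03 = data.frame(v = character(0), w = numeric(0)))
  for (id in man$image_id[-(1:3)])
    adj[[id]] <- data.frame(v = "n01", w = 2.2)
  g <- make_graph_stub(adj, stats::setNames(man$view_label, man$image_id))
  cfg <- train_config(n_inputs = 3, n_neighbors = 4, epochs = 1,
                      steps_per_epoch = 1, patience = 1)
  set.seed(1)
  for (k in 1:20) {
    b <- compose_batch(g, man, cfg)
    expect_equal(nrow(b$inputs), 3L)
    expect_equal(anyDuplicated(b$inputs$image_id), 0L)
    for (i in seq_len(3)) {
      id <- b$inputs$image_id[i]
      ns <- b$neighbor_sets[[i]]
      expect_equal(nrow(ns), min(4L, nrow(adj[[id]])))
      expect_equal(anyDuplicated(ns$v), 0L)
      expect_true(all(ns$v %in% adj[[id]]$v))
      expect_equal(ns$w, adj[[id]]$w[match(ns$v, adj[[id]]$v)])
    }
  }
  expect_error(compose_batch(g, man[0, ], cfg), "empty")
})

test_that("the graph regularizer matches its closed form", {
  expect_equal(graph_regularizer(matrix(1:6, 2), matrix(1:6, 2), c(1, 2)), 0)
  # one pair, w = 0.5, u = (1,1), v = (0,1): 0.5 * mean(c(1,0)^2) = 0.25
  expect_equal(graph_regularizer(matrix(c(1, 1), 1), matrix(c(0, 1), 1), 0.5),
               0.25)
  u <- matrix(rnorm(12), 3); v <- matrix(rnorm(12), 3); w <- runif(3)
  expect_equal(graph_regularizer(u, v, 2 * w),
               2 * graph_regularizer(u, v, w), tolerance = 1e-12)
  expect_equal(graph_regularizer(matrix(0, 0, 4), matrix(0, 0, 4),
                                 numeric(0)), 0)
  expect_error(graph_regularizer(matrix(0, 2, 3), matrix(0, 2, 4), c(1, 1)),
               "dimension mismatch")
  expect_error(graph_regularizer(u, v, 1), "one weight")
})

test_that("the composite loss matches an independent recomputation", {
  d <- tiny_dataset()
  man <- d$manifest
  store <- lapply(d$images, standardize_image, out_size = 64)
  net <- tiny_net(n_classes = 3, seed = 5)
  ids <- man$image_id[man$split == "train"][1:4]
  batch <- structure(list(
    inputs = man[man$image_id %in% ids[1:2], , drop = FALSE],
    neighbor_sets = list(
      data.frame(v = ids[3], w = 1.7, stringsAsFactors = FALSE),
      data.frame(v = ids[4], w = 2.3, stringsAsFactors = FALSE))),
    class = "training_batch")
  classes <- sort(unique(man$view_label))
  rep_ <- total_loss(batch, net, store, alpha = 0.4, classes = classes)

  # from-scratch oracle using only the public forward pass
  fw <- forward_pass(net, echograph:::stack_images(ids, store, 64))
  y <- match(batch$inputs$view_label, classes)
  ce <- -mean(log(fw$probs[cbind(1:2, y)]))
  gr <- 1.7 * mean((fw$embedding[1, ] - fw$embedding[3, ])^2) +
        2.3 * mean((fw$embedding[2, ] - fw$embedding[4, ])^2)
  expect_equal(rep_$supervised, ce, tolerance = 1e-6)
  expect_equal(rep_$graph, gr, tolerance = 1e-6)
  expect_equal(rep_$total, ce + 0.4 * gr, tolerance = 1e-6)
  expect_lt(abs(rep_$total - (rep_$supervised + rep_$alpha * rep_$graph)),
            1e-9)

  # alpha = 0 reduces exactly to plain cross-entropy
  rep0 <- total_loss(batch, net, store, alpha = 0, classes = classes)
  expect_identical(rep0$total, rep0$supervised)
  expect_error(total_loss(batch, net, store, classes = c("X", "Y", "Z")),
               "label outside vocabulary")
})

test_that("perfect predictions with identical embeddings give zero loss", {
  net <- tiny_net(n_classes = 3, seed = 1)
  for (nm in grep("^(conv|loc_conv|se_fc|head)", names(net$params), value = TRUE))
    net$params[[nm]][] <- 0
  net$params$loc_fc_W[] <- 0; net$params$loc_fc_b <- c(1, 0, 0, 0, 1, 0)
  net$params$head_b <- c(60, 0, 0)    # saturate the true class
  man <- data.frame(image_id = c("a", "b"), subject_id = "s",
                    view_label = "A2C", frame_index = 0,
                    stringsAsFactors = FALSE)
  batch <- structure(list(inputs = man, neighbor_sets = list(
    data.frame(v = "b", w = 3), data.frame(v = "a", w = 3))),
    class = "training_batch")
  store <- list(a = array(runif(64 * 64 * 3), c(64, 64, 3)),
                b = array(runif(64 * 64 * 3), c(64, 64, 3)))
  rep_ <- total_loss(batch, net, store, alpha = 0.4, classes = c("A2C", "B", "C"))
  expect_equal(rep_$graph, 0)
  expect_lt(rep_$total, 1e-8)
})

test_that("early stopping halts after patience stagnant epochs", {
  d <- tiny_dataset()
  ncfg <- network_config(backbone = "tiny", n_classes = 3, input_size = 64)
  # learning rate so small the validation accuracy is frozen by construction
  tcfg <- train_config(learning_rate = 1e-12, epochs = 10, steps_per_epoch = 2,
                       patience = 1, n_inputs = 4, n_neighbors = 2, seed = 3)
  fit <- fit_gcnn(d$manifest, graph = NULL, net_config = ncfg, config = tcfg,
                  images = d$images)
  expect_equal(nrow(fit$history), 2L)
  expect_equal(fit$best_epoch, 1L)

  tcfg$patience <- 3L
  fit3 <- fit_gcnn(d$manifest, graph = NULL, net_config = ncfg, config = tcfg,
                   images = d$images)
  expect_equal(nrow(fit3$history), 4L)
  expect_lte(nrow(fit3$history), tcfg$epochs)
})

test_that("training records a consistent loss decomposition every epoch", {
  d <- tiny_dataset()
  g <- tiny_graph()
  ncfg <- network_config(backbone = "tiny", n_classes = 3, input_size = 64)
  tcfg <- train_config(learning_rate = 1e-3, epochs = 3, steps_per_epoch = 4,
                       patience = 3, n_inputs = 4, n_neighbors = 2, seed = 7)
  fit <- fit_gcnn(d$manifest, graph = g, net_config = ncfg, config = tcfg,
                  images = d$images)
  h <- fit$history
  expect_named(h, c("epoch", "supervised", "graph", "total", "val_accuracy"))
  expect_true(all(abs(h$total - (h$supervised + tcfg$alpha * h$graph)) < 1e-9))
  expect_true(all(h$graph >= 0))
  expect_true(all(h$val_accuracy >= 0 & h$val_accuracy <= 1))
  expect_s3_class(fit, "echo_gcnn")
  expect_output(print(fit), "Graph-constrained")
})

test_that("training without a graph is plain supervised learning", {
  d <- tiny_dataset()
  ncfg <- network_config(backbone = "tiny", n_classes = 3, input_size = 64,
                         use_stm = FALSE, use_se = FALSE)
  tcfg <- train_config(learning_rate = 1e-3, epochs = 2, steps_per_epoch = 3,
                       patience = 2, n_inputs = 6, n_neighbors = 0, seed = 2)
  fit <- fit_gcnn(d$manifest, graph = NULL, net_config = ncfg, config = tcfg,
                  images = d$images)
  expect_true(all(fit$history$graph == 0))
  expect_true(all(fit$history$total == fit$history$supervised))
})

test_that("subject leakage between splits is refused", {
  d <- tiny_dataset()
  man <- d$manifest
  # force one validation subject to also have a train row
  vsub <- man$subject_id[man$split == "validation"][1]
  leaky <- man
  leaky$split[which(leaky$subject_id == vsub)[1]] <- "train"
  ncfg <- network_config(backbone = "tiny", n_classes = 3, input_size = 64)
  tcfg <- train_config(epochs = 1, steps_per_epoch = 1, patience = 1, seed = 1)
  expect_error(fit_gcnn(leaky, NULL, ncfg, tcfg, images = d$images),
               "both train and validation")
})

test_that("a graph built over non-training images is refused", {
  d <- tiny_dataset()
  man <- d$manifest
  nontrain <- man$image_id[man$split == "test"][1:2]
  adj <- stats::setNames(list(
    data.frame(v = nontrain[2], w = 1.0, stringsAsFactors = FALSE),
    data.frame(v = nontrain[1], w = 1.0, stringsAsFactors = FALSE)), nontrain)
  g <- make_graph_stub(adj, stats::setNames(man$view_label, man$image_id))
  ncfg <- network_config(backbone = "tiny", n_classes = 3, input_size = 64)
  tcfg <- train_config(epochs = 1, steps_per_epoch = 1, patience = 1, seed = 1)
  expect_error(fit_gcnn(man, g, ncfg, tcfg, images = d$images),
               "non-training")
})

test_that("training configuration invariants are enforced", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(patience = 10, epochs = 5), "patience")
  expect_error(train_config(learning_rate = -1), "learning_rate")
  expect_error(train_config(alpha = -0.1), "alpha")
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$epochs, 500L)
  expect_equal(cfg$steps_per_epoch, 100L)
  expect_equal(cfg$patience, 5L)
  expect_equal(cfg$alpha, 0.4)
})
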