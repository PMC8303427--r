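test_that("confusion matrix counts match hand tallies", {
  m <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(unname(m), matrix(c(1, 0, 1, 1), 2))
  perfect <- confusion_matrix(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(unname(perfect), diag(3))
  expect_equal(rownames(m), c("A", "B"))
  expect_error(confusion_matrix(character(0), character(0)), "non-empty")
  expect_error(confusion_matrix("A", c("A", "B")), "equal length")
  expect_error(confusion_matrix("A", "Z", classes = c("A", "B")), "unknown label")
})

test_that("row sums and the trace identity hold on random confusions", {
  set.seed(6)
  for (k in 1:10) {
    truth <- sample(LETTERS[1:4], 60, TRUE)
    pred <- sample(LETTERS[1:4], 60, TRUE)
    m <- confusion_matrix(truth, pred, classes = LETTERS[1:4])
    expect_equal(sum(m), 60)
    expect_equal(unname(rowSums(m)), unname(as.vector(table(factor(truth, LETTERS[1:4])))))
    pc <- per_class_metrics(m)
    expect_equal(attr(pc, "overall_accuracy"), sum(diag(m)) / sum(m))
  }
})

test_that("per-class formulas match the one-vs-rest definitions on a hand case", {
  conf <- matrix(c(2, 0, 0,
                   1, 1, 0,
                   0, 0, 2), 3, byrow = TRUE,
                 dimnames = list(true = c("c1", "c2", "c3"),
                                 predicted = c("c1", "c2", "c3")))
  pc <- per_class_metrics(conf)
  # class 2: TP=1, FN=1, FP=0, TN=4 over N=6
  expect_equal(pc$sensitivity[2], 1 / 2)
  expect_equal(pc$specificity[2], 4 / 4)
  expect_equal(pc$accuracy[2], 5 / 6)
  # class 1: TP=2, FN=0, FP=1, TN=3
  expect_equal(pc$sensitivity[1], 1)
  expect_equal(pc$specificity[1], 3 / 4)
  expect_equal(attr(pc, "overall_accuracy"), 5 / 6)
})

test_that("AUC is 1 under perfect separation and 0.5 for uninformative scores", {
  truth <- rep(c("A", "B", "C"), each = 4)
  scores <- matrix(1 / 3, 12, 3, dimnames = list(NULL, c("A", "B", "C")))
  conf <- confusion_matrix(truth, rep("A", 12), classes = c("A", "B", "C"))
  pc <- per_class_metrics(conf, scores = scores, true_labels = truth)
  expect_equal(pc$auc, rep(0.5, 3))
  perfect <- diag(3)[match(truth, c("A", "B", "C")), ]
  pcp <- per_class_metrics(
    confusion_matrix(truth, truth), scores = perfect, true_labels = truth)
  expect_equal(pcp$auc, rep(1, 3))
  expect_equal(pcp$sensitivity, rep(1, 3))
  expect_equal(pcp$specificity, rep(1, 3))
  expect_equal(attr(pcp, "mean_auc"), 1)
})

test_that("AUC agrees with an independent reference implementation", {
  set.seed(13)
  truth <- sample(c("A", "B", "C"), 80, TRUE)
  scores <- matrix(runif(240), 80, 3, dimnames = list(NULL, c("A", "B", "C")))
  scores <- scores / rowSums(scores)
  conf <- confusion_matrix(truth, c("A", "B", "C")[max.col(scores)],
                           classes = c("A", "B", "C"))
  pc <- per_class_metrics(conf, scores = scores, true_labels = truth)
  for (k in 1:3) {
    cls <- c("A", "B", "C")[k]
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = factor(truth == cls, c(FALSE, TRUE)),
      predictor = scores[, k], quiet = TRUE, direction = "<")))
    expect_equal(pc$auc[k], ref, tolerance = 1e-9)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  truth <- sample(c("A", "B"), 50, TRUE)
  s <- runif(50)
  pos <- truth == "A"
  a1 <- echograph:::auc_ovr(s, pos)
  expect_equal(echograph:::auc_ovr(exp(3 * s) - 1, pos), a1, tolerance = 1e-12)
  expect_equal(echograph:::auc_ovr(rank(s), pos), a1, tolerance = 1e-12)
})

test_that("swapping the positive class swaps sensitivity and specificity", {
  truth <- c("A", "A", "A", "B", "B")
  pred <- c("A", "B", "A", "B", "A")
  pc <- per_class_metrics(confusion_matrix(truth, pred, classes = c("A", "B")))
  expect_equal(pc$sensitivity[1], pc$specificity[2])
  expect_equal(pc$specificity[1], pc$sensitivity[2])
})

test_that("a class absent from the truth yields a missing AUC with a warning", {
  truth <- c("A", "A", "B")
  scores <- matrix(runif(9), 3, 3, dimnames = list(NULL, c("A", "B", "C")))
  conf <- confusion_matrix(truth, c("A", "B", "B"), classes = c("A", "B", "C"))
  expect_warning(pc <- per_class_metrics(conf, scores = scores,
                                         true_labels = truth), "absent")
  expect_true(is.na(pc$auc[3]))
  expect_false(anyNA(pc$auc[1:2]))
})

test_that("model evaluation satisfies the report invariants end to end", {
  d <- tiny_dataset()
  ncfg <- network_config(backbone = "tiny", n_classes = 3, input_size = 64)
  tcfg <- train_config(learning_rate = 1e-3, epochs = 2, steps_per_epoch = 3,
                       patience = 2, n_inputs = 4, n_neighbors = 2, seed = 9)
  fit <- fit_gcnn(d$manifest, graph = tiny_graph(), net_config = ncfg,
                  config = tcfg, images = d$images)
  ev <- evaluate_model(fit, d$manifest, split = "test", images = d$images)
  expect_equal(sum(ev$confusion), ev$n)
  expect_true(all(ev$confusion >= 0))
  expect_equal(ev$overall_accuracy, sum(diag(ev$confusion)) / ev$n)
  expect_true(all(ev$per_class$accuracy >= 0 & ev$per_class$accuracy <= 1))
  # deterministic single pass
  ev2 <- evaluate_model(fit, d$manifest, split = "test", images = d$images)
  expect_identical(ev$confusion, ev2$confusion)
  # subject overlap with training is refused
  leaky <- d$manifest
  leaky$split[which(leaky$split == "train")[1]] <- "test"
  expect_error(evaluate_model(fit, leaky, split = "test", images = d$images),
               "overlap")
  expect_output(print(ev), "overall accuracy")
})

test_that("evaluation reports are written as JSON and CSV artifacts", {
  d <- tiny_dataset()
  ncfg <- network_config(backbone = "tiny", n_classes = 3, input_size = 64)
  tcfg <- train_config(learning_rate = 1e-3, epochs = 1, steps_per_epoch = 2,
                       patience = 1, n_inputs = 4, n_neighbors = 0, seed = 10)
  fit <- fit_gcnn(d$manifest, NULL, ncfg, tcfg, images = d$images)
  ev <- evaluate_model(fit, d$manifest, images = d$images)
  dir <- withr::local_tempdir()
  paths <- write_eval_report(ev, dir)
  expect_true(all(file.exists(paths)))
  j <- jsonlite::fromJSON(paths[1])
  expect_equal(j$overall_accuracy, ev$overall_accuracy)
  tab <- utils::read.csv(paths[2], check.names = FALSE)
  expect_named(tab, c("Cardiac View", "Sensitivity", "Specificity",
                      "Accuracy", "AUC"))
  rp <- utils::read.csv(paths[3], row.names = 1)
  expect_equal(unname(rowSums(rp)), rep(100, 3), tolerance = 1e-9)
})
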