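# S3 methods for the fitted classifier.

#' @export
print.echo_gcnn <- function(x, ...) {
  cfg <- x$net$config
  cat("Graph-constrained echocardiographic view classifier\n")
  cat(sprintf("  backbone: %s (embedding %d channels)%s%s\n", cfg$backbone,
              cfg$embedding_channels,
              if (cfg$use_stm) ", STM" else "",
              if (cfg$use_se) ", SE" else ""))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained %d epoch(s); best validation accuracy %.4f at epoch %d\n",
              nrow(x$history), max(x$history$val_accuracy), x$best_epoch))
  invisible(x)
}

#' @export
summary.echo_gcnn <- function(object, ...) {
  print(object)
  cat("\nArchitecture\n")
  s <- architecture_summary(object)
  cat(jsonlite::toJSON(s, auto_unbox = TRUE, pretty = TRUE, null = "null"),
      "\n")
  cat("\nTraining history (last 5 epochs)\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Predict view classes or probabilities for new images
#'
#' @param object fitted `"echo_gcnn"`.
#' @param newdata a manifest data frame, a named list of image matrices, or
#'   a single image / image batch array.
#' @param type `"class"` (default) or `"prob"`.
#' @param images optional in-memory store backing a manifest `newdata`.
#' @param ... unused.
#' @return a character vector of classes, or an N x n_classes probability
#'   matrix.
#' @export
predict.echo_gcnn <- function(object, newdata, type = c("class", "prob"),
                              images = NULL, ...) {
  type <- match.arg(type)
  sz <- object$net$config$input_size
  x <- if (is.data.frame(newdata)) {
    store <- image_store(newdata, images, sz)
    stack_images(newdata$image_id, store, sz)
  } else if (is.list(newdata)) {
    store <- lapply(newdata, standardize_image, out_size = sz)
    stack_images(names(newdata), store, sz)
  } else {
    xb <- as_batch(newdata)
    if (dim(xb)[3] == 1L) {
      std <- array(0, c(dim(xb)[1:2], 3L, dim(xb)[4]))
      for (i in seq_len(dim(xb)[4]))
        std[, , , i] <- standardize_image(xb[, , 1, i], out_size = sz)
      xb <- std
    }
    xb
  }
  probs <- predict_probs(object$net, x)
  colnames(probs) <- object$classes
  if (type == "prob") probs
  else object$classes[max.col(probs, ties.method = "first")]
}

#' Coefficients (network weights) of a fitted model
#'
#' @param object fitted `"echo_gcnn"`.
#' @param ... unused.
#' @return the named list of parameter arrays (the shared weights used for
#'   inputs and neighbors alike).
#' @export
coef.echo_gcnn <- function(object, ...) object$net$params

#' Plot training history
#'
#' Left axis: supervised, graph and total loss per epoch; right axis:
#' validation accuracy, with the selected best epoch marked.
#'
#' @param x fitted `"echo_gcnn"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.echo_gcnn <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$supervised, h$graph, h$total),
                    type = "l", lty = 1, col = c("grey40", "steelblue", "black"),
                    xlab = "epoch", ylab = "loss",
                    main = "Training history", ...)
  graphics::par(new = TRUE)
  graphics::plot(h$epoch, h$val_accuracy, type = "l", col = "firebrick",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4); graphics::mtext("validation accuracy", side = 4, line = 2.5)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("right", bty = "n", lty = c(1, 1, 1, 1, 3),
                   col = c("grey40", "steelblue", "black", "firebrick", "black"),
                   legend = c("supervised", "graph", "total", "val accuracy",
                              "best epoch"), cex = 0.8)
  invisible(x)
}
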