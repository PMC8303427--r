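# Three-stage classification network: spatial-transformer pre-alignment,
# a pluggable convolutional backbone, squeeze-and-excitation channel
# recalibration, then global pooling -> embedding -> dropout -> softmax.
#
# The localization net pools the input to a fixed 16x16 grid, applies one
# 5x5 convolution (stride 2) producing 128 feature maps, global-averages
# and maps through a fully connected layer to the 6 affine parameters.
# Its final layer starts at zero weights with an identity-transform bias,
# so an untrained model warps nothing. The backbone sees the warped image
# pooled to 32x32; "tiny" is three stride-2 3x3 conv blocks ending at
# embedding_channels maps, "inception_v3_compatible" reproduces only the
# 2048-channel output contract of an Inception-V3 feature extractor.

#' Network configuration
#'
#' @param backbone `"tiny"` (desk-scale default) or
#'   `"inception_v3_compatible"` (2048-channel embedding contract).
#' @param embedding_channels channels of the embedding layer; fixed at 2048
#'   for the inception-compatible backbone, default 64 for tiny.
#' @param se_reduction squeeze-and-excitation bottleneck reduction ratio
#'   (must divide `embedding_channels`; default 16).
#' @param n_classes number of view classes (default 9).
#' @param input_size square input side in pixels; must be a multiple of 32.
#' @param dropout_rate dropout between embedding and classifier (default 0.5).
#' @param use_stm,use_se include the spatial transformer / SE block
#'   (ablation switches; both on by default).
#' @return a list of class `"network_config"`.
#' @export
network_config <- function(backbone = c("tiny", "inception_v3_compatible"),
                           embedding_channels = NULL, se_reduction = 16L,
                           n_classes = 9L, input_size = 128L,
                           dropout_rate = 0.5, use_stm = TRUE, use_se = TRUE) {
  backbone <- match.arg(backbone)
  if (backbone == "inception_v3_compatible") {
    if (!is.null(embedding_channels) && embedding_channels != 2048L)
      stop("inception_v3_compatible backbone has a fixed 2048-channel embedding")
    embedding_channels <- 2048L
  } else if (is.null(embedding_channels)) embedding_channels <- 64L
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (input_size < 32 || input_size %% 32 != 0)
    stop("input_size must be a positive multiple of 32")
  if (use_se && embedding_channels %% se_reduction != 0)
    stop("embedding_channels must be divisible by se_reduction")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  structure(list(backbone = backbone,
                 embedding_channels = as.integer(embedding_channels),
                 se_reduction = as.integer(se_reduction),
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 dropout_rate = dropout_rate,
                 use_stm = isTRUE(use_stm), use_se = isTRUE(use_se)),
            class = "network_config")
}

LOC_CHANNELS <- 128L
IDENTITY_AFFINE <- c(1, 0, 0, 0, 1, 0)

backbone_channels <- function(config) {
  if (config$backbone == "tiny") c(16L, 32L, config$embedding_channels)
  else c(32L, 64L, 2048L)
}

#' Initialize network weights
#'
#' All layers use Glorot-uniform initialization except the final
#' localization layer, which starts at zero weights with an
#' identity-transform bias (standard spatial-transformer practice, so
#' training begins from an undistorted view).
#'
#' @param config a [network_config()].
#' @param seed integer seed for the initializer.
#' @return a list of class `"gcnn_net"` with elements `config` and `params`.
#' @export
init_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  ch <- backbone_channels(config)
  k3 <- if (config$backbone == "tiny") c(3L, 3L, 3L) else c(3L, 3L, 1L)
  params <- with_local_seed(seed, {
    p <- list()
    if (config$use_stm) {
      p$loc_conv_W <- glorot_uniform(c(5, 5, 3, LOC_CHANNELS),
                                     5 * 5 * 3, 5 * 5 * LOC_CHANNELS)
      p$loc_conv_b <- numeric(LOC_CHANNELS)
      p$loc_fc_W <- matrix(0, LOC_CHANNELS, 6)
      p$loc_fc_b <- IDENTITY_AFFINE
    }
    cin <- 3L
    for (i in 1:3) {
      k <- k3[i]
      p[[sprintf("conv%d_W", i)]] <- glorot_uniform(c(k, k, cin, ch[i]),
                                                    k * k * cin, k * k * ch[i])
      p[[sprintf("conv%d_b", i)]] <- numeric(ch[i])
      cin <- ch[i]
    }
    C <- config$embedding_channels
    if (config$use_se) {
      Cr <- C %/% config$se_reduction
      p$se_fc1_W <- glorot_uniform(c(C, Cr), C, Cr)
      p$se_fc1_b <- numeric(Cr)
      p$se_fc2_W <- glorot_uniform(c(Cr, C), Cr, C)
      p$se_fc2_b <- numeric(C)
    }
    p$head_W <- glorot_uniform(c(C, config$n_classes), C, config$n_classes)
    p$head_b <- numeric(config$n_classes)
    p
  })
  structure(list(config = config, params = params), class = "gcnn_net")
}

check_batch_input <- function(x, config) {
  x <- as_batch(x)
  d <- dim(x)
  if (d[1] != config$input_size || d[2] != config$input_size || d[3] != 3L)
    stop(sprintf(paste0("input is not standardized: expected %dx%dx3 ",
                        "(got %s); run standardize_image() first"),
                 config$input_size, config$input_size,
                 paste(d[1:3], collapse = "x")))
  if (any(!is.finite(x)) || min(x) < 0 || max(x) > 1)
    stop("input is not standardized: intensities must be finite and in [0, 1]")
  x
}

# Localization forward with cache; x already pooled checks happen here.
loc_forward <- function(net, x) {
  cfg <- net$config; p <- net$params
  s <- cfg$input_size %/% 16L
  xp <- avgpool_fwd(x, s)
  cv <- conv_fwd(xp, p$loc_conv_W, p$loc_conv_b, stride = 2L, pad = 2L)
  act <- relu_fwd(cv$out)
  g <- gap_fwd(act)
  theta <- fc_fwd(g, p$loc_fc_W, p$loc_fc_b)
  list(theta = theta, pool_s = s, conv = cv, act = act, g = g)
}

#' Predict affine alignment parameters for images
#'
#' Runs the spatial-transformer localization network: a 5x5 convolution
#' producing 128 feature maps on a pooled copy of the input, global average
#' pooling, and a fully connected layer to the six parameters
#' `(a, b, tx, c, d, ty)` of a planar affine map in normalized coordinates.
#' At initialization this is the identity `(1, 0, 0, 0, 1, 0)` for any input.
#'
#' @param net a `"gcnn_net"` (or fitted `"echo_gcnn"`).
#' @param images standardized image array (`input_size` x `input_size` x 3,
#'   optionally x N).
#' @return an N x 6 matrix of affine parameters (a vector for one image).
#' @export
localize <- function(net, images) {
  net <- as_net(net)
  if (!net$config$use_stm) stop("this network was built without the STM")
  x <- check_batch_input(images, net$config)
  th <- loc_forward(net, x)$theta
  if (nrow(th) == 1L) drop(th) else th
}

#' Warp images with a planar affine map
#'
#' Bilinear resampling on normalized `[-1, 1]` coordinates (u along width,
#' v along height): the output pixel at `(u, v)` samples the input at
#' `(a*u + b*v + tx, c*u + d*v + ty)`; out-of-bounds samples are zero.
#' Identity parameters reproduce the input exactly.
#'
#' @param images matrix, H x W x C array, or H x W x C x N batch.
#' @param params affine parameters: a length-6 vector or an N x 6 matrix.
#' @return warped images, same shape as the input.
#' @export
warp_affine <- function(images, params) {
  d0 <- dim(images)
  x <- as_batch(images)
  if (is.null(dim(params))) params <- matrix(params, nrow = 1)
  if (ncol(params) != 6L) stop("params must have 6 affine coefficients")
  if (nrow(params) == 1L && dim(x)[4] > 1L)
    params <- params[rep(1L, dim(x)[4]), , drop = FALSE]
  if (nrow(params) != dim(x)[4])
    stop("one parameter row required per image")
  if (any(!is.finite(params))) stop("affine parameters must be finite")
  out <- cpp_affine_warp(x, params)
  dim(out) <- d0
  out
}

# SE forward on (H, W, C, N) maps with cache.
se_forward <- function(p, f) {
  s <- gap_fwd(f)
  z1 <- fc_fwd(s, p$se_fc1_W, p$se_fc1_b)
  a1 <- relu_fwd(z1)
  z2 <- fc_fwd(a1, p$se_fc2_W, p$se_fc2_b)
  g <- sigmoid(z2)                                    # N x C gates in (0,1)
  d <- dim(f)
  gf <- array(rep(as.vector(t(g)), each = d[1] * d[2]), d)
  list(out = f * gf, s = s, z1 = z1, a1 = a1, g = g, gf = gf)
}

#' Squeeze-and-excitation channel recalibration
#'
#' Squeezes each channel by global average pooling, passes the channel
#' descriptor through a bottleneck of size `embedding_channels /
#' se_reduction` with a ReLU, and gates every channel by a sigmoid weight in
#' (0, 1). Output shape equals input shape.
#'
#' @param net a `"gcnn_net"` (or fitted model) built with `use_se = TRUE`.
#' @param feature_maps array H x W x C (x N) with `C = embedding_channels`.
#' @return recalibrated feature maps, same shape.
#' @export
se_recalibrate <- function(net, feature_maps) {
  net <- as_net(net)
  if (!net$config$use_se) stop("this network was built without the SE block")
  d0 <- dim(feature_maps)
  f <- as_batch(feature_maps)
  if (dim(f)[3] != net$config$embedding_channels)
    stop(sprintf("channel mismatch: got %d maps, embedding has %d channels",
                 dim(f)[3], net$config$embedding_channels))
  out <- se_forward(net$params, f)$out
  dim(out) <- d0
  out
}

# Backbone on the already-pooled (32x32) input.
backbone_forward <- function(net, pool) {
  cfg <- net$config; p <- net$params
  strides <- c(2L, 2L, if (cfg$backbone == "tiny") 2L else 1L)
  pads <- c(1L, 1L, if (cfg$backbone == "tiny") 1L else 0L)
  x <- pool; caches <- vector("list", 3)
  for (i in 1:3) {
    cv <- conv_fwd(x, p[[sprintf("conv%d_W", i)]], p[[sprintf("conv%d_b", i)]],
                   stride = strides[i], pad = pads[i])
    act <- relu_fwd(cv$out)
    caches[[i]] <- list(conv = cv, act = act)
    x <- act
  }
  list(maps = x, pool = pool, caches = caches,
       strides = strides, pads = pads)
}

# Full forward pass; dropout_mask non-NULL means training mode. The warp of
# the input and the backbone's entry pooling are fused into one kernel
# (identical arithmetic to warp followed by block averaging).
nn_forward <- function(net, x, dropout_mask = NULL) {
  cfg <- net$config; p <- net$params
  s <- cfg$input_size %/% 32L
  loc <- NULL
  if (cfg$use_stm) {
    loc <- loc_forward(net, x)
    pooled <- cpp_warp_pool(x, loc$theta, s)
  } else {
    pooled <- avgpool_fwd(x, s)
  }
  bb <- backbone_forward(net, pooled)
  se <- if (cfg$use_se) se_forward(p, bb$maps) else NULL
  maps <- if (cfg$use_se) se$out else bb$maps
  emb <- gap_fwd(maps)                                  # N x C embedding
  dropped <- if (is.null(dropout_mask)) emb else emb * dropout_mask
  logits <- fc_fwd(dropped, p$head_W, p$head_b)
  probs <- softmax(logits)
  list(embedding = emb, probs = probs, logits = logits, loc = loc,
       pool_s = s, bb = bb, se = se, dropped = dropped, x = x)
}

#' Forward pass: embeddings and class probabilities
#'
#' Runs the full pipeline in evaluation mode (dropout disabled):
#' affine warp from the localization network, backbone feature extraction,
#' SE recalibration, global pooling to the embedding, and a softmax
#' classifier. Deterministic for a fixed model.
#'
#' @param net a `"gcnn_net"` or fitted `"echo_gcnn"`.
#' @param images standardized images (H x W x 3 (x N), intensities in
#'   `[0, 1]`).
#' @return list with `embedding` (N x embedding_channels) and `probs`
#'   (N x n_classes, rows summing to 1).
#' @export
forward_pass <- function(net, images) {
  net <- as_net(net)
  x <- check_batch_input(images, net$config)
  out <- nn_forward(net, x)
  list(embedding = out$embedding, probs = out$probs)
}

as_net <- function(x) {
  if (inherits(x, "echo_gcnn")) return(x$net)
  if (inherits(x, "gcnn_net")) return(x)
  stop("expected a 'gcnn_net' or fitted 'echo_gcnn' object")
}

#' Architecture summary for structural checks
#'
#' @param net a `"gcnn_net"` or fitted model.
#' @return a list describing the module structure (localization channels and
#'   affine-parameter count, backbone, embedding width, SE bottleneck,
#'   classifier size, total parameter count); serializable to JSON.
#' @export
architecture_summary <- function(net) {
  net <- as_net(net)
  cfg <- net$config
  list(
    backbone = cfg$backbone,
    input_size = cfg$input_size,
    n_classes = cfg$n_classes,
    stm = if (cfg$use_stm)
      list(localization_conv_channels = LOC_CHANNELS,
           localization_kernel = 5L, n_affine_params = 6L)
    else NULL,
    embedding_channels = cfg$embedding_channels,
    se = if (cfg$use_se)
      list(reduction = cfg$se_reduction,
           bottleneck = cfg$embedding_channels %/% cfg$se_reduction)
    else NULL,
    dropout_rate = cfg$dropout_rate,
    n_parameters = sum(vapply(net$params, length, 0L)))
}

#' Save model weights and configuration as JSON
#'
#' Stores the configuration and every parameter array (with dimensions) at
#' full precision in a plain-text checkpoint; for fitted models the training
#' history, class vocabulary and training subjects are included.
#'
#' @param model a `"gcnn_net"` or fitted `"echo_gcnn"`.
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  enc_params <- function(p) lapply(p, function(a)
    list(dim = if (is.null(dim(a))) length(a) else dim(a), data = as.vector(a)))
  obj <- if (inherits(model, "echo_gcnn")) {
    list(kind = "echo_gcnn", config = unclass(model$net$config),
         params = enc_params(model$net$params),
         classes = model$classes, history = model$history,
         best_epoch = model$best_epoch, train_subjects = model$train_subjects,
         train_config = unclass(model$train_config))
  } else {
    model <- as_net(model)
    list(kind = "gcnn_net", config = unclass(model$config),
         params = enc_params(model$params))
  }
  # 17 significant digits: doubles survive the decimal round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return a `"gcnn_net"` or `"echo_gcnn"`, matching what was saved.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, obj$config[c("backbone", "embedding_channels",
                                              "se_reduction", "n_classes",
                                              "input_size", "dropout_rate",
                                              "use_stm", "use_se")])
  params <- lapply(obj$params, function(e) {
    a <- e$data
    if (length(e$dim) > 1L) dim(a) <- e$dim            # vectors stay vectors
    a
  })
  net <- structure(list(config = cfg, params = params), class = "gcnn_net")
  if (identical(obj$kind, "echo_gcnn")) {
    structure(list(net = net, classes = obj$classes,
                   history = as.data.frame(obj$history),
                   best_epoch = obj$best_epoch,
                   train_subjects = obj$train_subjects,
                   train_config = obj$train_config),
              class = "echo_gcnn")
  } else net
}
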