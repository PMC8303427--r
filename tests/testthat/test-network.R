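test_that("localization returns the identity transform at initialization", {
  net <- tiny_net()
  for (k in 1:3) {
    img <- std64(matrix(runif(64 * 64), 64, 64))
    th <- localize(net, img)
    expect_length(th, 6L)
    expect_equal(unname(th), c(1, 0, 0, 0, 1, 0))
  }
  batch <- array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  ths <- localize(net, batch)
  expect_equal(dim(ths), c(4L, 6L))
  expect_error(localize(net, std64(matrix(0.5, 32, 32))[1:32, 1:32, ]),
               "not standardized")
})

test_that("localization conv stage emits 128 feature maps", {
  net <- tiny_net()
  expect_equal(dim(net$params$loc_conv_W)[4], 128L)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  act <- echograph:::loc_forward(net, x)$act
  expect_equal(dim(act)[3], 128L)
  s <- architecture_summary(net)
  expect_equal(s$stm$localization_conv_channels, 128L)
  expect_equal(s$stm$n_affine_params, 6L)
})

test_that("identity affine parameters reproduce the input", {
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  expect_lt(max(abs(warp_affine(img, c(1, 0, 0, 0, 1, 0)) - img)), 1e-5)
})

test_that("a one-pixel translation moves a delta by one pixel with zero fill", {
  n <- 9L
  d <- matrix(0, n, n); d[5, 5] <- 1
  # sampling source at u + 2/(n-1) shifts content one pixel toward column 1
  left <- warp_affine(d, c(1, 0, 2 / (n - 1), 0, 1, 0))
  expect_equal(left[5, 4], 1)
  expect_equal(sum(left), 1)
  down <- warp_affine(d, c(1, 0, 0, 0, 1, -2 / (n - 1)))
  expect_equal(down[6, 5], 1)
  # border samples fall outside and are zero-filled
  edge <- warp_affine(d, c(1, 0, 2, 0, 1, 0))
  expect_equal(sum(edge), 0)
})

test_that("warping with a transform then its inverse restores the interior", {
  g <- seq(0, 1, length.out = 40)
  img <- outer(g, g, function(y, x) 0.5 + 0.4 * sin(3 * x) * cos(2 * y))
  ang <- 0.15
  Tf <- c(cos(ang), -sin(ang), 0.1, sin(ang), cos(ang), -0.05)
  A <- matrix(Tf[c(1, 2, 4, 5)], 2, byrow = TRUE)
  Ai <- solve(A)
  bi <- -Ai %*% Tf[c(3, 6)]
  Ti <- c(Ai[1, ], bi[1], Ai[2, ], bi[2])
  back <- warp_affine(warp_affine(img, Ti), Tf)
  interior <- 12:28
  expect_lt(max(abs(back[interior, interior] - img[interior, interior])), 0.02)
  expect_error(warp_affine(img, c(1, 0, NA, 0, 1, 0)), "finite")
  expect_error(warp_affine(img, 1:5), "6 affine")
})

test_that("SE with unit gates reproduces the input exactly", {
  net <- tiny_net()
  # saturate the excitation sigmoid so every gate is exactly 1 in doubles
  net$params$se_fc2_W[] <- 0
  net$params$se_fc2_b[] <- 40
  f <- array(runif(4 * 4 * 64 * 2), c(4, 4, 64, 2))
  expect_identical(se_recalibrate(net, f), f)
})

test_that("SE gates lie strictly in (0,1) and scale channels", {
  net <- tiny_net()
  f <- array(runif(4 * 4 * 64), c(4, 4, 64))
  out <- se_recalibrate(net, f)
  expect_equal(dim(out), dim(f))
  g <- out / f
  expect_true(all(g > 0 & g < 1))
  # per-channel gate is constant over the spatial grid
  expect_lt(max(abs(apply(g, 3, stats::sd))), 1e-12)
  expect_identical(se_recalibrate(net, f * 0), f * 0)
  expect_error(se_recalibrate(net, array(0, c(4, 4, 32))), "channel mismatch")
})

test_that("forward pass yields normalized probabilities and fixed embedding width", {
  net <- tiny_net()
  x <- array(runif(64 * 64 * 3 * 3), c(64, 64, 3, 3))
  out <- forward_pass(net, x)
  expect_equal(dim(out$embedding), c(3L, 64L))
  expect_equal(dim(out$probs), c(3L, 3L))
  expect_equal(rowSums(out$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(out$probs >= 0))
  expect_true(all(is.finite(out$embedding)))
  # evaluation mode is deterministic
  expect_identical(out$probs, forward_pass(net, x)$probs)
  expect_error(forward_pass(net, x * 2), "not standardized")
})

test_that("the inception-compatible backbone honors the 2048-channel contract", {
  cfg <- network_config(backbone = "inception_v3_compatible",
                        n_classes = 9, input_size = 128)
  expect_equal(cfg$embedding_channels, 2048L)
  net <- init_network(cfg, seed = 2)
  x <- array(runif(128 * 128 * 3), c(128, 128, 3, 1))
  out <- forward_pass(net, x)
  expect_equal(ncol(out$embedding), 2048L)
  expect_equal(architecture_summary(net)$embedding_channels, 2048L)
  expect_error(network_config(backbone = "inception_v3_compatible",
                              embedding_channels = 64), "2048")
})

test_that("inputs and neighbors share one parameter store", {
  net <- tiny_net()
  x <- array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  # the same image produces the same embedding whatever its batch position
  e_first <- forward_pass(net, x[, , , c(1, 2, 3, 4)])$embedding[1, ]
  e_last <- forward_pass(net, x[, , , c(2, 3, 4, 1)])$embedding[4, ]
  expect_equal(e_first, e_last, tolerance = 1e-12)
  expect_identical(coef(structure(list(net = net), class = "echo_gcnn")),
                   net$params)
})

test_that("the graph-loss gradient reaches the STM localization parameters", {
  set.seed(14)
  net <- tiny_net(n_classes = 3)
  # move the localization away from the exact identity so the warp gradient
  # is evaluated at a generic operating point
  net$params$loc_fc_W[] <- rnorm(length(net$params$loc_fc_W), sd = 0.01)
  x <- array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  y <- c(1L, 2L)
  pairs <- list(ui = c(1L, 2L), vi = c(3L, 4L), w = c(1.5, 2.0))
  g0 <- echograph:::loss_and_grads(net, x, y, 2L, pairs, alpha = 0,
                                   train = FALSE)$grads
  g1 <- echograph:::loss_and_grads(net, x, y, 2L, pairs, alpha = 1,
                                   train = FALSE)$grads
  for (nm in c("loc_conv_W", "loc_conv_b", "loc_fc_W", "loc_fc_b")) {
    dg <- g1[[nm]] - g0[[nm]]
    expect_true(all(is.finite(dg)))
    expect_gt(max(abs(dg)), 0)
  }
})

test_that("checkpoints round-trip weights, config and predictions", {
  net <- tiny_net(seed = 23)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  expect_equal(net2$config, net$config)
  for (nm in names(net$params))
    expect_equal(net2$params[[nm]], net$params[[nm]], tolerance = 1e-15)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  expect_equal(forward_pass(net2, x)$probs, forward_pass(net, x)$probs,
               tolerance = 1e-12)
})

test_that("network configuration invariants are enforced", {
  expect_error(network_config(n_classes = 1), "n_classes")
  expect_error(network_config(input_size = 100), "multiple of 32")
  expect_error(network_config(embedding_channels = 60, se_reduction = 16),
               "divisible")
  expect_silent(network_config(embedding_channels = 60, se_reduction = 16,
                               use_se = FALSE))
})
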