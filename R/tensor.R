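# Internal dense tensor primitives backing the network module.
#
# Batches are numeric arrays with dim c(H, W, C, N); the image row index is
# the fastest-varying dimension (R column-major). Convolutions are computed
# by im2col gathers followed by a single BLAS matrix product; the backward
# pass scatters column gradients back with rowsum(). These ops carry their
# own caches so hand-derived backprop can reuse forward intermediates.

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array, got a bare vector")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected 2-, 3- or 4-dimensional input")
  x
}

pad_batch <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# Precompute im2col gather indices for one padded image.
conv_geom <- function(H, W, Cin, kh, kw, stride, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Hout <- (Hp - kh) %/% stride + 1L
  Wout <- (Wp - kw) %/% stride + 1L
  if (Hout < 1L || Wout < 1L) stop("kernel larger than (padded) input")
  # patch-element offsets ordered like a c(kh, kw, Cin) weight block
  r  <- rep.int(seq_len(kh) - 1L, kw * Cin)
  cc <- rep.int(rep(seq_len(kw) - 1L, each = kh), Cin)
  ch <- rep(seq_len(Cin) - 1L, each = kh * kw)
  off <- r + Hp * cc + Hp * Wp * ch
  i0 <- (seq_len(Hout) - 1L) * stride + 1L
  j0 <- (seq_len(Wout) - 1L) * stride
  corner <- rep.int(i0, Wout) + Hp * rep(j0, each = Hout)
  list(Hp = Hp, Wp = Wp, Hout = Hout, Wout = Wout,
       idx = outer(off, corner, `+`), plen = Hp * Wp * Cin)
}

conv_fwd <- function(x, W, b, stride = 1L, pad = 0L, geom = NULL) {
  d <- dim(x); k <- dim(W)
  if (k[3] != d[3])
    stop(sprintf("conv channel mismatch: input has %d, weights expect %d",
                 d[3], k[3]))
  if (is.null(geom)) geom <- conv_geom(d[1], d[2], d[3], k[1], k[2], stride, pad)
  xp <- pad_batch(x, pad)
  P <- length(geom$idx)
  N <- d[4]
  full_idx <- rep.int(as.vector(geom$idx), N) +
    rep(geom$plen * (seq_len(N) - 1L), each = P)
  cols <- matrix(xp[full_idx], nrow = nrow(geom$idx))
  Wm <- matrix(W, nrow = nrow(geom$idx))
  out <- crossprod(Wm, cols) + b          # Cout recycles down columns
  out <- array(out, c(k[4], geom$Hout, geom$Wout, N))
  list(out = aperm(out, c(2, 3, 1, 4)), cols = cols, geom = geom,
       full_idx = full_idx, dims = d, pad = pad)
}

conv_bwd <- function(cache, W, dY, want_dx = TRUE) {
  g <- cache$geom; k <- dim(W)
  dYm <- matrix(aperm(dY, c(3, 1, 2, 4)), nrow = k[4])
  dW <- array(tcrossprod(cache$cols, dYm), dim = k)
  db <- rowSums(dYm)
  dX <- NULL
  if (want_dx) {
    Wm <- matrix(W, nrow = nrow(cache$cols))
    dcols <- Wm %*% dYm
    N <- cache$dims[4]
    dxp <- cpp_scatter_add(as.vector(dcols), cache$full_idx,
                           as.integer(g$plen * N))
    dim(dxp) <- c(g$Hp, g$Wp, cache$dims[3], N)
    dX <- if (cache$pad > 0L)
      dxp[cache$pad + seq_len(cache$dims[1]),
          cache$pad + seq_len(cache$dims[2]), , , drop = FALSE]
    else dxp
  }
  list(dW = dW, db = db, dX = dX)
}

avgpool_fwd <- function(x, s) {
  if (s == 1L) return(x)
  d <- dim(x)
  if (d[1] %% s != 0L || d[2] %% s != 0L)
    stop("pooling window must divide the spatial size")
  y <- colMeans(matrix(x, nrow = s))
  dim(y) <- c(d[1] %/% s, d[2], d[3], d[4])
  y <- aperm(y, c(2, 1, 3, 4))
  y <- colMeans(matrix(y, nrow = s))
  dim(y) <- c(d[2] %/% s, d[1] %/% s, d[3], d[4])
  aperm(y, c(2, 1, 3, 4))
}

avgpool_bwd <- function(dY, s) {
  if (s == 1L) return(dY)
  d <- dim(dY)
  dY[rep(seq_len(d[1]), each = s), rep(seq_len(d[2]), each = s), , ,
     drop = FALSE] / (s * s)
}

# Global average pooling: (H, W, C, N) -> N x C matrix.
gap_fwd <- function(x) {
  d <- dim(x)
  t(matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3]))
}

gap_bwd <- function(dY, H, W) {
  v <- t(dY) / (H * W)                     # C x N
  array(rep(as.vector(v), each = H * W), c(H, W, nrow(v), ncol(v)))
}

fc_fwd <- function(x, W, b) x %*% W + rep(b, each = nrow(x))

fc_bwd <- function(x, W, dY) {
  list(dW = crossprod(x, dY), db = colSums(dY), dX = tcrossprod(dY, W))
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(dY, act) {
  dY[act <= 0] <- 0
  dY
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(z) {
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - m)
  e / rowSums(e)
}

# Mean cross-entropy over rows; y is a 1-based class index vector.
cross_entropy <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

# d(mean CE)/dlogits for softmax outputs.
cross_entropy_dlogits <- function(probs, y) {
  d <- probs
  d[cbind(seq_along(y), y)] <- d[cbind(seq_along(y), y)] - 1
  d / length(y)
}

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

# Bilinear resize of a 2-D matrix with corner-aligned coordinates; sizes
# equal in and out is an exact identity.
bilinear_resize <- function(img, h2, w2) {
  h <- nrow(img); w <- ncol(img)
  rs <- if (h2 > 1L) (seq_len(h2) - 1) * (h - 1) / (h2 - 1) + 1 else (h + 1) / 2
  cs <- if (w2 > 1L) (seq_len(w2) - 1) * (w - 1) / (w2 - 1) + 1 else (w + 1) / 2
  r0 <- pmin(floor(rs), h - 1L); c0 <- pmin(floor(cs), w - 1L)
  fr <- rs - r0; fc <- cs - c0
  a <- img[r0, c0, drop = FALSE]; b <- img[r0, c0 + 1, drop = FALSE]
  cc <- img[r0 + 1, c0, drop = FALSE]; dd <- img[r0 + 1, c0 + 1, drop = FALSE]
  wr <- matrix(fr, h2, w2); wc <- matrix(fc, h2, w2, byrow = TRUE)
  (1 - wr) * ((1 - wc) * a + wc * b) + wr * ((1 - wc) * cc + wc * dd)
}
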