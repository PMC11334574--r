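# Low-level differentiable primitives.  Feature maps are H x W x C
# arrays; token matrices are tokens x channels.  Every *_forward
# returns list(out, cache); every *_backward takes the upstream
# gradient plus the cache and returns the input gradient and any
# parameter gradients.  Gradients are hand-derived; no autodiff.

im2col <- function(x, k, pad) {
  d <- dim(x)
  .cn_im2col(as.double(x), d[1L], d[2L], d[3L], as.integer(k), as.integer(pad))
}

col2im <- function(cols, H, W, C, k, pad) {
  array(.cn_col2im(cols, H, W, C, as.integer(k), as.integer(pad)), c(H, W, C))
}

#' @noRd
conv2d_forward <- function(x, W, b) {
  d <- dim(x); kd <- dim(W)
  stopifnot(d[3L] == kd[3L])
  k <- kd[1L]; pad <- (k - 1L) %/% 2L
  cols <- im2col(x, k, pad)
  out <- cols %*% matrix(W, nrow = k * k * kd[3L])
  out <- out + rep(b, each = nrow(out))
  list(out = array(out, c(d[1L], d[2L], kd[4L])),
       cache = list(cols = cols, dims = d, k = k, pad = pad))
}

conv2d_backward <- function(dout, cache, W) {
  kd <- dim(W); d <- cache$dims
  dmat <- matrix(dout, ncol = kd[4L])
  dW <- array(crossprod(cache$cols, dmat), kd)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, matrix(W, nrow = kd[1L] * kd[2L] * kd[3L]))
  dx <- col2im(dcols, d[1L], d[2L], d[3L], cache$k, cache$pad)
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(dout, mask) dout * mask

maxpool_forward <- function(x) {
  d <- dim(x)
  r <- .cn_maxpool(as.double(x), d[1L], d[2L], d[3L])
  list(out = array(r$out, c(d[1L] %/% 2L, d[2L] %/% 2L, d[3L])),
       cache = list(argmax = r$argmax, n_in = length(x), dims = d))
}

maxpool_backward <- function(dout, cache) {
  d <- cache$dims
  array(.cn_maxpool_bw(as.double(dout), cache$argmax, cache$n_in),
        c(d[1L], d[2L], d[3L]))
}

# Dense layer on a matrix of row vectors: out = x %*% W + b.
linear_forward <- function(x, W, b) {
  x <- as.matrix(x)
  out <- x %*% W
  list(out = out + rep(b, each = nrow(out)), cache = x)
}

linear_backward <- function(dout, cache, W) {
  list(dx = tcrossprod(dout, W), dW = crossprod(cache, dout),
       db = colSums(dout))
}

# Exact GELU, x * pnorm(x); derivative pnorm(x) + x * dnorm(x).
gelu_forward <- function(x) {
  ph <- stats::pnorm(x)
  list(out = x * ph, cache = list(x = x, ph = ph))
}

gelu_backward <- function(dout, cache) {
  dout * (cache$ph + cache$x * stats::dnorm(cache$x))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Layer normalization across the channel (last) axis of a token
# matrix, with learnable per-channel scale and shift.
layernorm_forward <- function(x, gamma, beta, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

layernorm_backward <- function(dout, cache) {
  xhat <- cache$xhat
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxh <- sweep(dout, 2L, cache$gamma, "*")
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * xhat)
  dx <- cache$inv * (dxh - m1 - xhat * m2)
  list(dx = dx, dgamma = dg, dbeta = db)
}

bilinear_resize <- function(x, out_h, out_w) {
  if (length(dim(x)) == 2L) {
    d <- c(dim(x), 1L)
    return(matrix(.cn_bilinear(as.double(x), d[1L], d[2L], 1L,
                               as.integer(out_h), as.integer(out_w)),
                  out_h, out_w))
  }
  d <- dim(x)
  array(.cn_bilinear(as.double(x), d[1L], d[2L], d[3L],
                     as.integer(out_h), as.integer(out_w)),
        c(out_h, out_w, d[3L]))
}

# He-scaled Gaussian initializer used for conv and dense weights.
he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}
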