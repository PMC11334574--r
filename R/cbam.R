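# Convolutional block attention (CBAM): channel attention followed by
# spatial attention, each a sigmoid gate multiplied into the feature
# map.  M_cb = M_c * M_b, M_f = M_s * M_cb.  The channel gate pools
# the map spatially (max and average), pushes both descriptors
# through one shared two-layer bottleneck (reduction ratio r, ReLU in
# between) and adds them before the sigmoid; the spatial gate pools
# across channels, stacks the two maps and applies a k x k
# convolution.  Defaults r = 16, k = 7.

cbam_config <- function(channels, reduction = 16L, kernel = 7L) {
  bott <- channels %/% reduction
  if (bott < 1L)
    stop(sprintf("channel count %d incompatible with reduction ratio %d",
                 channels, reduction))
  list(channels = as.integer(channels), reduction = as.integer(reduction),
       bottleneck = as.integer(bott), kernel = as.integer(kernel))
}

cbam_init <- function(cfg, prefix = "cb") {
  C <- cfg$channels; B <- cfg$bottleneck; k <- cfg$kernel
  p <- list()
  p[[paste0(prefix, ".fc1.W")]] <- he_init(c(C, B), fan_in = C)
  p[[paste0(prefix, ".fc1.b")]] <- numeric(B)
  p[[paste0(prefix, ".fc2.W")]] <- he_init(c(B, C), fan_in = B)
  p[[paste0(prefix, ".fc2.b")]] <- numeric(C)
  p[[paste0(prefix, ".sp.W")]]  <- he_init(c(k, k, 2L, 1L), fan_in = 2 * k * k)
  p[[paste0(prefix, ".sp.b")]]  <- numeric(1L)
  p
}

# Shared bottleneck applied to one pooled channel descriptor (row
# vector): v -> ReLU(v W1 + b1) W2 + b2.
cbam_mlp_forward <- function(v, params, prefix) {
  l1 <- linear_forward(matrix(v, 1L), params[[paste0(prefix, ".fc1.W")]],
                       params[[paste0(prefix, ".fc1.b")]])
  r1 <- relu_forward(l1$out)
  l2 <- linear_forward(r1$out, params[[paste0(prefix, ".fc2.W")]],
                       params[[paste0(prefix, ".fc2.b")]])
  list(out = drop(l2$out), cache = list(l1 = l1$cache, r1 = r1$cache,
                                        l2 = l2$cache))
}

cbam_mlp_backward <- function(dout, cache, params, prefix) {
  b2 <- linear_backward(matrix(dout, 1L), cache$l2,
                        params[[paste0(prefix, ".fc2.W")]])
  dr <- relu_backward(b2$dx, cache$r1)
  b1 <- linear_backward(dr, cache$l1, params[[paste0(prefix, ".fc1.W")]])
  g <- list(); g[[paste0(prefix, ".fc1.W")]] <- b1$dW
  g[[paste0(prefix, ".fc1.b")]] <- b1$db
  g[[paste0(prefix, ".fc2.W")]] <- b2$dW
  g[[paste0(prefix, ".fc2.b")]] <- b2$db
  list(dv = drop(b1$dx), grads = g)
}

#' Channel attention weights
#'
#' Computes the per-channel sigmoid gate of the attention block:
#' spatial max and average pooling of the feature map, a shared
#' two-layer bottleneck on each descriptor, sum, sigmoid.
#'
#' @param m_b H x W x C feature map.
#' @param params,prefix Parameter list and key prefix (internal
#'   convention); see [cbam_init()].
#' @return List with `weights` (length-C vector strictly in (0, 1))
#'   and `cache` for the backward pass.
#' @keywords internal
channel_attention <- function(m_b, params, prefix = "cb") {
  d <- dim(m_b)
  Xm <- matrix(m_b, d[1L] * d[2L], d[3L])
  imax <- apply(Xm, 2L, which.max)
  vmax <- Xm[cbind(imax, seq_len(d[3L]))]
  vavg <- colMeans(Xm)
  fmax <- cbam_mlp_forward(vmax, params, prefix)
  favg <- cbam_mlp_forward(vavg, params, prefix)
  w <- sigmoid(fmax$out + favg$out)
  list(weights = w,
       cache = list(dims = d, imax = imax, fmax = fmax$cache,
                    favg = favg$cache, w = w))
}

#' Apply channel attention weights
#' @param m_c Length-C weight vector.
#' @param m_b H x W x C feature map.
#' @return The gated map `M_cb`, each channel scaled by its weight.
#' @keywords internal
apply_channel <- function(m_c, m_b) {
  d <- dim(m_b)
  if (length(m_c) != d[3L]) stop("channel counts do not match")
  m_b * rep(m_c, each = d[1L] * d[2L])
}

#' Spatial attention weights
#'
#' Channel-wise max and average pooling of the gated map, a k x k
#' convolution of the two stacked maps, sigmoid: one weight per
#' spatial position.
#'
#' @inheritParams channel_attention
#' @param m_cb H x W x C gated feature map.
#' @return List with `weights` (H x W matrix in (0, 1)) and `cache`.
#' @keywords internal
spatial_attention <- function(m_cb, params, prefix = "cb") {
  d <- dim(m_cb)
  Xm <- matrix(m_cb, d[1L] * d[2L], d[3L])
  jmax <- max.col(Xm, ties.method = "first")
  pmaxs <- Xm[cbind(seq_len(nrow(Xm)), jmax)]
  pavgs <- rowMeans(Xm)
  stack <- array(c(pmaxs, pavgs), c(d[1L], d[2L], 2L))
  cv <- conv2d_forward(stack, params[[paste0(prefix, ".sp.W")]],
                       params[[paste0(prefix, ".sp.b")]])
  w <- sigmoid(cv$out[, , 1L])
  list(weights = w,
       cache = list(dims = d, jmax = jmax, conv = cv$cache, w = w))
}

#' Attention-refined feature map
#'
#' Full attention chain: channel gate, multiply, spatial gate,
#' multiply.  Shape is preserved and, because both gates lie in
#' (0, 1), every element of the output is attenuated relative to the
#' input.
#'
#' @inheritParams channel_attention
#' @return List with `out` (the refined map `M_f`) and `cache`.
#' @keywords internal
cbam_forward <- function(m_b, params, prefix = "cb") {
  ca <- channel_attention(m_b, params, prefix)
  m_cb <- apply_channel(ca$weights, m_b)
  sa <- spatial_attention(m_cb, params, prefix)
  d <- dim(m_b)
  m_f <- m_cb * as.vector(sa$weights)  # recycles over channels
  list(out = m_f,
       cache = list(ca = ca$cache, sa = sa$cache, m_b = m_b, m_cb = m_cb))
}

cbam_backward <- function(dmf, cache, params, prefix = "cb") {
  d <- dim(cache$m_b); HW <- d[1L] * d[2L]; C <- d[3L]
  ws <- cache$sa$w
  # M_f = M_s (*) M_cb
  dmcb <- dmf * as.vector(ws)
  dws <- matrix(rowSums(matrix(dmf * cache$m_cb, HW, C)), d[1L], d[2L])
  # spatial gate: sigmoid then conv then channel pooling
  dz <- dws * ws * (1 - ws)
  sb <- conv2d_backward(array(dz, c(d[1L], d[2L], 1L)), cache$sa$conv,
                        params[[paste0(prefix, ".sp.W")]])
  g <- list()
  g[[paste0(prefix, ".sp.W")]] <- sb$dW
  g[[paste0(prefix, ".sp.b")]] <- sb$db
  dpool_max <- sb$dx[, , 1L]
  dpool_avg <- sb$dx[, , 2L]
  dmcb_m <- matrix(dmcb, HW, C)
  idx <- cbind(seq_len(HW), cache$sa$jmax)
  dmcb_m[idx] <- dmcb_m[idx] + as.vector(dpool_max)
  dmcb_m <- dmcb_m + as.vector(dpool_avg) / C
  dmcb <- array(dmcb_m, d)
  # channel gate: M_cb = M_c (*) M_b
  wc <- cache$ca$w
  dmb <- dmcb * rep(wc, each = HW)
  dwc <- colSums(matrix(dmcb * cache$m_b, HW, C))
  dsum <- dwc * wc * (1 - wc)
  bmax <- cbam_mlp_backward(dsum, cache$ca$fmax, params, prefix)
  bavg <- cbam_mlp_backward(dsum, cache$ca$favg, params, prefix)
  for (k in names(bmax$grads))
    g[[k]] <- bmax$grads[[k]] + bavg$grads[[k]]
  dmb_m <- matrix(dmb, HW, C)
  dmb_m[cbind(cache$ca$imax, seq_len(C))] <-
    dmb_m[cbind(cache$ca$imax, seq_len(C))] + bmax$dv
  dmb_m <- dmb_m + matrix(bavg$dv / HW, HW, C, byrow = TRUE)
  list(dx = array(dmb_m, d), grads = g)
}
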