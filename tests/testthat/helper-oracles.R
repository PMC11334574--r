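# Independent explicit-loop oracles used to verify the network
# arithmetic.  These deliberately avoid the package's vectorized
# implementations: plain loops and direct formula evaluation only.

# Cross-correlation with 3x3 kernel, same padding, explicit loops.
oracle_conv3 <- function(x, W, b) {
  d <- dim(x); kd <- dim(W)
  out <- array(0, c(d[1], d[2], kd[4]))
  for (oc in seq_len(kd[4])) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      acc <- b[oc]
      for (ic in seq_len(d[3])) for (a in 1:3) for (bb in 1:3) {
        ii <- i + a - 2; jj <- j + bb - 2
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
          acc <- acc + x[ii, jj, ic] * W[a, bb, ic, oc]
      }
      out[i, j, oc] <- acc
    }
  }
  out
}

oracle_sigmoid <- function(z) 1 / (1 + exp(-z))

# Channel gate: sigmoid(FC(max-pooled) + FC(avg-pooled)), shared
# two-layer bottleneck with ReLU.
oracle_channel_attention <- function(m_b, W1, b1, W2, b2) {
  C <- dim(m_b)[3]
  fc <- function(v) {
    h <- pmax(as.vector(v %*% W1) + b1, 0)
    as.vector(h %*% W2) + b2
  }
  vmax <- vnum <- numeric(C)
  for (c in seq_len(C)) {
    vmax[c] <- max(m_b[, , c])
    vnum[c] <- mean(m_b[, , c])
  }
  oracle_sigmoid(fc(vmax) + fc(vnum))
}

# Spatial gate: sigmoid(conv(stack(channel max, channel avg))).
oracle_spatial_attention <- function(m_cb, Ws, bs) {
  d <- dim(m_cb)
  pmaxs <- apply(m_cb, c(1, 2), max)
  pavgs <- apply(m_cb, c(1, 2), mean)
  k <- dim(Ws)[1]
  z <- matrix(bs, d[1], d[2])
  half <- (k - 1) / 2
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    for (a in seq_len(k)) for (b in seq_len(k)) {
      ii <- i + a - 1 - half; jj <- j + b - 1 - half
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
        z[i, j] <- z[i, j] + pmaxs[ii, jj] * Ws[a, b, 1, 1] +
          pavgs[ii, jj] * Ws[a, b, 2, 1]
    }
  oracle_sigmoid(z)
}

# Full attention chain M_b -> M_f.
oracle_cbam <- function(m_b, params) {
  mc <- oracle_channel_attention(m_b, params[["cb.fc1.W"]],
                                 params[["cb.fc1.b"]],
                                 params[["cb.fc2.W"]],
                                 params[["cb.fc2.b"]])
  d <- dim(m_b)
  m_cb <- m_b
  for (c in seq_len(d[3])) m_cb[, , c] <- m_b[, , c] * mc[c]
  ms <- oracle_spatial_attention(m_cb, params[["cb.sp.W"]],
                                 params[["cb.sp.b"]])
  m_f <- m_cb
  for (c in seq_len(d[3])) m_f[, , c] <- m_cb[, , c] * ms
  m_f
}

# Counting head, direct evaluation of the three equations.
oracle_head <- function(t_all, W1, b1, W2, b2) {
  flat <- as.vector(t_all)
  x1 <- pmax(as.vector(flat %*% W1) + b1, 0)
  x2 <- as.vector(x1 %*% W2) + b2
  list(count = max(0, mean(x2)), x2 = x2)
}

# Metrics, explicit loops.
oracle_metrics <- function(preds, trues) {
  n <- length(trues)
  sa <- 0; ss <- 0; sv <- 0; m <- sum(trues) / n
  for (i in seq_len(n)) {
    sa <- sa + abs(preds[i] - trues[i])
    ss <- ss + (preds[i] - trues[i])^2
    sv <- sv + (m - trues[i])^2
  }
  list(mae = sa / n, rmse = sqrt(ss / n), r2 = 1 - ss / sv)
}

# Exact mean of the rounded-then-clipped Gaussian count distribution:
# interior integers get the probability of their unit cell, the
# bounds absorb the tails.
oracle_clipped_mean <- function(mu, sd, lo, hi) {
  ks <- lo:hi
  p <- pnorm(ks + 0.5, mu, sd) - pnorm(ks - 0.5, mu, sd)
  p[1] <- pnorm(lo + 0.5, mu, sd)
  p[length(p)] <- 1 - pnorm(hi - 0.5, mu, sd)
  sum(ks * p)
}

# Connected components of a binary mask (4-neighbour flood fill).
oracle_n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (s0 in which(mask)) {
    if (lab[s0] != 0L) next
    nxt <- nxt + 1L
    queue <- s0
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (lab[q] != 0L || !mask[q]) next
      lab[q] <- nxt
      i <- (q - 1L) %% nrow(mask) + 1L
      j <- (q - 1L) %/% nrow(mask) + 1L
      for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + dd[1]; jj <- j + dd[2]
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
            mask[ii, jj] && lab[ii, jj] == 0L)
          queue <- c(queue, (jj - 1L) * nrow(mask) + ii)
      }
    }
  }
  nxt
}

# A consistently tiny assembled model for fast end-to-end tests.
tiny_model <- function(seed = 1, input_size = 32, cbam = TRUE,
                       dropout = 0, depth = 1) {
  countnet_model(input_size = input_size,
                 backbone = backbone_config(width = 1 / 16),
                 cbam = cbam,
                 mpm = mpm_config(slices = c(2, 1), embed_dim = 12,
                                  depth = depth, token_hidden = 6,
                                  channel_hidden = 10),
                 head = head_config(hidden = 16, dropout = dropout, k = 4),
                 reduction = 4, sp_kernel = 3, seed = seed)
}

# Build a model whose prediction reduces to w * mean(channel-1 of the
# backbone map): attention off, one 1x1 slice scale with a projection
# selecting channel 1, no mixer layers, and an averaging head.
linear_probe_model <- function(w = 2, seed = 1, input_size = 32) {
  m <- countnet_model(input_size = input_size,
                      backbone = backbone_config(width = 1 / 16),
                      cbam = FALSE,
                      mpm = mpm_config(slices = 1L, embed_dim = 1L,
                                       depth = 0L, token_hidden = 2L,
                                       channel_hidden = 2L,
                                       merge = FALSE),
                      head = head_config(hidden = 1L, dropout = 0, k = 1L),
                      seed = seed)
  side <- m$config$feature_side
  C <- m$config$channels
  m$params[["mpm.s1.proj.W"]][] <- 0
  m$params[["mpm.s1.proj.W"]][1, 1] <- 1  # token = channel-1 value
  m$params[["mpm.s1.proj.b"]][] <- 0
  m$params[["head.fc1.W"]][] <- 1 / side^2  # x1 = spatial mean
  m$params[["head.fc1.b"]][] <- 0
  m$params[["head.fc2.W"]][] <- w
  m$params[["head.fc2.b"]][] <- 0
  m
}
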