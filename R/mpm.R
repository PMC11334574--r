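#' Configure the multiscale perception module
#'
#' The module slices the attention-refined feature map into
#' non-overlapping p x p patches at several scales (defaults 16, 8,
#' 4), linearly projects each patch to a shared embedding dimension,
#' runs N mixer layers per scale, concatenates the per-scale token
#' matrices (coarse to fine) and mixes the result again.  A mixer
#' layer is MLP-only: a token-mixing sublayer (layer norm, transpose,
#' MLP across the token axis, transpose back, residual) followed by a
#' channel-mixing sublayer (layer norm, MLP across the embedding
#' axis, residual); GELU activations.
#'
#' @param slices Integer vector of patch sides; each must divide the
#'   feature-map side.
#' @param embed_dim Shared token embedding dimension d.
#' @param depth Number N of mixer layers per branch and for the
#'   merge stage.
#' @param token_hidden,channel_hidden Hidden widths of the
#'   token-mixing and channel-mixing MLPs.
#' @param merge If `FALSE` the concatenated tokens are returned
#'   without the final mixer stage (ablation hook).
#' @return An object of class `mpm_config`.
#' @export
mpm_config <- function(slices = c(16L, 8L, 4L), embed_dim = 512L,
                       depth = 4L, token_hidden = 256L,
                       channel_hidden = 1024L, merge = TRUE) {
  stopifnot(length(slices) >= 1L, all(slices >= 1L), depth >= 0L,
            embed_dim >= 1L)
  structure(list(slices = as.integer(slices),
                 embed_dim = as.integer(embed_dim),
                 depth = as.integer(depth),
                 token_hidden = as.integer(token_hidden),
                 channel_hidden = as.integer(channel_hidden),
                 merge = isTRUE(merge)),
            class = "mpm_config")
}

#' Slice a feature map into non-overlapping patches
#'
#' @param m_f H x W x C feature map.
#' @param p Patch side; must divide H and W.
#' @return A stack of dimension n_p x C x p x p where
#'   n_p = (H/p)(W/p); patches are ordered row-major (left to right,
#'   then top to bottom).
#' @export
slice_patches <- function(m_f, p) {
  d <- dim(m_f)
  if (d[1L] %% p != 0L || d[2L] %% p != 0L)
    stop(sprintf("patch side %d does not divide the feature side %d x %d",
                 p, d[1L], d[2L]))
  gh <- d[1L] %/% p; gw <- d[2L] %/% p
  stack <- array(0, c(gh * gw, d[3L], p, p))
  t <- 0L
  for (i in seq_len(gh)) {
    for (j in seq_len(gw)) {
      t <- t + 1L
      patch <- m_f[(i - 1L) * p + seq_len(p), (j - 1L) * p + seq_len(p), ,
                   drop = FALSE]
      stack[t, , , ] <- aperm(patch, c(3L, 1L, 2L))
    }
  }
  stack
}

#' Reassemble a patch stack into a feature map
#'
#' Inverse of [slice_patches()]: `unslice_patches(slice_patches(x, p),
#' p, nrow(x))` returns `x` exactly.
#'
#' @param stack n_p x C x p x p patch stack.
#' @param p Patch side used for slicing.
#' @param side Side of the original (square) feature map.
#' @return The H x W x C feature map.
#' @export
unslice_patches <- function(stack, p, side) {
  d <- dim(stack)
  g <- side %/% p
  if (side %% p != 0L || d[1L] != g * g || d[3L] != p || d[4L] != p)
    stop("patch stack geometry is inconsistent with `p` and `side`")
  m <- array(0, c(side, side, d[2L]))
  t <- 0L
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      t <- t + 1L
      m[(i - 1L) * p + seq_len(p), (j - 1L) * p + seq_len(p), ] <-
        aperm(array(stack[t, , , ], d[2:4]), c(2L, 3L, 1L))
    }
  }
  m
}

flatten_stack <- function(stack) {
  d <- dim(stack)
  matrix(stack, d[1L], prod(d[2:4]))
}

#' Project flattened patches to tokens
#'
#' @param stack n_p x C x p x p patch stack.
#' @param W,b Projection weights (C p^2 x d) and bias.
#' @return n_p x d token matrix, one token per patch.
#' @keywords internal
project_tokens <- function(stack, W, b) {
  flat <- flatten_stack(stack)
  if (ncol(flat) != nrow(W))
    stop(sprintf("flattened patch length %d does not match projection rows %d",
                 ncol(flat), nrow(W)))
  linear_forward(flat, W, b)$out
}

mixer_layer_init <- function(n_tokens, cfg, prefix) {
  d <- cfg$embed_dim; th <- cfg$token_hidden; ch <- cfg$channel_hidden
  p <- list()
  p[[paste0(prefix, ".ln1.g")]] <- rep(1, d)
  p[[paste0(prefix, ".ln1.b")]] <- numeric(d)
  p[[paste0(prefix, ".t1.W")]] <- he_init(c(n_tokens, th), fan_in = n_tokens)
  p[[paste0(prefix, ".t1.b")]] <- numeric(th)
  p[[paste0(prefix, ".t2.W")]] <- he_init(c(th, n_tokens), fan_in = th)
  p[[paste0(prefix, ".t2.b")]] <- numeric(n_tokens)
  p[[paste0(prefix, ".ln2.g")]] <- rep(1, d)
  p[[paste0(prefix, ".ln2.b")]] <- numeric(d)
  p[[paste0(prefix, ".c1.W")]] <- he_init(c(d, ch), fan_in = d)
  p[[paste0(prefix, ".c1.b")]] <- numeric(ch)
  p[[paste0(prefix, ".c2.W")]] <- he_init(c(ch, d), fan_in = ch)
  p[[paste0(prefix, ".c2.b")]] <- numeric(d)
  p
}

# Token-mixing sublayer: U = T + t(MLP_t(t(LN1(T)))).  The MLP acts
# along the token axis, identically for every embedding channel.
token_sublayer_forward <- function(T, params, prefix) {
  ln <- layernorm_forward(T, params[[paste0(prefix, ".ln1.g")]],
                          params[[paste0(prefix, ".ln1.b")]])
  a <- t(ln$out)
  l1 <- linear_forward(a, params[[paste0(prefix, ".t1.W")]],
                       params[[paste0(prefix, ".t1.b")]])
  g1 <- gelu_forward(l1$out)
  l2 <- linear_forward(g1$out, params[[paste0(prefix, ".t2.W")]],
                       params[[paste0(prefix, ".t2.b")]])
  list(out = T + t(l2$out),
       cache = list(ln = ln$cache, l1 = l1$cache, g1 = g1$cache,
                    l2 = l2$cache))
}

token_sublayer_backward <- function(dout, cache, params, prefix) {
  db <- t(dout)
  b2 <- linear_backward(db, cache$l2, params[[paste0(prefix, ".t2.W")]])
  dg <- gelu_backward(b2$dx, cache$g1)
  b1 <- linear_backward(dg, cache$l1, params[[paste0(prefix, ".t1.W")]])
  lb <- layernorm_backward(t(b1$dx), cache$ln)
  g <- list()
  g[[paste0(prefix, ".ln1.g")]] <- lb$dgamma
  g[[paste0(prefix, ".ln1.b")]] <- lb$dbeta
  g[[paste0(prefix, ".t1.W")]] <- b1$dW
  g[[paste0(prefix, ".t1.b")]] <- b1$db
  g[[paste0(prefix, ".t2.W")]] <- b2$dW
  g[[paste0(prefix, ".t2.b")]] <- b2$db
  list(dx = dout + lb$dx, grads = g)
}

# Channel-mixing sublayer: out = U + MLP_c(LN2(U)) acting along the
# embedding axis, identically for every token.
channel_sublayer_forward <- function(T, params, prefix) {
  ln <- layernorm_forward(T, params[[paste0(prefix, ".ln2.g")]],
                          params[[paste0(prefix, ".ln2.b")]])
  l1 <- linear_forward(ln$out, params[[paste0(prefix, ".c1.W")]],
                       params[[paste0(prefix, ".c1.b")]])
  g1 <- gelu_forward(l1$out)
  l2 <- linear_forward(g1$out, params[[paste0(prefix, ".c2.W")]],
                       params[[paste0(prefix, ".c2.b")]])
  list(out = T + l2$out,
       cache = list(ln = ln$cache, l1 = l1$cache, g1 = g1$cache,
                    l2 = l2$cache))
}

channel_sublayer_backward <- function(dout, cache, params, prefix) {
  b2 <- linear_backward(dout, cache$l2, params[[paste0(prefix, ".c2.W")]])
  dg <- gelu_backward(b2$dx, cache$g1)
  b1 <- linear_backward(dg, cache$l1, params[[paste0(prefix, ".c1.W")]])
  lb <- layernorm_backward(b1$dx, cache$ln)
  g <- list()
  g[[paste0(prefix, ".ln2.g")]] <- lb$dgamma
  g[[paste0(prefix, ".ln2.b")]] <- lb$dbeta
  g[[paste0(prefix, ".c1.W")]] <- b1$dW
  g[[paste0(prefix, ".c1.b")]] <- b1$db
  g[[paste0(prefix, ".c2.W")]] <- b2$dW
  g[[paste0(prefix, ".c2.b")]] <- b2$db
  list(dx = dout + lb$dx, grads = g)
}

mixer_layer_forward <- function(T, params, prefix) {
  tk <- token_sublayer_forward(T, params, prefix)
  ch <- channel_sublayer_forward(tk$out, params, prefix)
  list(out = ch$out, cache = list(tk = tk$cache, ch = ch$cache))
}

mixer_layer_backward <- function(dout, cache, params, prefix) {
  cb <- channel_sublayer_backward(dout, cache$ch, params, prefix)
  tb <- token_sublayer_backward(cb$dx, cache$tk, params, prefix)
  list(dx = tb$dx, grads = c(tb$grads, cb$grads))
}

mixer_stack_forward <- function(T, params, n_layers, prefix) {
  caches <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    r <- mixer_layer_forward(T, params, sprintf("%s.m%02d", prefix, i))
    T <- r$out
    caches[[i]] <- r$cache
  }
  list(out = T, cache = caches)
}

mixer_stack_backward <- function(dout, caches, params, n_layers, prefix) {
  g <- list()
  for (i in rev(seq_len(n_layers))) {
    r <- mixer_layer_backward(dout, caches[[i]],
                              params, sprintf("%s.m%02d", prefix, i))
    dout <- r$dx
    g <- c(g, r$grads)
  }
  list(dx = dout, grads = g)
}

mpm_init <- function(side, channels, cfg, prefix = "mpm") {
  p <- list()
  n_all <- 0L
  for (s in cfg$slices) {
    if (side %% s != 0L)
      stop(sprintf("slice size %d does not divide the feature side %d",
                   s, side))
    n_tok <- (side %/% s)^2
    n_all <- n_all + n_tok
    bp <- sprintf("%s.s%d", prefix, s)
    in_dim <- channels * s * s
    p[[paste0(bp, ".proj.W")]] <-
      he_init(c(in_dim, cfg$embed_dim), fan_in = in_dim)
    p[[paste0(bp, ".proj.b")]] <- numeric(cfg$embed_dim)
    for (i in seq_len(cfg$depth))
      p <- c(p, mixer_layer_init(n_tok, cfg, sprintf("%s.m%02d", bp, i)))
  }
  if (cfg$merge)
    for (i in seq_len(cfg$depth))
      p <- c(p, mixer_layer_init(n_all, cfg,
                                 sprintf("%s.all.m%02d", prefix, i)))
  p
}

mpm_n_tokens <- function(side, cfg) as.integer(sum((side %/% cfg$slices)^2))

# One scale branch: slice -> project -> N mixer layers.
scale_branch_forward <- function(m_f, s, params, cfg, prefix = "mpm") {
  bp <- sprintf("%s.s%d", prefix, s)
  stack <- slice_patches(m_f, s)
  flat <- flatten_stack(stack)
  pr <- linear_forward(flat, params[[paste0(bp, ".proj.W")]],
                       params[[paste0(bp, ".proj.b")]])
  mx <- mixer_stack_forward(pr$out, params, cfg$depth, bp)
  list(out = mx$out,
       cache = list(proj = pr$cache, mix = mx$cache, s = s,
                    side = dim(m_f)[1L]))
}

scale_branch_backward <- function(dout, cache, params, cfg, prefix = "mpm") {
  bp <- sprintf("%s.s%d", prefix, cache$s)
  mb <- mixer_stack_backward(dout, cache$mix, params, cfg$depth, bp)
  pb <- linear_backward(mb$dx, cache$proj, params[[paste0(bp, ".proj.W")]])
  g <- mb$grads
  g[[paste0(bp, ".proj.W")]] <- pb$dW
  g[[paste0(bp, ".proj.b")]] <- pb$db
  s <- cache$s; side <- cache$side
  C <- ncol(cache$proj) %/% (s * s)
  stack <- array(pb$dx, c(nrow(pb$dx), C, s, s))
  list(dmf = unslice_patches(stack, s, side), grads = g)
}

mpm_forward <- function(m_f, params, cfg, prefix = "mpm") {
  branches <- lapply(cfg$slices, function(s)
    scale_branch_forward(m_f, s, params, cfg, prefix))
  Ts <- lapply(branches, `[[`, "out")
  t_cat <- do.call(rbind, Ts)
  if (cfg$merge) {
    mx <- mixer_stack_forward(t_cat, params, cfg$depth,
                              paste0(prefix, ".all"))
    out <- mx$out; merge_cache <- mx$cache
  } else {
    out <- t_cat; merge_cache <- NULL
  }
  list(out = out,
       cache = list(branches = branches, merge = merge_cache,
                    n_tok = vapply(Ts, nrow, 1L), branch_T = Ts))
}

mpm_backward <- function(dout, cache, params, cfg, prefix = "mpm") {
  g <- list()
  if (cfg$merge) {
    mb <- mixer_stack_backward(dout, cache$merge, params, cfg$depth,
                               paste0(prefix, ".all"))
    dout <- mb$dx
    g <- mb$grads
  }
  ends <- cumsum(cache$n_tok)
  starts <- c(1L, head(ends, -1L) + 1L)
  dmf <- NULL
  branch_grads <- vector("list", length(cfg$slices))
  for (i in seq_along(cfg$slices)) {
    dTi <- dout[starts[i]:ends[i], , drop = FALSE]
    branch_grads[[i]] <- dTi
    bb <- scale_branch_backward(dTi, cache$branches[[i]]$cache, params,
                                cfg, prefix)
    dmf <- if (is.null(dmf)) bb$dmf else dmf + bb$dmf
    g <- c(g, bb$grads)
  }
  names(branch_grads) <- paste0("s", cfg$slices)
  list(dx = dmf, grads = g, branch_grads = branch_grads)
}
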