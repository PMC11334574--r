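test_that("slicing yields the patch-count law n_p = (side/p)^2", {
  m_f <- array(rnorm(64 * 64 * 4), c(64, 64, 4))
  expect_identical(dim(slice_patches(m_f, 16))[1], 16L)
  expect_identical(dim(slice_patches(m_f, 8))[1], 64L)
  expect_identical(dim(slice_patches(m_f, 4))[1], 256L)
  expect_identical(dim(slice_patches(m_f, 16)), c(16L, 4L, 16L, 16L))

  one <- slice_patches(m_f, 64)
  expect_identical(dim(one)[1], 1L)
  expect_equal(aperm(array(one[1, , , ], c(4, 64, 64)), c(2, 3, 1)), m_f)

  expect_error(slice_patches(m_f, 5), "5 does not divide.*64")
})

test_that("slice/unslice is a bijection on random maps", {
  set.seed(1)
  for (case in list(c(8, 4, 3), c(8, 8, 2), c(12, 4, 5), c(6, 2, 1))) {
    side <- case[1]; p <- case[2]; C <- case[3]
    x <- array(rnorm(side * side * C), c(side, side, C))
    st <- slice_patches(x, p)
    expect_equal(unslice_patches(st, p, side), x, tolerance = 1e-15)
  }
  # shuffling the patch order breaks the reconstruction
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  st <- slice_patches(x, 4)
  st_shuf <- st[c(2, 1, 3, 4), , , , drop = FALSE]
  expect_false(isTRUE(all.equal(unslice_patches(st_shuf, 4, 8), x)))
})

test_that("token projection is the expected linear map", {
  set.seed(2)
  st <- slice_patches(array(rnorm(8 * 8 * 3), c(8, 8, 3)), 4)
  flat <- countnet:::flatten_stack(st)

  # identity projection returns flattened patches
  d_in <- ncol(flat)
  got <- countnet:::project_tokens(st, diag(d_in), numeric(d_in))
  expect_equal(got, flat, tolerance = 1e-15)

  # zero stack, zero bias -> zero tokens
  z <- st; z[] <- 0
  W <- matrix(rnorm(d_in * 5), d_in, 5)
  expect_true(all(countnet:::project_tokens(z, W, numeric(5)) == 0))

  # random projection equals the explicit matrix product
  b <- rnorm(5)
  want <- flat %*% W + rep(b, each = nrow(flat))
  expect_equal(countnet:::project_tokens(st, W, b), want,
               tolerance = 1e-12)
  expect_error(countnet:::project_tokens(st, W[1:10, ], numeric(5)),
               "does not match")
})

make_mixer <- function(n_tokens, d = 8, seed = 3) {
  set.seed(seed)
  cfg <- mpm_config(slices = 1L, embed_dim = d, depth = 1L,
                    token_hidden = 5L, channel_hidden = 7L)
  params <- countnet:::mixer_layer_init(n_tokens, cfg, "mx")
  list(cfg = cfg, params = params)
}

test_that("a zero token matrix stays zero through a mixer layer", {
  mx <- make_mixer(6)
  T0 <- matrix(0, 6, 8)
  out <- countnet:::mixer_layer_forward(T0, mx$params, "mx")$out
  expect_true(all(out == 0))
})

test_that("the channel-mixing sublayer commutes with token permutations", {
  mx <- make_mixer(6)
  set.seed(4)
  for (rep in 1:5) {
    T <- matrix(rnorm(6 * 8), 6, 8)
    perm <- sample(6)
    a <- countnet:::channel_sublayer_forward(T[perm, ], mx$params,
                                             "mx")$out
    b <- countnet:::channel_sublayer_forward(T, mx$params, "mx")$out[perm, ]
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("the token-mixing sublayer commutes with channel permutations
          when its per-channel transforms are symmetric", {
  # the layer norm scale/shift and MLP act identically on every
  # channel column, so permuting channels commutes when gamma/beta
  # are channel-constant (their default initialization)
  mx <- make_mixer(6)
  set.seed(5)
  for (rep in 1:5) {
    T <- matrix(rnorm(6 * 8), 6, 8)
    perm <- sample(8)
    a <- countnet:::token_sublayer_forward(T[, perm], mx$params, "mx")$out
    b <- countnet:::token_sublayer_forward(T, mx$params, "mx")$out[, perm]
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("mixer gradients match finite differences", {
  mx <- make_mixer(5, d = 6, seed = 6)
  T <- matrix(rnorm(5 * 6), 5, 6)
  fw <- countnet:::mixer_layer_forward(T, mx$params, "mx")
  bw <- countnet:::mixer_layer_backward(2 * fw$out, fw$cache, mx$params,
                                        "mx")
  loss <- function(p, x = T)
    sum(countnet:::mixer_layer_forward(x, p, "mx")$out^2)
  eps <- 1e-6
  for (k in names(mx$params)) {
    i <- sample(length(mx$params[[k]]), 1)
    pp <- mx$params; pp[[k]][i] <- pp[[k]][i] + eps
    pm <- mx$params; pm[[k]][i] <- pm[[k]][i] - eps
    expect_equal(bw$grads[[k]][i], (loss(pp) - loss(pm)) / (2 * eps),
                 tolerance = 1e-4)
  }
  i <- sample(length(T), 1)
  xp <- T; xp[i] <- xp[i] + eps
  xm <- T; xm[i] <- xm[i] - eps
  expect_equal(bw$dx[i],
               (loss(mx$params, xp) - loss(mx$params, xm)) / (2 * eps),
               tolerance = 1e-4)
})

make_branch <- function(depth, seed = 7) {
  set.seed(seed)
  cfg <- mpm_config(slices = c(4L, 2L), embed_dim = 10L, depth = depth,
                    token_hidden = 6L, channel_hidden = 8L)
  params <- countnet:::mpm_init(8L, 3L, cfg)
  list(cfg = cfg, params = params)
}

test_that("a scale branch composes slicing, projection and N mixer layers", {
  m_f <- array(rnorm(8 * 8 * 3), c(8, 8, 3))

  b0 <- make_branch(0L)
  got0 <- countnet:::scale_branch_forward(m_f, 4L, b0$params, b0$cfg)$out
  st <- slice_patches(m_f, 4L)
  proj <- countnet:::project_tokens(st, b0$params[["mpm.s4.proj.W"]],
                                    b0$params[["mpm.s4.proj.b"]])
  expect_equal(got0, proj, tolerance = 1e-12)  # N = 0: projection only

  b4 <- make_branch(4L)
  got4 <- countnet:::scale_branch_forward(m_f, 4L, b4$params, b4$cfg)$out
  step <- countnet:::project_tokens(st, b4$params[["mpm.s4.proj.W"]],
                                    b4$params[["mpm.s4.proj.b"]])
  for (i in 1:4)
    step <- countnet:::mixer_layer_forward(step, b4$params,
                                           sprintf("mpm.s4.m%02d", i))$out
  expect_equal(got4, step, tolerance = 1e-12)
})

test_that("merging concatenates coarse to fine and mixes again", {
  b <- make_branch(1L)
  m_f <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  fw <- countnet:::mpm_forward(m_f, b$params, b$cfg)
  expect_identical(nrow(fw$out), 4L + 16L)  # (8/4)^2 + (8/2)^2
  expect_identical(fw$cache$n_tok, c(4L, 16L))

  # merge disabled: plain concatenation of the branch outputs
  cfg_nm <- b$cfg; cfg_nm$merge <- FALSE
  fw_nm <- countnet:::mpm_forward(m_f, b$params, cfg_nm)
  expect_equal(fw_nm$out, do.call(rbind, fw_nm$cache$branch_T),
               tolerance = 1e-15)

  # full-scale token counts: 16 + 64 + 256 = 336 from a 64-side map
  cfg64 <- mpm_config()
  expect_identical(countnet:::mpm_n_tokens(64L, cfg64), 336L)
})

test_that("mismatched slice sizes are rejected at build time", {
  expect_error(countnet:::mpm_init(10L, 3L, mpm_config(slices = c(4L))),
               "does not divide")
  expect_error(countnet_model(input_size = 80,
                              backbone = backbone_config(width = 1 / 16),
                              mpm = mpm_config(slices = c(16L, 8L, 4L)),
                              head = head_config(hidden = 8, k = 2),
                              reduction = 4),
               "16 does not divide")
})
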