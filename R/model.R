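#' Assemble a count-supervised counting network
#'
#' Builds the full model: truncated VGG-style backbone, optional
#' channel+spatial attention block, multiscale mixer perception
#' module, and the count-regression head.  The network is trained
#' with per-image totals only; it produces no boxes or density maps.
#' Configuration consistency (input side divisible by the output
#' stride, every slice size dividing the feature side, chained
#' dimensions) is checked at build time.
#'
#' @param input_size Side of the (square) preprocessed input image;
#'   default 512.
#' @param backbone A [backbone_config()].
#' @param cbam Logical; include the attention block (`FALSE` gives
#'   the pass-through ablation where the backbone map feeds the
#'   perception module directly).
#' @param mpm An [mpm_config()].
#' @param head A [head_config()].
#' @param seed Optional integer seeding the weight initialization.
#' @param reduction,sp_kernel Attention bottleneck ratio and spatial
#'   kernel size.
#' @return An object of class `countnet`: a list with `config` and
#'   the flat parameter list `params`.
#' @examples
#' m <- countnet_model(input_size = 64,
#'                     backbone = backbone_config(width = 1 / 16),
#'                     mpm = mpm_config(slices = c(4, 2), embed_dim = 16,
#'                                      depth = 1, token_hidden = 8,
#'                                      channel_hidden = 16),
#'                     head = head_config(hidden = 32, k = 4),
#'                     reduction = 4, seed = 1)
#' x <- array(stats::rnorm(64 * 64 * 3), c(64, 64, 3))
#' predict(m, x)
#' @export
countnet_model <- function(input_size = 512L,
                           backbone = backbone_config(),
                           cbam = TRUE,
                           mpm = mpm_config(),
                           head = head_config(),
                           seed = NULL,
                           reduction = 16L, sp_kernel = 7L) {
  stopifnot(inherits(backbone, "backbone_config"),
            inherits(mpm, "mpm_config"), inherits(head, "head_config"))
  input_size <- as.integer(input_size)
  if (input_size %% backbone$stride != 0L)
    stop(sprintf("input size %d is not divisible by the backbone stride %d",
                 input_size, backbone$stride))
  side <- input_size %/% backbone$stride
  for (s in mpm$slices)
    if (side %% s != 0L)
      stop(sprintf("slice size %d does not divide the feature side %d",
                   s, side))
  channels <- backbone$widths[length(backbone$widths)]
  if (!is.null(seed)) set.seed(seed)
  params <- backbone_init(backbone)
  cbam_cfg <- NULL
  if (isTRUE(cbam)) {
    cbam_cfg <- cbam_config(channels, reduction, sp_kernel)
    params <- c(params, cbam_init(cbam_cfg))
  }
  params <- c(params, mpm_init(side, channels, mpm))
  n_tok <- mpm_n_tokens(side, mpm)
  params <- c(params, head_init(n_tok * mpm$embed_dim, head))
  structure(list(config = list(input_size = input_size,
                               backbone = backbone, cbam = cbam_cfg,
                               mpm = mpm, head = head,
                               feature_side = side, channels = channels,
                               n_tokens = n_tok),
                 params = params),
            class = "countnet")
}

# Forward pass for one preprocessed image.  With keep_cache = TRUE
# the per-stage caches needed by the backward pass are returned.
countnet_forward <- function(params, config, x, train = FALSE,
                             keep_cache = FALSE) {
  bb <- backbone_forward(x, params, config$backbone,
                         keep_cache = keep_cache)
  m_b <- bb$out
  if (!is.null(config$cbam)) {
    cb <- cbam_forward(m_b, params)
    m_f <- cb$out
  } else {
    cb <- NULL
    m_f <- m_b
  }
  mp <- mpm_forward(m_f, params, config$mpm)
  hd <- head_forward(mp$out, params, config$head, train = train)
  out <- list(count = hd$count, x2 = hd$x2, m_b = m_b,
              branch_T = mp$cache$branch_T)
  if (keep_cache)
    out$cache <- list(bb = bb$cache, cb = cb$cache, mp = mp$cache,
                      hd = hd$cache)
  out
}

# Backward pass from d(loss)/d(count); returns parameter gradients
# and, for attention visualization, the gradients at the backbone map
# and at each perception branch's token matrix.
countnet_backward <- function(params, config, fw, dcount,
                              input_grad = FALSE) {
  hb <- head_backward(dcount, fw$cache$hd, params, config$head)
  mb <- mpm_backward(hb$dt_all, fw$cache$mp, params, config$mpm)
  g <- c(hb$grads, mb$grads)
  if (!is.null(config$cbam)) {
    cbb <- cbam_backward(mb$dx, fw$cache$cb, params)
    d_mb <- cbb$dx
    g <- c(g, cbb$grads)
  } else d_mb <- mb$dx
  bbb <- backbone_backward(d_mb, fw$cache$bb, params, config$backbone)
  res <- list(grads = c(g, bbb$grads), d_mb = d_mb,
              branch_grads = mb$branch_grads)
  if (input_grad) res$dx <- bbb$dx
  res
}

#' Predict counts with an (untrained or trained) network
#'
#' @param object A `countnet` model.
#' @param newdata One H x W x 3 preprocessed array, a list of them,
#'   or a `countnet_samples` object from [load_samples()] /
#'   [synth_samples()].
#' @param ... Unused.
#' @return Numeric vector of nonnegative predicted counts.
#' @export
predict.countnet <- function(object, newdata, ...) {
  xs <- sample_arrays(newdata)
  vapply(xs, function(x)
    countnet_forward(object$params, object$config, x)$count, numeric(1))
}

#' @export
print.countnet <- function(x, ...) {
  cfg <- x$config
  cat("Count-supervised counting network\n")
  cat(sprintf("  input %dx%d -> feature map %dx%dx%d (stride %d)\n",
              cfg$input_size, cfg$input_size, cfg$feature_side,
              cfg$feature_side, cfg$channels, cfg$backbone$stride))
  cat(sprintf("  attention block: %s\n",
              if (is.null(cfg$cbam)) "disabled" else
                sprintf("channel (r=%d) + spatial (k=%d)",
                        cfg$cbam$reduction, cfg$cbam$kernel)))
  cat(sprintf("  perception: slices [%s], %d tokens, d=%d, depth N=%d%s\n",
              paste(cfg$mpm$slices, collapse = ", "), cfg$n_tokens,
              cfg$mpm$embed_dim, cfg$mpm$depth,
              if (cfg$mpm$merge) ", merged" else ""))
  cat(sprintf("  head: hidden %d, dropout %.2f, K=%d\n",
              cfg$head$hidden, cfg$head$dropout, cfg$head$k))
  cat(sprintf("  parameters: %s\n",
              format(sum(vapply(x$params, length, numeric(1))),
                     big.mark = ",")))
  invisible(x)
}

# Coerce the accepted input forms to a plain list of image arrays.
sample_arrays <- function(newdata) {
  if (inherits(newdata, "countnet_samples")) return(newdata$x)
  if (is.array(newdata) && length(dim(newdata)) == 3L) return(list(newdata))
  if (is.list(newdata)) return(newdata)
  stop("`newdata` must be an image array, a list of them, or countnet_samples")
}
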