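#' Configure the truncated VGG-style backbone
#'
#' The backbone is the feature-extraction front of the counting
#' network: the first ten 3x3 convolution layers of the VGG16 layout
#' (channel widths 64,64 | 128,128 | 256,256,256 | 512,512,512, ReLU
#' after every convolution) with 2x2 stride-2 max pooling after the
#' first three blocks.  It maps a 3-channel image of side S to a
#' 512-channel feature map of side S/8 (output stride 8).  A width
#' multiplier shrinks every channel count proportionally for
#' desk-scale models that train on one CPU.
#'
#' @param width Width multiplier in (0, 1]; 1 gives the full
#'   512-channel backbone, 1/16 a 32-channel one.
#' @param widths Optional explicit integer vector of the ten
#'   convolution widths, overriding `width`.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(width = 1, widths = NULL) {
  full <- c(64L, 64L, 128L, 128L, 256L, 256L, 256L, 512L, 512L, 512L)
  if (is.null(widths)) {
    if (!is.numeric(width) || length(width) != 1L || width <= 0 || width > 1)
      stop("`width` must be a single multiplier in (0, 1]")
    widths <- pmax(1L, as.integer(round(full * width)))
  }
  if (any(widths < 1)) stop("channel widths must be positive")
  structure(list(widths = as.integer(widths),
                 pool_after = c(2L, 4L, 7L),  # ends of blocks 1-3
                 stride = 8L),
            class = "backbone_config")
}

backbone_init <- function(cfg, prefix = "bb") {
  p <- list()
  ins <- c(3L, cfg$widths[-length(cfg$widths)])
  for (i in seq_along(cfg$widths)) {
    cin <- ins[i]; cout <- cfg$widths[i]
    p[[sprintf("%s.c%02d.W", prefix, i)]] <-
      he_init(c(3L, 3L, cin, cout), fan_in = 9 * cin)
    p[[sprintf("%s.c%02d.b", prefix, i)]] <- numeric(cout)
  }
  p
}

#' Build a standalone backbone feature extractor
#'
#' Wraps a freshly initialized backbone as a callable object for use
#' outside the assembled counting network (e.g. to inspect feature
#' geometry).  Weights are drawn from the current RNG state; seed
#' beforehand for reproducibility.
#'
#' @param config A [backbone_config()].
#' @return An object of class `countnet_backbone` holding the
#'   configuration and parameters.
#' @seealso [extract_features()]
#' @export
build_backbone <- function(config = backbone_config()) {
  stopifnot(inherits(config, "backbone_config"))
  structure(list(config = config, params = backbone_init(config)),
            class = "countnet_backbone")
}

#' Run images through a backbone
#'
#' @param backbone A `countnet_backbone` from [build_backbone()].
#' @param images One preprocessed H x W x 3 array or a list of them;
#'   H and W must be divisible by 8.
#' @return For one image, the H/8 x W/8 x C feature map (the map
#'   `M_b`) with attribute `stride = 8`; for a list, a list of maps.
#' @export
extract_features <- function(backbone, images) {
  stopifnot(inherits(backbone, "countnet_backbone"))
  one <- function(x) {
    out <- backbone_forward(x, backbone$params, backbone$config,
                            keep_cache = FALSE)$out
    attr(out, "stride") <- backbone$config$stride
    out
  }
  if (is.list(images)) lapply(images, one) else one(images)
}

backbone_forward <- function(x, params, cfg, prefix = "bb",
                             keep_cache = TRUE) {
  d <- dim(x)
  if (length(d) != 3L || d[3L] != 3L)
    stop("backbone input must be an H x W x 3 array")
  if (d[1L] %% cfg$stride != 0L || d[2L] %% cfg$stride != 0L)
    stop(sprintf("input sides (%d x %d) must be divisible by %d",
                 d[1L], d[2L], cfg$stride))
  caches <- vector("list", length(cfg$widths))
  pools <- list()
  for (i in seq_along(cfg$widths)) {
    cv <- conv2d_forward(x, params[[sprintf("%s.c%02d.W", prefix, i)]],
                         params[[sprintf("%s.c%02d.b", prefix, i)]])
    rl <- relu_forward(cv$out)
    if (keep_cache) caches[[i]] <- list(conv = cv$cache, relu = rl$cache)
    x <- rl$out
    rm(cv, rl)
    if (i %in% cfg$pool_after) {
      mp <- maxpool_forward(x)
      if (keep_cache) pools[[as.character(i)]] <- mp$cache
      x <- mp$out
    }
  }
  list(out = x, cache = list(layers = caches, pools = pools))
}

backbone_backward <- function(dout, cache, params, cfg, prefix = "bb") {
  g <- list()
  for (i in rev(seq_along(cfg$widths))) {
    if (i %in% cfg$pool_after)
      dout <- maxpool_backward(dout, cache$pools[[as.character(i)]])
    dout <- relu_backward(dout, cache$layers[[i]]$relu)
    bw <- conv2d_backward(dout, cache$layers[[i]]$conv,
                          params[[sprintf("%s.c%02d.W", prefix, i)]])
    g[[sprintf("%s.c%02d.W", prefix, i)]] <- bw$dW
    g[[sprintf("%s.c%02d.b", prefix, i)]] <- bw$db
    dout <- bw$dx
  }
  list(dx = dout, grads = g)
}
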