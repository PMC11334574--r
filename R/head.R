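#' Configure the count-regression head
#'
#' The head flattens the merged token matrix to one vector and
#' regresses the count directly: `x1 = ReLU(FC1(flat))`,
#' `x2 = FC2(Dropout(x1))`, `C_hat = ReLU(mean(x2))`.  Predicting a
#' set of K counts and average-pooling them damps the variance of a
#' single regressed value; the terminal ReLU guarantees a
#' nonnegative count.
#'
#' @param hidden Width of the first fully connected layer.
#' @param dropout Dropout rate in \[0, 1), applied between the two
#'   layers during training only.
#' @param k Size K of the predicted count set (length of `x2`).
#' @return An object of class `head_config`.
#' @export
head_config <- function(hidden = 1024L, dropout = 0.5, k = 64L) {
  stopifnot(hidden >= 1L, k >= 1L, dropout >= 0, dropout < 1)
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 k = as.integer(k)),
            class = "head_config")
}

head_init <- function(in_dim, cfg, prefix = "head") {
  p <- list()
  p[[paste0(prefix, ".fc1.W")]] <- he_init(c(in_dim, cfg$hidden),
                                           fan_in = in_dim)
  p[[paste0(prefix, ".fc1.b")]] <- numeric(cfg$hidden)
  p[[paste0(prefix, ".fc2.W")]] <- he_init(c(cfg$hidden, cfg$k),
                                           fan_in = cfg$hidden)
  p[[paste0(prefix, ".fc2.b")]] <- numeric(cfg$k)
  p
}

#' Regress a count from a token matrix
#'
#' @param t_all Merged token matrix (tokens x embedding dim).
#' @param params,cfg Parameter list and [head_config()].
#' @param train If `TRUE`, dropout is sampled from the current RNG
#'   state; in evaluation mode the pass is deterministic.
#' @return List with `count` (nonnegative scalar), `x2` (the
#'   pre-pooling K-vector) and `cache`.
#' @keywords internal
head_forward <- function(t_all, params, cfg, train = FALSE,
                         prefix = "head") {
  flat <- matrix(as.vector(t_all), 1L)
  if (ncol(flat) != nrow(params[[paste0(prefix, ".fc1.W")]]))
    stop(sprintf("token matrix flattens to %d values but FC1 expects %d",
                 ncol(flat), nrow(params[[paste0(prefix, ".fc1.W")]])))
  l1 <- linear_forward(flat, params[[paste0(prefix, ".fc1.W")]],
                       params[[paste0(prefix, ".fc1.b")]])
  r1 <- relu_forward(l1$out)
  x1 <- r1$out
  if (train && cfg$dropout > 0) {
    keep <- (stats::runif(length(x1)) >= cfg$dropout) / (1 - cfg$dropout)
    x1 <- x1 * keep
  } else keep <- NULL
  l2 <- linear_forward(x1, params[[paste0(prefix, ".fc2.W")]],
                       params[[paste0(prefix, ".fc2.b")]])
  x2 <- drop(l2$out)
  m <- mean(x2)
  list(count = max(0, m), x2 = x2,
       cache = list(l1 = l1$cache, r1 = r1$cache, keep = keep,
                    l2 = l2$cache, m = m, dims = dim(t_all)))
}

head_backward <- function(dcount, cache, params, cfg, prefix = "head") {
  dm <- if (cache$m > 0) dcount else 0
  dx2 <- matrix(dm / cfg$k, 1L, cfg$k)
  b2 <- linear_backward(dx2, cache$l2, params[[paste0(prefix, ".fc2.W")]])
  dx1 <- b2$dx
  if (!is.null(cache$keep)) dx1 <- dx1 * cache$keep
  dx1 <- relu_backward(dx1, cache$r1)
  b1 <- linear_backward(dx1, cache$l1, params[[paste0(prefix, ".fc1.W")]])
  g <- list()
  g[[paste0(prefix, ".fc1.W")]] <- b1$dW
  g[[paste0(prefix, ".fc1.b")]] <- b1$db
  g[[paste0(prefix, ".fc2.W")]] <- b2$dW
  g[[paste0(prefix, ".fc2.b")]] <- b2$db
  list(dt_all = matrix(b1$dx, cache$dims[1L], cache$dims[2L]), grads = g)
}

#' Predict a count from a token matrix (standalone head)
#'
#' Convenience wrapper running only the counting head with freshly
#' initialized or supplied weights; the assembled network applies the
#' same computation after its perception stages.
#'
#' @inheritParams head_forward
#' @param params Parameter list from [head_init()]; if `NULL`, new
#'   weights are drawn for the given input.
#' @return List with `count` and `x2` as in [head_forward()].
#' @export
predict_count <- function(t_all, cfg = head_config(), params = NULL,
                          train = FALSE) {
  if (is.null(params)) params <- head_init(length(t_all), cfg)
  r <- head_forward(t_all, params, cfg, train = train)
  r[c("count", "x2")]
}
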