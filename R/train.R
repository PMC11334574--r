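#' Training control parameters
#'
#' The optimization protocol for count supervision: stochastic
#' gradient descent with momentum on the L1 loss between predicted
#' and true counts, batch size 16, initial learning rate 1e-4, and a
#' multi-step schedule multiplying the rate by `gamma` after each
#' milestone epoch.  L1 is preferred over L2 because count outliers
#' (very dense scenes) would otherwise dominate the gradient.  The
#' returned checkpoint is always the epoch with the best validation
#' MAE, never the last.
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Images per gradient step.
#' @param lr Initial learning rate (>= 0; 0 performs null
#'   updates, useful for baselines).
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient (0 disables).
#' @param milestones Strictly increasing epochs after which the
#'   learning rate is multiplied by `gamma`.
#' @param gamma Multiplicative decay factor.
#' @param seed Seed for data order, dropout and any other training
#'   randomness.
#' @param val_every Validate every this many epochs (the final epoch
#'   is always validated); checkpoint selection considers validated
#'   epochs only.
#' @param verbose Print one line per epoch.
#' @return An object of class `countnet_control`.
#' @export
countnet_control <- function(epochs = 100L, batch_size = 16L, lr = 1e-4,
                             momentum = 0.9, weight_decay = 0,
                             milestones = c(60L, 90L), gamma = 0.1,
                             seed = 1L, val_every = 1L, verbose = FALSE) {
  stopifnot(batch_size >= 1L, lr >= 0, epochs >= 1L, gamma > 0,
            val_every >= 1L)
  if (length(milestones) && any(diff(milestones) <= 0))
    stop("`milestones` must be strictly increasing")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 milestones = as.integer(milestones), gamma = gamma,
                 seed = as.integer(seed),
                 val_every = as.integer(val_every),
                 verbose = isTRUE(verbose)),
            class = "countnet_control")
}

#' Mean absolute (L1) count loss
#'
#' @param predictions,targets Equal-length nonempty count vectors.
#' @return Mean absolute difference.
#' @export
l1_loss <- function(predictions, targets) {
  if (length(predictions) == 0L)
    stop("empty batch")
  if (length(predictions) != length(targets))
    stop("prediction and target lengths differ")
  mean(abs(predictions - targets))
}

schedule_lr <- function(epoch, control) {
  control$lr * control$gamma^sum(epoch > control$milestones)
}

sgd_step <- function(params, grads, velocity, lr, momentum, weight_decay) {
  for (k in names(grads)) {
    g <- grads[[k]]
    if (weight_decay > 0) g <- g + weight_decay * params[[k]]
    v <- momentum * velocity[[k]] - lr * g
    velocity[[k]] <- v
    params[[k]] <- params[[k]] + v
  }
  list(params = params, velocity = velocity)
}

accumulate_grads <- function(total, g, scale = 1) {
  if (is.null(total)) return(lapply(g, `*`, scale))
  for (k in names(g)) total[[k]] <- total[[k]] + g[[k]] * scale
  total
}

#' Fit a counting network by count supervision
#'
#' Optimizes the model on per-image totals alone.  Each epoch
#' shuffles the training set (seeded), processes mini-batches with
#' SGD + momentum on the L1 loss, evaluates MAE/RMSE on the
#' validation set in deterministic mode, and keeps the weights of
#' the epoch with the lowest validation MAE.
#'
#' @param model A `countnet` from [countnet_model()].
#' @param train,val `countnet_samples` with preprocessed images.
#' @param control A [countnet_control()].
#' @param init_output_bias If `TRUE` (default), the output layer's
#'   bias is initialized so the untrained network predicts the mean
#'   training count.  Starting at the prior mean removes the long
#'   warmup in which the head must learn the count offset and keeps
#'   the terminal ReLU away from its dead zone.
#' @return An object of class `countnet_fit`: the best-epoch model,
#'   the per-epoch `history` data frame (epoch, lr, train_l1,
#'   val_mae, val_rmse), `best_epoch`, and the stored validation
#'   predictions of the best epoch.
#' @export
countnet_fit <- function(model, train, val,
                         control = countnet_control(),
                         init_output_bias = TRUE) {
  stopifnot(inherits(model, "countnet"),
            inherits(train, "countnet_samples"),
            inherits(val, "countnet_samples"))
  if (length(train) == 0L || length(val) == 0L)
    stop("training and validation sets must be nonempty")
  params <- model$params
  if (isTRUE(init_output_bias))
    params[["head.fc2.b"]][] <- mean(train$count)
  config <- model$config
  velocity <- lapply(params, function(p) { p[] <- 0; p })
  n <- length(train)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_l1 = numeric(), val_mae = numeric(),
                        val_rmse = numeric())
  best <- list(mae = Inf, params = params, epoch = 0L, val_pred = NULL)
  set.seed(control$seed)
  for (epoch in seq_len(control$epochs)) {
    lr <- schedule_lr(epoch, control)
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = control$batch_size)) {
      idx <- ord[start:min(start + control$batch_size - 1L, n)]
      grads <- NULL
      batch_preds <- numeric(length(idx))
      for (j in seq_along(idx)) {
        smp <- idx[j]
        fw <- countnet_forward(params, config, train$x[[smp]],
                               train = TRUE, keep_cache = TRUE)
        batch_preds[j] <- fw$count
        dcount <- sign(fw$count - train$count[smp]) / length(idx)
        bw <- countnet_backward(params, config, fw, dcount)
        grads <- accumulate_grads(grads, bw$grads)
      }
      loss <- l1_loss(batch_preds, train$count[idx])
      if (!is.finite(loss))
        stop(sprintf("non-finite training loss at epoch %d; %s", epoch,
                     "lower the learning rate or check the inputs"))
      losses <- c(losses, loss)
      st <- sgd_step(params, grads, velocity, lr, control$momentum,
                     control$weight_decay)
      params <- st$params
      velocity <- st$velocity
    }
    validate <- epoch %% control$val_every == 0L ||
      epoch == control$epochs
    if (validate) {
      val_pred <- vapply(val$x, function(x)
        countnet_forward(params, config, x)$count, numeric(1))
      vm <- count_mae(val_pred, val$count)
      vr <- count_rmse(val_pred, val$count)
    } else {
      vm <- NA_real_; vr <- NA_real_
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                train_l1 = mean(losses), val_mae = vm,
                                val_rmse = vr))
    if (control$verbose)
      cat(sprintf("epoch %3d lr %.2g train L1 %.3f val MAE %.3f RMSE %.3f\n",
                  epoch, lr, mean(losses), vm, vr))
    if (validate && vm < best$mae)
      best <- list(mae = vm, params = params, epoch = epoch,
                   val_pred = val_pred)
  }
  model$params <- best$params
  structure(list(model = model, control = control, history = history,
                 best_epoch = best$epoch, val_mae = best$mae,
                 val_pred = best$val_pred, val_count = val$count),
            class = "countnet_fit")
}

#' Evaluate a model on a labeled dataset
#'
#' Runs the model in deterministic (dropout-off) mode over every
#' sample and computes the counting metrics.
#'
#' @param object A `countnet` or `countnet_fit`.
#' @param data A `countnet_samples` object.
#' @param threshold If not `NULL`, also report density-stratified
#'   metrics at this true-count threshold.
#' @return A [metrics_report()] (with strata when requested).
#' @export
evaluate_counts <- function(object, data, threshold = NULL) {
  model <- if (inherits(object, "countnet_fit")) object$model else object
  stopifnot(inherits(model, "countnet"),
            inherits(data, "countnet_samples"), length(data) > 0L)
  preds <- predict(model, data)
  if (is.null(threshold)) metrics_report(preds, data$count)
  else stratified_report(preds, data$count, threshold)
}

#' @export
predict.countnet_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
print.countnet_fit <- function(x, ...) {
  cat("Fitted count-supervised counting network\n")
  cat(sprintf("  %d epochs; checkpoint from epoch %d (best val MAE %.3f)\n",
              nrow(x$history), x$best_epoch, x$val_mae))
  cat(sprintf("  final train L1 %.3f\n",
              x$history$train_l1[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.countnet_fit <- function(object, ...) {
  h <- object$history
  cat("Count-supervised counting network - training summary\n\n")
  print(object$model)
  cat(sprintf("\nEpochs: %d   batch %d   lr %.2g (x%.2g after %s)\n",
              nrow(h), object$control$batch_size, object$control$lr,
              object$control$gamma,
              paste(object$control$milestones, collapse = ", ")))
  cat(sprintf("Best epoch %d: val MAE %.3f, val RMSE %.3f\n",
              object$best_epoch, object$val_mae,
              h$val_rmse[object$best_epoch]))
  rep <- metrics_report(object$val_pred, object$val_count)
  cat("Validation metrics at checkpoint:\n")
  print(rep)
  invisible(rep)
}

#' Training-history plot
#'
#' @param x A `countnet_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.countnet_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_l1, h$val_mae), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "count error", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train L1", "val MAE"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
residuals.countnet_fit <- function(object, ...) {
  object$val_pred - object$val_count
}

#' @export
coef.countnet_fit <- function(object, ...) object$model$params
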