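tiny_samples <- function(n, seed = 1, size = 32) {
  cfg <- synth_config("ear_field", image_size = size,
                      count = list(mean = 5, sd = 2, min = 0, max = 10),
                      seed = seed)
  preprocess_samples(synth_samples(n, cfg),
                     preprocess_spec(size = size, normalize = "identity"))
}

test_that("the L1 loss is the mean absolute difference", {
  expect_equal(l1_loss(c(3, 5), c(3, 5)), 0)
  expect_equal(l1_loss(c(3, 5), c(1, 5)), 1)
  set.seed(1)
  for (rep in 1:10) {
    a <- rnorm(7); b <- rnorm(7)
    expect_equal(l1_loss(a, b), l1_loss(b, a))
    expect_equal(l1_loss(a, b), mean(abs(a - b)))
  }
  expect_error(l1_loss(numeric(0), numeric(0)), "empty")
  expect_error(l1_loss(1:3, 1:2), "lengths differ")
})

test_that("the multi-step schedule decays at its milestones", {
  ctl <- countnet_control(epochs = 4, lr = 0.5, milestones = c(2L),
                          gamma = 0.1)
  expect_equal(countnet:::schedule_lr(1, ctl), 0.5)
  expect_equal(countnet:::schedule_lr(2, ctl), 0.5)
  expect_equal(countnet:::schedule_lr(3, ctl), 0.05)
  expect_error(countnet_control(milestones = c(5L, 2L)),
               "strictly increasing")
})

test_that("a zero learning rate performs a null update", {
  m <- tiny_model(seed = 2)
  smp <- tiny_samples(4, seed = 10)
  ctl <- countnet_control(epochs = 1, batch_size = 2, lr = 0,
                          momentum = 0.9, seed = 3)
  fit <- countnet_fit(m, smp, smp, ctl, init_output_bias = FALSE)
  expect_equal(fit$model$params, m$params, tolerance = 1e-15)
  init_mae <- count_mae(predict(m, smp), smp$count)
  expect_equal(fit$val_mae, init_mae, tolerance = 1e-12)
})

test_that("training history and checkpointing follow the contract", {
  m <- tiny_model(seed = 4, dropout = 0.2)
  tr <- tiny_samples(6, seed = 11)
  va <- tiny_samples(3, seed = 12)
  ctl <- countnet_control(epochs = 3, batch_size = 2, lr = 1e-3,
                          milestones = c(2L), gamma = 0.1, seed = 5)
  fit <- countnet_fit(m, tr, va, ctl)
  h <- fit$history
  expect_identical(nrow(h), 3L)
  expect_equal(h$lr, c(1e-3, 1e-3, 1e-4))
  expect_identical(fit$best_epoch,
                   h$epoch[which.min(h$val_mae)])
  expect_equal(fit$val_mae, min(h$val_mae))
  # stored checkpoint reproduces its recorded validation MAE
  expect_equal(count_mae(predict(fit, va), va$count), fit$val_mae,
               tolerance = 1e-12)
})

test_that("training is deterministic given (config, seed, data)", {
  tr <- tiny_samples(4, seed = 13)
  ctl <- countnet_control(epochs = 2, batch_size = 2, lr = 1e-3, seed = 6)
  f1 <- countnet_fit(tiny_model(seed = 7), tr, tr, ctl)
  f2 <- countnet_fit(tiny_model(seed = 7), tr, tr, ctl)
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
})

test_that("a tiny model can descend the loss on a handful of images", {
  m <- tiny_model(seed = 8)
  tr <- tiny_samples(4, seed = 14)
  ctl <- countnet_control(epochs = 60, batch_size = 4, lr = 2e-3,
                          momentum = 0.9, seed = 9, val_every = 60)
  fit <- countnet_fit(m, tr, tr, ctl, init_output_bias = FALSE)
  h <- fit$history
  expect_lt(h$train_l1[nrow(h)], 0.5 * h$train_l1[1])
})

test_that("evaluation reports order-invariant metrics", {
  m <- tiny_model(seed = 10)
  smp <- tiny_samples(5, seed = 15)
  rep1 <- evaluate_counts(m, smp)
  expect_s3_class(rep1, "metrics_report")
  expect_identical(rep1$n, 5L)
  expect_equal(rep1$mae, count_mae(predict(m, smp), smp$count))

  perm <- c(3, 1, 5, 2, 4)
  shuf <- structure(list(x = smp$x[perm], count = smp$count[perm]),
                    class = "countnet_samples")
  rep2 <- evaluate_counts(m, shuf)
  expect_equal(rep2$mae, rep1$mae, tolerance = 1e-12)
  expect_equal(rep2$rmse, rep1$rmse, tolerance = 1e-12)
})

test_that("fit objects expose the modelling-idiom methods", {
  m <- tiny_model(seed = 11, dropout = 0)
  tr <- tiny_samples(4, seed = 16)
  fit <- countnet_fit(m, tr, tr,
                      countnet_control(epochs = 2, batch_size = 2,
                                       lr = 1e-3, seed = 12))
  expect_s3_class(fit, "countnet_fit")
  expect_length(residuals(fit), 4L)
  expect_equal(residuals(fit), fit$val_pred - fit$val_count)
  expect_type(coef(fit), "list")
  expect_true("head.fc1.W" %in% names(coef(fit)))
  out <- capture.output(print(fit))
  expect_true(any(grepl("checkpoint from epoch", out)))
  out2 <- capture.output(summary(fit))
  expect_true(any(grepl("Validation metrics", out2)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
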