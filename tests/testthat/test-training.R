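test_that("early stopping uses running-best semantics", {
  # constant validation loss: first stop exactly at patience + 1 epochs
  for (len in 1:5) expect_false(should_stop(rep(1, len), 0.005, 5))
  expect_true(should_stop(rep(1, 6), 0.005, 5))
  # a short history never stops
  expect_false(should_stop(c(1.0, 0.9), 0.005, 5))
  # improving by at least min_delta every epoch never stops
  expect_false(should_stop(seq(1, 0.5, by = -0.01), 0.005, 5))
  # once improvement is removed, stopping follows within patience epochs
  expect_true(should_stop(c(1, 0.8, 0.6, rep(0.6, 5)), 0.005, 5))
  expect_false(should_stop(c(1, 0.8, 0.6, rep(0.6, 4)), 0.005, 5))
  expect_error(should_stop(numeric(0)), "empty")
})

test_that("a one-epoch fit records exactly one epoch", {
  frames <- small_phantom(10, seed = 41)
  fit <- mtk_fit(frames[1:8], frames[9:10],
                 config = training_config(max_epochs = 1, seed = 5))
  expect_equal(nrow(fit$history), 1L)
  expect_equal(fit$best_epoch, 1L)
  expect_equal(fit$stopped_epoch, 1L)
  expect_s3_class(fit, "mtk_fit")
})

test_that("a non-learning model stops at epoch patience + 1", {
  frames <- small_phantom(14, seed = 42)
  # a vanishing learning rate leaves the validation loss constant, so
  # the stopping rule must fire as soon as patience is exhausted
  fit <- mtk_fit(frames[1:10], frames[11:14],
                 config = training_config(learning_rate = 1e-12,
                                          max_epochs = 30,
                                          es_min_delta = 0.005,
                                          es_patience = 5, seed = 6))
  expect_equal(fit$stopped_epoch, 6L)
  expect_lte(fit$best_epoch, fit$stopped_epoch)
})

test_that("training is deterministic for a fixed seed", {
  frames <- small_phantom(16, seed = 43)
  cfg <- training_config(max_epochs = 2, seed = 77)
  f1 <- mtk_fit(frames[1:12], frames[13:16], config = cfg)
  f2 <- mtk_fit(frames[1:12], frames[13:16], config = cfg)
  keep <- setdiff(names(f1$history), "seconds")
  expect_identical(f1$history[keep], f2$history[keep])
  expect_identical(f1$model$params, f2$model$params)
})

test_that("a frozen backbone is bitwise unchanged by training", {
  frames <- small_phantom(16, seed = 44)
  sp <- backbone_spec("tiny_cnn", fine_tune = FALSE)
  init <- build_model(sp, init_seed = 9)
  fit <- mtk_fit(frames[1:12], frames[13:16], spec = sp,
                 config = training_config(max_epochs = 2, seed = 9))
  for (nm in init$backbone_names) {
    expect_identical(fit$model$params[[nm]], init$params[[nm]])
  }
  expect_false(identical(fit$model$params[["cls2.W"]],
                         init$params[["cls2.W"]]))
})

test_that("evaluation is deterministic and internally consistent", {
  frames <- small_phantom(12, seed = 45)
  fit <- mtk_fit(frames[1:9], frames[10:12],
                 config = training_config(max_epochs = 1, seed = 3))
  r1 <- evaluate_model(fit, frames)
  r2 <- evaluate_model(fit, frames)
  expect_identical(r1, r2)
  expect_equal(r1$rmse^2, r1$mse, tolerance = 1e-12)
  expect_lte(r1$mae, r1$rmse + 1e-12)
  expect_error(evaluate_model(fit, list()), "empty")
})

test_that("a stub model with perfect hard predictions scores perfectly", {
  frames <- small_phantom(8, seed = 46, render = FALSE)
  targets <- lapply(frames, encode_targets)
  eps <- 1e-6
  preds <- lapply(targets, function(t) {
    list(probabilities = t$presence * (1 - 2 * eps) + eps,
         coords = t$coords)
  })
  rep <- metrics_report(targets, preds)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$micro_f1, 1)
  expect_equal(rep$mae, 0)
})

test_that("history, residuals and predict methods expose the fit", {
  frames <- small_phantom(12, seed = 47)
  fit <- mtk_fit(frames[1:9], frames[10:12],
                 config = training_config(max_epochs = 2, seed = 4))
  expect_named(fit$history,
               c("epoch", "train_total", "train_loss1", "train_loss2",
                 "valid_total", "valid_loss1", "valid_loss2", "seconds"))
  pred <- predict(fit, frames[1:3])
  expect_equal(dim(pred$probabilities), c(3L, 11L))
  res <- residuals(fit, frames[1:3])
  enc <- encode_targets(frames[[1]])
  expect_equal(is.na(res[1, ]), enc$mask == 0, ignore_attr = TRUE)
  dir <- withr::local_tempdir()
  write_history_csv(fit, file.path(dir, "h.csv"))
  expect_equal(nrow(read.csv(file.path(dir, "h.csv"))), 2L)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("training configuration validates and scales", {
  expect_error(training_config(learning_rate = -1), "learning_rate")
  expect_error(training_config(es_patience = 0), "es_patience")
  paper <- training_config(paper_scale = TRUE)
  expect_equal(paper$learning_rate, 1e-5)
  expect_equal(paper$batch_size, 64L)
  expect_equal(paper$max_epochs, 100L)
  desk <- training_config()
  expect_equal(desk$batch_size, 16L)
  expect_equal(desk$es_min_delta, 0.005)
  expect_equal(desk$es_patience, 5L)
  expect_equal(desk$optimizer, "rectified_adam")
})
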