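test_that("training reduces the loss on a small synthetic task", {
  # 3-seed majority: the training loss after 5 epochs is below epoch 1
  coh <- synth_cohort(10, 10, seed = 31)
  sp <- stratified_split(coh$labels, 0.2, seed = 1)
  wins <- 0L
  for (s in 1:3) {
    fit <- train_one_fold(coh, sp$train_ids, sp$test_ids,
                          trifuse_config("test"),
                          train_control(epochs = 5, patience = 50, lr = 1e-3),
                          seed = 1000 + s)
    h <- fit$history
    if (h$train_loss[5] < h$train_loss[1]) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("early stopping and determinism contracts hold", {
  coh <- synth_cohort(6, 6, seed = 32)
  sp <- stratified_split(coh$labels, 0.25, seed = 2)
  cfg <- trifuse_config("test")
  # patience = 0: stops right after the first non-improving epoch
  fit <- train_one_fold(coh, sp$train_ids, sp$test_ids, cfg,
                        train_control(epochs = 50, patience = 0), seed = 7)
  h <- fit$history
  expect_lt(nrow(h), 50)
  expect_equal(fit$best_val_loss, min(h$val_loss))
  expect_equal(fit$best_epoch, which.min(h$val_loss))
  # identical seeds give identical parameters and history
  f1 <- train_one_fold(coh, sp$train_ids, sp$test_ids, cfg,
                       train_control(epochs = 2, patience = 50), seed = 9)
  f2 <- train_one_fold(coh, sp$train_ids, sp$test_ids, cfg,
                       train_control(epochs = 2, patience = 50), seed = 9)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  expect_error(train_one_fold(coh, sp$train_ids, sp$train_ids[1], cfg,
                              train_control(epochs = 1), seed = 1), "overlap")
})

test_that("cross-validation produces complete, reproducible fold reports", {
  coh <- synth_cohort(8, 12, seed = 33)
  sp <- stratified_split(coh$labels, 0.25, seed = 3)
  cfg <- trifuse_config("test")
  ctl <- train_control(epochs = 2, patience = 50)
  cv <- run_cv(coh, sp, cfg, ctl, k = 2, seed = 5)
  expect_length(cv$fold_metrics, 2)
  expect_length(cv$test_metrics, 2)
  for (m in cv$fold_metrics) {
    expect_true(is.finite(m$accuracy))
    expect_true(is.finite(m$balanced_accuracy))
    expect_true(is.finite(m$auroc))
  }
  # mean +/- sd matches direct recomputation
  vals <- vapply(cv$fold_metrics, function(m) m$balanced_accuracy, numeric(1))
  expect_equal(unname(cv$mean["balanced_accuracy"]), mean(vals))
  expect_equal(unname(cv$sd["balanced_accuracy"]), sd(vals))
  cv2 <- run_cv(coh, sp, cfg, ctl, k = 2, seed = 5)
  expect_identical(cv$mean, cv2$mean)
})

test_that("the fitted-model interface predicts and reports consistently", {
  coh <- synth_cohort(10, 10, seed = 34)
  sp <- stratified_split(coh$labels, 0.25, seed = 4)
  fit <- trifuse(coh, train_ids = sp$train_ids, val_ids = NULL,
                 control = train_control(epochs = 2, patience = 50), seed = 6)
  expect_s3_class(fit, "trifuse")
  pr <- predict(fit, coh, ids = sp$test_ids)
  expect_length(pr, length(sp$test_ids))
  expect_true(all(pr > 0 & pr < 1))
  cl <- predict(fit, coh, ids = sp$test_ids, type = "class")
  expect_true(all(cl %in% 0:1))
  resp <- predict(fit, coh, ids = sp$test_ids, type = "response")
  expect_equal(resp$probability, unname(pr))
  expect_identical(names(coef(fit)),
                   c("tab", "enc_mri", "enc_pet", "hbam_mri", "hbam_pet",
                     "mmca", "head"))
  expect_output(print(fit), "fusion classifier")
  expect_silent(grDevices::pdf(NULL))
  plot(fit)
  grDevices::dev.off()
})
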