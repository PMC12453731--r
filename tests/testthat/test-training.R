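# Training protocol: class weights, plateau schedule, early stopping,
# integration on a tiny model, and fold pinning in cross-validation.

test_that("class weights are inverse-frequency with balanced normalization", {
  w <- class_weights(c(4303, 9734))
  expect_equal(w[1] / w[2], 9734 / 4303, tolerance = 1e-12)
  expect_equal(unname(w), c(14037 / (2 * 4303), 14037 / (2 * 9734)),
               tolerance = 1e-12)
  expect_identical(unname(class_weights(c(100, 100))), c(1, 1))
  expect_error(class_weights(c(0, 10)), "zero")
})

test_that("plateau schedule: decay after exactly 5 flat epochs, stop after 20", {
  cfg <- train_config()
  # strictly improving trace runs through unchanged at lr 0.01
  tr <- plateau_schedule(seq(1, 0.5, length.out = 30), cfg)
  expect_identical(nrow(tr), 30L)
  expect_true(all(tr$lr == 0.01))
  expect_false(any(tr$stopped))

  # improve for 3 epochs, then plateau forever
  losses <- c(1, 0.9, 0.8, rep(0.8, 40))
  tr <- plateau_schedule(losses, cfg)
  # epochs 4..7 keep lr 0.01; epoch 8 is the 5th non-improving epoch
  expect_equal(tr$lr[7], 0.01)
  expect_equal(tr$lr[8], 0.001)
  expect_equal(tr$lr[12], 0.001)
  expect_equal(tr$lr[13], 1e-4)
  # stop at the 20th consecutive non-improving epoch
  expect_identical(nrow(tr), 23L)
  expect_true(tr$stopped[23])
  expect_false(any(tr$stopped[-23]))
  # learning rate never increases
  expect_true(all(diff(tr$lr) <= 0))

  # an improvement resets the streak
  tr2 <- plateau_schedule(c(1, rep(1, 4), 0.5, rep(0.5, 4), 0.4), cfg)
  expect_true(all(tr2$lr == 0.01))
})

test_that("tolerance and patience validation", {
  expect_error(train_config(lr_patience = 5, stop_patience = 5))
  cfg <- train_config(tol = 0.05)
  # decreases smaller than tol do not count as improvement: the 5th
  # sub-tolerance epoch (row 6) triggers the decay
  tr <- plateau_schedule(c(1, 0.99, 0.98, 0.97, 0.96, 0.95), cfg)
  expect_equal(tr$lr[5], 0.01)
  expect_equal(tr$lr[6], 0.001)
})

test_that("training a tiny model reduces loss and records history", {
  cfg <- tiny_config()
  ds <- make_easy_dataset(4, seed = 20, n_beats = 5L)
  ds$ecg <- ds$ecg[seq(1, 2000, by = 8), ]     # 250-sample segments
  ds$pcg <- ds$pcg[seq(1, 2000, by = 8), ]
  ds$target_len <- 250L
  m <- build_model("full", cfg, seed = 21)
  fit <- train_model(m, ds, cfg = train_config(max_epochs = 6, seed = 22,
                                               batch_train = 16L,
                                               bn_recal_batches = 2L))
  h <- train_history(fit)
  expect_identical(nrow(h), 6L)
  expect_lt(h$loss[6], h$loss[1])
  expect_true(all(diff(h$lr) <= 0))
  expect_identical(attr(h, "stop_reason"), "max_epochs")
  # the input model is untouched (training works on a deep copy)
  expect_false(identical(get("head.out.W", fit$params),
                         get("head.out.W", m$params)))
})

test_that("cross-validation partitions cleanly and pins folds across variants", {
  cfg <- tiny_config()
  ds <- make_easy_dataset(4, seed = 30, n_beats = 5L)
  ds$ecg <- ds$ecg[seq(1, 2000, by = 8), ]
  ds$pcg <- ds$pcg[seq(1, 2000, by = 8), ]
  ds$target_len <- 250L
  folds <- make_folds(ds, k = 2, seed = 31)
  tc <- train_config(max_epochs = 2, seed = 32, batch_train = 16L,
                     bn_recal_batches = 2L)
  cv <- run_cross_validation(ds, folds, "full", cfg, tc, seed = 33)
  expect_s3_class(cv, "cf_cv")
  expect_identical(nrow(cv$per_fold), 2L)
  expect_identical(sum(cv$per_fold$n), nrow(ds$meta))
  g <- glance(cv)
  expect_identical(g$n_folds, 2L)
  expect_true(g$accuracy >= 0 && g$accuracy <= 1)
  expect_identical(nrow(tidy(cv)), 2L)
  # the fold vector is an input: two variants see the identical partition
  cv2 <- run_cross_validation(ds, folds, "single_ecg", cfg, tc, seed = 33)
  expect_identical(cv$per_fold$fold, cv2$per_fold$fold)
  expect_identical(cv$per_fold$n, cv2$per_fold$n)
})

test_that("monitor callback can stop training and is recorded", {
  cfg <- tiny_config()
  ds <- make_easy_dataset(3, seed = 40, n_beats = 5L)
  ds$ecg <- ds$ecg[seq(1, 2000, by = 8), ]
  ds$pcg <- ds$pcg[seq(1, 2000, by = 8), ]
  ds$target_len <- 250L
  m <- build_model("single_ecg", cfg, seed = 41)
  fit <- train_model(m, ds, cfg = train_config(max_epochs = 50, seed = 42,
                                               batch_train = 16L,
                                               bn_recal_batches = 0L),
                     monitor = function(e, mm, row) e >= 2)
  h <- train_history(fit)
  expect_identical(attr(h, "stop_reason"), "monitor")
  expect_identical(nrow(h), 2L)
})
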