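# Confusion metrics, ROC/AUC against a brute-force pairwise oracle, and the
# missing-modality evaluation protocol.

# independent oracle: Mann-Whitney probability over all (pos, neg) pairs
auc_bruteforce <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

test_that("confusion counts enumerate correctly and validate inputs", {
  expect_identical(confusion(c(1, 1, 0, 0), c(1, 0, 0, 1)),
                   c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  cm <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_identical(cm[["fp"]] + cm[["fn"]], 0L)
  expect_error(confusion(integer(), integer()), "nonempty")
  expect_error(confusion(c(0, 2), c(0, 1)), "labels")
})

test_that("metric formulas match their definitions", {
  m <- metrics_from_confusion(90, 20, 80, 10)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.80)
  expect_equal(m$fpr, 0.20)
  expect_equal(m$precision, 90 / 110)
  expect_equal(m$f1, 180 / 210)

  # degenerate: no positives -> sensitivity undefined, flagged as NA
  d <- metrics_from_confusion(0, 0, 100, 0)
  expect_identical(d$specificity, 1)
  expect_true(is.na(d$sensitivity))
  expect_true(is.na(d$precision))
  expect_error(metrics_from_confusion(0, 0, 0, 0), "zero")
})

test_that("FPR and specificity always sum to one when defined", {
  set.seed(5)
  for (i in 1:20) {
    cm <- as.list(sample(0:30, 4, replace = TRUE))
    if (cm[[2]] + cm[[3]] == 0 || sum(unlist(cm)) == 0) next
    m <- do.call(metrics_from_confusion, cm)
    expect_equal(m$fpr + m$specificity, 1, tolerance = 1e-12)
  }
})

test_that("AUC sweep equals the pairwise Mann-Whitney oracle (fuzzed)", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$auc, 0.75)
  # perfectly separated and fully tied edge cases
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "class")

  set.seed(11)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), sample(c(1, 2, 6), 1))   # force ties sometimes
    expect_equal(roc_auc(y, s)$auc, auc_bruteforce(y, s), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- sample(0:1, 60, replace = TRUE, prob = c(0.4, 0.6))
  y[1:2] <- 0:1
  s <- runif(60)
  ours <- roc_auc(y, s)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC curve starts at (0,0), ends at (1,1), and is monotone", {
  set.seed(13)
  y <- c(0, 1, sample(0:1, 30, replace = TRUE))
  r <- roc_auc(y, runif(32))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("missing-modality protocol zeroes inputs and guards variants", {
  cfg <- small_config()
  ds <- make_easy_dataset(3, seed = 50, n_beats = 4L)
  m <- build_model("full", cfg, seed = 51)

  plain <- evaluate_model(m, ds)
  none <- evaluate_missing_modality(m, ds, drop = "none")
  expect_identical(plain, none)

  # dropping pcg must equal scoring with an explicitly zeroed pcg matrix
  p_drop <- predict_proba(m, ds, drop = "pcg")
  ds0 <- ds
  ds0$pcg[] <- 0
  expect_equal(p_drop, predict_proba(m, ds0, drop = "none"),
               tolerance = 1e-12)

  single <- build_model("single_ecg", cfg, seed = 52)
  expect_error(evaluate_missing_modality(single, ds, drop = "pcg"),
               "two-input")
  # but plain evaluation of a single-modality model is fine
  expect_s3_class(evaluate_model(single, ds), "tbl_df")
})

test_that("evaluate_model metrics recompute from its own confusion counts", {
  cfg <- small_config()
  ds <- make_easy_dataset(3, seed = 60, n_beats = 4L)
  m <- build_model("full", cfg, seed = 61)
  met <- evaluate_model(m, ds)
  re <- metrics_from_confusion(met$tp, met$fp, met$tn, met$fn)
  for (col in c("accuracy", "sensitivity", "specificity", "precision", "f1"))
    expect_equal(met[[col]], re[[col]], tolerance = 1e-12)
  expect_identical(met$n, nrow(ds$meta))
})

test_that("dropping the only informative modality reduces AUC to chance", {
  # class signal confined to the ECG; record-grouped folds prevent
  # segment-level leakage of record-specific noise into the test fold
  cfg <- model_config(input_len = 500L, channels = c(16L, 32L, 48L, 64L),
                      se_ratio = 8)
  tmpl <- synth_preset("ecg_only", n_beats = 8L)
  recs <- synth_dataset(10, list(normal = tmpl, abnormal = tmpl), seed = 77)
  ds <- build_dataset(recs, target_len = 500L)
  folds <- make_folds(ds, k = 2, seed = 77, group_by_record = TRUE)
  te <- which(folds == 0)
  tr <- which(folds != 0)
  aucs <- vapply(1:3, function(s) {
    fit <- train_model(build_model("full", cfg, seed = 70 + s), ds, tr,
                       train_config(max_epochs = 12, seed = 80 + s))
    expect_gte(evaluate_model(fit, ds, te)$accuracy, 0.9)
    evaluate_missing_modality(fit, ds, te, drop = "ecg")$auc
  }, numeric(1))
  expect_true(all(aucs > 0.3 & aucs < 0.7))
})
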