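# Normalization, beat segmentation, fixed-length resampling and folds.

test_that("z-score normalization gives per-channel mean 0 / sd 1 and is idempotent", {
  r <- synth_record(synth_params(n_beats = 5L, seed = 1))
  z <- zscore_record(r)
  expect_lt(abs(mean(z$ecg)), 1e-9)
  expect_lt(abs(mean(z$pcg)), 1e-9)
  expect_lt(abs(stats::sd(z$ecg) - 1), 1e-9)
  expect_lt(abs(stats::sd(z$pcg) - 1), 1e-9)
  z2 <- zscore_record(z)
  expect_equal(z2$ecg, z$ecg, tolerance = 1e-12)

  const <- r
  const$pcg <- rep(1, length(const$pcg))
  expect_error(zscore_record(const), "zero-variance")
})

test_that("resample_to_length is linear, endpoint-preserving and idempotent", {
  w <- rnorm(2000)
  expect_identical(resample_to_length(w, 2000L), w)

  ramp <- seq(0, 1, length.out = 1000)
  up <- resample_to_length(ramp, 2000L)
  expect_equal(up, seq(0, 1, length.out = 2000), tolerance = 1e-12)

  expect_equal(resample_to_length(rep(3.5, 123), 2000L), rep(3.5, 2000))
  expect_error(resample_to_length(1, 2000L), "length")
})

test_that("segmentation is a fencepost over S1 onsets with synchronized slices", {
  r <- new_rec <- cardiofuse:::new_sync_record(
    "t1", ecg = seq_len(4000) / 4000, pcg = -seq_len(4000) / 4000,
    fs = 2000, label = 1L, s1_onsets = c(0L, 1900L, 3900L))
  segs <- segment_beats(r)
  expect_length(segs, 2)
  expect_length(segs[[1]]$ecg, 2000)
  expect_length(segs[[2]]$pcg, 2000)
  # ECG and PCG slices come from identical sample ranges: here pcg == -ecg
  for (s in segs) expect_equal(s$pcg, -s$ecg, tolerance = 1e-12)
  # raw lengths 1900 and 2000: slice [0,1900) starts at the first sample
  expect_equal(segs[[1]]$ecg[1], 1 / 4000, tolerance = 1e-12)
  expect_equal(segs[[1]]$ecg[2000], 1900 / 4000, tolerance = 1e-12)

  # K annotated beats in a synthetic record give K-1 segments
  rec10 <- synth_record(synth_params(n_beats = 10L, seed = 5))
  expect_length(segment_beats(zscore_record(rec10)), 9)
})

test_that("length gates skip out-of-range beats and log them", {
  r <- cardiofuse:::new_sync_record(
    "t2", rnorm(8100), rnorm(8100), 2000, 0L,
    s1_onsets = c(0L, 50L, 2050L, 8049L))
  segs <- segment_beats(r)
  # [0,50) too short; [50,2050) ok; [2050,8049) within the 3 s maximum
  expect_length(segs, 2)
  skipped <- attr(segs, "skipped")
  expect_identical(nrow(skipped), 1L)
  expect_identical(skipped$reason, "too_short")

  expect_error(segment_beats(cardiofuse:::new_sync_record(
    "t3", rnorm(100), rnorm(100), 2000, 0L, s1_onsets = 5L)),
    "fewer than 2")
})

test_that("build_dataset aggregates, honors exclusions and keeps counts consistent", {
  tmpl <- synth_params(n_beats = 10L)
  recs <- synth_dataset(5, list(normal = tmpl, abnormal = tmpl), seed = 3)
  ds <- build_dataset(recs)
  expect_identical(nrow(ds$meta), 90L)           # 10 records x 9 beats
  expect_identical(unname(sum(ds$class_counts)), 90L)
  expect_identical(ncol(ds$ecg), 90L)

  ds2 <- build_dataset(recs, exclusions = "s0001")
  expect_identical(nrow(ds2$meta), 81L)
  expect_false("s0001" %in% ds2$meta$record_id)

  recs[[1]]$label <- NA_integer_
  expect_error(build_dataset(recs), "labels")
})

test_that("stratified folds partition segments evenly and deterministically", {
  ds <- make_easy_dataset(6, seed = 8, n_beats = 11L)  # 120 segments
  f <- make_folds(ds, k = 5, seed = 2)
  expect_length(f, 120)
  expect_identical(sort(unique(f)), 0:4)
  expect_true(all(table(f) == 24))
  # stratification: each fold holds 12 of each class
  expect_true(all(table(f, ds$meta$label) == 12))
  expect_identical(f, make_folds(ds, k = 5, seed = 2))
  expect_false(identical(f, make_folds(ds, k = 5, seed = 3)))

  g <- make_folds(ds, k = 3, seed = 2, group_by_record = TRUE)
  per_record <- tapply(g, ds$meta$record_id, function(x) length(unique(x)))
  expect_true(all(per_record == 1))
})
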