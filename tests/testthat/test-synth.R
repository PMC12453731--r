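# Synthetic ECG/PCG generator: beat morphology, class effects, record
# assembly, annotation fidelity and determinism.

test_that("ECG beat morphology: R peak dominates and zero effect is identity", {
  p <- synth_params(seed = 3)
  w <- synth_ecg_beat(1.0, p)
  expect_length(w, 2000)
  # R deflection is the global maximum by construction
  centers <- round(cardiofuse:::ECG_FRAC * 2000)
  expect_equal(which.max(w) - 1L, unname(centers[["r"]]))

  pn <- synth_params(ecg_effect = 0, class_label = "normal", seed = 3)
  pa <- synth_params(ecg_effect = 0, class_label = "abnormal", seed = 3)
  expect_identical(synth_ecg_beat(1.0, pn), synth_ecg_beat(1.0, pa))

  pa2 <- synth_params(ecg_effect = 0.8, class_label = "abnormal", seed = 3)
  expect_false(identical(synth_ecg_beat(1.0, pn), synth_ecg_beat(1.0, pa2)))
})

test_that("beats too short to hold the five deflections are rejected", {
  p <- synth_params()
  expect_error(synth_ecg_beat(0.02, p), "50")
  expect_error(synth_pcg_beat(0.02, p), "50")
  # 50 samples is allowed
  expect_length(synth_ecg_beat(0.025, p), 50)
})

test_that("PCG beat: S1 burst energy dominates the quiet systolic interval", {
  p <- synth_params(class_label = "normal", seed = 11)
  w <- synth_pcg_beat(0.8, p)
  n <- length(w)
  s1_center <- round(cardiofuse:::ECG_FRAC[["r"]] * n) + round(50 * 2)
  bounds <- cardiofuse:::systole_bounds(n, 2000, 50)
  s1_band <- w[(s1_center - 30):(s1_center + 30) + 1L]
  sys_band <- w[(bounds[["start"]] + 10):(bounds[["end"]] - 10) + 1L]
  expect_gt(mean(s1_band^2), mean(sys_band^2))
})

test_that("murmur: zero effect is identity, energy grows monotonically", {
  base <- function(eff, lab = "abnormal") {
    synth_pcg_beat(0.8, synth_params(pcg_effect = eff, class_label = lab,
                                     seed = 21))
  }
  expect_identical(base(0), base(0.7, lab = "normal"))

  n <- length(base(0))
  bounds <- cardiofuse:::systole_bounds(n, 2000, 50)
  sys_idx <- (bounds[["start"]]:bounds[["end"]]) + 1L
  energies <- vapply(c(0, 0.25, 0.5, 1, 2),
                     function(e) sum(base(e)[sys_idx]^2), numeric(1))
  expect_true(all(diff(energies) > 0))
  # paired comparison: abnormal systole strictly louder than matched normal
  expect_gt(sum(base(1)[sys_idx]^2), sum(base(0)[sys_idx]^2))
})

test_that("records assemble synchronized channels with one S1 per beat", {
  p <- synth_params(n_beats = 10L, seed = 9)
  r <- synth_record(p)
  expect_s3_class(r, "sync_record")
  expect_length(r$s1_onsets, 10)
  expect_true(all(diff(r$s1_onsets) > 0))
  expect_identical(length(r$ecg), length(r$pcg))
  expect_true(all(r$s1_onsets >= 0 & r$s1_onsets < length(r$ecg)))

  r2 <- synth_record(p)
  expect_identical(r$ecg, r2$ecg)
  expect_identical(r$pcg, r2$pcg)
  expect_identical(r$s1_onsets, r2$s1_onsets)
})

test_that("stored S1 onsets sit on the S1 envelope peak (within 2 samples)", {
  p <- synth_params(n_beats = 8L, noise_sd = 0.02, seed = 33)
  r <- synth_record(p)
  env <- stats::filter(abs(r$pcg), rep(1 / 21, 21), sides = 2)
  for (s in r$s1_onsets) {
    win <- max(1, s - 60):min(length(r$pcg), s + 60)   # 1-based window
    peak <- win[which.max(env[win])] - 1L              # back to 0-based
    expect_lte(abs(peak - s), 2)
  }
})

test_that("synth_dataset balances classes with distinct seeds, deterministically", {
  dsl <- synth_dataset(5, seed = 4)
  expect_length(dsl, 10)
  labs <- vapply(dsl, `[[`, integer(1), "label")
  expect_identical(sum(labs == 1L), 5L)
  ids <- vapply(dsl, `[[`, character(1), "record_id")
  expect_identical(anyDuplicated(ids), 0L)
  # per-record waveforms differ (distinct derived seeds)
  expect_false(identical(dsl[[1]]$ecg, dsl[[2]]$ecg))
  dsl2 <- synth_dataset(5, seed = 4)
  expect_identical(dsl, dsl2)
})

test_that("parameter invariants are enforced", {
  expect_error(synth_params(n_beats = 1))
  expect_error(synth_params(heart_rate_bpm = 300))
  expect_error(synth_params(hr_jitter = 0.6))
  expect_error(synth_params(fs = -1))
})

test_that("complementary dataset splits abnormal effects across modalities", {
  recs <- synth_complementary_dataset(4, seed = 17, n_beats = 4L)
  expect_length(recs, 8)
  labs <- vapply(recs, `[[`, integer(1), "label")
  expect_identical(sum(labs == 1L), 4L)
  subs <- vapply(recs[labs == 1L], `[[`, character(1), "subtype")
  expect_identical(sum(subs == "ecg"), 2L)
  expect_identical(sum(subs == "pcg"), 2L)
  expect_identical(recs,
                   synth_complementary_dataset(4, seed = 17, n_beats = 4L))
})
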