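# Synchronized ECG + PCG simulator with ground-truth S1 annotations.
#
# One beat spans one RR interval.  The ECG beat is a sum of five Gaussian
# deflections (P, Q, R, S, T) placed at fixed fractions of the RR interval;
# the PCG beat holds two Gaussian-enveloped cosine bursts (S1 shortly after
# the R peak, S2 near 38% of RR).  Class-discriminative structure: abnormal
# beats get an ST-segment offset (ECG) and a band-limited systolic murmur
# (PCG).  All timing constants are fractions of RR except burst widths and
# the electromechanical R-to-S1 lag, which are physiological time constants.

ECG_FRAC <- c(p = 0.04, q = 0.10, r = 0.13, s = 0.16, t = 0.45)
ECG_AMP <- c(p = 0.15, q = -0.12, r = 1.00, s = -0.25, t = 0.35)
ECG_SIG <- c(p = 0.025, q = 0.010, r = 0.016, s = 0.010, t = 0.055) # frac of RR
ST_WINDOW <- c(0.20, 0.40)      # ST-segment, fraction of RR
S1_SIGMA_S <- 0.020             # burst envelope SDs, seconds
S2_SIGMA_S <- 0.015
S1_FREQ <- 100                  # carrier frequencies, Hz
S2_FREQ <- 130
S1_AMP <- 1.0
S2_AMP <- 0.7
S2_FRAC <- 0.38                 # S2 centre, fraction of RR

#' Simulation parameters for synchronized ECG/PCG records
#'
#' @param fs Sampling rate (Hz).
#' @param heart_rate_bpm Mean heart rate in beats/min (30-220).
#' @param hr_jitter Fractional beat-to-beat RR variation (multiplicative
#'   lognormal, so intervals stay positive); in `[0, 0.5)`.
#' @param n_beats Beats per record (>= 2).
#' @param noise_sd Additive white Gaussian noise SD per modality, in units of
#'   the R-peak / S1-burst amplitude (1.0).
#' @param class_label `"normal"` or `"abnormal"`.
#' @param ecg_effect ST-segment offset applied to abnormal beats.
#' @param pcg_effect Amplitude (RMS) of the band-limited systolic murmur
#'   added to abnormal beats.
#' @param s1_lag_ms Delay of the S1 burst centre after the R peak, ms.
#' @param seed Integer seed; identical parameters (including seed) give
#'   bit-identical records.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(fs = 2000, heart_rate_bpm = 75, hr_jitter = 0.05,
                         n_beats = 40L, noise_sd = 0.05,
                         class_label = c("normal", "abnormal"),
                         ecg_effect = 0.3, pcg_effect = 0.3,
                         s1_lag_ms = 50, seed = 1L) {
  class_label <- match.arg(class_label)
  stopifnot(fs > 0, n_beats >= 2, heart_rate_bpm >= 30, heart_rate_bpm <= 220,
            hr_jitter >= 0, hr_jitter < 0.5, noise_sd >= 0)
  structure(list(fs = fs, heart_rate_bpm = heart_rate_bpm,
                 hr_jitter = hr_jitter, n_beats = as.integer(n_beats),
                 noise_sd = noise_sd, class_label = class_label,
                 ecg_effect = ecg_effect, pcg_effect = pcg_effect,
                 s1_lag_ms = s1_lag_ms, seed = as.integer(seed)),
            class = "synth_params")
}

#' Named simulation presets
#'
#' * `"default"`: moderate effects in both modalities.
#' * `"easy"`: large effects, low noise - a regime any working pipeline
#'   should classify almost perfectly.
#' * `"complementary"`: both modalities informative but individually
#'   imperfect, for comparing fusion against single-modality models.
#' * `"ecg_only"` / `"pcg_only"`: class signal confined to one modality,
#'   for missing-modality evaluations.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [synth_params()].
#' @return A `synth_params` object.
#' @export
synth_preset <- function(name = c("default", "easy", "complementary",
                                  "ecg_only", "pcg_only"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    default = list(),
    easy = list(ecg_effect = 1.5, pcg_effect = 1.5, noise_sd = 0.02,
                n_beats = 10L),
    complementary = list(ecg_effect = 0.6, pcg_effect = 0.6, noise_sd = 0.25,
                         n_beats = 10L),
    ecg_only = list(ecg_effect = 1.0, pcg_effect = 0, noise_sd = 0.1,
                    n_beats = 10L),
    pcg_only = list(ecg_effect = 0, pcg_effect = 1.2, noise_sd = 0.1,
                    n_beats = 10L))
  do.call(synth_params, utils::modifyList(base, list(...)))
}

check_beat_len <- function(rr_s, fs) {
  n <- round(rr_s * fs)
  if (n < 50)
    stop("RR interval ", rr_s, " s gives ", n,
         " samples; too short to place the five ECG deflections (minimum 50)")
  as.integer(n)
}

# Raised-cosine plateau window over sample indices [a, b] with ramp `ramp`.
plateau_window <- function(n, a, b, ramp) {
  i <- seq_len(n) - 1
  w <- numeric(n)
  w[i >= a & i <= b] <- 1
  up <- i >= (a - ramp) & i < a
  w[up] <- 0.5 * (1 + cos(pi * (a - i[up]) / ramp))
  dn <- i > b & i <= (b + ramp)
  w[dn] <- 0.5 * (1 + cos(pi * (i[dn] - b) / ramp))
  w
}

#' Generate one synthetic ECG beat
#'
#' Sum of five Gaussian deflections (P, Q, R, S, T) over one RR interval,
#' with the R deflection the global maximum. Abnormal beats have their ST
#' segment (between the S and T waves) offset by `params$ecg_effect`.
#'
#' @param rr_s RR interval in seconds; `rr_s * fs` must be >= 50 samples.
#' @param params A [synth_params()].
#' @return Numeric waveform of `round(rr_s * fs)` samples.
#' @export
synth_ecg_beat <- function(rr_s, params) {
  n <- check_beat_len(rr_s, params$fs)
  i <- seq_len(n) - 1
  centers <- round(ECG_FRAC * n)
  sigmas <- pmax(ECG_SIG * n, 1)
  y <- numeric(n)
  for (k in seq_along(centers))
    y <- y + ECG_AMP[k] * exp(-0.5 * ((i - centers[k]) / sigmas[k])^2)
  if (params$class_label == "abnormal" && params$ecg_effect != 0) {
    win <- plateau_window(n, round(ST_WINDOW[1] * n), round(ST_WINDOW[2] * n),
                          ramp = max(round(0.02 * n), 2))
    y <- y + params$ecg_effect * win
  }
  unname(y)
}

burst <- function(i, center, sigma_samp, freq, fs, amp) {
  env <- exp(-0.5 * ((i - center) / sigma_samp)^2)
  amp * env * cos(2 * pi * freq * (i - center) / fs)
}

# Systolic interval (between the S1 and S2 bursts) in 0-based samples.
systole_bounds <- function(n, fs, s1_lag_ms) {
  s1 <- round(ECG_FRAC[["r"]] * n) + round(s1_lag_ms * fs / 1000)
  s2 <- round(S2_FRAC * n)
  c(start = s1 + round(3 * S1_SIGMA_S * fs), end = s2 - round(3 * S2_SIGMA_S * fs))
}

#' Generate one synthetic PCG beat
#'
#' Two Gaussian-enveloped cosine bursts: S1 centred `s1_lag_ms` after the R
#' peak and S2 near 38% of the RR interval. Abnormal beats additionally get
#' a band-limited noise murmur of RMS amplitude `params$pcg_effect` filling
#' the systolic (S1-to-S2) interval. The murmur noise is drawn from an RNG
#' stream derived from `params$seed`, so beats with the same seed pair
#' exactly across `pcg_effect` values.
#'
#' @inheritParams synth_ecg_beat
#' @return Numeric waveform of `round(rr_s * fs)` samples.
#' @export
synth_pcg_beat <- function(rr_s, params) {
  fs <- params$fs
  n <- check_beat_len(rr_s, fs)
  i <- seq_len(n) - 1
  s1_center <- round(ECG_FRAC[["r"]] * n) + round(params$s1_lag_ms * fs / 1000)
  s2_center <- round(S2_FRAC * n)
  y <- burst(i, s1_center, S1_SIGMA_S * fs, S1_FREQ, fs, S1_AMP) +
    burst(i, s2_center, S2_SIGMA_S * fs, S2_FREQ, fs, S2_AMP)
  murmur <- with_seed(derive_seed(params$seed, n, 2L), {
    raw <- rnorm(n)
    # 150-400 Hz band via a 4th-order Butterworth (zero-phase)
    ny <- fs / 2
    bf <- signal::butter(4, c(150, min(400, 0.9 * ny)) / ny, type = "pass")
    as.numeric(signal::filtfilt(bf, raw))
  })
  bounds <- systole_bounds(n, fs, params$s1_lag_ms)
  if (bounds["end"] > bounds["start"]) {
    win <- plateau_window(n, bounds["start"], bounds["end"],
                          ramp = max(round(0.01 * n), 2))
    m <- murmur * win
    rms <- sqrt(mean(m[win > 0.5]^2))
    if (is.finite(rms) && rms > 0) {
      scale <- if (params$class_label == "abnormal") params$pcg_effect else 0
      y <- y + scale * m / rms
    }
  }
  unname(y)
}

new_sync_record <- function(record_id, ecg, pcg, fs, label = NA_integer_,
                            s1_onsets = integer(), source = "synthetic") {
  stopifnot(length(ecg) == length(pcg), fs > 0,
            all(diff(s1_onsets) > 0),
            all(s1_onsets >= 0 & s1_onsets < length(ecg)))
  structure(list(record_id = record_id, ecg = as.numeric(ecg),
                 pcg = as.numeric(pcg), fs = fs,
                 label = as.integer(label),
                 s1_onsets = as.integer(s1_onsets), source = source),
            class = "sync_record")
}

#' @export
print.sync_record <- function(x, ...) {
  cat("<sync_record>", x$record_id, "|", length(x$ecg), "samples @", x$fs,
      "Hz |", length(x$s1_onsets), "S1 onsets | label:",
      if (is.na(x$label)) "unknown" else c("normal", "abnormal")[x$label + 1],
      "\n")
  invisible(x)
}

#' Generate one synchronized ECG+PCG record
#'
#' Concatenates `n_beats` beats with lognormally jittered RR intervals into
#' equal-length ECG and PCG channels, adds white observation noise, and
#' records the ground-truth S1 onset sample indices (R-peak sample plus the
#' `s1_lag_ms` electromechanical delay; 0-based).
#'
#' @param params A [synth_params()].
#' @param record_id Record identifier string.
#' @return A `sync_record`.
#' @export
synth_record <- function(params, record_id = sprintf("s%05d", params$seed)) {
  fs <- params$fs
  with_seed(params$seed, {
    rr_mean <- 60 / params$heart_rate_bpm
    z <- rnorm(params$n_beats)
    rr <- rr_mean * exp(params$hr_jitter * z - params$hr_jitter^2 / 2)
    ns <- vapply(rr, function(r) check_beat_len(r, fs), integer(1))
    ecg <- vector("list", params$n_beats)
    pcg <- vector("list", params$n_beats)
    s1 <- integer(params$n_beats)
    offset <- 0L
    for (b in seq_len(params$n_beats)) {
      bp <- params
      bp$seed <- derive_seed(params$seed, b)
      ecg[[b]] <- synth_ecg_beat(rr[b], bp)
      pcg[[b]] <- synth_pcg_beat(rr[b], bp)
      s1[b] <- offset + round(ECG_FRAC[["r"]] * ns[b]) +
        round(params$s1_lag_ms * fs / 1000)
      offset <- offset + ns[b]
    }
    ecg <- unlist(ecg)
    pcg <- unlist(pcg)
    if (params$noise_sd > 0) {
      ecg <- ecg + rnorm(length(ecg), 0, params$noise_sd)
      pcg <- pcg + rnorm(length(pcg), 0, params$noise_sd)
    }
    new_sync_record(record_id, ecg, pcg, fs,
                    label = if (params$class_label == "abnormal") 1L else 0L,
                    s1_onsets = s1, source = "synthetic")
  })
}

#' Generate a balanced labelled dataset of synthetic records
#'
#' @param n_per_class Records per class (>= 1).
#' @param params_by_class Named list with elements `normal` and `abnormal`,
#'   each a [synth_params()] serving as the class template (its seed and
#'   class label are overridden per record).
#' @param seed Root seed; every record receives a distinct derived seed.
#' @return List of `2 * n_per_class` `sync_record` objects (normal first).
#' @export
synth_dataset <- function(n_per_class,
                          params_by_class = list(
                            normal = synth_preset("default"),
                            abnormal = synth_preset("default")),
                          seed = 1L) {
  stopifnot(n_per_class >= 1)
  recs <- vector("list", 2L * n_per_class)
  i <- 0L
  for (cls in c("normal", "abnormal")) {
    tmpl <- params_by_class[[cls]]
    stopifnot(inherits(tmpl, "synth_params"))
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      p <- tmpl
      p$class_label <- cls
      p$seed <- derive_seed(seed, match(cls, c("normal", "abnormal")), j)
      recs[[i]] <- synth_record(p, record_id = sprintf("s%04d", i))
    }
  }
  recs
}

#' Generate a complementary-modality dataset
#'
#' Operationalizes "complementary information": abnormal records split into
#' two equal subtypes, one expressing the class effect only in the ECG
#' (ST-segment offset) and one only in the PCG (systolic murmur). Neither
#' modality alone can identify both subtypes, so a single-modality model is
#' capped near 75% accuracy on balanced data while a fused model can use
#' both. Normal records carry no effect.
#'
#' @param n_per_class Records per class (abnormal is split evenly between
#'   the two subtypes).
#' @param seed Root seed.
#' @param n_beats Beats per record.
#' @param noise_sd Additive noise SD for all records.
#' @param ecg_effect,pcg_effect Effect sizes of the two abnormal subtypes.
#' @return List of `2 * n_per_class` `sync_record`s (normal first); each
#'   abnormal record carries a `subtype` field (`"ecg"` or `"pcg"`).
#' @export
synth_complementary_dataset <- function(n_per_class, seed = 1L,
                                        n_beats = 10L, noise_sd = 0.1,
                                        ecg_effect = 1.0, pcg_effect = 1.2) {
  stopifnot(n_per_class >= 2)
  recs <- vector("list", 2L * n_per_class)
  i <- 0L
  for (j in seq_len(n_per_class)) {
    i <- i + 1L
    p <- synth_params(n_beats = n_beats, noise_sd = noise_sd,
                      class_label = "normal",
                      seed = derive_seed(seed, 1L, j))
    recs[[i]] <- synth_record(p, record_id = sprintf("s%04d", i))
  }
  for (j in seq_len(n_per_class)) {
    i <- i + 1L
    sub <- if (j %% 2L == 1L) "ecg" else "pcg"
    p <- synth_params(n_beats = n_beats, noise_sd = noise_sd,
                      class_label = "abnormal",
                      ecg_effect = if (sub == "ecg") ecg_effect else 0,
                      pcg_effect = if (sub == "pcg") pcg_effect else 0,
                      seed = derive_seed(seed, 2L, j))
    r <- synth_record(p, record_id = sprintf("s%04d", i))
    r$subtype <- sub
    recs[[i]] <- r
  }
  recs
}
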