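# Record normalization, S1-to-S1 beat segmentation, fixed-length resampling
# and cross-validation fold assembly.

#' Z-score normalize a record
#'
#' Each channel independently gets mean 0 and standard deviation 1 over the
#' whole record (normalization precedes segmentation, so per-beat amplitude
#' differences within a record survive).
#'
#' @param record A `sync_record`.
#' @return The normalized `sync_record`.
#' @export
zscore_record <- function(record) {
  norm1 <- function(x, ch) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("degenerate signal: zero-variance ", ch, " channel in record '",
           record$record_id, "'")
    (x - mean(x)) / s
  }
  record$ecg <- norm1(record$ecg, "ECG")
  record$pcg <- norm1(record$pcg, "PCG")
  record
}

#' Resample a waveform to a fixed length
#'
#' Linear interpolation onto `target_len` uniformly spaced points spanning
#' the original support; endpoints are preserved exactly.
#'
#' @param waveform Numeric vector, length >= 2.
#' @param target_len Output length.
#' @return Numeric vector of length `target_len`.
#' @export
resample_to_length <- function(waveform, target_len = 2000L) {
  n <- length(waveform)
  if (n < 2) stop("cannot resample a waveform of length ", n, " (need >= 2)")
  if (n == target_len) return(waveform)
  stats::approx(seq(0, 1, length.out = n), waveform,
                xout = seq(0, 1, length.out = target_len))$y
}

#' Segment a record into synchronized single-cardiac-cycle pairs
#'
#' For each pair of consecutive S1 onsets `(s_i, s_{i+1})` the half-open
#' slice `[s_i, s_{i+1})` (0-based samples) is cut from BOTH channels - the
#' ECG and PCG slices always cover identical sample ranges - and each slice
#' is resampled to exactly `target_len` samples (1 s at 2000 Hz). Slices
#' shorter than `min_len` or longer than `max_len` raw samples are skipped
#' and logged in the `"skipped"` attribute, guarding against annotation
#' glitches.
#'
#' @param record A normalized `sync_record` with >= 2 S1 onsets.
#' @param target_len Fixed segment length after resampling.
#' @param min_len,max_len Raw slice length gates in samples (defaults 0.1 s
#'   and 3 s at 2000 Hz).
#' @return List of beat segments (each: `ecg`, `pcg`, `label`, `record_id`,
#'   `beat_index`), with a `"skipped"` attribute tibble.
#' @export
segment_beats <- function(record, target_len = 2000L, min_len = 200L,
                          max_len = 6000L) {
  on <- record$s1_onsets
  if (length(on) < 2)
    stop("empty annotation: record '", record$record_id,
         "' has fewer than 2 S1 onsets; cannot segment")
  segs <- list()
  skipped <- list()
  for (i in seq_len(length(on) - 1L)) {
    len <- on[i + 1L] - on[i]
    if (len < min_len || len > max_len) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(record_id = record$record_id, beat_index = i,
                       raw_len = len,
                       reason = if (len < min_len) "too_short" else "too_long")
      next
    }
    idx <- (on[i] + 1L):on[i + 1L]   # [s_i, s_{i+1}) in 0-based samples
    segs[[length(segs) + 1L]] <- list(
      ecg = resample_to_length(record$ecg[idx], target_len),
      pcg = resample_to_length(record$pcg[idx], target_len),
      label = record$label, record_id = record$record_id, beat_index = i)
  }
  attr(segs, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped)
    else tibble::tibble(record_id = character(), beat_index = integer(),
                        raw_len = integer(), reason = character())
  segs
}

#' Build a segment dataset from labelled records
#'
#' Drops excluded records, z-score normalizes each remaining record,
#' segments it beat-to-beat, and aggregates everything into a
#' `segment_dataset`: two `target_len x n_segments` waveform matrices plus a
#' metadata tibble and per-class counts.
#'
#' @param records List of labelled, annotated `sync_record`s.
#' @param exclusions Character vector of record ids to drop (e.g. records
#'   rejected for noise).
#' @inheritParams segment_beats
#' @return A `segment_dataset` with elements `ecg`, `pcg`, `meta`
#'   (record_id, beat_index, label, fold), `class_counts`, `target_len` and
#'   attribute `"skipped"`.
#' @export
build_dataset <- function(records, exclusions = character(),
                          target_len = 2000L, min_len = 200L,
                          max_len = 6000L) {
  keep <- records[!vapply(records, function(r) r$record_id %in% exclusions,
                          logical(1))]
  if (!length(keep)) stop("no records left after exclusions")
  if (any(vapply(keep, function(r) is.na(r$label), logical(1))))
    stop("labels must be available for all records")
  all_segs <- list()
  skipped <- list()
  for (r in keep) {
    segs <- segment_beats(zscore_record(r), target_len, min_len, max_len)
    skipped[[length(skipped) + 1L]] <- attr(segs, "skipped")
    all_segs <- c(all_segs, segs)
  }
  n <- length(all_segs)
  if (!n) stop("no segments produced from ", length(keep), " records")
  ecg <- vapply(all_segs, `[[`, numeric(target_len), "ecg")
  pcg <- vapply(all_segs, `[[`, numeric(target_len), "pcg")
  meta <- tibble::tibble(
    record_id = vapply(all_segs, `[[`, character(1), "record_id"),
    beat_index = vapply(all_segs, `[[`, integer(1), "beat_index"),
    label = vapply(all_segs, `[[`, integer(1), "label"),
    fold = NA_integer_)
  counts <- c(normal = sum(meta$label == 0L), abnormal = sum(meta$label == 1L))
  out <- structure(list(ecg = ecg, pcg = pcg, meta = meta,
                        class_counts = counts,
                        target_len = as.integer(target_len)),
                   class = "segment_dataset")
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat("<segment_dataset>", nrow(x$meta), "segments x", x$target_len,
      "samples |", x$class_counts[["normal"]], "normal /",
      x$class_counts[["abnormal"]], "abnormal |",
      dplyr::n_distinct(x$meta$record_id), "records\n")
  invisible(x)
}

#' Segment metadata as a tibble
#' @param dataset A `segment_dataset`.
#' @return The metadata tibble (one row per segment).
#' @export
segment_meta <- function(dataset) dataset$meta

#' Assign cross-validation folds
#'
#' Segment-level random partition into `k` folds, by default stratified by
#' class so fold class balance matches the dataset. An optional record-level
#' grouping mode keeps all segments of a record in one fold for stricter
#' evaluation.
#'
#' @param dataset A `segment_dataset`.
#' @param k Number of folds.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @param stratify Stratify by class label (requires >= k segments per
#'   class).
#' @param group_by_record Assign whole records to folds instead of
#'   individual segments.
#' @return Integer vector of fold ids in `0:(k-1)`, one per segment.
#' @export
make_folds <- function(dataset, k = 5L, seed = 1L, stratify = TRUE,
                       group_by_record = FALSE) {
  meta <- dataset$meta
  n <- nrow(meta)
  fold <- integer(n)
  with_seed(seed, {
    if (group_by_record) {
      recs <- unique(meta$record_id)
      if (length(recs) < k) stop("fewer records (", length(recs),
                                 ") than folds (", k, ")")
      rf <- setNames(rep_len(0:(k - 1L), length(recs)),
                     recs[sample(length(recs))])
      fold <- unname(rf[meta$record_id])
    } else if (stratify) {
      for (lab in unique(meta$label)) {
        idx <- which(meta$label == lab)
        if (length(idx) < k)
          stop("too few segments of class ", lab, " (", length(idx),
               ") for ", k, " stratified folds")
        fold[idx[sample(length(idx))]] <- rep_len(0:(k - 1L), length(idx))
      }
    } else {
      if (n < k) stop("too few segments (", n, ") for ", k, " folds")
      fold[sample(n)] <- rep_len(0:(k - 1L), n)
    }
  })
  as.integer(fold)
}
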