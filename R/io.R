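# Readers for the reference label CSV and S1 annotation files, the segment
# archive container, and the on-disk dataset layout shared by real and
# synthetic data.

#' Read a reference label file
#'
#' Parses the PhysioNet-2016 `REFERENCE.csv` dialect: two columns, record
#' name and label, where `-1` marks a normal and `1` an abnormal record.
#'
#' @param csv_path Path to the CSV (no header).
#' @return A tibble with columns `record_id` and `label` (0 = normal,
#'   1 = abnormal).
#' @export
read_reference <- function(csv_path) {
  df <- utils::read.csv(csv_path, header = FALSE, strip.white = TRUE,
                        colClasses = "character")
  if (ncol(df) < 2) stop("reference format error: expected two columns")
  lab <- suppressWarnings(as.integer(df[[2]]))
  bad <- which(!(lab %in% c(-1L, 1L)) | is.na(lab))
  if (length(bad))
    stop("reference format error: unknown label '", df[[2]][bad[1]],
         "' at line ", bad[1])
  tibble::tibble(record_id = df[[1]],
                 label = ifelse(lab == 1L, 1L, 0L))
}

#' Read S1 onset annotations
#'
#' Accepts CSV or TSV files with one row per annotated heart-sound state.
#' The position column may be sample-indexed (header containing `sample`) or
#' second-indexed (header containing `time` or `second`); the state column
#' (header containing `state`, `label`, `type` or `annotation`) selects rows
#' whose value is `S1` (case-insensitive). Positions are returned as sorted,
#' deduplicated 0-based sample indices.
#'
#' @param path Annotation file path.
#' @param fs Sampling rate used to convert second-indexed positions.
#' @return Integer vector of S1 onset samples.
#' @export
read_s1_annotations <- function(path, fs = 2000) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, strip.white = TRUE)
  nms <- tolower(names(df))
  pos_col <- which(grepl("sample", nms))[1]
  in_seconds <- FALSE
  if (is.na(pos_col)) {
    pos_col <- which(grepl("time|second", nms))[1]
    in_seconds <- TRUE
  }
  state_col <- which(grepl("state|label|type|annotation", nms))[1]
  if (is.na(pos_col) || is.na(state_col))
    stop("annotation format error: need a sample/time column and a state column in ",
         path)
  keep <- toupper(trimws(as.character(df[[state_col]]))) == "S1"
  pos <- as.numeric(df[[pos_col]][keep])
  if (!length(pos))
    stop("empty annotation: no S1 rows in ", path,
         " (record unusable for beat segmentation)")
  samp <- if (in_seconds) round(pos * fs) else round(pos)
  sort(unique(as.integer(samp)))
}

CF_ARCHIVE_SCHEMA <- 1L

#' Write / read a segment archive
#'
#' A segment archive is the cached, preprocessed form of a dataset: the
#' fixed-length ECG and PCG segment matrices plus per-segment metadata
#' (record, beat index, label, fold), stored with a schema version.
#' Round-trips are lossless; reading an archive written by a newer schema
#' version raises an error.
#'
#' @param dataset A `segment_dataset` (see [build_dataset()]).
#' @param path Archive file path.
#' @return `read_segment_archive()` returns the `segment_dataset`.
#' @export
write_segment_archive <- function(dataset, path) {
  stopifnot(inherits(dataset, "segment_dataset"))
  obj <- list(schema = CF_ARCHIVE_SCHEMA, ecg = dataset$ecg,
              pcg = dataset$pcg, meta = dataset$meta,
              class_counts = dataset$class_counts,
              target_len = dataset$target_len)
  saveRDS(obj, path, compress = "gzip")
  invisible(path)
}

#' @rdname write_segment_archive
#' @export
read_segment_archive <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema) || obj$schema > CF_ARCHIVE_SCHEMA)
    stop("segment archive schema version ", obj$schema %||% "<missing>",
         " is newer than supported version ", CF_ARCHIVE_SCHEMA)
  structure(list(ecg = obj$ecg, pcg = obj$pcg, meta = obj$meta,
                 class_counts = obj$class_counts,
                 target_len = obj$target_len),
            class = "segment_dataset")
}

#' Write a dataset of records to disk in the shared layout
#'
#' Writes each record as a WFDB pair, a per-record S1 annotation CSV
#' (`<id>.s1.csv`, columns `sample,label`), and a `REFERENCE.csv`
#' (`record,-1|1`), mirroring the real data layout so the same readers serve
#' both.
#'
#' @param records List of `sync_record`s with labels and S1 onsets.
#' @param dir Output directory.
#' @return A manifest tibble (record_id, label, n_samples, n_s1, files).
#' @export
write_record_set <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(records, function(r) {
    write_wfdb_record(r, dir)
    utils::write.csv(data.frame(sample = r$s1_onsets, label = "S1"),
                     file.path(dir, paste0(r$record_id, ".s1.csv")),
                     row.names = FALSE, quote = FALSE)
    tibble::tibble(record_id = r$record_id, label = r$label,
                   n_samples = length(r$ecg), n_s1 = length(r$s1_onsets))
  })
  manifest <- dplyr::bind_rows(rows)
  ref <- data.frame(record = manifest$record_id,
                    label = ifelse(manifest$label == 1L, 1L, -1L))
  utils::write.table(ref, file.path(dir, "REFERENCE.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  manifest
}

#' Read a dataset of records from the shared on-disk layout
#'
#' @param dir Directory holding WFDB records, `<id>.s1.csv` annotation files
#'   and `REFERENCE.csv`.
#' @param reference Optional path to the label CSV (default
#'   `dir/REFERENCE.csv`).
#' @return List of labelled, annotated `sync_record`s.
#' @export
read_record_set <- function(dir, reference = file.path(dir, "REFERENCE.csv")) {
  ref <- read_reference(reference)
  lapply(seq_len(nrow(ref)), function(i) {
    id <- ref$record_id[i]
    rec <- read_wfdb_record(file.path(dir, id))
    rec$label <- ref$label[i]
    ann <- file.path(dir, paste0(id, ".s1.csv"))
    if (file.exists(ann)) rec$s1_onsets <- read_s1_annotations(ann, rec$fs)
    rec
  })
}
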