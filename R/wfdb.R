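# Minimal WFDB (PhysioNet waveform database) support: single-segment records,
# signal format 16 (interleaved little-endian int16), which covers the
# training-a layout (one PCG channel, one ECG channel at 2000 Hz) and the
# synthetic writer.  Physical value = (adc - baseline) / gain.

parse_gain_spec <- function(spec) {
  # "200", "200(0)", "200/mV", "200(0)/mV"
  units <- sub("^[^/]*/?", "", spec)
  core <- sub("/.*$", "", spec)
  baseline <- 0
  if (grepl("\\(", core)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", core))
    core <- sub("\\(.*$", "", core)
  }
  gain <- as.numeric(core)
  if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default ADC gain
  list(gain = gain, baseline = baseline, units = units)
}

read_wfdb_header <- function(hea_path) {
  if (!file.exists(hea_path)) stop("WFDB header not found: ", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("WFDB format error: empty header ", hea_path)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 3) stop("WFDB format error: bad record line in ", hea_path)
  nsig <- as.integer(top[2])
  fs <- as.numeric(sub("/.*$", "", top[3]))
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (length(lines) < 1 + nsig)
    stop("WFDB format error: header lists ", nsig, " signals but has ",
         length(lines) - 1, " signal lines")
  sig <- lapply(lines[1 + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 2) stop("WFDB format error: bad signal line: ", ln)
    fmt <- as.integer(sub("x.*$", "", f[2]))
    g <- parse_gain_spec(if (length(f) >= 3) f[3] else "200")
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], fmt = fmt, gain = g$gain, baseline = g$baseline,
         units = g$units, desc = desc)
  })
  list(record = top[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

#' Read a WFDB record as a synchronized ECG/PCG pair
#'
#' Reads a single-segment, format-16 WFDB record and selects the PCG and ECG
#' channels by case-insensitive substring match on the header signal
#' descriptions, falling back to explicit indices in `channel_map`. Signals
#' whose header sampling rate differs from `target_fs` are resampled with a
#' polyphase (anti-aliased) rational resampler. Label and S1 onsets are left
#' unset.
#'
#' @param path Record path with or without the `.hea` extension.
#' @param channel_map Optional `c(pcg = i, ecg = j)` 1-based channel indices
#'   used when name matching fails.
#' @param target_fs Output sampling rate (Hz).
#' @return A `sync_record` with `label = NA` and no S1 onsets.
#' @export
read_wfdb_record <- function(path, channel_map = NULL, target_fs = 2000) {
  base <- sub("\\.hea$", "", path)
  hdr <- read_wfdb_header(paste0(base, ".hea"))
  fmts <- vapply(hdr$signals, `[[`, numeric(1), "fmt")
  if (any(fmts != 16))
    stop("WFDB format error: only format 16 is supported (got ",
         paste(unique(fmts), collapse = ","), ")")
  descs <- vapply(hdr$signals, `[[`, character(1), "desc")
  find_ch <- function(tag) {
    hit <- grep(tag, descs, ignore.case = TRUE)
    if (length(hit)) return(hit[1])
    j <- match(tolower(tag), tolower(names(channel_map)))
    if (!is.na(j)) as.integer(channel_map[[j]]) else NA_integer_
  }
  i_pcg <- find_ch("PCG")
  i_ecg <- find_ch("ECG")
  if (is.na(i_ecg))
    stop("modality missing: record '", hdr$record, "' has no ECG channel")
  if (is.na(i_pcg))
    stop("modality missing: record '", hdr$record, "' has no PCG channel")

  dat_path <- file.path(dirname(base), hdr$signals[[1]]$file)
  raw <- readBin(dat_path, "integer", n = file.size(dat_path) / 2, size = 2,
                 endian = "little")
  nsig <- hdr$nsig
  n <- length(raw) %/% nsig
  mat <- matrix(raw[seq_len(n * nsig)], nrow = nsig)
  chan <- function(i) {
    s <- hdr$signals[[i]]
    (mat[i, ] - s$baseline) / s$gain
  }
  ecg <- chan(i_ecg)
  pcg <- chan(i_pcg)
  if (hdr$fs != target_fs) {
    ecg <- resample_rate(ecg, target_fs, hdr$fs)
    pcg <- resample_rate(pcg, target_fs, hdr$fs)
  }
  new_sync_record(hdr$record, ecg, pcg, target_fs, label = NA_integer_,
                  s1_onsets = integer(), source = "real")
}

# Polyphase rational resampling from `from_fs` to `to_fs`, trimmed/padded to
# the exact expected output length.
resample_rate <- function(x, to_fs, from_fs) {
  r <- to_fs / from_fs
  p <- as.integer(round(to_fs))
  q <- as.integer(round(from_fs))
  g <- gcd_int(p, q)
  y <- as.numeric(signal::resample(x, p %/% g, q %/% g))
  n_out <- round(length(x) * r)
  if (length(y) >= n_out) y[seq_len(n_out)] else c(y, rep(0, n_out - length(y)))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Write a synchronized record in WFDB format
#'
#' Writes `<id>.hea` and `<id>.dat` (format 16, channels PCG then ECG,
#' gain 1000) into `dir`.
#'
#' @param record A `sync_record`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the header path.
#' @export
write_wfdb_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- record$record_id
  gain <- 1000
  enc <- function(x) {
    v <- as.integer(round(x * gain))
    pmin(pmax(v, -32768L), 32767L)
  }
  pcg <- enc(record$pcg)
  ecg <- enc(record$ecg)
  inter <- as.vector(rbind(pcg, ecg))
  writeBin(inter, file.path(dir, paste0(id, ".dat")), size = 2,
           endian = "little")
  hea <- c(
    paste(id, 2, record$fs, length(record$ecg)),
    paste0(id, ".dat 16 ", gain, "(0)/mV 16 0 0 0 0 PCG"),
    paste0(id, ".dat 16 ", gain, "(0)/mV 16 0 0 0 0 ECG"))
  writeLines(hea, file.path(dir, paste0(id, ".hea")))
  invisible(file.path(dir, paste0(id, ".hea")))
}
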