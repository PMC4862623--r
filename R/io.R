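#' Write a recording as EDF
#'
#' Minimal continuous-EDF writer: one data record per second, 16-bit samples,
#' physical range set from the data. The recording must have a whole-second
#' duration and an integer sampling rate.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$rate_hz
  if (abs(fs - round(fs)) > 1e-9) abort("EDF writer needs an integer rate.")
  fs <- as.integer(round(fs))
  n <- nrow(rec$samples)
  if (n %% fs != 0L) abort("EDF writer needs a whole-second recording.")
  nrec <- n %/% fs
  ns <- ncol(rec$samples)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(rec$subject_id, 80), pad(rec$session_id, 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256L * (1L + ns), 8), pad("", 44), pad(nrec, 8), pad(1L, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  pmin_num <- floor(apply(rec$samples, 2, min))
  pmax_num <- ceiling(apply(rec$samples, 2, max))
  pmax_num <- ifelse(pmax_num > pmin_num, pmax_num, pmin_num + 1)
  field <- function(vals, w) paste(vapply(vals, pad, character(1), w = w),
                                   collapse = "")
  writeChar(paste0(
    field(rec$channel_labels, 16), field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    field(format(pmin_num), 8), field(format(pmax_num), 8),
    field(rep("-32768", ns), 8), field(rep("32767", ns), 8),
    field(rep("", ns), 80), field(rep(fs, ns), 8), field(rep("", ns), 32)
  ), con, eos = NULL)
  dig <- matrix(0L, n, ns)
  for (j in seq_len(ns)) {
    dig[, j] <- as.integer(round(-32768 + (rec$samples[, j] - pmin_num[j]) *
                                   65535 / (pmax_num[j] - pmin_num[j])))
  }
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (j in seq_len(ns)) {
      writeBin(dig[idx, j], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Minimal reader for continuous EDF written by this package or similar
#' single-rate files (no annotations, equal samples-per-record across
#' signals of interest).
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                       # version
  subject <- rd(80)
  session <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  rd(80 * ns); rd(8 * ns)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(32 * ns)
  out <- matrix(0, nrow = nrec * spr[1], ncol = ns)
  for (r in seq_len(nrec)) {
    for (j in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[j], size = 2L, endian = "little",
                   signed = TRUE)
      out[((r - 1L) * spr[j] + 1L):(r * spr[j]), j] <-
        pmin_[j] + (d - dmin_[j]) * (pmax_[j] - pmin_[j]) / (dmax_[j] - dmin_[j])
    }
  }
  eeg_recording(out, spr[1] / dur, channel_labels = labels,
                subject_id = subject, session_id = session)
}

#' Write a recording in BrainVision format
#'
#' Minimal writer: multiplexed IEEE float32 binary `.eeg` plus a text
#' `.vhdr`. `path` is the header path; the data file sits next to it.
#'
#' @param rec An [eeg_recording()].
#' @param path Path of the `.vhdr` header file.
#' @return `path`, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  stem <- sub("\\.vhdr$", "", path)
  datafile <- paste0(basename(stem), ".eeg")
  ns <- ncol(rec$samples)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", datafile),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", ns),
    paste0("SamplingInterval=", format(1e6 / rec$rate_hz, digits = 12)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    vapply(seq_len(ns), function(j)
      sprintf("Ch%d=%s,,1,uV", j, rec$channel_labels[j]), character(1)))
  writeLines(hdr, path)
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$samples)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a BrainVision recording
#'
#' Minimal reader for multiplexed binary files (IEEE_FLOAT_32 or INT_16) as
#' referenced by a `.vhdr` header.
#'
#' @param path Path of the `.vhdr` header file.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get <- function(key, default = NULL) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(hit) == 0L) return(default)
    sub(paste0("^", key, "="), "", hit[1])
  }
  ns <- as.integer(get("NumberOfChannels"))
  si_us <- as.numeric(get("SamplingInterval"))
  fmt <- get("BinaryFormat", "IEEE_FLOAT_32")
  datafile <- file.path(dirname(path), get("DataFile"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[[`, character(1), 1L)
  res <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","), function(p) {
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1
  }, numeric(1))
  sz <- file.info(datafile)$size
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(datafile, "numeric", n = sz / 4, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    raw <- readBin(datafile, "integer", n = sz / 2, size = 2L,
                   endian = "little", signed = TRUE)
  } else {
    abort(sprintf("unsupported BinaryFormat '%s'.", fmt))
  }
  m <- matrix(raw, ncol = ns, byrow = TRUE)
  m <- sweep(m, 2, res, `*`)
  eeg_recording(m, 1e6 / si_us, channel_labels = labels)
}

#' Write a BOLD series as CSV
#'
#' Two columns: `roi` (the ROI BOLD value) and `tr_s` (the repetition time,
#' constant).
#'
#' @param values Numeric BOLD series at native TR.
#' @param path Output path.
#' @param tr_s Repetition time in seconds.
#' @return `path`, invisibly.
#' @export
write_bold_csv <- function(values, path, tr_s = 3) {
  utils::write.csv(data.frame(roi = values, tr_s = tr_s), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a BOLD series CSV
#'
#' @param path CSV written by [write_bold_csv()].
#' @return Numeric vector with a `tr_s` attribute.
#' @export
read_bold_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("roi", "tr_s") %in% names(df))) {
    abort("expected columns `roi` and `tr_s`.")
  }
  structure(as.numeric(df$roi), tr_s = df$tr_s[1])
}
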