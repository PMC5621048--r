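#' Read an EEG recording from disk
#'
#' Two formats are supported. The plain-text dialect (`"csv"`) is used
#' for fixtures and synthetic data: first line `# fs=<Hz>`, second line
#' comma-separated channel labels, then one sample per line (one column
#' per channel). `"edf"` reads a minimal subset of the European Data
#' Format (16-bit, one data record), sufficient to round-trip files
#' written by [write_recording()].
#'
#' @param path file path.
#' @param format `"csv"`, `"edf"`, or `"auto"` (by file extension).
#' @param subject_id optional subject identifier to attach.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           subject_id = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", csv = "csv",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  switch(format, csv = read_recording_csv(path, subject_id),
         edf = read_recording_edf(path, subject_id))
}

#' Write an EEG recording to disk
#'
#' @param rec an [eeg_recording()].
#' @param path destination path.
#' @param format `"csv"`, `"edf"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), edf = "edf", "csv")
  if (format == "csv") write_recording_csv(rec, path) else write_recording_edf(rec, path)
  invisible(path)
}

read_recording_csv <- function(path, subject_id = NA_character_) {
  con <- file(path, "r"); on.exit(close(con))
  l1 <- readLines(con, n = 1L)
  if (!grepl("^#\\s*fs\\s*=", l1))
    stop("malformed header: expected '# fs=<Hz>' on line 1 of ", path)
  fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", l1))
  if (!is.finite(fs)) stop("non-numeric sampling rate in header of ", path)
  labels <- trimws(strsplit(readLines(con, n = 1L), ",")[[1]])
  vals <- scan(con, what = double(), sep = ",", quiet = TRUE)
  if (anyNA(vals)) stop("non-numeric sample values in ", path)
  if (length(vals) %% length(labels) != 0L)
    stop("sample count is not a multiple of the channel count in ", path)
  m <- matrix(vals, nrow = length(labels),
              ncol = length(vals) %/% length(labels))
  eeg_recording(m, fs, labels, subject_id)
}

write_recording_csv <- function(rec, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", rec$fs),
               paste(rec$channel_labels, collapse = ",")), con)
  write.table(t(rec$data), con, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# --- minimal EDF (16-bit integer, single data record) ------------------

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_recording_edf <- function(rec, path) {
  ns <- nrow(rec$data); n <- ncol(rec$data)
  pmin_ <- apply(rec$data, 1, min); pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- c(edf_pad("0", 8), edf_pad(ifelse(is.na(rec$subject_id), "X",
                                           rec$subject_id), 80),
           edf_pad("hmidecode", 80), edf_pad("01.01.00", 8),
           edf_pad("00.00.00", 8), edf_pad(256 * (1 + ns), 8),
           edf_pad("", 44), edf_pad(1, 8),
           edf_pad(sprintf("%.6g", n / rec$fs), 8), edf_pad(ns, 4))
  writeChar(paste(hdr, collapse = ""), con, eos = NULL)
  fields <- list(edf_pad(rec$channel_labels, 16),
                 edf_pad(rep("", ns), 80), edf_pad(rep("uV", ns), 8),
                 edf_pad(sprintf("%.8g", pmin_), 8),
                 edf_pad(sprintf("%.8g", pmax_), 8),
                 edf_pad(rep(dmin, ns), 8), edf_pad(rep(dmax, ns), 8),
                 edf_pad(rep("", ns), 80), edf_pad(rep(n, ns), 8),
                 edf_pad(rep("", ns), 32))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  for (ch in seq_len(ns)) {
    scaled <- round((rec$data[ch, ] - pmin_[ch]) / (pmax_[ch] - pmin_[ch]) *
                      (dmax - dmin) + dmin)
    writeBin(as.integer(scaled), con, size = 2L, endian = "little")
  }
  invisible(path)
}

edf_read_field <- function(con, width, n = 1L) {
  trimws(vapply(seq_len(n), function(i) readChar(con, width), ""))
}

read_recording_edf <- function(path, subject_id = NA_character_) {
  con <- file(path, "rb"); on.exit(close(con))
  readChar(con, 8)                              # version
  patient <- edf_read_field(con, 80)
  edf_read_field(con, 80); edf_read_field(con, 8); edf_read_field(con, 8)
  edf_read_field(con, 8); edf_read_field(con, 44)
  n_rec <- as.integer(edf_read_field(con, 8))
  dur <- as.numeric(edf_read_field(con, 8))
  ns <- as.integer(edf_read_field(con, 4))
  labels <- edf_read_field(con, 16, ns)
  edf_read_field(con, 80, ns); edf_read_field(con, 8, ns)
  pmin_ <- as.numeric(edf_read_field(con, 8, ns))
  pmax_ <- as.numeric(edf_read_field(con, 8, ns))
  dmin <- as.numeric(edf_read_field(con, 8, ns))
  dmax <- as.numeric(edf_read_field(con, 8, ns))
  edf_read_field(con, 80, ns)
  spr <- as.integer(edf_read_field(con, 8, ns))
  edf_read_field(con, 32, ns)
  total <- spr * n_rec
  data <- matrix(0, ns, total[1L])
  for (r in seq_len(n_rec)) for (ch in seq_len(ns)) {
    dig <- readBin(con, integer(), n = spr[ch], size = 2L, endian = "little")
    phys <- (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) *
      (pmax_[ch] - pmin_[ch]) + pmin_[ch]
    data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
  }
  fs <- spr[1L] / dur
  if (is.na(subject_id) && nzchar(patient) && patient != "X")
    subject_id <- patient
  eeg_recording(data, fs, labels, subject_id)
}

# --- trial labels ------------------------------------------------------

HMI_CLASSES <- paste0("A", 1:11)

#' Hand motor-imagery trial label
#'
#' The eleven task codes are grouped into three sets: set 1 is the rest
#' configuration (A1); set 2 holds the grasps - small diameter (A2),
#' lateral (A3) and extension-type (A4); set 3 holds basic wrist/finger
#' movements (A5-A11). Trial duration follows the experimental
#' paradigm: 10 s for sets 1 and 3, 12 s for A4, 14 s for A2 and A3.
#'
#' @param code one of `"A1"`..`"A11"`.
#' @return A list with fields `code`, `set_id` and `duration` (seconds).
#' @export
trial_label <- function(code) {
  if (length(code) != 1L || !code %in% HMI_CLASSES)
    stop("unknown class code: ", code)
  set_id <- if (code == "A1") 1L else if (code %in% c("A2", "A3", "A4")) 2L else 3L
  duration <- if (code %in% c("A2", "A3")) 14 else if (code == "A4") 12 else 10
  list(code = code, set_id = set_id, duration = duration)
}

#' All eleven class codes
#' @return Character vector `A1`..`A11`.
#' @export
hmi_classes <- function() HMI_CLASSES

#' Read / write trial-label sidecar files
#'
#' Sidecar files are JSON arrays of objects with fields `trial_id`,
#' `subject_id`, `code`, `onset_sample`, `duration_samples`.
#'
#' @param labels data.frame with those columns.
#' @param path file path.
#' @return `read_trial_labels` returns the data.frame.
#' @export
write_trial_labels <- function(labels, path) {
  stopifnot(all(c("trial_id", "subject_id", "code", "onset_sample",
                  "duration_samples") %in% names(labels)))
  jsonlite::write_json(labels, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trial_labels
#' @export
read_trial_labels <- function(path) {
  jsonlite::fromJSON(path)
}
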