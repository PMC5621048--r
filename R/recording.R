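#' Multichannel EEG recording
#'
#' Container for a multichannel EEG time series: a channels x samples
#' matrix of scalp potentials (microvolts), a sampling rate, ordered
#' 10-20 electrode labels, and optional trial annotations in sample
#' units (half-open spans `[onset, onset + duration)`).
#'
#' @param data numeric matrix, channels x samples, finite values.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique electrode names, one
#'   per row of `data`. Matching elsewhere is case-insensitive; labels
#'   are stored in their canonical 10-20 capitalisation when recognised.
#' @param subject_id opaque subject identifier.
#' @param annotations optional data.frame with columns `onset`,
#'   `duration` (samples) and `label`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, subject_id = NA_character_,
                          annotations = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("EEG samples must be finite numbers")
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) stop("fs must be a positive number")
  channel_labels <- canonical_labels(as.character(channel_labels))
  if (length(channel_labels) != nrow(data))
    stop("number of channel labels (", length(channel_labels),
         ") does not match number of data rows (", nrow(data), ")")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    stopifnot(all(c("onset", "duration", "label") %in% names(annotations)))
    bad <- annotations$onset < 0 |
      (annotations$onset + annotations$duration) > ncol(data)
    if (any(bad)) stop("annotation spans must lie inside [0, n_samples)")
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 subject_id = subject_id, annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (",
      format(ncol(x$data) / x$fs, digits = 4), " s)\n", sep = "")
  cat("  channels: ", paste(x$channel_labels, collapse = ", "), "\n", sep = "")
  if (!is.na(x$subject_id)) cat("  subject:  ", x$subject_id, "\n", sep = "")
  if (!is.null(x$annotations))
    cat("  annotations: ", nrow(x$annotations), " spans\n", sep = "")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

# 16-electrode 10-20 montage used throughout (CMS/DRL reference
# electrodes are assumed absent from data files).
HMI_MONTAGE <- c("Fp1", "Fp2", "C3", "C4", "Cz", "F3", "F4", "Fz",
                 "T7", "T8", "O1", "O2", "Oz", "P3", "P4", "Pz")

HMI_CHANNEL_GROUPS <- list(
  G1 = c("C3", "C4", "Cz", "P3", "P4", "Pz", "F3", "F4", "Fz", "T7", "T8"),
  G2 = c("C3", "P3", "F3", "T7"),
  G3 = c("C4", "P4", "F4", "T8"),
  G4 = c("C3", "C4", "Cz", "Pz", "Fz"))

#' The 16-channel montage
#'
#' @return Character vector of the 16 electrode names, 10-20 system.
#' @export
hmi_montage <- function() HMI_MONTAGE

canonical_labels <- function(labels) {
  idx <- match(tolower(labels), tolower(HMI_MONTAGE))
  out <- labels
  out[!is.na(idx)] <- HMI_MONTAGE[idx[!is.na(idx)]]
  out
}

#' Electrode groups over the motor cortex
#'
#' Four named electrode groups covering motor-cortex-related regions:
#' broad bilateral (G1, 11 electrodes), left side (G2, 4), right side
#' (G3, 4) and narrow bilateral (G4, 5).
#'
#' @param group_name one of `"G1"`, `"G2"`, `"G3"`, `"G4"`.
#' @return An object of class `channel_group` with fields `name` and
#'   `electrodes` (ordered).
#' @export
channels_in_group <- function(group_name) {
  if (length(group_name) != 1L || !group_name %in% names(HMI_CHANNEL_GROUPS))
    stop("unknown channel group: ", paste(group_name, collapse = ", "),
         " (expected one of G1, G2, G3, G4)")
  structure(list(name = group_name,
                 electrodes = HMI_CHANNEL_GROUPS[[group_name]]),
            class = "channel_group")
}

#' @export
print.channel_group <- function(x, ...) {
  cat("<channel_group> ", x$name, ": ",
      paste(x$electrodes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Restrict a recording to a channel group
#'
#' @param rec an [eeg_recording()].
#' @param group a `channel_group` (or a group name passed to
#'   [channels_in_group()]).
#' @return An `eeg_recording` whose rows are the group electrodes, in
#'   group order.
#' @export
select_channels <- function(rec, group) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(group)) group <- channels_in_group(group)
  idx <- match(tolower(group$electrodes), tolower(rec$channel_labels))
  if (anyNA(idx))
    stop("recording lacks electrode(s): ",
         paste(group$electrodes[is.na(idx)], collapse = ", "))
  eeg_recording(rec$data[idx, , drop = FALSE], rec$fs,
                rec$channel_labels[idx], rec$subject_id, rec$annotations)
}
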