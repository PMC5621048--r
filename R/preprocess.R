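#' Zero-phase band-pass filter
#'
#' Band-passes every channel with a cascade of 4th-order Butterworth
#' high-pass (at `low`) and low-pass (at `high`) sections, each applied
#' forward-backward ([signal::filtfilt()]): the effective magnitude
#' response is squared and the phase response is zero, so waveform
#' timing is preserved for later segment alignment. The cascade is used
#' instead of a single band-pass polynomial because the band edges span
#' almost three decades at 2048 Hz and a direct 8-pole transfer
#' function is numerically unstable there. The default band 0.5-35 Hz
#' keeps the mu (8-12 Hz) and beta (13-30 Hz) rhythms and rejects drift
#' and line noise.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order of each section.
#' @return A filtered `eeg_recording` with identical shape and labels.
#' @export
eeg_bandpass <- function(rec, low = 0.5, high = 35, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2 (fs = ", rec$fs, ")")
  hp <- signal::butter(order, low / (rec$fs / 2), type = "high")
  lp <- signal::butter(order, high / (rec$fs / 2), type = "low")
  out <- rec$data
  for (ch in seq_len(nrow(out)))
    out[ch, ] <- signal::filtfilt(lp, signal::filtfilt(hp, rec$data[ch, ]))
  eeg_recording(out, rec$fs, rec$channel_labels, rec$subject_id,
                rec$annotations)
}

#' Integer-factor downsampling
#'
#' Decimates each channel by an integer factor `fs / target_fs` after a
#' zero-phase anti-alias guard low-pass at 80% of the target Nyquist.
#' The guard is applied even when the signal is already band-limited by
#' [eeg_bandpass()]; it is cheap and makes the operation safe in
#' isolation.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target sampling rate in Hz; `fs` must be an integer
#'   multiple of it.
#' @param guard apply the anti-alias low-pass (default `TRUE`).
#' @return An `eeg_recording` at `target_fs` with
#'   `floor(n_samples * target_fs / fs)` samples per channel.
#' @export
eeg_downsample <- function(rec, target_fs = 256, guard = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9 || q < 1)
    stop("fs (", rec$fs, ") must be an integer multiple of target_fs (",
         target_fs, ")")
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  dat <- rec$data
  if (guard) {
    lp <- signal::butter(6, 0.8 / q, type = "low")
    for (ch in seq_len(nrow(dat)))
      dat[ch, ] <- signal::filtfilt(lp, dat[ch, ])
  }
  keep <- seq(1L, ncol(dat), by = q)
  ann <- rec$annotations
  if (!is.null(ann)) {
    ann$onset <- ann$onset %/% q
    ann$duration <- ann$duration %/% q
  }
  eeg_recording(dat[, keep, drop = FALSE], target_fs, rec$channel_labels,
                rec$subject_id, ann)
}

#' Segment a single-channel signal into overlapping windows
#'
#' Windows of `W` samples start at 0, `W - O`, `2(W - O)`, ...; a
#' trailing remainder shorter than `W` is dropped, giving
#' `floor((L - W) / (W - O)) + 1` windows.
#'
#' @param x numeric vector (one channel), `length(x) >= W`.
#' @param W window length in samples (default 256).
#' @param O overlap in samples, `0 <= O < W` (default 128).
#' @return A list of numeric vectors of length `W`; each carries its
#'   start index (0-based) as attribute `"onset"`.
#' @export
segment_channel <- function(x, W = 256L, O = 128L) {
  W <- as.integer(W); O <- as.integer(O)
  if (O < 0L || O >= W) stop("overlap must satisfy 0 <= O < W")
  L <- length(x)
  if (L < W) stop("signal length (", L, ") is shorter than the window (", W, ")")
  step <- W - O
  starts <- seq(0L, L - W, by = step)
  lapply(starts, function(s) structure(x[(s + 1L):(s + W)], onset = s))
}
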