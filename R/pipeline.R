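#' Feature table from a synthetic (or loaded) dataset
#'
#' Runs the full front end on every trial: channel-group selection,
#' zero-phase band-pass, integer-factor downsampling to `target_fs`
#' when needed, removal of the cue interval, sliding-window
#' segmentation, analytic transform, quadratic time-frequency
#' distribution, and feature extraction. Returns one row per analysis
#' window with the concatenated per-channel features.
#'
#' @param dataset a [simulate_dataset()] result, or any list with a
#'   `trials` element of `(subject_id, trial_id, code, rec)` entries.
#' @param group channel group name or `channel_group` (default `"G1"`).
#' @param band band-pass edges in Hz (default `c(0.5, 35)`).
#' @param target_fs analysis sampling rate (default 256 Hz).
#' @param W,O window length and overlap in samples (defaults 256/128).
#' @param kernel a [kernel_spec()] (default Choi-Williams, gamma 0.5).
#' @param N frequency bins (default 512).
#' @param features feature subset (default all twelve).
#' @param cue_s cue interval excluded from analysis, seconds
#'   (default 3).
#' @param max_windows cap on analysis windows per trial (default all);
#'   windows are taken from the start of the imagery period.
#' @param artifact_hook optional function `(eeg_recording) ->
#'   eeg_recording` applied after band-passing (pluggable artifact
#'   removal; none by default).
#' @return data.frame with columns `subject`, `trial`, `label`,
#'   `window` and one column per `<channel>:<feature>`.
#' @export
features_from_dataset <- function(dataset, group = "G1",
                                  band = c(0.5, 35), target_fs = 256,
                                  W = 256L, O = 128L,
                                  kernel = kernel_spec(), N = 512L,
                                  features = HMI_FEATURES, cue_s = 3,
                                  max_windows = Inf,
                                  artifact_hook = NULL) {
  if (is.character(group)) group <- channels_in_group(group)
  rows <- list()
  for (tr in dataset$trials) {
    rec <- select_channels(tr$rec, group)
    rec <- eeg_bandpass(rec, band[1], band[2])
    if (!is.null(artifact_hook)) rec <- artifact_hook(rec)
    if (rec$fs > target_fs) rec <- eeg_downsample(rec, target_fs)
    cue_n <- as.integer(cue_s * rec$fs)
    imagery <- rec$data[, (cue_n + 1):ncol(rec$data), drop = FALSE]
    segs <- lapply(seq_len(nrow(imagery)), function(ch)
      segment_channel(imagery[ch, ], W, O))
    n_win <- min(length(segs[[1]]), max_windows)
    for (w in seq_len(n_win)) {
      tfrs <- lapply(seq_along(segs), function(ch)
        compute_tfd(analytic_signal(segs[[ch]][[w]], rec$fs), kernel, N))
      names(tfrs) <- rec$channel_labels
      fv <- extract_features(tfrs, group, features)
      rows[[length(rows) + 1L]] <- c(
        list(subject = tr$subject_id, trial = tr$trial_id,
             label = tr$code, window = w), as.list(fv))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Read / write feature tables
#'
#' Delimited text with header columns `subject`, `trial`, `label`,
#' `window` and `<channel>:<feature>`; one row per analysis window.
#'
#' @param feats feature table (see [features_from_dataset()]).
#' @param path file path.
#' @return `read_features` returns the data.frame.
#' @export
write_features <- function(feats, path) {
  utils::write.table(feats, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Default run configuration
#'
#' All pipeline parameters with their defaults: band 0.5-35 Hz,
#' analysis rate 256 Hz, W = 256, O = 128, N = 512, Choi-Williams
#' kernel with gamma 0.5, all twelve features, channel group G1,
#' 10-fold subject-dependent evaluation.
#'
#' @return Nested list of defaults, suitable for YAML serialization
#'   and for the command-line driver.
#' @export
default_config <- function() {
  list(preprocessing = list(band = c(0.5, 35), target_fs = 256,
                            W = 256L, O = 128L, cue_s = 3),
       tfr = list(family = "cwd", gamma = 0.5, N = 512L),
       features = list(categories = c("C1", "C2", "C3", "C4", "C5")),
       channels = list(group = "G1"),
       classifier = list(C_grid = 2^seq(-3, 9, by = 2),
                         sigma_grid = 2^seq(-4, 4, by = 1),
                         inner_folds = 5L),
       evaluation = list(protocol = "sdtp", k = 10L, seed = 1L),
       synthetic = list(n_subjects = 18L, n_trials = 7L, fs = 2048,
                        separability = 0.9, subject_variation = 0.3,
                        seed = 1L, max_windows = Inf))
}
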