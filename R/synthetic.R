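# Synthetic motor-imagery EEG.
#
# Classes are distinguished by (a) distinct spatial amplitude patterns
# over the sensorimotor electrodes and (b) class-specific oscillation
# frequencies in the mu (8-12 Hz) / beta (13-30 Hz) bands; rest (A1)
# carries attenuated class components. Oscillations are amplitude-
# modulated tones under Gaussian burst envelopes on top of 1/f
# background noise - a pipeline-testing emulation, not a physiological
# ERD/ERS model.

synth_focus_pool <- function() HMI_CHANNEL_GROUPS$G1

# class-level templates shared by all subjects of a dataset
class_templates <- function(separability = 0.9, template_seed = 1L) {
  set.seed(template_seed)
  pool <- synth_focus_pool()
  perm <- sample(length(pool))
  freqs <- seq(8, 30, length.out = 11)[sample(11)]
  f_base <- 11
  base_w <- c(C3 = 1, C4 = 1, Cz = 0.8, F3 = 0.4, F4 = 0.4, Fz = 0.3,
              P3 = 0.4, P4 = 0.4, Pz = 0.3, T7 = 0.2, T8 = 0.2)
  lapply(seq_len(11), function(k) {
    focus <- pool[perm[k]]
    second <- pool[perm[(k %% 11) + 1]]
    w <- 0.3 * base_w
    w[focus] <- w[focus] + 1.5
    w[second] <- w[second] + 0.75
    # blend toward the shared base pattern as separability decreases
    w_eff <- (1 - separability) * base_w[names(w)] + separability * w
    names(w_eff) <- names(w)
    f_eff <- f_base + separability * (freqs[k] - f_base)
    amp <- 6 * if (k == 1) 1 - 0.9 * separability else 1
    list(code = paste0("A", k), weights = w_eff, freq = f_eff,
         amp = amp, bandwidth = 2)
  })
}

#' Subject profile for the synthetic generator
#'
#' Draws a subject's per-class oscillatory signatures around shared
#' class templates. The template perturbation (channel weights,
#' frequency jitter, global gain, noise exponent) scales with
#' `subject_variation`; the distance between class templates scales
#' with `separability` (at 0 all eleven signatures are identical, so
#' classes are indistinguishable by construction).
#'
#' @param subject_id identifier.
#' @param separability class-separation scalar in `[0, 1]`.
#' @param subject_variation inter-subject variation scalar in `[0, 1]`.
#' @param seed subject-level RNG seed.
#' @param template_seed seed of the shared class templates (equal
#'   across the subjects of one dataset).
#' @return An object of class `subject_profile`.
#' @export
make_profile <- function(subject_id, separability = 0.9,
                         subject_variation = 0.3, seed = 1L,
                         template_seed = 1L) {
  stopifnot(separability >= 0, separability <= 1,
            subject_variation >= 0, subject_variation <= 1)
  tmpl <- class_templates(separability, template_seed)
  set.seed(seed)
  sv <- subject_variation
  gain <- exp(rnorm(1, 0, 0.2 * sv))
  signatures <- lapply(tmpl, function(tt) {
    w <- tt$weights * exp(rnorm(length(tt$weights), 0, 0.5 * sv))
    f <- min(30, max(8, tt$freq + rnorm(1, 0, 4 * sv)))
    list(code = tt$code, weights = w, freq = f,
         amp = tt$amp * gain, bandwidth = tt$bandwidth)
  })
  names(signatures) <- vapply(signatures, `[[`, "", "code")
  # inter-subject topography: a fraction ~ subject_variation of the
  # movement classes exchange their spatial patterns pairwise, so the
  # same imagery task maps to different scalp patterns in different
  # subjects while staying internally consistent
  n_swaps <- round(sv * 5)
  if (n_swaps > 0) {
    movers <- sample(paste0("A", 2:11))
    for (p in seq_len(n_swaps)) {
      i <- movers[2 * p - 1]; j <- movers[2 * p]
      tmp <- signatures[[i]]$weights
      signatures[[i]]$weights <- signatures[[j]]$weights
      signatures[[j]]$weights <- tmp
    }
  }
  structure(list(subject_id = subject_id, signatures = signatures,
                 noise_exponent = 1 + 0.2 * sv * rnorm(1),
                 noise_amp = 2, separability = separability,
                 subject_variation = sv, seed = seed,
                 template_seed = template_seed),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat("<subject_profile> ", x$subject_id, ": separability = ",
      x$separability, ", subject_variation = ", x$subject_variation,
      "\n", sep = "")
  freqs <- vapply(x$signatures, `[[`, 0, "freq")
  cat("  class frequencies (Hz): ",
      paste(sprintf("%s=%.1f", names(freqs), freqs), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# band-limited 1/f noise via spectral shaping; logistic roll-off above
# ~40 Hz keeps spectral mass above the analysis band negligible
pink_noise <- function(n, fs, exponent = 1, sd_target = 1) {
  freqs <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f_fold <- pmin(freqs, fs - freqs)
  w <- ifelse(f_fold < 0.25, 0, 1 / sqrt(pmax(f_fold, 0.5)^exponent))
  w <- w / (1 + exp((f_fold - 40) / 2))
  spec <- complex(real = rnorm(n), imaginary = rnorm(n)) * w
  x <- Re(fft(spec, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x <- x * (sd_target / s)
  x
}

burst_envelope <- function(n, fs, cue_n) {
  tt <- seq_len(n) / fs
  t0 <- cue_n / fs
  centers <- seq(t0 + 0.4, max(tt), by = 0.8) + rnorm(
    length(seq(t0 + 0.4, max(tt), by = 0.8)), 0, 0.15)
  amps <- exp(rnorm(length(centers), 0, 0.25))
  env <- numeric(n)
  for (b in seq_along(centers))
    env <- env + amps[b] * exp(-(tt - centers[b])^2 / (2 * 0.25^2))
  env[seq_len(cue_n)] <- 0 # cue interval carries noise only
  env
}

#' Simulate one motor-imagery trial
#'
#' Generates a 16-channel recording of one trial: 1/f background noise
#' on all channels for the full duration, plus the subject's class
#' signature (amplitude-modulated, random-phase tones on its weighted
#' channels) during the imagery period. The first 3 s (visual cue)
#' contain noise only. Trial duration follows the paradigm (10 s for
#' A1 and A5-A11, 12 s for A4, 14 s for A2/A3).
#'
#' @param profile a [make_profile()].
#' @param code task code `A1`..`A11`.
#' @param fs sampling rate, default 2048 Hz (use 256 for fast tests).
#' @param seed trial-level RNG seed.
#' @return An [eeg_recording()] with one annotation spanning the trial.
#' @export
simulate_trial <- function(profile, code, fs = 2048, seed = 1L) {
  stopifnot(inherits(profile, "subject_profile"))
  lab <- trial_label(code)
  set.seed(seed)
  n <- as.integer(lab$duration * fs)
  cue_n <- as.integer(3 * fs)
  dat <- matrix(0, length(HMI_MONTAGE), n,
                dimnames = list(HMI_MONTAGE, NULL))
  for (ch in seq_len(nrow(dat)))
    dat[ch, ] <- pink_noise(n, fs, profile$noise_exponent,
                            profile$noise_amp)
  sig <- profile$signatures[[code]]
  tt <- seq_len(n) / fs
  for (ch_name in names(sig$weights)) {
    w <- sig$weights[[ch_name]]
    if (w <= 0) next
    env <- burst_envelope(n, fs, cue_n)
    phase <- runif(1, 0, 2 * pi)
    tone <- cos(2 * pi * sig$freq * tt + phase)
    dat[ch_name, ] <- dat[ch_name, ] + sig$amp * w * env * tone
  }
  eeg_recording(dat, fs, HMI_MONTAGE, profile$subject_id,
                annotations = data.frame(onset = 0, duration = n,
                                         label = code))
}

#' Simulate a labeled multi-subject dataset
#'
#' Full factorial design: `n_subjects` x 11 classes x `n_trials`
#' trials, with per-subject and per-trial seeds derived
#' deterministically from the global seed so any unit is reproducible
#' in isolation.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_trials trials per class per subject (default 7).
#' @param fs sampling rate (default 2048; 256 is the fast shortcut).
#' @param separability,subject_variation generator scalars, see
#'   [make_profile()].
#' @param seed global seed.
#' @return An object of class `synthetic_dataset`: list with `trials`
#'   (each holding `subject_id`, `trial_id`, `code` and the
#'   [eeg_recording()]), `profiles` and `params`.
#' @export
simulate_dataset <- function(n_subjects = 18L, n_trials = 7L, fs = 2048,
                             separability = 0.9, subject_variation = 0.3,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, n_trials >= 1)
  template_seed <- split_seed(seed, 0L)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  profiles <- lapply(seq_len(n_subjects), function(si)
    make_profile(subjects[si], separability, subject_variation,
                 seed = split_seed(seed, si), template_seed = template_seed))
  names(profiles) <- subjects
  trials <- list()
  for (si in seq_len(n_subjects)) {
    counter <- 0L
    for (code in HMI_CLASSES) for (tr in seq_len(n_trials)) {
      counter <- counter + 1L
      tseed <- split_seed(split_seed(seed, si), counter)
      trial_id <- sprintf("%s_%s_T%02d", subjects[si], code, tr)
      trials[[trial_id]] <- list(
        subject_id = subjects[si], trial_id = trial_id, code = code,
        rec = simulate_trial(profiles[[si]], code, fs, tseed))
    }
  }
  structure(list(trials = trials, profiles = profiles,
                 params = list(n_subjects = n_subjects,
                               n_trials = n_trials, fs = fs,
                               separability = separability,
                               subject_variation = subject_variation,
                               seed = seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$params
  cat("<synthetic_dataset> ", p$n_subjects, " subjects x 11 classes x ",
      p$n_trials, " trials = ", length(x$trials), " trials @ ", p$fs,
      " Hz\n", sep = "")
  cat("  separability = ", p$separability, ", subject_variation = ",
      p$subject_variation, ", seed = ", p$seed, "\n", sep = "")
  invisible(x)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory holding one recording file per trial, the
#'   `trial_labels.json` sidecar and (optionally) `manifest.json`.
#' @return A list with `trials` (as in [simulate_dataset()]) and
#'   `params` (the manifest, if present).
#' @export
read_dataset <- function(dir) {
  lab_path <- file.path(dir, "trial_labels.json")
  if (!file.exists(lab_path)) stop("no trial_labels.json in ", dir)
  labels <- read_trial_labels(lab_path)
  trials <- lapply(seq_len(nrow(labels)), function(i) {
    base <- file.path(dir, labels$trial_id[i])
    path <- if (file.exists(paste0(base, ".csv"))) paste0(base, ".csv")
            else paste0(base, ".edf")
    list(subject_id = labels$subject_id[i], trial_id = labels$trial_id[i],
         code = labels$code[i],
         rec = read_recording(path, subject_id = labels$subject_id[i]))
  })
  names(trials) <- labels$trial_id
  params <- NULL
  if (file.exists(file.path(dir, "manifest.json")))
    params <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  list(trials = trials, params = params)
}

#' Write a synthetic dataset to disk
#'
#' Writes one recording file per trial (CSV dialect or EDF), a JSON
#' trial-label sidecar and a manifest recording all generator
#' parameters.
#'
#' @param dataset a [simulate_dataset()].
#' @param dir destination directory (created if missing).
#' @param format `"csv"` or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- do.call(rbind, lapply(dataset$trials, function(tr)
    data.frame(trial_id = tr$trial_id, subject_id = tr$subject_id,
               code = tr$code, onset_sample = 0,
               duration_samples = ncol(tr$rec$data))))
  for (tr in dataset$trials)
    write_recording(tr$rec, file.path(dir, paste0(tr$trial_id, ".", format)),
                    format)
  write_trial_labels(labels, file.path(dir, "trial_labels.json"))
  jsonlite::write_json(dataset$params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
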