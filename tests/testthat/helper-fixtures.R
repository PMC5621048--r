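# Shared, lazily built fixtures (expensive ones are reused across
# test files within a run).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# reduced hyperparameter grid used by the evaluation-scale experiments
reduced_grid <- list(C = c(1, 16), sigma = c(4, 8, 16), inner_folds = 3L)

# the scaled-down end-to-end study: 6 subjects x 11 classes x 7 trials,
# high separability with raised inter-subject variation, fs = 256
# shortcut, 3 analysis windows per trial
e2e_dataset <- function() memo("e2e_dataset", function()
  simulate_dataset(n_subjects = 6, n_trials = 7, fs = 256,
                   separability = 0.95, subject_variation = 0.5,
                   seed = 42))

e2e_features <- function() memo("e2e_features", function()
  features_from_dataset(e2e_dataset(), group = "G1", max_windows = 3))

two_tone_segment <- function(fs = 256, f1 = 8, f2 = 24) {
  t <- (0:255) / fs
  analytic_signal(cos(2 * pi * f1 * t) + cos(2 * pi * f2 * t), fs)
}
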