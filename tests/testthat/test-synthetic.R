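test_that("profiles degenerate and replicate as the control scalars dictate", {
  # separability 0: all class signatures identical
  p0 <- make_profile("S01", separability = 0, subject_variation = 0,
                     seed = 3, template_seed = 5)
  w <- lapply(p0$signatures, `[[`, "weights")
  f <- vapply(p0$signatures, `[[`, 0, "freq")
  a <- vapply(p0$signatures, `[[`, 0, "amp")
  for (k in 2:11) expect_equal(w[[k]], w[[1]])
  expect_true(all(abs(f - f[1]) < 1e-12))
  expect_true(all(abs(a - a[1]) < 1e-12))
  # zero subject variation: profiles identical across subjects
  pa <- make_profile("S01", 0.8, 0, seed = 10, template_seed = 5)
  pb <- make_profile("S02", 0.8, 0, seed = 77, template_seed = 5)
  expect_equal(lapply(pa$signatures, `[[`, "weights"),
               lapply(pb$signatures, `[[`, "weights"))
  expect_equal(vapply(pa$signatures, `[[`, 0, "freq"),
               vapply(pb$signatures, `[[`, 0, "freq"))
  # full separability: class signatures are pairwise distinct (focus
  # channel or frequency separated)
  p1 <- make_profile("S01", 1, 0, seed = 3, template_seed = 5)
  focus <- vapply(p1$signatures, function(s)
    names(which.max(s$weights)), "")
  fr <- vapply(p1$signatures, `[[`, 0, "freq")
  for (i in 1:10) for (j in (i + 1):11) {
    expect_true(focus[i] != focus[j] || abs(fr[i] - fr[j]) > 1,
                info = paste(i, j))
  }
  expect_error(make_profile("S01", separability = 2), "separability")
})

test_that("trial simulation honours durations, rest attenuation and seeds", {
  prof <- make_profile("S01", 1, 0.2, seed = 4, template_seed = 6)
  tr <- simulate_trial(prof, "A3", fs = 256, seed = 8)
  expect_identical(dim(tr$data), c(16L, 14L * 256L))
  expect_identical(tr$channel_labels, hmi_montage())
  tr4 <- simulate_trial(prof, "A4", fs = 256, seed = 8)
  expect_identical(ncol(tr4$data), 12L * 256L)
  tr1 <- simulate_trial(prof, "A1", fs = 256, seed = 8)
  expect_identical(ncol(tr1$data), 10L * 256L)
  # determinism
  again <- simulate_trial(prof, "A3", fs = 256, seed = 8)
  expect_identical(tr$data, again$data)
  # rest: mu-band power on the motor channels stays near the noise
  # floor (class components attenuated at high separability)
  band_power <- function(x, fs, lo, hi) {
    X <- Mod(fft(x))^2
    fr <- (seq_along(x) - 1) * fs / length(x)
    sum(X[fr >= lo & fr <= hi & fr <= fs / 2])
  }
  imag1 <- tr1$data[, (3 * 256 + 1):ncol(tr1$data)]
  mu_c3 <- band_power(imag1["C3", ], 256, 8, 12)
  mu_ref <- band_power(imag1["O1", ], 256, 8, 12) # no signature channel
  expect_lt(mu_c3, 2 * mu_ref)
  # cue interval carries noise only: no excess mu/beta power vs rest
  act <- simulate_trial(prof, "A6", fs = 256, seed = 9)
  cue <- act$data[, 1:(3 * 256)]
  sig_ch <- names(which.max(prof$signatures$A6$weights))
  cue_p <- band_power(cue[sig_ch, ], 256, 8, 30)
  imag_p <- band_power(act$data[sig_ch, (3 * 256 + 1):(6 * 256)], 256, 8, 30)
  expect_gt(imag_p, 3 * cue_p)
})

test_that("generated signals stay inside the analysis band", {
  prof <- make_profile("S01", 0.9, 0.3, seed = 4, template_seed = 6)
  tr <- simulate_trial(prof, "A5", fs = 2048, seed = 12)
  X <- Mod(fft(tr$data["C3", ]))^2
  fr <- (seq_along(X) - 1) * 2048 / length(X)
  keep <- fr <= 1024
  mass_hi <- sum(X[keep & fr > 40]) / sum(X[keep])
  expect_lt(mass_hi, 0.01)
})

test_that("datasets have the full factorial layout and derived seeds", {
  ds <- simulate_dataset(n_subjects = 2, n_trials = 2, fs = 64, seed = 5)
  expect_length(ds$trials, 2 * 11 * 2)
  codes <- vapply(ds$trials, `[[`, "", "code")
  expect_identical(unname(table(codes))[1], 4L) # 2 subjects x 2 trials
  subj <- vapply(ds$trials, `[[`, "", "subject_id")
  expect_setequal(unique(subj), c("S01", "S02"))
  # full study scale arithmetic (fast at a coarse rate)
  big <- simulate_dataset(n_subjects = 18, n_trials = 7, fs = 64, seed = 5)
  expect_length(big$trials, 1386L)
  # reproducibility down to written files
  ds2 <- simulate_dataset(n_subjects = 2, n_trials = 2, fs = 64, seed = 5)
  expect_identical(lapply(ds$trials, function(tr) tr$rec$data),
                   lapply(ds2$trials, function(tr) tr$rec$data))
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  sub <- ds; sub$trials <- ds$trials[1:3]
  sub2 <- ds2; sub2$trials <- ds2$trials[1:3]
  write_dataset(sub, d1); write_dataset(sub2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)),
                   unname(tools::md5sum(file.path(d2, basename(f1)))))
})

test_that("classification difficulty tracks the separability scalar", {
  accs <- vapply(c(0, 0.3, 0.6, 1), function(sep) {
    ds <- simulate_dataset(n_subjects = 2, n_trials = 3, fs = 256,
                           separability = sep, subject_variation = 0.2,
                           seed = 33)
    feats <- features_from_dataset(ds, group = "G4", max_windows = 2)
    rep_ <- suppressWarnings(
      evaluate_sdtp(feats, k = 3, C_grid = c(1, 16), sigma_grid = c(4, 16),
                    inner_folds = 2, seed = 3))
    rep_$detail$end_to_end_acc
  }, 0)
  # non-decreasing within Monte-Carlo tolerance at fixed seeds
  expect_true(all(diff(accs) > -5))
  expect_gt(accs[4], accs[1] + 30)
  # separability 0: end-to-end accuracy within the 99% binomial
  # interval of chance (1/11); windows of one trial are correlated, so
  # the effective sample size is counted in trials
  n <- 2 * 11 * 3
  half <- 2.576 * sqrt((1 / 11) * (10 / 11) / n) * 100
  expect_lt(abs(accs[1] - 100 / 11), half + 1e-9)
})
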