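test_that("metrics reproduce hand-computed confusion values", {
  m <- classification_metrics(TP = 50, FP = 50, FN = 0, TN = 0)
  expect_equal(unname(m), c(50, 100, 2 * 50 * 100 / 150, 50),
               tolerance = 1e-12)
  m2 <- classification_metrics(TP = 8, FP = 2, FN = 4, TN = 6)
  expect_equal(unname(m2["PRC"]), 80)
  expect_equal(unname(m2["RCL"]), 100 * 8 / 12, tolerance = 1e-12)
  expect_equal(unname(m2["F1"]),
               2 * 80 * (800 / 12) / (80 + 800 / 12), tolerance = 1e-9)
  expect_equal(unname(m2["ACC"]), 70)
  expect_warning(m3 <- classification_metrics(0, 0, 3, 7), "precision")
  expect_equal(unname(m3["PRC"]), 0)
})

test_that("node metrics macro-average one-vs-rest counts", {
  y <- c("a", "a", "a", "b", "b", "c")
  expect_equal(unname(node_metrics(y, y)), c(100, 100, 100, 100))
  yt <- rep(c("x", "y"), each = 10)
  expect_equal(unname(node_metrics(yt, rep("x", 20))["ACC"]), 50)
  # constructed 3-class confusion, macro averages computed by hand
  y_true <- c(rep("a", 4), rep("b", 3), rep("c", 3))
  y_pred <- c("a", "a", "b", "c", "b", "b", "a", "c", "c", "b")
  prc <- mean(c(2 / 3, 2 / 4, 2 / 3)) * 100
  rcl <- mean(c(2 / 4, 2 / 3, 2 / 3)) * 100
  got <- node_metrics(y_true, y_pred, classes = c("a", "b", "c"))
  expect_equal(unname(got["PRC"]), prc, tolerance = 1e-9)
  expect_equal(unname(got["RCL"]), rcl, tolerance = 1e-9)
  expect_equal(unname(got["F1"]), 2 * prc * rcl / (prc + rcl),
               tolerance = 1e-9)
  expect_equal(unname(got["ACC"]), 60)
  expect_error(node_metrics(character(0), character(0)), "empty")
})

test_that("stratified folds partition every segment exactly once", {
  set.seed(14)
  y <- sample(rep(hmi_classes(), times = 13))
  folds <- hmidecode:::stratified_folds(y, 10, seed = 3)
  expect_length(folds, length(y))
  expect_identical(sort(unique(folds)), 1:10)
  # stratification: each class spread over folds as evenly as possible
  for (cl in unique(y)) {
    tab <- table(folds[y == cl])
    expect_lte(max(tab) - min(tab), 1)
  }
})

test_that("subject-dependent harness averages folds and stays deterministic", {
  feats <- make_blob_features(n_subjects = 2, per_class = 6, sep = 8,
                              seed = 41)
  args <- list(feats = feats, k = 3, C_grid = 4, sigma_grid = 2,
               inner_folds = 2, seed = 7)
  r1 <- suppressWarnings(do.call(evaluate_sdtp, args))
  r2 <- suppressWarnings(do.call(evaluate_sdtp, args))
  expect_identical(r1$per_node, r2$per_node)
  expect_identical(r1$detail, r2$detail)
  expect_s3_class(r1, "hmi_eval")
  expect_identical(rownames(r1$per_node), paste0("CN", 1:6))
  expect_true(all(r1$per_node >= 0 & r1$per_node <= 100))
  # harmonic-mean identity on every reported row including the overall
  for (i in seq_len(nrow(r1$per_node))) {
    row <- r1$per_node[i, ]
    expect_equal(unname(row["F1"]),
                 2 * row[["PRC"]] * row[["RCL"]] /
                   (row[["PRC"]] + row[["RCL"]]), tolerance = 1e-9)
  }
  ov <- r1$overall
  expect_equal(unname(ov["F1"]),
               2 * ov[["PRC"]] * ov[["RCL"]] / (ov[["PRC"]] + ov[["RCL"]]),
               tolerance = 1e-9)
  # wide-margin blobs are classified nearly perfectly within subject
  expect_gte(ov[["ACC"]], 90)
  expect_error(evaluate_sdtp(feats[feats$label == "A1", ], k = 3),
               "2 task classes")
})

test_that("leave-one-subject-out tests each subject exactly once", {
  feats <- make_blob_features(n_subjects = 3, per_class = 5, sep = 8,
                              subject_shift = 0.2, seed = 42)
  rep_ <- evaluate_sitp(feats, C_grid = 4, sigma_grid = 2,
                        inner_folds = 2, seed = 7)
  expect_identical(rep_$detail$subjects, unique(feats$subject))
  expect_length(rep_$detail$subject_overall_acc, 3L)
  # subjects drawn from one distribution transfer well
  expect_gte(rep_$overall[["ACC"]], 80)
  expect_error(evaluate_sitp(feats[feats$subject == "S01", ]),
               "2 subjects")
})

test_that("disjoint per-subject signatures break transfer but not recall", {
  # each subject's classes live in a different feature subspace:
  # within-subject CV succeeds, cross-subject transfer collapses
  set.seed(15)
  f1 <- make_blob_features(n_subjects = 1, per_class = 5, sep = 8, seed = 1)
  f2 <- make_blob_features(n_subjects = 1, per_class = 5, sep = 8, seed = 99)
  f2$subject <- "S02"
  f2$trial <- sub("S01", "S02", f2$trial)
  feats <- rbind(f1, f2)
  sdtp <- suppressWarnings(
    evaluate_sdtp(feats, k = 3, C_grid = 4, sigma_grid = 2,
                  inner_folds = 2, seed = 5))
  sitp <- evaluate_sitp(feats, C_grid = 4, sigma_grid = 2,
                        inner_folds = 2, seed = 5)
  expect_gte(sdtp$detail$end_to_end_acc, 80)
  expect_lte(sitp$detail$end_to_end_acc, 35)
})

test_that("paired t-tests follow the classical formula and edge policy", {
  expect_identical(paired_ttest(c(1, 2, 3), c(1, 2, 3)), list(t = 0, p = 1))
  out <- paired_ttest(c(6, 7, 8), c(1, 2, 3))
  expect_identical(out$p, 0)
  expect_true(is.infinite(out$t) && out$t > 0)
  a <- c(83.2, 79.1, 88.4, 74.9, 91.0, 82.7, 78.8, 85.5, 80.2, 84.1)
  b <- c(80.0, 76.3, 84.1, 77.2, 86.8, 80.1, 77.9, 84.6, 76.4, 81.0)
  d <- a - b
  tt <- paired_ttest(a, b)
  expect_equal(tt$t, mean(d) / (sd(d) / sqrt(length(d))), tolerance = 1e-12)
  expect_equal(tt$p, t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-12)
  expect_error(paired_ttest(1, 1), ">= 2")
})

test_that("evaluation reports serialize to JSON and tables", {
  feats <- make_blob_features(n_subjects = 2, per_class = 4, sep = 8,
                              seed = 43)
  rep_ <- suppressWarnings(
    evaluate_sdtp(feats, k = 2, C_grid = 4, sigma_grid = 2,
                  inner_folds = 2, seed = 7))
  jpath <- tempfile(fileext = ".json"); tpath <- tempfile(fileext = ".tsv")
  write_eval_report(rep_, jpath, tpath)
  back <- jsonlite::fromJSON(jpath)
  expect_equal(back$protocol, "SDTP")
  expect_equal(back$overall$ACC, rep_$overall[["ACC"]], tolerance = 1e-9)
  tab <- utils::read.delim(tpath)
  expect_identical(nrow(tab), 7L) # six nodes + overall average
})
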