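#' Classification metrics from confusion counts
#'
#' Precision, recall, F1 and accuracy in percent from one-vs-rest
#' confusion counts. A metric whose denominator is zero is reported as
#' 0 with a warning.
#'
#' @param TP,FP,FN,TN non-negative integer counts.
#' @return Named numeric vector `c(PRC, RCL, F1, ACC)`, percentages.
#' @export
classification_metrics <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0")
      return(0)
    }
    100 * num / den
  }
  prc <- safe(TP, TP + FP, "precision")
  rcl <- safe(TP, TP + FN, "recall")
  f1 <- if (prc + rcl == 0) 0 else 2 * prc * rcl / (prc + rcl)
  acc <- safe(TP + TN, TP + TN + FP + FN, "accuracy")
  c(PRC = prc, RCL = rcl, F1 = f1, ACC = acc)
}

#' Per-node metrics from labels and predictions
#'
#' One-vs-rest confusion counts are formed per node class and
#' macro-averaged (unweighted over classes) into PRC and RCL; F1 is
#' recomputed from the macro PRC/RCL so the harmonic-mean identity
#' holds on every reported row; ACC is the overall fraction correct at
#' the node.
#'
#' @param y_true,y_pred factors/characters over the node's output
#'   labels.
#' @param classes class order; default the union of observed labels.
#' @return Named numeric vector `c(PRC, RCL, F1, ACC)`, percentages.
#' @export
node_metrics <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (!length(y_true)) stop("empty input")
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  per <- vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prc <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
    rcl <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
    c(prc, rcl)
  }, numeric(2))
  prc <- mean(per[1, ]); rcl <- mean(per[2, ])
  f1 <- if (prc + rcl == 0) 0 else 2 * prc * rcl / (prc + rcl)
  c(PRC = prc, RCL = rcl, F1 = f1,
    ACC = 100 * mean(y_true == y_pred))
}

# Apply one node classifier directly to (unscaled) feature rows whose
# true leaf lies beneath the node; returns relabeled truth and the
# node's own decisions. This is the node's classification task as
# reported per-node, independent of routing errors upstream.
node_task_predictions <- function(model, x, y, node_id) {
  sub <- node_training_labels(as.character(y), node_id, model$spec)
  if (!length(sub$index)) return(NULL)
  xs <- scale(as.matrix(x)[sub$index, , drop = FALSE], model$center,
              model$scale)
  list(y_true = sub$labels,
       y_pred = predict(model$nodes[[node_id]]$model, xs))
}

meta_cols <- c("subject", "trial", "label", "window")

feature_matrix <- function(feats) {
  as.matrix(feats[, setdiff(names(feats), meta_cols), drop = FALSE])
}

eval_one_fit <- function(model, test_x, test_y, spec) {
  per_node <- matrix(NA_real_, length(names(spec)), 4,
                     dimnames = list(names(spec),
                                     c("PRC", "RCL", "F1", "ACC")))
  for (id in names(spec)) {
    np <- node_task_predictions(model, test_x, test_y, id)
    if (is.null(np)) next
    per_node[id, ] <- node_metrics(np$y_true, np$y_pred,
                                   classes = levels(np$y_true))
  }
  e2e <- mean(as.character(predict(model, test_x)) ==
                as.character(test_y))
  list(per_node = per_node, end_to_end = 100 * e2e)
}

# average fold-level per-node matrices (na.rm) and recompute F1 from
# the averaged PRC/RCL so the harmonic identity holds on every row
average_per_node <- function(mats) {
  arr <- simplify2array(mats)
  out <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  out[, "F1"] <- ifelse(out[, "PRC"] + out[, "RCL"] == 0, 0,
                        2 * out[, "PRC"] * out[, "RCL"] /
                          (out[, "PRC"] + out[, "RCL"]))
  out
}

finish_report <- function(per_node, protocol, detail, seed, n) {
  overall <- colMeans(per_node)
  overall["F1"] <- if (overall["PRC"] + overall["RCL"] == 0) 0 else
    2 * overall["PRC"] * overall["RCL"] / (overall["PRC"] + overall["RCL"])
  structure(list(per_node = per_node, overall = overall,
                 protocol = protocol, detail = detail, seed = seed,
                 n_samples = n),
            class = "hmi_eval")
}

#' Subject-dependent evaluation (per-subject k-fold CV)
#'
#' For every subject, segments are split into `k` stratified folds (by
#' task label); a hierarchical model is fitted on k-1 folds and
#' evaluated on the held-out fold, rotating. Node metrics are averaged
#' over folds, then over subjects; F1 and the overall row are
#' recomputed from averaged PRC/RCL. End-to-end (cascaded 11-class)
#' accuracy is reported alongside.
#'
#' @param feats feature table: data.frame with `subject`, `trial`,
#'   `label`, `window` plus one column per feature (see
#'   [features_from_dataset()]).
#' @param k folds per subject (default 10).
#' @param C_grid,sigma_grid,inner_folds grid-search settings, see
#'   [fit_hierarchy()].
#' @param seed RNG seed controlling fold assignment and node training.
#' @param trial_grouped if `TRUE`, all segments of a trial share a fold
#'   (the leakage-safe variant); default `FALSE`, matching segmentation
#'   before cross-validation.
#' @return An object of class `hmi_eval`: per-node metric matrix,
#'   overall (unweighted node mean) row, end-to-end accuracy, and
#'   per-subject accuracies (for paired comparisons).
#' @export
evaluate_sdtp <- function(feats, k = 10L,
                          C_grid = 2^seq(-3, 9, by = 2),
                          sigma_grid = 2^seq(-4, 4, by = 1),
                          inner_folds = 5L, seed = 1L,
                          trial_grouped = FALSE) {
  stopifnot(all(meta_cols %in% names(feats)))
  if (length(unique(feats$label)) < 2) stop("need at least 2 task classes")
  x_all <- feature_matrix(feats)
  subjects <- unique(feats$subject)
  subj_mats <- list(); subj_acc <- numeric(0); subj_e2e <- numeric(0)
  for (si in seq_along(subjects)) {
    rows <- which(feats$subject == subjects[si])
    y <- feats$label[rows]
    if (min(table(y)) < k)
      warning("subject ", subjects[si], ": fewer than k = ", k,
              " segments in some class; stratification relaxed")
    fseed <- split_seed(seed, si)
    if (trial_grouped) {
      trials <- unique(feats$trial[rows])
      tl <- feats$label[rows][match(trials, feats$trial[rows])]
      tf <- stratified_folds(tl, k, fseed)
      folds <- tf[match(feats$trial[rows], trials)]
    } else {
      folds <- stratified_folds(y, k, fseed)
    }
    fold_mats <- list(); fold_e2e <- numeric(0)
    for (f in sort(unique(folds))) {
      tr <- rows[folds != f]; te <- rows[folds == f]
      model <- fit_hierarchy(x_all[tr, , drop = FALSE], feats$label[tr],
                             C_grid, sigma_grid, inner_folds,
                             split_seed(fseed, f))
      ev <- eval_one_fit(model, x_all[te, , drop = FALSE],
                         feats$label[te], model$spec)
      fold_mats[[length(fold_mats) + 1L]] <- ev$per_node
      fold_e2e <- c(fold_e2e, ev$end_to_end)
    }
    m <- average_per_node(fold_mats)
    subj_mats[[length(subj_mats) + 1L]] <- m
    subj_acc <- c(subj_acc, mean(m[, "ACC"], na.rm = TRUE))
    subj_e2e <- c(subj_e2e, mean(fold_e2e))
  }
  per_node <- average_per_node(subj_mats)
  detail <- list(subjects = subjects, subject_overall_acc = subj_acc,
                 subject_end_to_end_acc = subj_e2e, k = k,
                 end_to_end_acc = mean(subj_e2e))
  finish_report(per_node, "SDTP", detail, seed, nrow(feats))
}

#' Subject-independent evaluation (leave-one-subject-out CV)
#'
#' One fold per subject: a single hierarchical model is trained on all
#' remaining subjects and evaluated on the held-out subject; metrics
#' are averaged over folds.
#'
#' @inheritParams evaluate_sdtp
#' @return An `hmi_eval`, with per-fold (held-out subject) accuracies
#'   in `detail`.
#' @export
evaluate_sitp <- function(feats, C_grid = 2^seq(-3, 9, by = 2),
                          sigma_grid = 2^seq(-4, 4, by = 1),
                          inner_folds = 5L, seed = 1L) {
  stopifnot(all(meta_cols %in% names(feats)))
  subjects <- unique(feats$subject)
  if (length(subjects) < 2)
    stop("leave-one-subject-out evaluation needs at least 2 subjects")
  x_all <- feature_matrix(feats)
  fold_mats <- list(); fold_acc <- numeric(0); fold_e2e <- numeric(0)
  for (si in seq_along(subjects)) {
    te <- which(feats$subject == subjects[si])
    tr <- which(feats$subject != subjects[si])
    model <- fit_hierarchy(x_all[tr, , drop = FALSE], feats$label[tr],
                           C_grid, sigma_grid, inner_folds,
                           split_seed(seed, si))
    ev <- eval_one_fit(model, x_all[te, , drop = FALSE],
                       feats$label[te], model$spec)
    fold_mats[[length(fold_mats) + 1L]] <- ev$per_node
    fold_acc <- c(fold_acc, mean(ev$per_node[, "ACC"], na.rm = TRUE))
    fold_e2e <- c(fold_e2e, ev$end_to_end)
  }
  per_node <- average_per_node(fold_mats)
  detail <- list(subjects = subjects, subject_overall_acc = fold_acc,
                 subject_end_to_end_acc = fold_e2e,
                 end_to_end_acc = mean(fold_e2e))
  finish_report(per_node, "SITP", detail, seed, nrow(feats))
}

#' @export
print.hmi_eval <- function(x, digits = 1, ...) {
  cat("<hmi_eval> protocol: ", x$protocol, ", ", x$n_samples,
      " segments, ", length(x$detail$subjects), " subject(s)\n", sep = "")
  tab <- rbind(x$per_node, `Overall average` = x$overall)
  print(round(tab, digits))
  cat("End-to-end 11-class accuracy: ",
      round(x$detail$end_to_end_acc, digits), "%\n", sep = "")
  invisible(x)
}

#' Write an evaluation report
#'
#' Emits the report as JSON and, optionally, as a delimited node-by-
#' metric table mirroring the layout used for per-node results.
#'
#' @param report an `hmi_eval`.
#' @param path JSON destination.
#' @param tsv optional TSV destination for the metric table.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, tsv = NULL) {
  stopifnot(inherits(report, "hmi_eval"))
  jsonlite::write_json(
    list(protocol = report$protocol,
         per_node = as.data.frame(report$per_node),
         overall = as.list(report$overall),
         end_to_end_acc = report$detail$end_to_end_acc,
         subjects = report$detail$subjects,
         subject_overall_acc = report$detail$subject_overall_acc,
         seed = report$seed, n_samples = report$n_samples),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv)) {
    tab <- rbind(report$per_node, `Overall average` = report$overall)
    utils::write.table(data.frame(node = rownames(tab), round(tab, 1)),
                       tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Paired t-test between two accuracy vectors
#'
#' Classical two-sided paired t-test, paired by subject (SDTP) or by
#' held-out subject (SITP). Degenerate zero-variance differences are
#' reported with `p = 1` when the mean difference is 0 and `p = 0`
#' otherwise.
#'
#' @param acc_a,acc_b equal-length accuracy vectors (length >= 2),
#'   paired by unit.
#' @return List with `t` and `p`.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 2)
  d <- acc_a - acc_b
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1))
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  ht <- t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}
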