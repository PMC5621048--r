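#' Structure of the four-layer hierarchical classifier
#'
#' Six classification nodes route a segment from the root to one of the
#' eleven task leaves: CN1 separates rest (A1) from movement (IC1); CN2
#' splits movement into grasps (IC2) versus wrist/finger movements
#' (IC3); CN3 resolves the three grasps (A2, A3, A4); CN4 splits IC3
#' into wrist (IC4) and finger (IC5) movements; CN5 resolves A5/A6; CN6
#' resolves the five finger tasks (A7-A11). CN1, CN2, CN4 and CN5 are
#' binary; CN3 is ternary and CN6 five-way.
#'
#' @return An object of class `hierarchy_spec`: list of nodes, each
#'   with `id`, `outputs` (named list: each output has `leaves`, the
#'   task codes beneath it, and `child`, the next node id or `NA` for a
#'   leaf output).
#' @export
build_hierarchy <- function() {
  node <- function(id, outputs) list(id = id, outputs = outputs)
  out <- function(leaves, child = NA_character_) list(leaves = leaves, child = child)
  spec <- list(
    CN1 = node("CN1", list(A1 = out("A1"),
                           IC1 = out(paste0("A", 2:11), "CN2"))),
    CN2 = node("CN2", list(IC2 = out(paste0("A", 2:4), "CN3"),
                           IC3 = out(paste0("A", 5:11), "CN4"))),
    CN3 = node("CN3", list(A2 = out("A2"), A3 = out("A3"), A4 = out("A4"))),
    CN4 = node("CN4", list(IC4 = out(c("A5", "A6"), "CN5"),
                           IC5 = out(paste0("A", 7:11), "CN6"))),
    CN5 = node("CN5", list(A5 = out("A5"), A6 = out("A6"))),
    CN6 = node("CN6", list(A7 = out("A7"), A8 = out("A8"), A9 = out("A9"),
                           A10 = out("A10"), A11 = out("A11"))))
  structure(spec, class = "hierarchy_spec")
}

node_leaves <- function(node) unique(unlist(lapply(node$outputs, `[[`, "leaves")))

#' Root-to-leaf path of a task code
#'
#' @param leaf one of `"A1"`..`"A11"`.
#' @param spec a [build_hierarchy()] spec.
#' @return Named character vector: for each visited node, the output it
#'   takes.
#' @export
hierarchy_path <- function(leaf, spec = build_hierarchy()) {
  stopifnot(leaf %in% HMI_CLASSES)
  path <- character(0)
  at <- "CN1"
  while (!is.na(at)) {
    node <- spec[[at]]
    hit <- vapply(node$outputs, function(o) leaf %in% o$leaves, logical(1))
    out_name <- names(node$outputs)[hit]
    path[at] <- out_name
    at <- node$outputs[[out_name]]$child
  }
  path
}

#' Training subset and relabeling for one node
#'
#' Selects the samples whose true task lies beneath the node and
#' relabels them to the node's immediate outputs (e.g. CN2 sees IC2 for
#' A2-A4 and IC3 for A5-A11).
#'
#' @param labels character vector of task codes `A1`..`A11`.
#' @param node_id one of `"CN1"`..`"CN6"`.
#' @param spec a [build_hierarchy()] spec.
#' @return List with `index` (positions of the retained samples) and
#'   `labels` (factor over the node's outputs, in output order).
#' @export
node_training_labels <- function(labels, node_id, spec = build_hierarchy()) {
  if (!node_id %in% names(spec)) stop("unknown node: ", node_id)
  bad <- setdiff(unique(labels), HMI_CLASSES)
  if (length(bad)) stop("unknown task codes: ", paste(bad, collapse = ", "))
  node <- spec[[node_id]]
  map <- character(0)
  for (out_name in names(node$outputs))
    map[node$outputs[[out_name]]$leaves] <- out_name
  keep <- which(labels %in% names(map))
  list(index = keep,
       labels = factor(map[labels[keep]], levels = names(node$outputs)))
}

# --- one-against-one RBF-SVM ensemble ---------------------------------

rbf_gamma <- function(sigma) 1 / (2 * sigma^2)

fit_oao <- function(x, y, C, sigma) {
  classes <- levels(y)
  n_class <- length(classes)
  pairs <- utils::combn(n_class, 2)
  fits <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    sel <- y %in% classes[c(i, j)]
    yy <- factor(as.character(y[sel]), levels = classes[c(i, j)])
    fits[[p]] <- list(i = i, j = j,
                      fit = e1071::svm(x[sel, , drop = FALSE], yy,
                                       type = "C-classification",
                                       kernel = "radial",
                                       gamma = rbf_gamma(sigma), cost = C,
                                       scale = FALSE))
  }
  structure(list(classes = classes, fits = fits, C = C, sigma = sigma),
            class = "oao_svm")
}

#' @export
predict.oao_svm <- function(object, newdata, ...) {
  n <- nrow(newdata)
  votes <- matrix(0L, n, length(object$classes))
  for (f in object$fits) {
    pred <- as.character(predict(f$fit, newdata))
    votes[, f$i] <- votes[, f$i] + (pred == object$classes[f$i])
    votes[, f$j] <- votes[, f$j] + (pred == object$classes[f$j])
  }
  # majority vote; ties resolved toward the lowest class index
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(as.character(y))) {
    idx <- which(as.character(y) == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Grid-searched node classifier
#'
#' Trains the RBF max-margin classifier of one node: every `(C, sigma)`
#' pair on the grid is scored by stratified inner cross-validation on
#' the training samples only, the pair with the highest mean inner
#' accuracy wins (ties broken toward smaller `C`, then larger `sigma`),
#' and the winning configuration is refit on all training samples.
#' Multiclass nodes are one-against-one ensembles of `n(n-1)/2` binary
#' classifiers with majority vote.
#'
#' @param x numeric feature matrix (rows = samples), already scaled.
#' @param y factor of node-output labels (see [node_training_labels()]).
#' @param node_id node identifier (metadata).
#' @param C_grid,sigma_grid numeric grids for the regularization and
#'   kernel-width parameters.
#' @param inner_folds inner CV folds (default 5).
#' @param seed RNG seed for the inner fold assignment.
#' @return A `node_model`: list with the fitted `oao_svm`, chosen `C`,
#'   `sigma`, the inner-CV accuracy table and per-class counts.
#' @export
grid_search_train <- function(x, y, node_id = NA_character_,
                              C_grid = 2^seq(-3, 9, by = 2),
                              sigma_grid = 2^seq(-4, 4, by = 1),
                              inner_folds = 5L, seed = 1L) {
  y <- droplevels_check(y, node_id)
  if (length(C_grid) < 1 || length(sigma_grid) < 1) stop("empty grid")
  counts <- table(y)
  if (any(counts < 2)) stop("node ", node_id, ": need >= 2 samples per class")
  grid <- expand.grid(C = C_grid, sigma = sigma_grid)
  folds <- stratified_folds(y, min(inner_folds, min(counts)), seed)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fold_acc <- rep(NA_real_, max(folds))
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      if (length(unique(y[tr])) < nlevels(y)) next
      m <- fit_oao(x[tr, , drop = FALSE], y[tr], grid$C[g], grid$sigma[g])
      fold_acc[f] <- mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }
    acc[g] <- mean(fold_acc, na.rm = TRUE)
  }
  # maximize accuracy; ties -> smaller C, then larger sigma
  best <- order(-acc, grid$C, -grid$sigma)[1L]
  model <- fit_oao(x, y, grid$C[best], grid$sigma[best])
  structure(list(node_id = node_id, model = model, C = grid$C[best],
                 sigma = grid$sigma[best], cv_accuracy = acc[best],
                 grid = cbind(grid, accuracy = acc),
                 n_per_class = as.integer(counts), seed = seed),
            class = "node_model")
}

droplevels_check <- function(y, node_id) {
  y <- as.factor(y)
  if (any(table(y) == 0))
    stop("node ", node_id, ": class absent from training data: ",
         paste(levels(y)[table(y) == 0], collapse = ", "))
  y
}

# --- full hierarchy ----------------------------------------------------

#' Fit the four-layer hierarchical model
#'
#' Standardizes the features (z-score with training statistics;
#' constant features get unit scale), then trains the six node
#' classifiers with [grid_search_train()], each on the samples beneath
#' it, relabeled to its immediate outputs.
#'
#' @param x numeric feature matrix, one row per segment.
#' @param y task codes `A1`..`A11`, one per row.
#' @param C_grid,sigma_grid hyperparameter grids (log-spaced defaults).
#' @param inner_folds inner CV folds for the grid search.
#' @param seed RNG seed; node-level seeds are derived from it.
#' @param spec hierarchy layout, default [build_hierarchy()].
#' @return An object of class `hmi_hierarchy` with the node models,
#'   the scaler and the feature index.
#' @export
fit_hierarchy <- function(x, y, C_grid = 2^seq(-3, 9, by = 2),
                          sigma_grid = 2^seq(-4, 4, by = 1),
                          inner_folds = 5L, seed = 1L,
                          spec = build_hierarchy()) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  xs <- scale(x, center, scale_)
  nodes <- vector("list", length(spec)); names(nodes) <- names(spec)
  for (i in seq_along(spec)) {
    id <- names(spec)[i]
    sub <- node_training_labels(y, id, spec)
    nodes[[id]] <- grid_search_train(xs[sub$index, , drop = FALSE],
                                     sub$labels, id, C_grid, sigma_grid,
                                     inner_folds, split_seed(seed, i))
  }
  structure(list(spec = spec, nodes = nodes, center = center,
                 scale = scale_, feature_names = colnames(x), seed = seed),
            class = "hmi_hierarchy")
}

#' @export
predict.hmi_hierarchy <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names))
    stop("feature index of newdata does not match the trained model")
  if (ncol(newdata) != length(object$center))
    stop("feature index of newdata does not match the trained model")
  xs <- scale(newdata, object$center, object$scale)
  at <- rep("CN1", nrow(xs))
  out <- rep(NA_character_, nrow(xs))
  for (id in names(object$spec)) {
    here <- which(at == id)
    if (!length(here)) next
    node <- object$spec[[id]]
    dec <- as.character(predict(object$nodes[[id]]$model,
                                xs[here, , drop = FALSE]))
    for (out_name in names(node$outputs)) {
      sel <- here[dec == out_name]
      if (!length(sel)) next
      child <- node$outputs[[out_name]]$child
      if (is.na(child)) out[sel] <- out_name else at[sel] <- child
    }
  }
  factor(out, levels = HMI_CLASSES)
}

#' @export
print.hmi_hierarchy <- function(x, ...) {
  cat("<hmi_hierarchy> four-layer hierarchical RBF-SVM model\n")
  for (id in names(x$nodes)) {
    nm <- x$nodes[[id]]
    cat(sprintf("  %s: %d-way, %d binary classifier(s), C = %g, sigma = %g, inner-CV acc = %.3f\n",
                id, length(nm$model$classes), length(nm$model$fits),
                nm$C, nm$sigma, nm$cv_accuracy))
  }
  invisible(x)
}

#' @export
summary.hmi_hierarchy <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$nodes, function(nm)
    data.frame(node = nm$node_id, classes = length(nm$model$classes),
               binary_classifiers = length(nm$model$fits), C = nm$C,
               sigma = nm$sigma, inner_cv_accuracy = nm$cv_accuracy)))
  rownames(tab) <- NULL
  tab
}
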