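test_that("hierarchy layout routes every task through exactly one path", {
  spec <- build_hierarchy()
  expect_named(spec, paste0("CN", 1:6))
  arity <- vapply(spec, function(nd) length(nd$outputs), 0L)
  expect_identical(unname(arity), c(2L, 2L, 3L, 2L, 2L, 5L))
  leaves <- unlist(lapply(spec, function(nd)
    lapply(nd$outputs, function(o) if (is.na(o$child)) o$leaves)))
  expect_setequal(unname(leaves), hmi_classes())
  expect_length(leaves, 11L)
  # each leaf reachable by exactly one root-to-leaf path
  for (leaf in hmi_classes()) {
    path <- hierarchy_path(leaf)
    expect_identical(unname(path[length(path)]), leaf)
  }
  expect_identical(hierarchy_path("A6"),
                   c(CN1 = "IC1", CN2 = "IC3", CN4 = "IC4", CN5 = "A6"))
  expect_identical(hierarchy_path("A1"), c(CN1 = "A1"))
})

test_that("node training labels subset and relabel to immediate outputs", {
  labels <- rep(hmi_classes(), each = 2)
  cn1 <- node_training_labels(labels, "CN1")
  expect_length(cn1$index, 22L)
  expect_identical(levels(cn1$labels), c("A1", "IC1"))
  expect_identical(sum(cn1$labels == "A1"), 2L)
  expect_identical(sum(cn1$labels == "IC1"), 20L)
  cn2 <- node_training_labels(labels, "CN2")
  expect_length(cn2$index, 20L)
  expect_identical(as.character(cn2$labels[1:2]), c("IC2", "IC2"))
  cn5 <- node_training_labels(labels, "CN5")
  expect_identical(sort(unique(labels[cn5$index])), c("A5", "A6"))
  cn6 <- node_training_labels(labels, "CN6")
  expect_identical(levels(cn6$labels), paste0("A", 7:11))
  expect_identical(as.character(cn6$labels),
                   rep(paste0("A", 7:11), each = 2))
  expect_error(node_training_labels(labels, "CN9"), "unknown")
  expect_error(node_training_labels(c("A1", "B2"), "CN1"), "unknown")
})

test_that("one-against-one ensembles hold n(n-1)/2 binary classifiers", {
  set.seed(12)
  mk <- function(classes, n = 12, d = 4, sep = 10) {
    y <- factor(rep(classes, each = n), levels = classes)
    x <- t(vapply(as.integer(y), function(ci)
      rnorm(d, mean = c(ci * sep, rep(0, d - 1))), numeric(d)))
    list(x = x, y = y)
  }
  d3 <- mk(c("A2", "A3", "A4"))
  n3 <- grid_search_train(d3$x, d3$y, "CN3", C_grid = 1, sigma_grid = 4,
                          inner_folds = 3, seed = 1)
  expect_length(n3$model$fits, 3L)
  d5 <- mk(paste0("A", 7:11))
  n5 <- grid_search_train(d5$x, d5$y, "CN6", C_grid = 1, sigma_grid = 4,
                          inner_folds = 3, seed = 1)
  expect_length(n5$model$fits, 10L)
  d2 <- mk(c("A5", "A6"))
  n2 <- grid_search_train(d2$x, d2$y, "CN5", C_grid = 1, sigma_grid = 4,
                          inner_folds = 3, seed = 1)
  expect_length(n2$model$fits, 1L)
})

test_that("grid search finds separable solutions and applies tie policy", {
  set.seed(13)
  n <- 30; d <- 8
  x <- rbind(matrix(rnorm(n * d, 0), n, d), matrix(rnorm(n * d, 10), n, d))
  y <- factor(rep(c("a", "b"), each = n))
  nm <- grid_search_train(x, y, "CN1", C_grid = c(0.5, 8),
                          sigma_grid = c(1, 4), inner_folds = 5, seed = 2)
  expect_gte(nm$cv_accuracy, 0.99)
  single <- grid_search_train(x, y, "CN1", C_grid = 2, sigma_grid = 3,
                              inner_folds = 3, seed = 2)
  expect_equal(single$C, 2)
  expect_equal(single$sigma, 3)
  # ties break toward smaller C then larger sigma: on perfectly
  # separable data every grid point reaches accuracy 1
  tie <- grid_search_train(x, y, "CN1", C_grid = c(4, 1),
                           sigma_grid = c(2, 8), inner_folds = 3,
                           seed = 2)
  expect_true(all(abs(tie$grid$accuracy - 1) < 1e-12))
  expect_equal(tie$C, 1)
  expect_equal(tie$sigma, 8)
  expect_error(grid_search_train(x[1:30, ], factor(rep("a", 30),
                                                   levels = c("a", "b")),
                                 "CN1", 1, 1),
               "absent|samples per class")
})

test_that("majority vote ties resolve to the lowest class index", {
  classes <- c("A2", "A3", "A4")
  fits <- list(list(i = 1L, j = 2L, fit = const_model(classes[1:2], "A2")),
               list(i = 1L, j = 3L, fit = const_model(classes[c(1, 3)], "A4")),
               list(i = 2L, j = 3L, fit = const_model(classes[2:3], "A3")))
  oao <- structure(list(classes = classes, fits = fits), class = "oao_svm")
  pred <- predict(oao, matrix(0, 2, 3)) # one vote each: tie of all three
  expect_identical(as.character(pred), c("A2", "A2"))
})

test_that("routing with oracle nodes reproduces every leaf", {
  spec <- build_hierarchy()
  nodes <- lapply(spec, function(nd)
    list(node_id = nd$id, model = lookup_model(nd)))
  model <- structure(list(spec = spec, nodes = nodes,
                          center = rep(0, 3), scale = rep(1, 3),
                          feature_names = NULL, seed = 1L),
                     class = "hmi_hierarchy")
  x <- cbind(1:11, 0, 0) # first feature encodes the true class index
  pred <- predict(model, x)
  expect_identical(as.character(pred), hmi_classes())
  # cascade masking: a CN1 stuck on IC1 can never emit A1
  nodes$CN1$model <- const_model(c("A1", "IC1"), "IC1")
  model$nodes <- nodes
  pred2 <- predict(model, x)
  expect_false(any(pred2 == "A1"))
  expect_identical(as.character(pred2[2:11]), hmi_classes()[2:11])
})

test_that("hierarchical training is reproducible and learns blob data", {
  feats <- make_blob_features(n_subjects = 1, per_class = 6, sep = 8,
                              seed = 31)
  x <- as.matrix(feats[, grep("^F", names(feats))])
  y <- feats$label
  m1 <- fit_hierarchy(x, y, C_grid = c(1, 8), sigma_grid = c(1, 4),
                      inner_folds = 2, seed = 9)
  m2 <- fit_hierarchy(x, y, C_grid = c(1, 8), sigma_grid = c(1, 4),
                      inner_folds = 2, seed = 9)
  expect_identical(summary(m1), summary(m2))
  expect_identical(as.character(predict(m1, x)), as.character(predict(m2, x)))
  # resubstitution on wide-margin blobs is essentially perfect
  expect_gte(mean(as.character(predict(m1, x)) == y), 0.95)
  expect_error(predict(m1, x[, 1:3]), "feature index")
})
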