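# Independent direct-summation oracles, written from the defining
# equations with plain loops; deliberately naive and separate from the
# package implementation.

# instantaneous autocorrelation with ceil/floor integer-lag indexing
oracle_autocorr <- function(s, L) {
  W <- length(s)
  K <- matrix(0 + 0i, W, L)
  for (k in -(W - 1):(W - 1)) {
    up <- ceiling(k / 2)
    dn <- floor(k / 2)
    cc <- (k %% L) + 1L
    for (n in 0:(W - 1)) {
      ia <- n + up; ib <- n - dn
      if (ia >= 0 && ia < W && ib >= 0 && ib < W)
        K[n + 1, cc] <- s[ia + 1] * Conj(s[ib + 1])
    }
  }
  K
}

# full Cohen-class chain by explicit summation: time -> Doppler,
# kernel weighting, Doppler -> time, lag -> frequency (2N bins, keep N)
oracle_tfd <- function(s, N, family = "cwd", gamma = 0.5, fs = 1) {
  W <- length(s)
  L <- 2L * N
  K <- oracle_autocorr(s, L)
  if (family == "cwd") {
    A <- matrix(0 + 0i, W, L)
    for (m in 0:(W - 1)) for (cc in 0:(L - 1)) {
      acc <- 0 + 0i
      for (n in 0:(W - 1))
        acc <- acc + K[n + 1, cc + 1] * exp(-2i * pi * m * n / W)
      A[m + 1, cc + 1] <- acc
    }
    for (m in 0:(W - 1)) for (cc in 0:(L - 1)) {
      phi <- if (m <= W / 2) m / W else (m - W) / W
      tau <- if (cc < N) cc else cc - L
      A[m + 1, cc + 1] <- A[m + 1, cc + 1] * exp(-(phi * tau)^2 / gamma^2)
    }
    for (n in 0:(W - 1)) for (cc in 0:(L - 1)) {
      acc <- 0 + 0i
      for (m in 0:(W - 1))
        acc <- acc + A[m + 1, cc + 1] * exp(2i * pi * m * n / W)
      K[n + 1, cc + 1] <- acc / W
    }
  }
  G <- matrix(0 + 0i, W, N)
  for (n in 0:(W - 1)) for (f in 0:(N - 1)) {
    acc <- 0 + 0i
    for (cc in 0:(L - 1))
      acc <- acc + K[n + 1, cc + 1] * exp(-2i * pi * f * cc / L)
    G[n + 1, f + 1] <- acc / fs
  }
  Re(G)
}

# feature oracles: plain-loop translations of the printed definitions
oracle_floor <- function(a, eps = 1e-12) pmax(a, eps * max(a, .Machine$double.xmin))

oracle_tf <- function(G) {
  W <- nrow(G); N <- ncol(G); n <- W * N
  a <- oracle_floor(abs(G))
  m <- sum(G) / n
  v <- sum((G - m)^2) / n
  q <- function(col) {
    srt <- sort(col)
    srt[round(3 * (W + 1) / 4)] - srt[round((W + 1) / 4)]
  }
  tf4 <- mean(apply(G, 2, q))
  flux <- 0
  for (t in 1:(W - 1)) for (f in 1:(N - 1))
    flux <- flux + G[t + 1, f + 1] - G[t, f]
  p <- G / sum(G)
  c(TF1 = sum(log(a)),
    TF2 = sum(abs(G - m)) / n,
    TF3 = sqrt(sum(G^2) / n),
    TF4 = tf4,
    TF5 = m,
    TF6 = v,
    TF7 = sum((G - m)^3) / n / v^1.5,
    TF8 = sum((G - m)^4) / n / v^2,
    TF9 = n * prod(a^(1 / n)) / sum(a),
    TF10 = flux,
    TF11 = -0.5 * log2(sum(p^3)),
    TF12 = sum(abs(G)^2))
}

rel_err <- function(x, ref) abs(x - ref) / pmax(abs(ref), 1e-300)

rel_l2 <- function(x, ref) sqrt(sum((x - ref)^2) / sum(ref^2))

# Gaussian-blob feature table for exercising the classifier/evaluation
# machinery without the signal pipeline: distinct class means scaled by
# `sep`, shared across subjects up to a per-subject shift of size
# `subject_shift`.
make_blob_features <- function(n_subjects = 2, per_class = 6, d = 8,
                               sep = 6, subject_shift = 0, seed = 1) {
  set.seed(seed)
  classes <- hmi_classes()
  mu <- matrix(rnorm(length(classes) * d), length(classes), d)
  mu <- mu / sqrt(rowSums(mu^2)) * sep
  rows <- list()
  for (si in seq_len(n_subjects)) {
    shift <- rnorm(d, 0, subject_shift)
    for (ci in seq_along(classes)) for (r in seq_len(per_class)) {
      x <- mu[ci, ] + shift + rnorm(d)
      rows[[length(rows) + 1L]] <- c(
        list(subject = sprintf("S%02d", si),
             trial = sprintf("S%02d_%s_T%02d", si, classes[ci], r),
             label = classes[ci], window = 1L),
        as.list(structure(x, names = paste0("F", seq_len(d)))))
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

# constant-output node stand-in, dispatchable through predict()
const_model <- function(classes, out) {
  structure(list(classes = classes, out = out), class = "const_model")
}
predict.const_model <- function(object, newdata, ...) {
  factor(rep(object$out, nrow(newdata)), levels = object$classes)
}
registerS3method("predict", "const_model", predict.const_model,
                 envir = asNamespace("stats"))

# node stand-in that reads the true class index from the first feature
# column and answers with the node output on the true leaf's path
lookup_model <- function(node) {
  structure(list(node = node, classes = names(node$outputs)),
            class = "lookup_model")
}
predict.lookup_model <- function(object, newdata, ...) {
  leaf <- hmi_classes()[round(newdata[, 1])]
  out <- vapply(leaf, function(lf) {
    hit <- vapply(object$node$outputs, function(o) lf %in% o$leaves,
                  logical(1))
    # a mis-routed sample still gets a decision: first output
    if (any(hit)) names(object$node$outputs)[hit][1]
    else names(object$node$outputs)[1]
  }, "")
  factor(out, levels = object$classes)
}
registerS3method("predict", "lookup_model", predict.lookup_model,
                 envir = asNamespace("stats"))
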