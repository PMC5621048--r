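HMI_FEATURES <- paste0("TF", 1:12)
HMI_FEATURE_CATEGORIES <- list(
  C1 = "TF1",
  C2 = c("TF2", "TF3", "TF4"),
  C3 = c("TF5", "TF6", "TF7", "TF8"),
  C4 = c("TF9", "TF10"),
  C5 = c("TF11", "TF12"))

#' Feature categories
#'
#' The twelve time-frequency features fall into five categories:
#' log-amplitude (C1: TF1), amplitude (C2: TF2-TF4), statistical
#' (C3: TF5-TF8), spectral (C4: TF9-TF10) and spectral entropy
#' (C5: TF11-TF12).
#'
#' @param categories subset of `c("C1","C2","C3","C4","C5")`.
#' @return Ordered character vector of the feature ids in those
#'   categories.
#' @export
features_in_categories <- function(categories = names(HMI_FEATURE_CATEGORIES)) {
  bad <- setdiff(categories, names(HMI_FEATURE_CATEGORIES))
  if (length(bad)) stop("unknown feature categories: ", paste(bad, collapse = ", "))
  feats <- unlist(HMI_FEATURE_CATEGORIES[names(HMI_FEATURE_CATEGORIES) %in%
                                           categories], use.names = FALSE)
  HMI_FEATURES[HMI_FEATURES %in% feats]
}

as_tf_matrix <- function(G) {
  if (inherits(G, "hmi_tfr")) G <- G$gamma_matrix
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  G
}

# magnitude floor applied before log / geometric-mean operations
tf_floor <- function(absG, eps_rel = 1e-12) {
  pmax(absG, eps_rel * max(absG, .Machine$double.xmin))
}

#' Log-amplitude feature (TF1)
#'
#' Sum of the natural-log magnitudes of all cells. Zero-magnitude cells
#' are floored at `1e-12 * max|G|` so the feature is always finite.
#'
#' @param G a time-frequency matrix or `hmi_tfr`.
#' @return Scalar feature value.
#' @export
tf1_log_amplitude <- function(G) {
  G <- as_tf_matrix(G)
  sum(log(tf_floor(abs(G))))
}

#' Amplitude features (TF2-TF4)
#'
#' TF2 is the mean absolute deviation of the cells about their mean
#' (printed under the name "median absolute deviation", implemented
#' exactly as printed). TF3 is the root mean square of the cells
#' (`tf3 = "literal"` reproduces the printed formula, which is the
#' plain mean). TF4 averages, over frequency bins, the spread between
#' the upper and lower quartile order statistics of the time samples
#' in the bin (ranks `round(3(W+1)/4)` and `round((W+1)/4)` of the
#' sorted column).
#'
#' @param G a time-frequency matrix or `hmi_tfr`.
#' @param tf3 `"rms"` (default) or `"literal"`.
#' @return Scalar feature value.
#' @export
tf2_mad <- function(G) {
  G <- as_tf_matrix(G)
  mean(abs(G - mean(G)))
}

#' @rdname tf2_mad
#' @export
tf3_rms <- function(G, tf3 = c("rms", "literal")) {
  tf3 <- match.arg(tf3)
  G <- as_tf_matrix(G)
  if (tf3 == "rms") sqrt(mean(G^2)) else mean(G)
}

#' @rdname tf2_mad
#' @export
tf4_iqr <- function(G) {
  G <- as_tf_matrix(G)
  if (nrow(G) < 4L) stop("TF4 needs at least 4 time samples per frequency bin")
  cpp_iqr_mean(G)
}

#' Statistical features (TF5-TF8)
#'
#' Mean, variance, skewness and kurtosis of all cells. On a
#' (near-)constant matrix (`TF6 <= 1e-12 * TF5^2`) skewness and
#' kurtosis are undefined; they are returned as 0 with a warning so
#' downstream classifiers stay total.
#'
#' @param G a time-frequency matrix or `hmi_tfr`.
#' @return Scalar feature value.
#' @export
tf5_mean <- function(G) mean(as_tf_matrix(G))

#' @rdname tf5_mean
#' @export
tf6_var <- function(G) {
  G <- as_tf_matrix(G)
  mean((G - mean(G))^2)
}

tf_degenerate_var <- function(m, v) v <= 1e-12 * max(m^2, .Machine$double.xmin)

#' @rdname tf5_mean
#' @export
tf7_skew <- function(G) {
  G <- as_tf_matrix(G)
  m <- mean(G); v <- mean((G - m)^2)
  if (tf_degenerate_var(m, v)) {
    warning("near-constant matrix: skewness degenerate, returning 0")
    return(0)
  }
  mean((G - m)^3) / v^1.5
}

#' @rdname tf5_mean
#' @export
tf8_kurt <- function(G) {
  G <- as_tf_matrix(G)
  m <- mean(G); v <- mean((G - m)^2)
  if (tf_degenerate_var(m, v)) {
    warning("near-constant matrix: kurtosis degenerate, returning 0")
    return(0)
  }
  mean((G - m)^4) / v^2
}

#' Spectral features (TF9-TF10)
#'
#' TF9 is the flatness of the distribution: the ratio of the geometric
#' mean of the cell magnitudes to their arithmetic mean, in (0, 1],
#' equal to 1 for a uniform surface. Magnitudes are floored as in
#' [tf1_log_amplitude()]. TF10 is the flux with unit steps in both
#' directions: the sum of the diagonal first differences
#' `G[t+1, f+1] - G[t, f]`.
#'
#' @param G a time-frequency matrix or `hmi_tfr`.
#' @return Scalar feature value.
#' @export
tf9_flatness <- function(G) {
  G <- as_tf_matrix(G)
  a <- tf_floor(abs(G))
  exp(mean(log(a))) / mean(a)
}

#' @rdname tf9_flatness
#' @export
tf10_flux <- function(G) {
  G <- as_tf_matrix(G)
  W <- nrow(G); N <- ncol(G)
  sum(G[2:W, 2:N] - G[1:(W - 1), 1:(N - 1)])
}

#' Spectral-entropy features (TF11-TF12)
#'
#' TF11 is the normalized Renyi entropy of order 3 (default):
#' `-(1/2) log2 sum p^3` with `p = G / sum(G)`; it is at most
#' `log2(W N)` with equality iff the surface is uniform, and 0 for a
#' point mass. `order = 2` switches to the second-order variant
#' `-log2 sum p^2`. TF12 is the energy concentration `sum |G|^2`.
#'
#' @param G a time-frequency matrix or `hmi_tfr`.
#' @param order Renyi order, 3 (default) or 2.
#' @return Scalar feature value.
#' @export
tf11_renyi <- function(G, order = 3) {
  G <- as_tf_matrix(G)
  tot <- sum(G)
  if (tot == 0) stop("Renyi entropy undefined for a zero-sum matrix")
  p <- G / tot
  if (order == 3) -0.5 * log2(sum(p^3))
  else if (order == 2) -log2(sum(p^2))
  else stop("order must be 2 or 3")
}

#' @rdname tf11_renyi
#' @export
tf12_energy <- function(G) {
  G <- as_tf_matrix(G)
  sum(G^2)
}

#' All selected features of one time-frequency matrix
#'
#' @param G a time-frequency matrix or `hmi_tfr`.
#' @param features ordered subset of `TF1`..`TF12` (default all).
#' @param tf3,renyi_order variant switches, see [tf3_rms()] and
#'   [tf11_renyi()].
#' @return Named numeric vector in feature order.
#' @export
tf_features <- function(G, features = HMI_FEATURES, tf3 = "rms",
                        renyi_order = 3) {
  G <- as_tf_matrix(G)
  bad <- setdiff(features, HMI_FEATURES)
  if (length(bad)) stop("unknown features: ", paste(bad, collapse = ", "))
  tf3 <- match.arg(tf3, c("rms", "literal"))
  res <- cpp_tf_features(G, 1e-12, as.integer(tf3 == "literal"),
                         as.integer(renyi_order))
  out <- res$tf
  names(out) <- HMI_FEATURES
  if (res$degenerate && any(c("TF7", "TF8") %in% features))
    warning("near-constant matrix: skewness/kurtosis degenerate, returning 0")
  if (res$zero_sum && "TF11" %in% features)
    stop("Renyi entropy undefined for a zero-sum matrix")
  out[features]
}

#' Per-channel-group feature vector
#'
#' Concatenates the selected features of one time-frequency matrix per
#' group channel, channel-major in group order, with names
#' `"<channel>:<feature>"` recording provenance.
#'
#' @param tfrs named list of `hmi_tfr` (or matrices), one per channel;
#'   names are electrode labels and must cover the group. All matrices
#'   must share one shape.
#' @param group a `channel_group` (or group name).
#' @param features ordered subset of `TF1`..`TF12`.
#' @param ... passed to [tf_features()].
#' @return Named numeric vector of length
#'   `n_channels * n_selected_features`.
#' @export
extract_features <- function(tfrs, group, features = HMI_FEATURES, ...) {
  if (is.character(group)) group <- channels_in_group(group)
  idx <- match(tolower(group$electrodes), tolower(names(tfrs)))
  if (anyNA(idx))
    stop("missing time-frequency matrices for: ",
         paste(group$electrodes[is.na(idx)], collapse = ", "))
  mats <- lapply(tfrs[idx], as_tf_matrix)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("time-frequency matrices differ in shape across channels")
  out <- unlist(lapply(seq_along(mats), function(i) {
    v <- tf_features(mats[[i]], features, ...)
    names(v) <- paste0(group$electrodes[i], ":", names(v))
    v
  }))
  out
}
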