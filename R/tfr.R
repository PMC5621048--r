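#' Analytic signal of a real segment
#'
#' Forms `s(t) = x(t) + j H{x(t)}` with the Hilbert transform computed
#' by one-sided spectral weighting (zero out negative frequencies,
#' double positive ones, keep DC and Nyquist). The real part of the
#' result is the input segment exactly; the negative-frequency energy
#' of the output is zero up to round-off.
#'
#' @param x finite real vector.
#' @param fs sampling rate in Hz (metadata only).
#' @return An object of class `analytic_segment`: complex vector with
#'   attributes `fs`.
#' @export
analytic_signal <- function(x, fs = 256) {
  if (!is.numeric(x) || !all(is.finite(x))) stop("input must be finite and real")
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  s <- fft(X * h, inverse = TRUE) / n
  s <- complex(real = x, imaginary = Im(s)) # real part is x, exactly
  structure(s, fs = fs, class = "analytic_segment")
}

#' @export
print.analytic_segment <- function(x, ...) {
  cat("<analytic_segment> ", length(x), " samples @ ", attr(x, "fs"),
      " Hz\n", sep = "")
  invisible(x)
}

#' Smoothing-kernel specification
#'
#' @param family `"cwd"` (Choi-Williams, exponential kernel) or
#'   `"wvd"` (Wigner-Ville, kernel identically 1).
#' @param gamma positive cross-term suppression parameter of the
#'   Choi-Williams kernel; smaller values suppress more. Default 0.5.
#' @param form `"denominator"` evaluates `exp(-phi^2 tau^2 / gamma^2)`;
#'   `"multiplicative"` the variant `exp(-phi^2 tau^2 gamma^2)`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("cwd", "wvd"), gamma = 0.5,
                        form = c("denominator", "multiplicative")) {
  family <- match.arg(family)
  form <- match.arg(form)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a positive number")
  structure(list(family = family, gamma = gamma, form = form),
            class = "kernel_spec")
}

#' Kernel value at a Doppler-lag point
#'
#' @param phi Doppler coordinate.
#' @param tau lag coordinate.
#' @param spec a [kernel_spec()].
#' @return Kernel weight in (0, 1]; 1 on both axes (`phi = 0` or
#'   `tau = 0`) and for the Wigner-Ville family everywhere.
#' @export
kernel_value <- function(phi, tau, spec = kernel_spec()) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$family == "wvd") return(rep(1, length(phi * tau)))
  pt2 <- (phi * tau)^2
  if (spec$form == "denominator") exp(-pt2 / spec$gamma^2)
  else exp(-pt2 * spec$gamma^2)
}

#' Ambiguity function of an analytic segment
#'
#' Doppler transform of the instantaneous autocorrelation
#' `K(t, tau) = s(t + tau/2) s*(t - tau/2)` on the discrete grid used by
#' [compute_tfd()]: rows index Doppler (DFT over time, positive-exponent
#' convention), columns index lag (wrapped, length `2N`). The value at
#' `(0, 0)` is the total signal energy `sum |s|^2`, and the matrix is
#' Hermitian under joint sign flip of Doppler and lag.
#'
#' @param seg an [analytic_signal()] (or complex vector).
#' @param N number of non-negative lag bins (half the stored lag axis);
#'   default 512.
#' @return Complex `W x 2N` matrix.
#' @export
ambiguity_function <- function(seg, N = 512L) {
  s <- as.complex(unclass(seg))
  if (anyNA(s)) stop("invalid analytic segment")
  cpp_ambiguity(s, as.integer(N))
}

#' Quadratic time-frequency distribution of an EEG segment
#'
#' Computes the Cohen-class distribution of an analytic segment: the
#' instantaneous autocorrelation is taken on integer lags without
#' interpolation, transformed over time to the ambiguity (Doppler-lag)
#' domain, weighted by the smoothing kernel, transformed back, and
#' finally Fourier-transformed over lag (zero-padded to `2N` points)
#' keeping the `N` non-negative-frequency bins. With the Wigner-Ville
#' kernel the Doppler round trip is the identity and the result is the
#' discrete Wigner-Ville distribution.
#'
#' The matrix is scaled so that the (full-axis) time marginal equals
#' the instantaneous power `|s(t)|^2`; frequency resolution is
#' `fs / (2N)` Hz over `[0, fs/2)`. Negative values, inherent to
#' quadratic distributions, are retained.
#'
#' @param seg an [analytic_signal()].
#' @param spec a [kernel_spec()]; default Choi-Williams with
#'   `gamma = 0.5`.
#' @param N number of frequency bins, `N >= length(seg)`; default 512.
#' @return An object of class `hmi_tfr`: list with `gamma_matrix`
#'   (real `W x N`), `time_axis` (s), `freq_axis` (Hz), `kernel`, `W`,
#'   `N`, `fs` and `im_ratio` (relative norm of the discarded imaginary
#'   residue, checked < 1e-6).
#' @export
compute_tfd <- function(seg, spec = kernel_spec(), N = 512L) {
  stopifnot(inherits(spec, "kernel_spec"))
  s <- as.complex(unclass(seg))
  W <- length(s)
  N <- as.integer(N)
  if (N < W) stop("N (", N, ") must be at least the window length W (", W, ")")
  fs <- attr(seg, "fs")
  if (is.null(fs)) fs <- 256
  res <- cpp_tfd(s, N, family = if (spec$family == "cwd") 1L else 0L,
                 gamma_par = spec$gamma,
                 mult_form = if (spec$form == "multiplicative") 1L else 0L,
                 fs = fs)
  if (res$im_ratio > 1e-6)
    warning("imaginary residue of the distribution is unexpectedly large: ",
            format(res$im_ratio))
  structure(list(gamma_matrix = res$gamma,
                 time_axis = (seq_len(W) - 1) / fs,
                 freq_axis = (seq_len(N) - 1) * fs / (2 * N),
                 kernel = spec, W = W, N = N, fs = fs,
                 im_ratio = res$im_ratio),
            class = "hmi_tfr")
}

#' @export
print.hmi_tfr <- function(x, ...) {
  cat("<hmi_tfr> ", x$W, " x ", x$N, " (time x frequency), fs = ", x$fs,
      " Hz, kernel = ", x$kernel$family,
      if (x$kernel$family == "cwd") paste0(" (gamma = ", x$kernel$gamma, ")"),
      "\n", sep = "")
  cat("  frequency resolution ", format(x$fs / (2 * x$N), digits = 4),
      " Hz over [0, ", x$fs / 2, ") Hz\n", sep = "")
  invisible(x)
}

#' @export
plot.hmi_tfr <- function(x, ...) {
  graphics::image(x$time_axis, x$freq_axis, pmax(x$gamma_matrix, 0),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  main = paste0(toupper(x$kernel$family),
                                " time-frequency representation"), ...)
  invisible(x)
}

#' Export a time-frequency representation
#'
#' Writes the matrix as delimited text next to a JSON header carrying
#' `W`, `N`, `fs`, kernel family and gamma.
#'
#' @param tfr an `hmi_tfr`.
#' @param path base path; `<path>.tsv` and `<path>.json` are written.
#' @return Base path, invisibly.
#' @export
write_tfr <- function(tfr, path) {
  stopifnot(inherits(tfr, "hmi_tfr"))
  utils::write.table(tfr$gamma_matrix, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(W = tfr$W, N = tfr$N, fs = tfr$fs,
                            family = tfr$kernel$family,
                            gamma = tfr$kernel$gamma),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
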