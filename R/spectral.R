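#' Multichannel time-series container
#'
#' @param data channels x time numeric matrix (volts or tesla).
#' @param sampling_rate Hz.
#' @param labels optional channel labels.
#' @return Object of class `ts_data`.
#' @export
ts_data <- function(data, sampling_rate, labels = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("time series contains non-finite values")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  structure(list(data = data, sampling_rate = sampling_rate, labels = labels),
            class = "ts_data")
}

#' Default analysis frequency grid
#'
#' Positive frequencies df, 2 df, ..., fmax. With the defaults (50 Hz
#' maximum at 0.5 Hz resolution) this is exactly 100 frequencies; 0 Hz is
#' excluded (DC is removed by detrending).
#'
#' @param fmax maximum frequency, Hz.
#' @param df resolution, Hz; must divide fmax.
#' @return Numeric vector of length fmax/df.
#' @export
default_frequency_grid <- function(fmax = 50, df = 0.5) {
  if (df <= 0) stop("df must be > 0")
  k <- fmax / df
  if (abs(k - round(k)) > 1e-9) stop("fmax must be an integer multiple of df")
  seq_len(round(k)) * df
}

#' Default physiological band partition
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 14-30, gamma 30 Hz to
#' 0.9 x Nyquist: the five-band partition used for the band-filtered
#' Hilbert cross-spectral tensor.
#'
#' @param sampling_rate Hz, used to bound gamma; NA leaves the upper gamma
#'   edge symbolic.
#' @return Named list of `c(lo, hi)` band edges in Hz.
#' @export
default_bands <- function(sampling_rate = NA) {
  hi <- if (is.na(sampling_rate)) NA_real_ else 0.9 * sampling_rate / 2
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(14, 30), gamma = c(30, hi))
}

.detrend <- function(x) {
  n <- ncol(x)
  t <- seq_len(n)
  t0 <- t - mean(t)
  beta <- (x %*% t0) / sum(t0^2)
  x - rowMeans(x) - beta %*% t(t0)
}

#' Windowed-segment Fourier coefficients
#'
#' Splits each channel into non-overlapping segments, applies a window,
#' and returns one-sided Fourier coefficients per segment. The frequency
#' resolution is `sampling_rate / segment_length` and the per-frequency
#' sample count is the number of segments.
#'
#' @param x a [ts_data()].
#' @param segment_length samples per segment.
#' @param window "rectangular" or "hann".
#' @param detrend remove per-channel linear trend first.
#' @return Object of class `spectral_coeffs`: complex array
#'   channels x frequencies x segments, `frequencies`, `transform = "fft"`.
#' @export
fft_coefficients <- function(x, segment_length = 256L,
                             window = c("hann", "rectangular"),
                             detrend = TRUE) {
  window <- match.arg(window)
  d <- x$data
  nt <- ncol(d)
  segment_length <- as.integer(segment_length)
  if (segment_length > nt) stop("segment_length exceeds time-series length")
  if (detrend) d <- .detrend(d)
  nseg <- nt %/% segment_length
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(segment_length) / (segment_length + 1))
  } else rep(1, segment_length)
  w <- w / sqrt(mean(w^2))   # unit-power window normalization
  nfreq <- segment_length %/% 2L
  freqs <- seq_len(nfreq) * x$sampling_rate / segment_length
  nch <- nrow(d)
  out <- array(0i, c(nch, nfreq, nseg))
  scale <- 1 / sqrt(segment_length)
  for (s in seq_len(nseg)) {
    seg <- d[, ((s - 1L) * segment_length + 1L):(s * segment_length),
             drop = FALSE]
    seg <- sweep(seg, 2L, w, "*")
    F <- t(stats::mvfft(t(seg))) * scale
    out[, , s] <- F[, 2L:(nfreq + 1L), drop = FALSE]
  }
  structure(list(coeffs = out, frequencies = freqs, transform = "fft",
                 sampling_rate = x$sampling_rate, labels = x$labels),
            class = "spectral_coeffs")
}

# analytic signal per channel after multiplying the spectrum by `gain`
# (a length-nt nonnegative vector over FFT bin frequencies)
.analytic_filtered <- function(d, gain) {
  nt <- ncol(d)
  F <- t(stats::mvfft(t(d)))
  F <- sweep(F, 2L, gain, "*")
  # one-sided analytic spectrum: double positive frequencies, zero negatives
  h <- numeric(nt)
  h[1L] <- 1
  if (nt %% 2L == 0L) {
    h[2L:(nt / 2L)] <- 2; h[nt / 2L + 1L] <- 1
  } else h[2L:((nt + 1L) / 2L)] <- 2
  F <- sweep(F, 2L, h, "*")
  t(stats::mvfft(t(F), inverse = TRUE)) / nt
}

.fft_bin_freqs <- function(nt, rate) {
  k <- 0:(nt - 1L)
  f <- k * rate / nt
  f[f > rate / 2] <- f[f > rate / 2] - rate
  f
}

#' Gaussian-filtered Hilbert transform coefficients
#'
#' For each target frequency, the analytic signal of the data filtered by
#' a Gaussian frequency-domain window centered there. The per-frequency
#' sample count equals the length of the time series, which is why this
#' transform is preferred when many cross-spectral samples are needed; as
#' the bandwidth shrinks it approximates the Fourier representation.
#' The "bandwidth" is two standard deviations of the frequency-domain
#' Gaussian.
#'
#' @param x a [ts_data()].
#' @param frequencies target frequencies, Hz (all below Nyquist).
#' @param bandwidth_hz Gaussian bandwidth (2 sd), Hz; default 1.
#' @param detrend remove linear trend first.
#' @return `spectral_coeffs` with `transform = "gfht"`, coefficient array
#'   channels x frequencies x time.
#' @export
gfht_coefficients <- function(x, frequencies = default_frequency_grid(),
                              bandwidth_hz = 1, detrend = TRUE) {
  if (bandwidth_hz <= 0) stop("bandwidth must be > 0")
  nyq <- x$sampling_rate / 2
  if (any(frequencies >= nyq)) stop("target frequency at or above Nyquist")
  d <- x$data
  if (detrend) d <- .detrend(d)
  nt <- ncol(d); nch <- nrow(d)
  binf <- .fft_bin_freqs(nt, x$sampling_rate)
  sdv <- bandwidth_hz / 2
  out <- array(0i, c(nch, length(frequencies), nt))
  for (k in seq_along(frequencies)) {
    gain <- exp(-((abs(binf) - frequencies[k])^2) / (2 * sdv^2))
    out[, k, ] <- .analytic_filtered(d, gain)
  }
  structure(list(coeffs = out, frequencies = frequencies, transform = "gfht",
                 bandwidth = bandwidth_hz, sampling_rate = x$sampling_rate,
                 labels = x$labels),
            class = "spectral_coeffs")
}

#' Band-filtered Hilbert transform coefficients
#'
#' Zero-phase band-pass (frequency-domain brick-wall) followed by the
#' analytic signal, per band. The default five-band partition yields the
#' five-slice cross-spectral tensor used as the pipeline's default
#' spectral representation.
#'
#' @param x a [ts_data()].
#' @param bands named list of `c(lo, hi)` Hz; defaults to
#'   [default_bands()] bounded by 0.9 x Nyquist.
#' @param detrend remove linear trend first.
#' @return `spectral_coeffs` with `transform = "bfht"`, array
#'   channels x bands x time, `frequencies` = band centers, `bands` kept.
#' @export
bfht_coefficients <- function(x, bands = NULL, detrend = TRUE) {
  nyq <- x$sampling_rate / 2
  if (is.null(bands)) bands <- default_bands(x$sampling_rate)
  bands <- lapply(bands, function(b) {
    if (is.na(b[2L])) b[2L] <- 0.9 * nyq
    b
  })
  ok <- vapply(bands, function(b) b[1L] >= 0 && b[2L] > b[1L] && b[2L] <= nyq,
               TRUE)
  if (!all(ok)) stop("invalid band edges (need 0 <= lo < hi <= Nyquist)")
  d <- x$data
  if (detrend) d <- .detrend(d)
  nt <- ncol(d); nch <- nrow(d)
  binf <- abs(.fft_bin_freqs(nt, x$sampling_rate))
  out <- array(0i, c(nch, length(bands), nt))
  for (k in seq_along(bands)) {
    gain <- as.numeric(binf >= bands[[k]][1L] & binf <= bands[[k]][2L])
    out[, k, ] <- .analytic_filtered(d, gain)
  }
  structure(list(coeffs = out,
                 frequencies = vapply(bands, mean, 1),
                 bands = bands, transform = "bfht",
                 sampling_rate = x$sampling_rate, labels = x$labels),
            class = "spectral_coeffs")
}

#' Hermitian cross-spectral tensor from spectral coefficients
#'
#' Per frequency (or band), the Hermitian covariance of the coefficient
#' samples, S_f = (1/m) sum_k z_k z_k^H; coefficients are zero-mean by
#' construction so no mean is removed. Every frontal slice is Hermitian
#' positive semidefinite; the effective sample count m is recorded.
#'
#' @param coeffs a `spectral_coeffs`.
#' @return Object of class `cross_spectrum`: `S` (n x n x F complex),
#'   `frequencies`, `m`, `labels`, `transform`.
#' @export
cross_spectrum <- function(coeffs) {
  a <- coeffs$coeffs
  nch <- dim(a)[1L]; nf <- dim(a)[2L]; m <- dim(a)[3L]
  if (m < 2L) warning("single spectral sample: rank-1 cross-spectral slices")
  S <- array(0i, c(nch, nch, nf))
  for (k in seq_len(nf)) {
    Z <- matrix(a[, k, ], nch, m)
    Sk <- (Z %*% Conj(t(Z))) / m
    S[, , k] <- (Sk + Conj(t(Sk))) / 2
  }
  structure(list(S = S, frequencies = coeffs$frequencies, m = m,
                 labels = coeffs$labels, transform = coeffs$transform,
                 bands = coeffs$bands),
            class = "cross_spectrum")
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat(sprintf("cross_spectrum: %d x %d x %d (%s), m = %d\n",
              dim(x$S)[1L], dim(x$S)[2L], dim(x$S)[3L], x$transform, x$m))
  invisible(x)
}

# hermitian PSD checks used across modules
is_hermitian <- function(M, tol = 1e-10) {
  nm <- sqrt(sum(Mod(M)^2))
  if (nm == 0) return(TRUE)
  sqrt(sum(Mod(M - Conj(t(M)))^2)) < tol * nm
}
min_eig_ratio <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(ev) / max(abs(ev))
}
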