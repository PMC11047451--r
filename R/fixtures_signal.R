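#' Oscillatory source-network specification
#'
#' Ground truth for the recovery fixtures: a set of band-limited coupled
#' stationary Gaussian sources whose theoretical cross-spectrum is known
#' in closed form. The coupling matrix is a Hermitian coherency target
#' with unit diagonal on the active set.
#'
#' @param n_sources total sources.
#' @param active integer indices of active sources.
#' @param center_hz,bandwidth_hz Gaussian spectral bump location/width
#'   (bandwidth = 2 sd).
#' @param amplitude RMS amplitude of the active oscillation.
#' @param coupling Hermitian matrix (length(active) square, unit
#'   diagonal, PSD) of coherency targets; NULL = independent sources.
#' @param noise_floor white background standard-deviation per source.
#' @param n_time total samples; sampling_rate Hz; seed RNG seed.
#' @param sampling_rate sampling rate in Hz.
#' @param seed integer seed.
#' @return Object of class `osc_network_spec`.
#' @export
osc_network_spec <- function(n_sources, active, center_hz = 10,
                             bandwidth_hz = 2, amplitude = 1,
                             coupling = NULL, noise_floor = 0.05,
                             n_time = 6000L, sampling_rate = 200,
                             seed = 1L) {
  if (any(active < 1L | active > n_sources)) stop("active set out of range")
  if (!is.null(coupling)) {
    coupling <- as.matrix(coupling)
    if (nrow(coupling) != length(active)) stop("coupling/active size mismatch")
    if (!is_hermitian(coupling, tol = 1e-8)) stop("coupling must be Hermitian")
    if (max(abs(Re(diag(coupling)) - 1)) > 1e-8)
      stop("coupling must have unit diagonal")
    if (min_eig_ratio(coupling) < -1e-10)
      stop("coupling matrix must be positive semidefinite")
  }
  structure(list(n_sources = as.integer(n_sources), active = as.integer(active),
                 center_hz = center_hz, bandwidth_hz = bandwidth_hz,
                 amplitude = amplitude, coupling = coupling,
                 noise_floor = noise_floor, n_time = as.integer(n_time),
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "osc_network_spec")
}

# theoretical source cross-spectral density at frequency f (n x n complex);
# density convention matches fft_coefficients with a rectangular window:
# E[z z^H] at bin f equals this matrix
theoretical_source_csd <- function(spec, f) {
  n <- spec$n_sources
  S <- diag(spec$noise_floor^2, n) + 0i
  sdv <- spec$bandwidth_hz / 2
  g <- exp(-((f - spec$center_hz)^2) / (2 * sdv^2))
  C <- if (is.null(spec$coupling)) diag(length(spec$active)) + 0i
       else spec$coupling
  amp2 <- spec$amplitude^2 * g
  S[spec$active, spec$active] <- S[spec$active, spec$active] + amp2 * C
  S
}

#' Simulate stationary oscillatory sources with known cross-spectra
#'
#' Builds the sources segment-wise in the frequency domain: per segment
#' and per positive FFT bin an independent complex Gaussian vector with
#' the theoretical cross-spectral covariance, then an inverse FFT with
#' conjugate symmetry yields real stationary Gaussian series. The
#' returned theoretical tensor is exact for the matching rectangular-
#' window FFT estimator.
#'
#' @param spec an [osc_network_spec()].
#' @param segment_length samples per segment (default 200).
#' @return List: `sources` ([ts_data()]), `theoretical` (function(f) ->
#'   n x n complex CSD), `segment_length`.
#' @export
simulate_oscillatory_sources <- function(spec, segment_length = 200L) {
  set.seed(spec$seed)
  n <- spec$n_sources
  nseg <- spec$n_time %/% segment_length
  if (nseg < 1L) stop("n_time shorter than one segment")
  nfreq <- segment_length %/% 2L
  freqs <- seq_len(nfreq) * spec$sampling_rate / segment_length
  # precompute matrix square roots of the CSD per bin
  roots <- vector("list", nfreq)
  for (k in seq_len(nfreq)) {
    S <- theoretical_source_csd(spec, freqs[k])
    ee <- eigen(S, symmetric = TRUE)
    roots[[k]] <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * Conj(t(ee$vectors)))
  }
  out <- matrix(0, n, nseg * segment_length)
  for (s in seq_len(nseg)) {
    F <- matrix(0i, n, segment_length)
    for (k in seq_len(nfreq)) {
      z <- (stats::rnorm(n) + 1i * stats::rnorm(n)) / sqrt(2)
      zk <- roots[[k]] %*% z
      F[, k + 1L] <- zk
      if (k < nfreq || segment_length %% 2L == 1L) {
        F[, segment_length - k + 1L] <- Conj(zk)
      } else {
        # Nyquist bin must be real
        F[, k + 1L] <- sqrt(2) * Re(zk)
      }
    }
    # scale so that the rectangular-window FFT estimator (1/sqrt(T) z)
    # recovers E[z z^H] = S(f)
    seg <- Re(t(stats::mvfft(t(F), inverse = TRUE))) / sqrt(segment_length)
    out[, ((s - 1L) * segment_length + 1L):(s * segment_length)] <- seg
  }
  if (spec$amplitude == 0 && spec$noise_floor == 0) out[] <- 0
  list(sources = ts_data(out, spec$sampling_rate,
                         labels = paste0("src", seq_len(n))),
       theoretical = function(f) theoretical_source_csd(spec, f),
       segment_length = segment_length)
}

#' Project source series through a lead field with additive sensor noise
#'
#' v = L j + white Gaussian noise scaled so that the sensor-level
#' signal-to-noise power ratio matches `snr_db`; `snr_db = Inf` gives the
#' noiseless projection.
#'
#' @param L [lead_field()] or matrix (sensors x sources).
#' @param sources a [ts_data()].
#' @param snr_db target SNR in dB.
#' @param seed RNG seed for the noise.
#' @return A [ts_data()] of sensor series.
#' @export
project_to_sensors <- function(L, sources, snr_db = 10, seed = 1L) {
  Lm <- if (inherits(L, "lead_field")) L$matrix else as.matrix(L)
  if (ncol(Lm) != nrow(sources$data)) stop("lead field / source dims mismatch")
  v <- Lm %*% sources$data
  if (is.finite(snr_db)) {
    set.seed(seed)
    psig <- mean(v^2)
    pnoise <- psig / 10^(snr_db / 10)
    noise <- matrix(stats::rnorm(length(v), sd = sqrt(pnoise)), nrow(v))
    v <- v + noise
  }
  ts_data(v, sources$sampling_rate,
          labels = if (inherits(L, "lead_field") && !is.null(L$labels))
            L$labels else paste0("s", seq_len(nrow(v))))
}

#' Paired MEG/EEG spectra tensors from the scaling generative model
#'
#' EEG spectra are drawn log-normal; MEG spectra follow
#' MEG = exp(a_f) * EEG^(b_f) * exp(noise), the generative reading of the
#' per-frequency scaling model, so the regression recovers (a_f, b_f)
#' exactly when noise_sd = 0.
#'
#' @param S,F,C sources, frequencies, cases per modality.
#' @param a_f intercepts (recycled to length F).
#' @param b_f slopes (recycled to length F).
#' @param noise_sd log-scale residual standard deviation.
#' @param base_log_sd spread of the EEG log spectra.
#' @param seed RNG seed.
#' @return List: `meg`, `eeg` ([spectra_tensor()]s, natural scale).
#' @export
make_paired_spectra_tensors <- function(S, F, C, a_f = 1.5, b_f = 0.8,
                                        noise_sd = 0.1, base_log_sd = 1,
                                        seed = 7L) {
  if (S < 1 || F < 1 || C < 1) stop("invalid tensor sizes")
  set.seed(seed)
  a_f <- rep_len(a_f, F); b_f <- rep_len(b_f, F)
  eeg_log <- array(stats::rnorm(S * F * C, sd = base_log_sd), c(S, F, C))
  noise <- if (noise_sd > 0)
    array(stats::rnorm(S * F * C, sd = noise_sd), c(S, F, C))
  else array(0, c(S, F, C))
  meg_log <- array(0, c(S, F, C))
  for (f in seq_len(F))
    meg_log[, f, ] <- a_f[f] + b_f[f] * eeg_log[, f, ] + noise[, f, ]
  list(meg = spectra_tensor(exp(meg_log), "meg"),
       eeg = spectra_tensor(exp(eeg_log), "eeg"))
}

#' Inject a deterministic artifact into a head model or lead field
#'
#' Emulates the failure taxonomy the quality control is built for:
#' `dent_inner_skull` pushes inner-skull vertices inward toward the
#' cortex, `jitter_sensors` perturbs electrode positions, `noise_column`
#' replaces lead-field source columns with Gaussian noise, `blur_mesh`
#' adds vertex-position noise.
#'
#' @param object `head_model`, [sensor_array()] or [lead_field()]
#'   matching the artifact kind.
#' @param kind one of "dent_inner_skull", "jitter_sensors",
#'   "noise_column", "blur_mesh".
#' @param magnitude artifact size: meters for geometric kinds, relative
#'   column norm for `noise_column`.
#' @param targets indices (vertices / sensors / source columns).
#' @param seed RNG seed.
#' @return The corrupted object.
#' @export
inject_artifact <- function(object, kind, magnitude, targets = NULL,
                            seed = 1L) {
  if (magnitude <= 0) stop("artifact magnitude must be > 0")
  set.seed(seed)
  switch(kind,
    dent_inner_skull = {
      if (!inherits(object, "head_model")) stop("need a head_model")
      v <- object$inner_skull$vertices
      if (is.null(targets)) targets <- seq_len(10L)
      ctr <- colMeans(v)
      dir <- sweep(v[targets, , drop = FALSE], 2L, ctr)
      dir <- dir / sqrt(rowSums(dir^2))
      v[targets, ] <- v[targets, , drop = FALSE] - magnitude * dir
      object$inner_skull <- tri_mesh(v, object$inner_skull$triangles)
      object
    },
    jitter_sensors = {
      if (!inherits(object, "sensor_array")) stop("need a sensor_array")
      if (is.null(targets)) targets <- seq_along(object$labels)
      p <- object$positions
      p[targets, ] <- p[targets, , drop = FALSE] +
        matrix(stats::rnorm(3L * length(targets), sd = magnitude),
               length(targets))
      sensor_array(object$labels, p, type = object$type,
                   orientations = object$orientations,
                   reference = object$reference)
    },
    noise_column = {
      if (!inherits(object, "lead_field")) stop("need a lead_field")
      if (is.null(targets)) stop("noise_column needs target source indices")
      M <- object$matrix
      for (j in targets) {
        M[, j] <- stats::rnorm(nrow(M)) * magnitude *
          sqrt(mean(object$matrix[, j]^2))
      }
      lead_field(M, object$orientation_mode, units = object$units,
                 reference = "none", provenance = object$provenance,
                 labels = object$labels)
    },
    blur_mesh = {
      if (!inherits(object, "tri_mesh")) stop("need a tri_mesh")
      v <- object$vertices +
        matrix(stats::rnorm(length(object$vertices), sd = magnitude),
               nrow(object$vertices))
      tri_mesh(v, object$triangles)
    },
    stop(sprintf("unknown artifact kind '%s'", kind)))
}

#' Distance-sensitive lead-field provider for QC fixtures
#'
#' Wraps a forward model so that source columns degrade as the source
#' approaches the inner skull, emulating the numerical instability of
#' boundary-element solvers near critical surface-surface distances: a
#' source at distance d below `critical_distance_m` receives additive
#' deterministic noise with relative amplitude
#' `noise_scale * (critical/d - 1)`.
#'
#' @param base function(head, src, sensors) -> [lead_field()] (defaults
#'   to the three-shell sphere model using the head's radii and
#'   conductivities).
#' @param critical_distance_m distance below which degradation starts.
#' @param noise_scale degradation rate.
#' @param seed seed for the frozen noise pattern.
#' @return function(head, src, sensors) -> [lead_field()].
#' @export
make_unstable_lf_provider <- function(base = NULL,
                                      critical_distance_m = 0.002,
                                      noise_scale = 1,
                                      seed = 99L) {
  if (is.null(base)) base <- function(head, src, sensors) {
    three_shell_sphere_leadfield_eeg(
      src, sensors, radii = head$radii[2:4],
      sigmas = unname(head$conductivities), reference = "average")
  }
  function(head, src, sensors) {
    lf <- base(head, src, sensors)
    if (lf$orientation_mode == "free")
      lf <- apply_orientation_constraint(lf, src$orientations)
    dd <- surface_surface_distances(src$positions, head$inner_skull,
                                    critical_distance_m)
    bad <- which(dd$distances < critical_distance_m)
    if (length(bad)) {
      set.seed(seed)
      M <- lf$matrix
      noise <- matrix(stats::rnorm(nrow(M) * ncol(M)), nrow(M))
      sev <- noise_scale * (critical_distance_m / pmax(dd$distances, 1e-6) - 1)
      for (j in bad) {
        M[, j] <- M[, j] + sev[j] * sqrt(mean(M[, j]^2)) * noise[, j]
      }
      lf$matrix <- M
    }
    lf
  }
}
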