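# shared fixtures, built once per test run and memoized
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

qc_scene <- function() cached("qc_scene", function() make_qc_scene(2L))

# 19-sensor / 500-source sphere fixture used by the solver recovery tests
solver_scene <- function() cached("solver_scene", function() {
  cortex <- resample_mesh(make_icosphere(3L, 0.079), 500L)
  src <- source_space(cortex$vertices, vertex_normals(cortex))
  sensors <- make_1020_layout(make_icosphere(3L, 0.092))
  L <- three_shell_sphere_leadfield_eeg(src, sensors,
                                        radii = c(0.082, 0.088, 0.092),
                                        sigmas = c(0.33, 0.0042, 0.33))
  e <- esikit:::mesh_edges(cortex)
  ring1 <- lapply(seq_len(nrow(cortex$vertices)), function(i)
    c(i, e[e[, 1L] == i, 2L], e[e[, 2L] == i, 1L]))
  # planted sources under the montage (cortex beneath the electrode cap)
  dirs <- rbind(c(0.6, 0.4, 0.7), c(-0.5, -0.5, 0.7), c(0.1, -0.7, 0.7))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  active <- apply(dirs, 1L, function(d) which.max(cortex$vertices %*% d))
  list(cortex = cortex, src = src, sensors = sensors, L = L,
       ring1 = ring1, active = as.integer(active))
})

# alpha-band sensor cross-spectrum with the 3 planted sources
solver_alpha_csd <- function() cached("solver_alpha_csd", function() {
  sc <- solver_scene()
  spec <- osc_network_spec(n_sources = 500L, active = sc$active,
                           center_hz = 10, bandwidth_hz = 2, amplitude = 1,
                           noise_floor = 0.03, n_time = 40000L,
                           sampling_rate = 200, seed = 11L)
  sim <- simulate_oscillatory_sources(spec, segment_length = 200L)
  v <- project_to_sensors(sc$L, sim$sources, snr_db = 10, seed = 12L)
  cs <- cross_spectrum(fft_coefficients(v, segment_length = 200L,
                                        window = "rectangular"))
  k <- which.min(abs(cs$frequencies - 10))
  list(cs = cs, k = k, S_alpha = cs$S[, , k], m = cs$m, spec = spec)
})

# sparse Hermitian precision fixture (ring + chords) with sampled data
hermitian_graph_fixture <- function(m = 2000L, seed = 21L) {
  set.seed(seed)
  n <- 10L
  Theta <- diag(n) + 0i
  edges <- rbind(cbind(1:(n - 1L), 2:n), c(n, 1L), c(1L, 5L), c(3L, 8L))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    w <- 0.45 * exp(1i * stats::runif(1, -pi, pi))
    Theta[a, b] <- w; Theta[b, a] <- Conj(w)
  }
  ev <- eigen(Theta, symmetric = TRUE, only.values = TRUE)$values
  Theta <- Theta + diag(abs(min(Re(ev))) + 0.3, n)
  S_true <- solve(Theta)
  ee <- eigen(S_true, symmetric = TRUE)
  rt <- ee$vectors %*% (sqrt(pmax(Re(ee$values), 0)) * Conj(t(ee$vectors)))
  Z <- rt %*% matrix(complex(real = stats::rnorm(n * m),
                             imaginary = stats::rnorm(n * m)) / sqrt(2), n)
  S_hat <- Z %*% Conj(t(Z)) / m
  list(Theta = Theta, S_true = S_true, S_hat = (S_hat + Conj(t(S_hat))) / 2,
       truth_edges = Mod(Theta) > 1e-9 & !diag(TRUE, n), m = m)
}

edge_f1 <- function(est, truth, tol = 1e-9) {
  pred <- Mod(est) > tol & !diag(TRUE, nrow(est))
  tp <- sum(pred & truth) / 2
  fp <- sum(pred & !truth) / 2
  fn <- sum(!pred & truth) / 2
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

random_hermitian_psd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(complex(real = stats::rnorm(n * n),
                      imaginary = stats::rnorm(n * n)), n)
  S <- A %*% Conj(t(A)) / n
  (S + Conj(t(S))) / 2
}

expect_hermitian_psd <- function(S, tol = 1e-8) {
  testthat::expect_true(esikit:::is_hermitian(S, tol = 1e-8))
  testthat::expect_gte(esikit:::min_eig_ratio((S + Conj(t(S))) / 2), -tol)
}
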