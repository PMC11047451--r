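test_that("rotational-invariance standardization equals the normal constraint", {
  set.seed(20)
  Lf <- lead_field(matrix(rnorm(8 * 15), 8), "free")
  nrm <- matrix(rnorm(15), 5, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  std <- rotational_invariance_standardize(Lf, nrm)
  ref <- apply_orientation_constraint(Lf, nrm)
  expect_equal(std$L_std$matrix, ref$matrix, tolerance = 1e-14)
  expect_error(rotational_invariance_standardize(Lf, nrm * 0), "zero normal")
})

test_that("de-standardization lifts tensors, normalizes directions, is consistent", {
  set.seed(21)
  nrm <- matrix(rnorm(12), 4, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  Lf <- lead_field(matrix(rnorm(8 * 12), 8), "free")
  std <- rotational_invariance_standardize(Lf, nrm)
  S <- random_hermitian_psd(4, seed = 2)
  out <- rotational_invariance_destandardize(S, std$machinery)
  # fallback lift: directions are unit vectors aligned with the normals
  expect_equal(rowSums(out$max_directions^2), rep(1, 4), tolerance = 1e-10)
  expect_equal(abs(rowSums(out$max_directions * nrm)), rep(1, 4),
               tolerance = 1e-8)
  expect_equal(out$S_projected, S, tolerance = 1e-8)
  expect_error(rotational_invariance_destandardize(S + diag(0:3) * 1i,
                                                   std$machinery),
               "Hermitian")
})

test_that("orientation recovery: a normal-aligned source yields a near-normal direction", {
  sc <- qc_scene()
  sub <- 1:40
  src <- source_space(sc$src$positions[sub, ], sc$src$orientations[sub, ])
  Lfree <- three_shell_sphere_leadfield_eeg(
    source_space(src$positions), sc$sensors,
    c(0.082, 0.088, 0.092), c(0.33, 0.0042, 0.33))
  std <- rotational_invariance_standardize(Lfree, src$orientations)
  # simulate one source active along its normal at SNR 10
  j <- 17L
  spec <- osc_network_spec(n_sources = 40L, active = j, center_hz = 10,
                           bandwidth_hz = 2, amplitude = 1,
                           noise_floor = 0.02, n_time = 20000L,
                           sampling_rate = 200, seed = 23L)
  sim <- simulate_oscillatory_sources(spec, segment_length = 200L)
  v <- project_to_sensors(std$L_std, sim$sources, snr_db = 10, seed = 24L)
  cs <- cross_spectrum(fft_coefficients(v, segment_length = 200L,
                                        window = "rectangular"))
  k <- which.min(abs(cs$frequencies - 10))
  fit <- sssbl_solve(array(cs$S[, , k], c(19, 19, 1)), std$L_std, m = cs$m,
                     cfg = solver_config(alpha1 = 0.1, alpha2 = 0.1,
                                         max_iter = 300L))
  out <- rotational_invariance_destandardize(
    fit$S_jj[, , 1], std$machinery, S_vv = cs$S[, , k],
    gamma = fit$gamma[, 1], sigma2 = fit$sigma2[1])
  ang <- acos(min(1, abs(sum(out$max_directions[j, ] * src$orientations[j, ]))))
  expect_lt(ang * 180 / pi, 15)
})

test_that("curvature weights: branches, disabled limit, hand values, positivity", {
  expect_identical(curvature_compensation_weights(0, 0.5, 1.2, 0.9, 0.7), 1.2)
  H <- seq(-2, 2, by = 0.5)
  expect_identical(curvature_compensation_weights(H, 0, 1, 0, 1),
                   rep(1, length(H)))
  w <- curvature_compensation_weights(c(0.5, -0.5), slope_gyri = 0.4,
                                      intercept_gyri = 1.1,
                                      slope_sulci = 0.3,
                                      intercept_sulci = 0.8)
  expect_equal(w, c(1.1 + 0.4 * 0.5, 0.8 - 0.3 * 0.5), tolerance = 1e-14)
  expect_error(curvature_compensation_weights(-10, 0.5, 1, 0.5, 1), "positive")
  expect_error(curvature_compensation_weights(NaN), "finite")
  # standardize/de-standardize inverse pair
  set.seed(22)
  L <- matrix(rnorm(6 * 9), 6)
  wts <- curvature_compensation_weights(rnorm(9) * 0.3)
  std <- curvature_standardize(L, wts)
  x <- rnorm(9)
  expect_equal(destandardize(x * wts, std$machinery), x, tolerance = 1e-12)
  S <- random_hermitian_psd(9, seed = 3)
  back <- destandardize(S * (wts %o% wts), std$machinery, cross_spectrum = TRUE)
  expect_equal(back, S, tolerance = 1e-10)
})

test_that("Laplacian standardization inverts exactly for deformed operators", {
  m <- make_icosphere(1L)
  lap <- graph_laplacian(m, 1e-3)
  set.seed(23)
  L <- matrix(rnorm(10 * nrow(m$vertices)), 10)
  std <- laplacian_standardize(L, lap)
  x <- rnorm(nrow(m$vertices))
  x_std <- solve(std$machinery$M, x)
  expect_equal(as.vector(destandardize(x_std, std$machinery)), x,
               tolerance = 1e-8)
  expect_error(laplacian_standardize(L[, 1:5], lap), "mismatch")
})

test_that("the Laplacian prior improves smooth-patch recovery of a linear inverse", {
  sc <- qc_scene()
  cap <- sc$source_vertices
  Lc <- three_shell_sphere_leadfield_eeg(sc$src, sc$sensors,
                                         c(0.082, 0.088, 0.092),
                                         c(0.33, 0.0042, 0.33))
  # smooth patch: amplitudes fall off with distance from a seed vertex
  seedv <- 10L
  d <- sqrt(rowSums(sweep(sc$src$positions, 2L, sc$src$positions[seedv, ])^2))
  amp <- exp(-(d / 0.04)^2)
  set.seed(25)
  nsamp <- 400L
  J <- amp * matrix(rnorm(length(amp) * nsamp), length(amp))
  V <- Lc$matrix %*% J
  V <- V + matrix(rnorm(length(V), sd = 0.1 * sd(V)), nrow(V))
  Svv <- V %*% t(V) / nsamp
  truth <- amp^2
  L <- Lc$matrix
  ridge_T <- function(Lm, lam) t(Lm) %*% solve(Lm %*% t(Lm) + lam * diag(19))
  T0 <- ridge_T(L, 0.01 * mean(diag(L %*% t(L))))
  c0 <- cor(diag(T0 %*% Svv %*% t(T0)), truth)
  M <- laplacian_pseudoinverse_factor(
    graph_laplacian(sc$head$cortex, 0.3))[cap, cap]
  Lsm <- L %*% M
  Ts <- M %*% ridge_T(Lsm, 0.01 * mean(diag(Lsm %*% t(Lsm))))
  cL <- cor(diag(Ts %*% Svv %*% t(Ts)), truth)
  expect_gt(cL, c0)
})

test_that("parcellation groups validate labels and drive grouped scales", {
  pg <- parcellation_groups(c(1, 1, 2, 2, 2, 3))
  expect_identical(pg$n_groups, 3L)
  expect_identical(pg$groups[[2L]], 3:5)
  expect_error(parcellation_groups(c(1, NA, 2)), "label")
  # degenerate grouping (one label per source) reproduces ungrouped output
  set.seed(26)
  L <- matrix(rnorm(8 * 12), 8)
  Svv <- random_hermitian_psd(8, seed = 5)
  cfg <- solver_config(alpha1 = 0.1, alpha2 = 0.1, max_iter = 80L)
  f_un <- sssbl_solve(array(Svv, c(8, 8, 1)), L, m = 50, cfg = cfg)
  f_deg <- sssbl_solve(array(Svv, c(8, 8, 1)), L, m = 50, cfg = cfg,
                       parcellation = parcellation_groups(1:12))
  expect_equal(f_deg$gamma, f_un$gamma, tolerance = 1e-10)
  # a group holding the truly active sources gets the larger shared scale
  set.seed(30)
  Lr <- matrix(rnorm(12 * 30), 12)
  gam_true <- c(rep(1, 3), rep(0, 27))
  Svv_true <- Lr %*% (gam_true * t(Lr)) + diag(0.1, 12)
  ee <- eigen(Svv_true, symmetric = TRUE)
  Z <- (ee$vectors %*% (sqrt(ee$values) * t(ee$vectors))) %*%
    matrix(rnorm(12 * 500), 12)
  Svv2 <- Z %*% t(Z) / 500
  fitp <- sssbl_solve(array(Svv2, c(12, 12, 1)), Lr, m = 500,
                      cfg = solver_config(alpha1 = 0.1, alpha2 = 0.1,
                                          max_iter = 200L,
                                          noise_variance = 0.1),
                      parcellation = parcellation_groups(c(rep(1, 3),
                                                           rep(2, 27))))
  g_active <- fitp$gamma[1L, 1]
  g_inactive <- fitp$gamma[30L, 1]
  expect_gt(g_active, 10 * g_inactive)
  expect_equal(g_active, 1, tolerance = 0.25)
})
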