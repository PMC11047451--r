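test_that("icospheres have the closed-form vertex counts and exact radii", {
  m0 <- make_icosphere(0L)
  expect_identical(nrow(m0$vertices), 12L)
  expect_identical(nrow(m0$triangles), 20L)
  m3 <- make_icosphere(3L, radius = 0.08)
  expect_identical(nrow(m3$vertices), 642L)
  expect_lt(max(abs(sqrt(rowSums(m3$vertices^2)) - 0.08)), 1e-12 * 0.08)
  expect_true(is_closed_manifold(m3))
  expect_error(make_icosphere(9L), "subdivisions")
})

test_that("the nested head model is strictly nested with known gaps", {
  head <- make_nested_head(subdivisions = 2L)
  ss <- surface_surface_distances(head$cortex, head$inner_skull)
  expect_equal(ss$distances, rep(0.003, 162), tolerance = 0.05)
  expect_gt(min(surface_surface_distances(head$inner_skull,
                                          head$outer_skull)$distances), 0)
  expect_error(make_nested_head(radii = c(0.092, 0.088, 0.082, 0.079)),
               "ascending")
})

test_that("the 10-20 layout has 19 on-scalp electrodes with Cz at the apex", {
  scalp <- make_icosphere(3L, 0.092)
  sens <- make_1020_layout(scalp)
  expect_identical(length(sens$labels), 19L)
  expect_identical(sens$labels[which.max(sens$positions[, 3L])], "Cz")
  d <- surface_surface_distances(sens$positions, scalp)$distances
  expect_lt(max(d), 1e-9)
})

test_that("simulated oscillatory sources match their theoretical cross-spectra", {
  cpl <- matrix(c(1, 0.6 * exp(1i * 0.7), 0.2,
                  0.6 * exp(-1i * 0.7), 1, 0.4i,
                  0.2, -0.4i, 1), 3, 3)
  cpl <- (cpl + Conj(t(cpl))) / 2
  diag(cpl) <- 1
  spec <- osc_network_spec(n_sources = 4L, active = c(1L, 2L, 4L),
                           center_hz = 10, bandwidth_hz = 2, amplitude = 1,
                           coupling = cpl, noise_floor = 0.1,
                           n_time = 500000L, sampling_rate = 200, seed = 33L)
  sim <- simulate_oscillatory_sources(spec, segment_length = 100L)
  co <- fft_coefficients(sim$sources, segment_length = 100L,
                         window = "rectangular", detrend = FALSE)
  cs <- cross_spectrum(co)
  expect_identical(cs$m, 5000L)
  for (f in c(8, 10, 12)) {
    k <- which.min(abs(cs$frequencies - f))
    theo <- sim$theoretical(cs$frequencies[k])
    relerr <- sqrt(sum(Mod(cs$S[, , k] - theo)^2)) / sqrt(sum(Mod(theo)^2))
    expect_lt(relerr, 0.1)
    expect_hermitian_psd(theo)
  }
  # brute-force check of the theoretical density on a 4-source instance
  g <- exp(-((10 - spec$center_hz)^2) / (2 * (spec$bandwidth_hz / 2)^2))
  manual <- diag(spec$noise_floor^2, 4) + 0i
  manual[c(1, 2, 4), c(1, 2, 4)] <-
    manual[c(1, 2, 4), c(1, 2, 4)] + spec$amplitude^2 * g * cpl
  expect_equal(sim$theoretical(10), manual, tolerance = 1e-12)
})

test_that("oscillatory generators are pure functions of spec and seed", {
  spec <- osc_network_spec(n_sources = 3L, active = 1:2, n_time = 2000L,
                           sampling_rate = 200, seed = 5L)
  s1 <- simulate_oscillatory_sources(spec)
  s2 <- simulate_oscillatory_sources(spec)
  expect_identical(s1$sources$data, s2$sources$data)
  z <- osc_network_spec(n_sources = 3L, active = 1L, amplitude = 0,
                        noise_floor = 0, n_time = 1000L, sampling_rate = 200,
                        seed = 5L)
  expect_true(all(simulate_oscillatory_sources(z)$sources$data == 0))
  expect_error(osc_network_spec(3L, active = 7L), "active")
  bad_cpl <- matrix(c(1, 2, 2, 1), 2)
  expect_error(osc_network_spec(4L, active = 1:2, coupling = bad_cpl),
               "positive semidefinite")
})

test_that("sensor projection hits the requested SNR and handles edge cases", {
  set.seed(50)
  L <- matrix(rnorm(8 * 5), 8)
  src <- ts_data(matrix(rnorm(5 * 20000), 5), 200)
  v <- project_to_sensors(L, src, snr_db = 10, seed = 60L)
  clean <- L %*% src$data
  noise <- v$data - clean
  snr_meas <- 10 * log10(mean(clean^2) / mean(noise^2))
  expect_lt(abs(snr_meas - 10), 0.5)
  v0 <- project_to_sensors(L, src, snr_db = Inf)
  expect_equal(v0$data, clean, tolerance = 1e-12)
  zsrc <- ts_data(matrix(0, 5, 1000), 200)
  vz <- project_to_sensors(L, zsrc, snr_db = 10, seed = 61L)
  expect_true(all(vz$data == 0))   # zero signal: SNR scaling gives zero noise
  expect_error(project_to_sensors(L, ts_data(matrix(1, 3, 10), 200)),
               "mismatch")
})

test_that("paired spectra tensors are positive, deterministic, and exactly invertible", {
  p1 <- make_paired_spectra_tensors(10L, 4L, 6L, seed = 7L)
  p2 <- make_paired_spectra_tensors(10L, 4L, 6L, seed = 7L)
  expect_identical(p1$meg$values, p2$meg$values)
  expect_true(all(p1$meg$values > 0) && all(p1$eeg$values > 0))
  p0 <- make_paired_spectra_tensors(10L, 4L, 6L, a_f = c(1, 2, 0.5, -1),
                                    b_f = c(1.2, 0.8, 1, 0.9),
                                    noise_sd = 0, seed = 8L)
  fit <- fit_scaling_model(log_transform(p0$meg), log_transform(p0$eeg))
  expect_equal(fit$a, c(1, 2, 0.5, -1), tolerance = 1e-10)
  expect_equal(fit$b, c(1.2, 0.8, 1, 0.9), tolerance = 1e-10)
  expect_error(make_paired_spectra_tensors(0L, 4L, 6L), "sizes")
})

test_that("artifact injectors produce the failure modes the QC flags", {
  sc <- qc_scene()
  # dent: raises distance flags
  tgt <- order(sc$src$positions %*% c(0.3, 0.2, 0.93), decreasing = TRUE)[1:10]
  iv <- unique(apply(sc$src$positions[tgt, ], 1L, function(p)
    which.min(rowSums(sweep(sc$head$inner_skull$vertices, 2L, p)^2))))
  dent <- inject_artifact(sc$head, "dent_inner_skull", magnitude = 0.0028,
                          targets = iv)
  expect_gte(sum(distance_flag_sources(sc$src, dent$inner_skull,
                                       0.002)$flags), 10L)
  # jitter: at least one sensor correlation falls strictly below 0.7
  jit <- inject_artifact(sc$sensors, "jitter_sensors", magnitude = 0.01,
                         seed = 5L)
  jit <- project_sensors_to_scalp(jit, sc$head$scalp)
  Lj <- three_shell_sphere_leadfield_eeg(sc$src, jit, c(0.082, 0.088, 0.092),
                                         c(0.33, 0.0042, 0.33))
  Lh <- homogeneous_leadfield_eeg(sc$src, sc$sensors)
  qj <- leadfield_correlations(Lj, Lh)
  expect_gte(sum(qj$per_sensor_corr < 0.7), 1L)
  # noise column: that source's correlation falls strictly below 0.33
  Lt <- three_shell_sphere_leadfield_eeg(sc$src, sc$sensors,
                                         c(0.082, 0.088, 0.092),
                                         c(0.33, 0.0042, 0.33))
  Ln <- inject_artifact(Lt, "noise_column", magnitude = 1, targets = 7L,
                        seed = 3L)
  qn <- leadfield_correlations(Ln, Lh)
  expect_lt(qn$per_source_corr[7L], 0.33)
  expect_gt(min(qn$per_source_corr[-7L]), 0.33)
  expect_error(inject_artifact(sc$head, "melt", 1), "unknown artifact")
  expect_error(inject_artifact(sc$head, "dent_inner_skull", -1), "magnitude")
  # blur: vertex noise of the requested size
  blur <- inject_artifact(sc$head$cortex, "blur_mesh", magnitude = 1e-4,
                          seed = 6L)
  d <- sqrt(rowSums((blur$vertices - sc$head$cortex$vertices)^2))
  expect_equal(mean(d), 1e-4 * sqrt(8 / pi), tolerance = 0.1)
})
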