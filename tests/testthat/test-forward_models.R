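test_that("scalp projection moves electrodes onto the surface and keeps labels", {
  scalp <- make_icosphere(4L, 0.10)
  s <- sensor_array(c("a", "b"), rbind(c(0, 0, 0.11), c(0.05, 0.02, 0.12)))
  p <- project_sensors_to_scalp(s, scalp)
  expect_identical(p$labels, c("a", "b"))
  r <- sqrt(rowSums(p$positions^2))
  expect_equal(r, c(0.10, 0.10), tolerance = 1e-3)  # faceted sphere
  # direction preserved for a radial projection
  expect_equal(p$positions[1L, ] / r[1L], c(0, 0, 1), tolerance = 2e-2)
  # sensor already on the scalp barely moves
  v1 <- scalp$vertices[1L, , drop = FALSE]
  p2 <- project_sensors_to_scalp(sensor_array("x", v1), scalp)
  expect_equal(p2$positions[1L, ], as.vector(v1), tolerance = 1e-12)
  # a sensor inside still lands on the surface
  p3 <- project_sensors_to_scalp(sensor_array("o", matrix(c(0, 0, 1e-5), 1)),
                                 scalp)
  expect_equal(sqrt(sum(p3$positions^2)), 0.10, tolerance = 2e-3)
  meg <- sensor_array("m", matrix(c(0, 0, 0.3), 1), type = "meg_magnetometer",
                      orientations = matrix(c(0, 0, 1), 1))
  expect_error(project_sensors_to_scalp(meg, scalp), "EEG")
})

test_that("rigid landmark alignment recovers a known rotation + translation", {
  lm <- rbind(c(0.08, 0, 0), c(-0.08, 0.01, 0), c(0, 0.09, 0.02),
              c(0, -0.07, 0.05))
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(0.01, -0.02, 0.005)
  moved <- sweep(lm %*% t(R), 2L, tr, "+")
  sens <- sensor_array(letters[1:4], lm)
  out <- landmark_rigid_align(sens, lm, moved)
  expect_equal(out$positions, moved, tolerance = 1e-9)
  ident <- landmark_rigid_align(sens, lm, lm)
  expect_equal(ident$positions, lm, tolerance = 1e-12)
  expect_error(landmark_rigid_align(sens, lm[1:2, ], moved[1:2, ]), "3")
  coll <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(landmark_rigid_align(sens, coll, coll), "collinear")
})

test_that("homogeneous dipole potential matches the closed form", {
  src <- source_space(matrix(0, 1, 3))
  sens <- sensor_array("e1", matrix(c(0, 0, 0.1), 1))
  L <- homogeneous_leadfield_eeg(src, sens, sigma = 0.33, reference = "none")
  # V = q (r - r0) / (4 pi sigma |r|^3); q = 1e-9 A.m along z
  expect_equal(1e-9 * L$matrix[1L, 3L], 2.4114e-8, tolerance = 1e-4)
  expect_equal(L$matrix[1L, 3L], 0.1 / (4 * pi * 0.33 * 0.1^3),
               tolerance = 1e-12)
  # sensor displacement perpendicular to the moment gives zero potential
  sens2 <- sensor_array("e2", matrix(c(0.07, 0, 0), 1))
  L2 <- homogeneous_leadfield_eeg(src, sens2, reference = "none")
  expect_equal(L2$matrix[1L, 3L], 0, tolerance = 1e-15)
  # conductivity scaling: doubling sigma halves all entries
  La <- homogeneous_leadfield_eeg(src, sens, sigma = 0.33, reference = "none")
  Lb <- homogeneous_leadfield_eeg(src, sens, sigma = 0.66, reference = "none")
  expect_equal(Lb$matrix, La$matrix / 2, tolerance = 1e-12)
  expect_error(homogeneous_leadfield_eeg(
    source_space(matrix(c(0, 0, 0.1), 1)), sens), "coincides")
})

test_that("three-shell sphere with equal conductivities matches the homogeneous-sphere series", {
  sc <- qc_scene()
  radii <- c(0.082, 0.088, 0.092)
  sub <- source_space(sc$src$positions[1:25, ], sc$src$orientations[1:25, ])
  L3 <- three_shell_sphere_leadfield_eeg(sub, sc$sensors, radii,
                                         c(0.33, 0.33, 0.33), n_terms = 60L,
                                         reference = "none")
  # independent oracle: insulated homogeneous sphere, exterior coefficient
  # (2n+1)/n per degree
  Gn <- (2 * seq_len(60) + 1) / seq_len(60) / (4 * pi * 0.33 * 0.092)
  sp <- sc$sensors$positions / sqrt(rowSums(sc$sensors$positions^2)) * 0.092
  oracle <- vapply(seq_len(25), function(j) {
    free <- esikit:::.sphere_series_potential(sp, sub$positions[j, ], Gn, 0.092)
    as.vector(free %*% sub$orientations[j, ])
  }, numeric(19))
  expect_lt(max(abs(L3$matrix - oracle)) / max(abs(oracle)), 1e-6)
})

test_that("three-shell series: superficial sources dominate and truncation converges", {
  sens <- make_1020_layout(make_icosphere(2L, 0.092))
  radii <- c(0.082, 0.088, 0.092); sig <- c(0.33, 0.0042, 0.33)
  dirv <- c(0, 0.6, 0.8)
  pos <- rbind(0.3 * 0.082 * dirv, 0.8 * 0.082 * dirv)
  src <- source_space(pos, rbind(dirv, dirv))
  L <- three_shell_sphere_leadfield_eeg(src, sens, radii, sig,
                                        reference = "none")
  expect_gt(sqrt(sum(L$matrix[, 2L]^2)), sqrt(sum(L$matrix[, 1L]^2)))
  L40 <- three_shell_sphere_leadfield_eeg(src, sens, radii, sig,
                                          n_terms = 40L, reference = "none")
  L80 <- three_shell_sphere_leadfield_eeg(src, sens, radii, sig,
                                          n_terms = 80L, reference = "none")
  # series tail is bounded by (b/R)^n: small at 0.8 eccentricity, machine
  # level at 0.5
  expect_lt(max(abs(L40$matrix - L80$matrix)), 1e-4 * max(abs(L80$matrix)))
  shall <- source_space(matrix(0.5 * 0.082 * dirv, 1), matrix(dirv, 1))
  S40 <- three_shell_sphere_leadfield_eeg(shall, sens, radii, sig,
                                          n_terms = 40L, reference = "none")
  S80 <- three_shell_sphere_leadfield_eeg(shall, sens, radii, sig,
                                          n_terms = 80L, reference = "none")
  expect_lt(max(abs(S40$matrix - S80$matrix)), 1e-8 * max(abs(S80$matrix)))
  expect_error(three_shell_sphere_leadfield_eeg(
    source_space(matrix(c(0, 0, 0.085), 1)), sens, radii, sig), "inside")
  expect_error(three_shell_sphere_leadfield_eeg(src, sens, rev(radii), sig),
               "ascending")
})

test_that("spherical MEG: radial silence, moment antisymmetry, distance decay", {
  pos <- rbind(c(0, 0, 0.05), c(0.02, 0.03, 0.04), c(-0.04, 0.01, 0.02))
  src <- source_space(pos)
  orient <- matrix(rep(c(0, 0, 1), 7), 7, 3, byrow = TRUE)
  spos <- cbind(0.02, 0.01, seq(0.12, 0.3, length.out = 7))
  mags <- sensor_array(paste0("m", 1:7), spos, type = "meg_magnetometer",
                       orientations = orient)
  L <- sphere_leadfield_meg(src, mags)
  # radial moment = position direction: silent for every source
  for (j in seq_len(3)) {
    rhat <- pos[j, ] / sqrt(sum(pos[j, ]^2))
    silent <- L$matrix[, (3 * j - 2):(3 * j)] %*% rhat
    expect_lt(max(abs(silent)), 1e-12 * max(abs(L$matrix)))
  }
  # linearity: flipping the moment flips the field
  expect_equal(L$matrix %*% rep(c(1, 0, 0), 3),
               -(L$matrix %*% rep(c(-1, 0, 0), 3)), tolerance = 1e-12)
  # tangential dipole field decays monotonically along a radial sensor line
  b <- abs(L$matrix[, 1L])
  expect_true(all(diff(b) < 0))
})

test_that("orientation constraint projects free columns onto normals", {
  set.seed(4)
  Lf <- lead_field(matrix(rnorm(6 * 9), 6), "free")
  nx <- matrix(rep(c(1, 0, 0), 3), 3, 3, byrow = TRUE)
  Lc <- apply_orientation_constraint(Lf, nx)
  expect_equal(Lc$matrix, Lf$matrix[, c(1, 4, 7)], tolerance = 1e-14)
  # a source tangential to its normal produces zero response
  n1 <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  Lc2 <- apply_orientation_constraint(Lf, n1)
  tang <- c(1, 0, 0)  # tangential to normal (0,0,1) of source 1
  expect_equal(as.vector(Lf$matrix[, 1:3] %*% (n1[1, ] * sum(n1[1, ] * tang))),
               as.vector(Lc2$matrix[, 1L] * sum(n1[1, ] * tang)),
               tolerance = 1e-12)
  expect_error(apply_orientation_constraint(Lc, nx), "already")
  expect_error(apply_orientation_constraint(Lf, nx * 2), "unit")
})

test_that("EEG average reference zeroes the column means", {
  sc <- qc_scene()
  sub <- source_space(sc$src$positions[1:10, ], sc$src$orientations[1:10, ])
  L <- three_shell_sphere_leadfield_eeg(sub, sc$sensors,
                                        c(0.082, 0.088, 0.092),
                                        c(0.33, 0.0042, 0.33))
  expect_lt(max(abs(colMeans(L$matrix))), 1e-12 * max(abs(L$matrix)))
  Lh <- homogeneous_leadfield_eeg(sub, sc$sensors)
  expect_lt(max(abs(colMeans(Lh$matrix))), 1e-12 * max(abs(Lh$matrix)))
})
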