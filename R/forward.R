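#' Sensor array
#'
#' Labeled sensor positions in meters (RAS frame). MEG magnetometers also
#' carry unit orientation vectors.
#'
#' @param labels character vector of unique sensor labels.
#' @param positions N x 3 numeric matrix (meters).
#' @param type "eeg" or "meg_magnetometer".
#' @param orientations N x 3 unit vectors (MEG only).
#' @param reference EEG reference policy, currently "average" or "none".
#' @return Object of class `sensor_array`.
#' @export
sensor_array <- function(labels, positions, type = c("eeg", "meg_magnetometer"),
                         orientations = NULL, reference = "average") {
  type <- match.arg(type)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  labels <- as.character(labels)
  if (length(labels) != nrow(positions)) stop("labels/positions length mismatch")
  if (anyDuplicated(labels)) stop(sprintf("duplicate sensor label '%s'",
                                          labels[duplicated(labels)][1L]))
  if (!all(is.finite(positions))) stop("non-finite sensor coordinates")
  if (type == "meg_magnetometer") {
    if (is.null(orientations)) stop("MEG magnetometers need orientations")
    orientations <- as.matrix(orientations)
    nrm <- sqrt(rowSums(orientations^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("MEG orientations must be unit norm")
  }
  structure(list(labels = labels, positions = positions, type = type,
                 orientations = orientations, reference = reference),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array: %d %s sensors\n", length(x$labels), x$type))
  invisible(x)
}

#' Source space
#'
#' Dipole positions (strictly inside the innermost head surface) with free
#' or surface-normal-constrained orientations.
#'
#' @param positions S x 3 matrix, meters.
#' @param orientations S x 3 unit normals, or NULL for free orientation.
#' @return Object of class `source_space` with `orientation_mode` in
#'   `{"free","constrained"}`.
#' @export
source_space <- function(positions, orientations = NULL) {
  positions <- as.matrix(positions)
  mode <- if (is.null(orientations)) "free" else "constrained"
  if (!is.null(orientations)) {
    orientations <- as.matrix(orientations)
    nrm <- sqrt(rowSums(orientations^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("source orientations must be unit norm")
  }
  structure(list(positions = positions, orientations = orientations,
                 orientation_mode = mode), class = "source_space")
}

#' Lead field
#'
#' Dense real matrix with sensors in rows and sources (or 3 Cartesian
#' components per source, free orientation) in columns.
#'
#' @param matrix numeric N x S or N x 3S matrix.
#' @param orientation_mode "constrained" or "free".
#' @param units "V/(A.m)" for EEG, "T/(A.m)" for MEG.
#' @param reference EEG reference applied ("average" or "none").
#' @param provenance model that produced it.
#' @param labels optional sensor labels.
#' @return Object of class `lead_field`.
#' @export
lead_field <- function(matrix, orientation_mode = c("constrained", "free"),
                       units = "V/(A.m)", reference = "none",
                       provenance = "unknown", labels = NULL) {
  orientation_mode <- match.arg(orientation_mode)
  matrix <- as.matrix(matrix)
  if (!all(is.finite(matrix))) stop("lead field contains non-finite entries")
  if (orientation_mode == "free" && ncol(matrix) %% 3L != 0L)
    stop("free-orientation lead field must have 3 columns per source")
  structure(list(matrix = matrix, orientation_mode = orientation_mode,
                 units = units, reference = reference,
                 provenance = provenance, labels = labels),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  ns <- if (x$orientation_mode == "free") ncol(x$matrix) / 3L else ncol(x$matrix)
  cat(sprintf("lead_field: %d sensors x %d sources (%s orientation, %s, ref=%s)\n",
              nrow(x$matrix), ns, x$orientation_mode, x$provenance, x$reference))
  invisible(x)
}

apply_average_reference <- function(M) {
  sweep(M, 2L, colMeans(M), "-")
}

#' Project EEG sensors onto the scalp surface
#'
#' Replaces each electrode position by its nearest point on the scalp
#' mesh (labels preserved). MEG sensors are not projected.
#'
#' @param sensors an EEG [sensor_array()].
#' @param scalp scalp [tri_mesh()].
#' @return The projected [sensor_array()].
#' @export
project_sensors_to_scalp <- function(sensors, scalp) {
  if (sensors$type != "eeg")
    stop("scalp projection applies to EEG sensors only")
  ss <- surface_surface_distances(sensors$positions, scalp, min_distance_m = 0)
  sensor_array(sensors$labels, ss$closest, type = "eeg",
               reference = sensors$reference)
}

#' Rigid landmark alignment of a sensor array
#'
#' Least-squares rigid (rotation + translation) Procrustes transform from
#' labeled sensor-space landmarks to matching head-space landmarks,
#' applied to all sensors.
#'
#' @param sensors a [sensor_array()].
#' @param sensor_landmarks named list or 3-column matrix with rownames:
#'   landmark positions in the sensor frame.
#' @param head_landmarks matching landmark positions in the head frame
#'   (same names/order).
#' @return The transformed [sensor_array()].
#' @export
landmark_rigid_align <- function(sensors, sensor_landmarks, head_landmarks) {
  X <- as.matrix(sensor_landmarks); Y <- as.matrix(head_landmarks)
  if (nrow(X) < 3L || nrow(Y) != nrow(X))
    stop("need at least 3 matching landmark pairs")
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2L, cx); Y0 <- sweep(Y, 2L, cy)
  if (qr(X0)$rank < 2L) stop("landmarks are collinear")
  s <- svd(t(X0) %*% Y0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  newpos <- sweep(sensors$positions, 2L, cx) %*% t(R)
  newpos <- sweep(newpos, 2L, cy, "+")
  sensor_array(sensors$labels, newpos, type = sensors$type,
               orientations = if (!is.null(sensors$orientations))
                 sensors$orientations %*% t(R) else NULL,
               reference = sensors$reference)
}

#' Homogeneous (infinite-medium) EEG lead field
#'
#' Boundary-free dipole solution of the Poisson equation,
#' V(r) = q . (r - r0) / (4 pi sigma |r - r0|^3): the analytic, artifact-
#' free baseline the lead-field quality control correlates every tested
#' lead field against. Any positive conductivity gives identical QC
#' correlations (Pearson r is scale-free).
#'
#' @param src a [source_space()].
#' @param sensors an EEG [sensor_array()].
#' @param sigma mean-field conductivity, S/m (default 0.33).
#' @param reference "average" (default) or "none".
#' @return A [lead_field()]; free orientation N x 3S unless `src` is
#'   constrained, in which case the normal projection N x S.
#' @export
homogeneous_leadfield_eeg <- function(src, sensors, sigma = 0.33,
                                      reference = "average") {
  pos <- src$positions; sp <- sensors$positions
  n <- nrow(sp); s <- nrow(pos)
  L <- matrix(0, n, 3L * s)
  for (j in seq_len(s)) {
    d <- sweep(sp, 2L, pos[j, ])
    r3 <- rowSums(d * d)^1.5
    if (any(r3 < (1e-6)^3)) stop("sensor coincides with a source")
    L[, (3L * j - 2L):(3L * j)] <- d / (4 * pi * sigma * r3)
  }
  lf <- lead_field(L, "free", units = "V/(A.m)", reference = "none",
                   provenance = "homogeneous", labels = sensors$labels)
  if (src$orientation_mode == "constrained")
    lf <- apply_orientation_constraint(lf, src$orientations)
  if (identical(reference, "average")) {
    lf$matrix <- apply_average_reference(lf$matrix)
    lf$reference <- "average"
  }
  lf
}

#' Orientation constraint: project a free lead field onto source normals
#'
#' Column i of the result is `L[, 3i-2:3i] %*% normal_i`.
#'
#' @param lf a free-orientation [lead_field()].
#' @param normals S x 3 unit normals.
#' @return Constrained [lead_field()].
#' @export
apply_orientation_constraint <- function(lf, normals) {
  if (lf$orientation_mode != "free") stop("lead field is already constrained")
  normals <- as.matrix(normals)
  s <- ncol(lf$matrix) / 3L
  if (nrow(normals) != s) stop("normals/source count mismatch")
  if (any(abs(sqrt(rowSums(normals^2)) - 1) > 1e-6))
    stop("normals must be unit norm")
  out <- matrix(0, nrow(lf$matrix), s)
  for (j in seq_len(s))
    out[, j] <- lf$matrix[, (3L * j - 2L):(3L * j)] %*% normals[j, ]
  lead_field(out, "constrained", units = lf$units, reference = lf$reference,
             provenance = lf$provenance, labels = lf$labels)
}

# Legendre polynomial values and derivatives P_n(x), P_n'(x) for n = 1..N,
# x a vector; returns list of two N x length(x) matrices
.legendre_pn <- function(N, x) {
  P <- matrix(0, N + 1L, length(x))
  P[1L, ] <- 1; if (N >= 1L) P[2L, ] <- x
  for (n in 2:N) if (N >= 2L)
    P[n + 1L, ] <- ((2 * n - 1) * x * P[n, ] - (n - 1) * P[n - 1L, ]) / n
  dP <- matrix(0, N + 1L, length(x))
  at1 <- abs(abs(x) - 1) < 1e-12
  den <- x^2 - 1
  den[at1] <- 1    # placeholder; overwritten by the limit below
  for (n in 1:N) {
    dP[n + 1L, ] <- n * (x * P[n + 1L, ] - P[n, ]) / den
    if (any(at1)) {
      lim <- n * (n + 1) / 2    # P_n'(+-1) limits
      dP[n + 1L, at1] <- ifelse(x[at1] > 0, lim, (-1)^(n + 1) * lim)
    }
  }
  list(P = P[-1L, , drop = FALSE], dP = dP[-1L, , drop = FALSE])
}

# per-degree radial transfer coefficient G_n for the 3-shell concentric
# sphere: solves the 5x5 boundary-value system in radii scaled by the
# outer radius; returns the exterior-surface coefficient per n
.three_shell_gain <- function(n_max, radii, sigmas) {
  r1 <- radii[1L]; r2 <- radii[2L]; r3 <- radii[3L]
  s1 <- sigmas[1L]; s2 <- sigmas[2L]; s3 <- sigmas[3L]
  p1 <- r1 / r3; p2 <- r2 / r3
  G <- numeric(n_max)
  for (n in seq_len(n_max)) {
    # unknowns A1,A2,B2,A3,B3 ; radial basis rho^n and rho^-(n+1)
    # source free term S * rho^-(n+1) in shell 1 with S = 1/(4 pi s1 r3)
    S <- 1 / (4 * pi * s1 * r3)
    M <- matrix(0, 5L, 5L); b <- numeric(5L)
    # continuity of V at p1
    M[1L, ] <- c(p1^n, -p1^n, -p1^(-(n + 1)), 0, 0)
    b[1L] <- -S * p1^(-(n + 1))
    # continuity of sigma dV/drho at p1
    M[2L, ] <- c(s1 * n * p1^(n - 1), -s2 * n * p1^(n - 1),
                 s2 * (n + 1) * p1^(-(n + 2)), 0, 0)
    b[2L] <- s1 * (n + 1) * S * p1^(-(n + 2))
    # continuity of V at p2
    M[3L, ] <- c(0, p2^n, p2^(-(n + 1)), -p2^n, -p2^(-(n + 1)))
    # continuity of sigma dV/drho at p2
    M[4L, ] <- c(0, s2 * n * p2^(n - 1), -s2 * (n + 1) * p2^(-(n + 2)),
                 -s3 * n * p2^(n - 1), s3 * (n + 1) * p2^(-(n + 2)))
    # insulating outer boundary at rho = 1
    M[5L, ] <- c(0, 0, 0, n, -(n + 1))
    sol <- solve(M, b)
    G[n] <- sol[4L] + sol[5L]   # A3 + B3 at rho = 1
  }
  G
}

# dipole potential series from per-degree gains: sensors on the outer
# sphere, dipole at r0 with moment columns (identity for lead field)
.sphere_series_potential <- function(sens, r0, Gn, r3) {
  n_max <- length(Gn)
  b <- sqrt(sum(r0^2))
  R <- sqrt(rowSums(sens^2))
  er <- sens / R
  # for a central dipole only n = 1 survives and the result is independent
  # of the auxiliary axis, so any unit ub is valid there
  ub <- if (b < 1e-12) c(0, 0, 1) else r0 / b
  t <- drop(er %*% ub)
  t <- pmin(1, pmax(-1, t))
  leg <- .legendre_pn(n_max, t)
  rho0 <- b / r3
  pow <- rho0^(seq_len(n_max) - 1L)        # rho0^(n-1)
  # V = sum_n Gn * rho0^(n-1)/r3 * [ n P_n(t) (q.ub) + P_n'(t) (q.er - t q.ub) ]
  coef <- Gn * pow / r3
  nseq <- seq_len(n_max)
  radial <- drop(t(coef * nseq) %*% leg$P)          # per sensor
  tang <- drop(t(coef) %*% leg$dP)                  # per sensor
  # columns = d/dq_x, d/dq_y, d/dq_z
  out <- matrix(0, nrow(sens), 3L)
  for (c3 in 1:3) {
    out[, c3] <- radial * ub[c3] + tang * (er[, c3] - t * ub[c3])
  }
  out
}

#' Three-shell concentric-sphere EEG lead field
#'
#' Truncated Legendre-series solution for nested spherical shells
#' (brain, skull, scalp) with isotropic homogeneous conductivities: the
#' built-in stand-in for a BEM lead field. Sensors are projected to the
#' outermost radius.
#'
#' @param src a [source_space()]; all positions strictly inside the
#'   innermost radius.
#' @param sensors an EEG [sensor_array()].
#' @param radii ascending numeric(3): brain, skull, scalp outer radii (m).
#' @param sigmas numeric(3) conductivities (S/m).
#' @param n_terms series truncation (>= 20, default 60).
#' @param reference "average" (default) or "none".
#' @return A [lead_field()].
#' @export
three_shell_sphere_leadfield_eeg <- function(src, sensors, radii, sigmas,
                                             n_terms = 60L,
                                             reference = "average") {
  if (length(radii) != 3L || any(diff(radii) <= 0))
    stop("radii must be 3 ascending values")
  if (n_terms < 20L) stop("n_terms must be >= 20")
  ecc <- sqrt(rowSums(src$positions^2))
  if (any(ecc >= radii[1L]))
    stop("all sources must lie strictly inside the innermost radius")
  sp <- sensors$positions
  rs <- sqrt(rowSums(sp^2))
  sp <- sp / rs * radii[3L]                 # project to outer sphere
  Gn <- .three_shell_gain(n_terms, radii, sigmas)
  s <- nrow(src$positions)
  L <- matrix(0, nrow(sp), 3L * s)
  for (j in seq_len(s))
    L[, (3L * j - 2L):(3L * j)] <-
      .sphere_series_potential(sp, src$positions[j, ], Gn, radii[3L])
  lf <- lead_field(L, "free", units = "V/(A.m)", reference = "none",
                   provenance = "three_shell_sphere", labels = sensors$labels)
  if (src$orientation_mode == "constrained")
    lf <- apply_orientation_constraint(lf, src$orientations)
  if (identical(reference, "average")) {
    lf$matrix <- apply_average_reference(lf$matrix)
    lf$reference <- "average"
  }
  lf
}

#' Spherical-conductor MEG lead field (magnetometers)
#'
#' Closed-form magnetic field of a current dipole in a spherically
#' symmetric conductor (Sarvas formula), measured along each
#' magnetometer's orientation. Independent of the conductivity profile;
#' radial dipoles are magnetically silent.
#'
#' @param src a [source_space()].
#' @param sensors a `meg_magnetometer` [sensor_array()] with orientations.
#' @param sphere_center conductor center (default origin).
#' @return A [lead_field()] in T/(A.m).
#' @export
sphere_leadfield_meg <- function(src, sensors, sphere_center = c(0, 0, 0)) {
  if (sensors$type != "meg_magnetometer")
    stop("sphere MEG model needs magnetometer sensors")
  mu0 <- 4 * pi * 1e-7
  sp <- sweep(sensors$positions, 2L, sphere_center)
  q0 <- sweep(src$positions, 2L, sphere_center)
  ns <- nrow(sp); s <- nrow(q0)
  L <- matrix(0, ns, 3L * s)
  for (j in seq_len(s)) {
    r0 <- q0[j, ]
    for (i in seq_len(ns)) {
      r <- sp[i, ]
      a_vec <- r - r0
      a <- sqrt(sum(a_vec^2)); rn <- sqrt(sum(r^2))
      if (a < 1e-9) stop("sensor coincides with a source")
      F <- a * (rn * a + rn^2 - sum(r0 * r))
      gF <- (a^2 / rn + sum(a_vec * r) / a + 2 * a + 2 * rn) * r -
        (a + 2 * rn + sum(a_vec * r) / a) * r0
      # B(q) = mu0/(4 pi F^2) * (F (q x r0) - (q x r0 . r) gF); linear in q
      # columns for unit moments ex, ey, ez
      for (c3 in 1:3) {
        q <- c(0, 0, 0); q[c3] <- 1
        qxr0 <- c(q[2L] * r0[3L] - q[3L] * r0[2L],
                  q[3L] * r0[1L] - q[1L] * r0[3L],
                  q[1L] * r0[2L] - q[2L] * r0[1L])
        B <- mu0 / (4 * pi * F^2) * (F * qxr0 - sum(qxr0 * r) * gF)
        L[i, 3L * (j - 1L) + c3] <- sum(B * sensors$orientations[i, ])
      }
    }
  }
  lf <- lead_field(L, "free", units = "T/(A.m)", reference = "none",
                   provenance = "sphere_meg", labels = sensors$labels)
  if (src$orientation_mode == "constrained")
    lf <- apply_orientation_constraint(lf, src$orientations)
  lf
}
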