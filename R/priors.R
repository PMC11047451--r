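#' Rotational-invariance standardization of a free lead field
#'
#' Realizes the rotationally invariant orientation prior via the
#' standardization route: the free-orientation (3 columns per source)
#' lead field is projected onto the cortical normals, so the inverse
#' problem is solved for a complex scalar field per source; the stored
#' machinery lets [rotational_invariance_destandardize()] lift solutions
#' back to 3 x 3 tensor-field cross-spectra and re-project them onto the
#' empirical maximum-amplitude directions.
#'
#' @param L_free a free-orientation [lead_field()].
#' @param normals S x 3 unit normals.
#' @return List of class `std_leadfield`: `L_std` (constrained
#'   [lead_field()]), `machinery` (normals, the free matrix, transform
#'   tags).
#' @export
rotational_invariance_standardize <- function(L_free, normals) {
  normals <- as.matrix(normals)
  if (any(sqrt(rowSums(normals^2)) < 1e-12))
    stop("zero normal vector")
  if (any(abs(sqrt(rowSums(normals^2)) - 1) > 1e-6))
    stop("normals must be unit norm")
  L_std <- apply_orientation_constraint(L_free, normals)
  structure(list(L_std = L_std,
                 machinery = list(kind = "rotational_invariance",
                                  normals = normals, L_free = L_free,
                                  L_std_matrix = L_std$matrix)),
            class = "std_leadfield")
}

#' De-standardize a scalar source cross-spectrum to the tensor field
#'
#' Inverts the rotational-invariance standardization: lifts the
#' normal-projected (scalar per source) cross-spectral solution back to
#' 3 x 3 complex spectral tensors per source, finds each source's real
#' unit direction of maximum spectral amplitude, and returns the solution
#' re-projected onto those directions. When the sensor cross-spectrum and
#' the solver's source variance scales are supplied, the lift uses the
#' free-orientation lead field (so tangential components can be
#' recovered); otherwise it degenerates to the normal direction.
#'
#' @param S_scalar S x S complex Hermitian source cross-spectrum from the
#'   standardized (normal-projected) problem.
#' @param machinery the `machinery` element of
#'   [rotational_invariance_standardize()].
#' @param S_vv optional N x N sensor cross-spectral slice.
#' @param gamma optional per-source prior variance scales (length S).
#' @param sigma2 sensor noise variance used by the solver.
#' @return List: `tensor_diag` (S x 3 x 3 per-source spectral tensors),
#'   `max_directions` (S x 3 real unit vectors), `S_projected`
#'   (S x S complex, solution projected on the max-amplitude directions).
#' @export
rotational_invariance_destandardize <- function(S_scalar, machinery,
                                                S_vv = NULL, gamma = NULL,
                                                sigma2 = NULL) {
  if (!is_hermitian(S_scalar, tol = 1e-8))
    stop("source cross-spectrum must be Hermitian")
  nrm <- machinery$normals
  s <- nrow(nrm)
  tensor_diag <- array(0i, c(s, 3L, 3L))
  if (!is.null(S_vv) && !is.null(gamma) && !is.null(sigma2)) {
    # isotropic free-orientation posterior: each source carries a 3D
    # moment with prior variance gamma_i/3 per Cartesian component, so
    # the lifted tensors are not biased by the local lead-field Gram
    Lf <- machinery$L_free$matrix
    g3 <- rep(gamma / 3, each = 3L)
    Sigma3 <- Lf %*% (g3 * t(Lf)) + diag(sigma2, nrow(Lf))
    T3 <- (g3 * t(Lf)) %*% solve(Sigma3)
    G <- T3 %*% S_vv %*% Conj(t(T3))
    for (i in seq_len(s)) {
      idx <- (3L * i - 2L):(3L * i)
      tensor_diag[i, , ] <- G[idx, idx]
    }
  } else {
    for (i in seq_len(s))
      tensor_diag[i, , ] <- Re(S_scalar[i, i]) * (nrm[i, ] %o% nrm[i, ])
  }
  maxdir <- matrix(0, s, 3L)
  for (i in seq_len(s)) {
    M <- Re(tensor_diag[i, , ])
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
    v <- ev$vectors[, 1L]
    if (sum(v * nrm[i, ]) < 0) v <- -v    # deterministic sign
    maxdir[i, ] <- v
  }
  proj <- rowSums(maxdir * nrm)      # cos(angle to normal) per source
  S_projected <- S_scalar * (proj %o% proj)
  list(tensor_diag = tensor_diag, max_directions = maxdir,
       S_projected = S_projected)
}

#' Curvature depth-compensation weights
#'
#' Piecewise-linear transform of mean curvature into strictly positive
#' per-source weights, with separate slope and intercept for the gyral
#' (H >= 0) and sulcal (H < 0) branches; lead-field columns are divided
#' by these weights to compensate the curvature-dependent observability
#' bias. Defaults of slope 0 and intercept 1 disable the compensation.
#'
#' @param H mean curvature per source (1/m).
#' @param slope_gyri,intercept_gyri gyral branch parameters.
#' @param slope_sulci,intercept_sulci sulcal branch parameters.
#' @return Strictly positive weight vector, length S.
#' @export
curvature_compensation_weights <- function(H, slope_gyri = 0.5,
                                           intercept_gyri = 1,
                                           slope_sulci = 0.5,
                                           intercept_sulci = 1) {
  if (!all(is.finite(H))) stop("curvature values must be finite")
  w <- ifelse(H >= 0, intercept_gyri + slope_gyri * H,
              intercept_sulci + slope_sulci * H)
  if (any(w <= 0))
    stop("curvature weights must be strictly positive; adjust slopes/intercepts")
  w
}

#' Apply curvature weights to a lead field (standardization)
#'
#' @param L a constrained [lead_field()] or matrix.
#' @param weights output of [curvature_compensation_weights()].
#' @return `std_leadfield` whose de-standardization divides estimated
#'   source amplitudes by the weights.
#' @export
curvature_standardize <- function(L, weights) {
  M <- if (inherits(L, "lead_field")) L$matrix else as.matrix(L)
  if (ncol(M) != length(weights)) stop("weights/source count mismatch")
  Ms <- sweep(M, 2L, weights, "/")
  Ls <- if (inherits(L, "lead_field"))
    lead_field(Ms, L$orientation_mode, units = L$units, reference = L$reference,
               provenance = L$provenance, labels = L$labels)
  else Ms
  structure(list(L_std = Ls,
                 machinery = list(kind = "curvature", weights = weights)),
            class = "std_leadfield")
}

#' Graph-Laplacian standardization of a lead field
#'
#' Multiplies the lead field by the (deformed) graph-Laplacian
#' pseudoinverse, so smooth source configurations become cheap under the
#' solver's penalty; the inverse transform maps standardized estimates
#' back (`x = M x_std`).
#'
#' @param L constrained [lead_field()] or matrix (sensors x sources).
#' @param lap a [graph_laplacian()] built on the source mesh.
#' @return `std_leadfield` with `machinery$M` the standardization factor.
#' @export
laplacian_standardize <- function(L, lap) {
  Lm <- if (inherits(L, "lead_field")) L$matrix else as.matrix(L)
  M <- laplacian_pseudoinverse_factor(lap)
  if (ncol(Lm) != nrow(M)) stop("lead field / Laplacian dimension mismatch")
  Ms <- Lm %*% M
  Ls <- if (inherits(L, "lead_field"))
    lead_field(Ms, L$orientation_mode, units = L$units, reference = L$reference,
               provenance = L$provenance, labels = L$labels)
  else Ms
  structure(list(L_std = Ls,
                 machinery = list(kind = "laplacian", M = M,
                                  deformation = lap$deformation)),
            class = "std_leadfield")
}

#' De-standardize estimates through a standardization machinery
#'
#' Maps solver outputs on the standardized problem back to the original
#' source scale: curvature weights divide back, the Laplacian factor
#' multiplies back (coefficients `x = M x_std`; cross-spectra
#' `M S M^H`).
#'
#' @param x vector/matrix of standardized source coefficients, or an
#'   S x S cross-spectral matrix when `cross_spectrum = TRUE`.
#' @param machinery machinery from a `std_leadfield`.
#' @param cross_spectrum treat `x` as an S x S Hermitian matrix.
#' @return De-standardized estimate.
#' @export
destandardize <- function(x, machinery, cross_spectrum = FALSE) {
  switch(machinery$kind,
    curvature = {
      w <- machinery$weights
      if (cross_spectrum) x / (w %o% w) else x / w
    },
    laplacian = {
      M <- machinery$M
      if (cross_spectrum) M %*% x %*% Conj(t(M)) else M %*% x
    },
    rotational_invariance = x,
    stop(sprintf("unknown standardization '%s'", machinery$kind)))
}

#' Parcellation grouping structure
#'
#' Maps an integer label per source to the group index structure the
#' type-one solver consumes (one variance scale per brain area instead of
#' one per source).
#'
#' @param labels integer/character labels, length S, no NA.
#' @return List of class `parcellation`: `groups` (named list of member
#'   indices), `index` (group id per source).
#' @export
parcellation_groups <- function(labels) {
  if (anyNA(labels)) stop("every source needs a parcellation label")
  f <- factor(labels)
  groups <- split(seq_along(labels), f)
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty parcellation group")
  structure(list(groups = groups, index = as.integer(f),
                 n_groups = nlevels(f)), class = "parcellation")
}
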