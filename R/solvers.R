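#' Solver configuration
#'
#' @param method "sssbl", "eloreta" or "lcmv".
#' @param type2 Hermitian-graph penalty: "hglasso" or "hgridge".
#' @param alpha1 square-root (quasinorm) penalty weight on source scales.
#' @param alpha2 linear (nuclear) penalty weight on source scales.
#' @param alpha_graph off-diagonal l1 weight for HGLASSO / Frobenius
#'   weight for HGRidge.
#' @param noise_variance sensor noise variance sigma^2; NA = estimate as
#'   the mean of the smallest ceiling(N/4) eigenvalues of each slice.
#' @param max_iter,tolerance iteration controls.
#' @param support_threshold posterior-probability cutoff for the sparse
#'   support.
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(method = c("sssbl", "eloreta", "lcmv"),
                          type2 = c("hglasso", "hgridge"),
                          alpha1 = 0.1, alpha2 = 0.01, alpha_graph = 0.1,
                          noise_variance = NA, max_iter = 200L,
                          tolerance = 1e-6, support_threshold = 0.95) {
  method <- match.arg(method); type2 <- match.arg(type2)
  if (alpha1 < 0 || alpha2 < 0 || alpha_graph < 0)
    stop("penalty weights must be >= 0")
  if (tolerance <= 0) stop("tolerance must be > 0")
  structure(list(method = method, type2 = type2, alpha1 = alpha1,
                 alpha2 = alpha2, alpha_graph = alpha_graph,
                 noise_variance = noise_variance,
                 max_iter = as.integer(max_iter), tolerance = tolerance,
                 support_threshold = support_threshold),
            class = "solver_config")
}

.estimate_noise_variance <- function(S_slice) {
  ev <- sort(Re(eigen(S_slice, symmetric = TRUE, only.values = TRUE)$values))
  k <- ceiling(nrow(S_slice) / 4)
  max(mean(ev[seq_len(k)]), 1e-18 * max(ev))
}

# unique positive root of a2*u^4 + (a1/2)*u^3 + m*u^2 - m*M = 0 (u = sqrt(gamma));
# vectorized safeguarded Newton from u0 = sqrt(M)
.gamma_update <- function(M, m, a1, a2) {
  M <- pmax(M, 0)
  if (a1 == 0 && a2 == 0) return(M)
  u <- sqrt(M)
  for (it in 1:60) {
    f <- a2 * u^4 + (a1 / 2) * u^3 + m * u^2 - m * M
    fp <- 4 * a2 * u^3 + 1.5 * a1 * u^2 + 2 * m * u
    step <- ifelse(fp > 0, f / fp, 0)
    u_new <- pmax(u - step, 0)
    if (max(abs(u_new - u)) < 1e-14 * max(1, max(u))) { u <- u_new; break }
    u <- u_new
  }
  u^2
}

#' Spectral structured sparse Bayesian learning (type-one solver)
#'
#' Evidence-maximization estimate of per-source (or per-parcel) variance
#' scales gamma under the complex Gaussian data model
#' v ~ CN(0, L diag(gamma) L^H + sigma^2 I), with the combined
#' square-root (quasinorm) and linear (nuclear) penalty
#' alpha1 * sum sqrt(gamma) + alpha2 * sum gamma on the scales. On
#' convergence the per-frequency quasilinear operator is
#' T = diag(gamma) L^H (L diag(gamma) L^H + sigma^2 I)^-1, the source
#' cross-spectrum T S_vv T^H plus the posterior-covariance correction,
#' and the sparse support thresholds the posterior concentration
#' p_i = gamma_i l_i^H Sigma^-1 l_i in [0, 1].
#'
#' @param S_vv a `cross_spectrum` (sensor-level) or an N x N x F array.
#' @param L constrained [lead_field()] or N x S matrix (standardize
#'   through the prior transforms first where wanted).
#' @param m effective sample count (taken from `S_vv` when absent).
#' @param cfg a [solver_config()].
#' @param parcellation optional [parcellation_groups()] output: one
#'   gamma per group.
#' @return List of class `sssbl_fit`: `operator` (S x N x F complex),
#'   `S_jj` (S x S x F), `gamma` (S x F), `support_prob` (S x F),
#'   `support` (logical S x F), `sigma2` (F), `frequencies`, `iterations`.
#' @export
sssbl_solve <- function(S_vv, L, m = NULL, cfg = solver_config(),
                        parcellation = NULL) {
  Sarr <- if (inherits(S_vv, "cross_spectrum")) S_vv$S else S_vv
  if (length(dim(Sarr)) == 2L) Sarr <- array(Sarr, c(dim(Sarr), 1L))
  freqs <- if (inherits(S_vv, "cross_spectrum")) S_vv$frequencies
           else seq_len(dim(Sarr)[3L])
  if (is.null(m)) m <- if (inherits(S_vv, "cross_spectrum")) S_vv$m else 1L
  Lm <- if (inherits(L, "lead_field")) L$matrix else as.matrix(L)
  if (inherits(L, "lead_field") && L$orientation_mode == "free")
    stop("sssbl needs an orientation-constrained (or standardized) lead field")
  n <- nrow(Lm); s <- ncol(Lm)
  if (any(colSums(abs(Lm)) == 0)) stop("lead field has an all-zero column")
  nf <- dim(Sarr)[3L]
  gam <- matrix(0, s, nf)
  prob <- matrix(0, s, nf)
  Tarr <- array(0i, c(s, n, nf))
  Sjj <- array(0i, c(s, s, nf))
  sig2 <- numeric(nf)
  iters <- integer(nf)
  # scale handling: solver works on the raw scale; gamma initialized from
  # a matched-filter estimate per slice
  for (k in seq_len(nf)) {
    Sk <- Sarr[, , k]
    if (min_eig_ratio((Re(Sk) + t(Re(Sk))) / 2) < -1e-8)
      stop("sensor cross-spectral slice is not positive semidefinite")
    sigma2 <- if (is.na(cfg$noise_variance)) .estimate_noise_variance(Sk)
              else cfg$noise_variance
    cn2 <- colSums(Lm^2)
    g <- pmax(Re(colSums(Conj(Lm) * (Sk %*% Lm))) / cn2^2, 0) # matched filter
    g <- pmax(g, 1e-12 * max(g))
    for (it in seq_len(cfg$max_iter)) {
      Sigma <- Lm %*% (g * t(Lm)) + diag(sigma2, n)
      Si <- solve(Sigma)
      TL <- g * (t(Lm) %*% Si)            # s x n operator (real Si if real Sk)
      # posterior second moments: data part + posterior covariance
      data_part <- Re(rowSums((TL %*% Sk) * Conj(TL)))
      lSl <- Re(colSums(Lm * (Si %*% Lm)))       # l_i^H Si l_i
      post_var <- pmax(g - g^2 * lSl, 0)
      M2 <- data_part + post_var
      if (!is.null(parcellation)) {
        # one scale per group: average the moment over group members
        gm <- vapply(parcellation$groups, function(ix) mean(M2[ix]), 1)
        gnew_g <- .gamma_update(gm, m, cfg$alpha1, cfg$alpha2)
        g_new <- gnew_g[parcellation$index]
      } else {
        g_new <- .gamma_update(M2, m, cfg$alpha1, cfg$alpha2)
      }
      rel <- max(abs(g_new - g)) / max(max(g), 1e-300)
      g <- g_new
      if (rel < cfg$tolerance) break
    }
    iters[k] <- it
    Sigma <- Lm %*% (g * t(Lm)) + diag(sigma2, n)
    Si <- solve(Sigma)
    TL <- g * (t(Lm) %*% Si)
    Sjj_k <- TL %*% Sk %*% Conj(t(TL))
    lSl <- Re(colSums(Lm * (Si %*% Lm)))
    post_var <- pmax(g - g^2 * lSl, 0)
    diag(Sjj_k) <- Re(diag(Sjj_k)) + post_var
    Tarr[, , k] <- TL
    Sjj[, , k] <- (Sjj_k + Conj(t(Sjj_k))) / 2
    gam[, k] <- g
    prob[, k] <- pmin(pmax(g * lSl, 0), 1)
    sig2[k] <- sigma2
  }
  support <- prob >= cfg$support_threshold
  structure(list(operator = Tarr, S_jj = Sjj, gamma = gam,
                 support_prob = prob, support = support, sigma2 = sig2,
                 frequencies = freqs, iterations = iters, m = m,
                 config = cfg),
            class = "sssbl_fit")
}

#' Sparse support from SSSBL posterior statistics
#'
#' Thresholds the per-frequency posterior concentration; `joint` unions
#' ("union") or intersects ("intersection") the per-frequency supports
#' into a single joint support across the frequency domain.
#'
#' @param fit an `sssbl_fit`.
#' @param threshold posterior-probability cutoff (sources with
#'   probability >= threshold are kept).
#' @param joint NULL (per frequency), "union" or "intersection".
#' @return Logical S x F matrix, or logical S vector in joint mode.
#' @export
sssbl_support <- function(fit, threshold = 0.95, joint = NULL) {
  mask <- fit$support_prob >= threshold
  if (is.null(joint)) return(mask)
  joint <- match.arg(joint, c("union", "intersection"))
  if (joint == "union") apply(mask, 1L, any) else apply(mask, 1L, all)
}

#' Hermitian graphical ridge (closed form)
#'
#' Unique Hermitian positive-definite stationary point of
#' -logdet(Theta) + tr(S Theta) + (alpha/2) ||Theta||_F^2: with
#' S = U diag(d) U^H, Theta = U diag(theta) U^H where
#' theta_i = (-d_i + sqrt(d_i^2 + 4 alpha)) / (2 alpha).
#'
#' @param S Hermitian PSD matrix.
#' @param alpha Frobenius penalty weight, > 0.
#' @return Hermitian PD precision matrix.
#' @export
hgridge_solve <- function(S, alpha) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (!is_hermitian(S, tol = 1e-8)) stop("S must be Hermitian")
  ee <- eigen((S + Conj(t(S))) / 2, symmetric = TRUE)
  th <- (-ee$values + sqrt(ee$values^2 + 4 * alpha)) / (2 * alpha)
  Th <- ee$vectors %*% (th * Conj(t(ee$vectors)))
  (Th + Conj(t(Th))) / 2
}

.soft_complex <- function(z, lam) {
  mod <- Mod(z)
  shrink <- pmax(mod - lam, 0)
  out <- z
  nz <- mod > 0
  out[nz] <- z[nz] * (shrink[nz] / mod[nz])
  out[!nz] <- 0
  out
}

#' Hermitian graphical lasso
#'
#' Minimizes -logdet(Theta) + tr(S Theta) + alpha * sum_{i != j}
#' |Theta_ij| over Hermitian positive-definite matrices (complex l1 on
#' moduli, diagonal unpenalized), by ADMM with complex soft-thresholding.
#' The returned matrix is the sparse iterate, so off-diagonal zeros are
#' exact. alpha = 0 returns the unpenalized inverse.
#'
#' @param S Hermitian matrix with positive diagonal.
#' @param alpha_graph off-diagonal penalty weight, >= 0.
#' @param rho ADMM step parameter.
#' @param max_iter,tol iteration controls (`tol` on primal/dual
#'   residuals).
#' @return Hermitian PD precision matrix with exact off-diagonal zeros.
#' @export
hglasso_solve <- function(S, alpha_graph, rho = 1, max_iter = 5000L,
                          tol = 1e-7) {
  if (!is_hermitian(S, tol = 1e-8)) stop("S must be Hermitian")
  if (any(Re(diag(S)) <= 0)) stop("S must have a positive diagonal")
  if (alpha_graph < 0) stop("alpha_graph must be >= 0")
  n <- nrow(S)
  if (alpha_graph == 0) return(solve((S + Conj(t(S))) / 2))
  Z <- diag(1 / Re(diag(S)))
  U <- matrix(0i, n, n)
  Theta <- Z
  for (it in seq_len(max_iter)) {
    # Theta update: argmin -logdet + tr(S Theta) + rho/2 ||Theta - Z + U||^2
    A <- rho * (Z - U) - S
    A <- (A + Conj(t(A))) / 2
    ee <- eigen(A, symmetric = TRUE)
    th <- (ee$values + sqrt(ee$values^2 + 4 * rho)) / (2 * rho)
    Theta <- ee$vectors %*% (th * Conj(t(ee$vectors)))
    Theta <- (Theta + Conj(t(Theta))) / 2
    # Z update: soft-threshold off-diagonals
    Z_old <- Z
    W <- Theta + U
    Z <- .soft_complex(W, alpha_graph / rho)
    diag(Z) <- diag(W)
    Z <- (Z + Conj(t(Z))) / 2
    U <- U + Theta - Z
    pri <- sqrt(sum(Mod(Theta - Z)^2))
    dua <- rho * sqrt(sum(Mod(Z - Z_old)^2))
    if (pri < tol * max(1, sqrt(sum(Mod(Z)^2))) && dua < tol * max(1, rho))
      return(Z)
  }
  stop(sprintf(
    "hglasso did not reach tolerance in %d iterations (primal residual %.3e)",
    max_iter, pri))
}

#' Two-step HIGGS: Hermitian graph on the SSSBL source cross-spectrum
#'
#' Per frequency slice, restricts the source cross-spectrum to the sparse
#' support and estimates the Hermitian precision there with HGLASSO or
#' HGRidge; off-support entries are fixed at zero.
#'
#' @param S_jj S x S x F complex array (or `sssbl_fit` whose `S_jj` and
#'   `support` are used).
#' @param support logical S x F (or S) mask.
#' @param cfg a [solver_config()] (`type2`, `alpha_graph`).
#' @return List of class `higgs_fit`: `precision` (S x S x F complex),
#'   `support`.
#' @export
higgs_two_step <- function(S_jj, support = NULL, cfg = solver_config()) {
  if (inherits(S_jj, "sssbl_fit")) {
    if (is.null(support)) support <- S_jj$support
    S_jj <- S_jj$S_jj
  }
  if (length(dim(S_jj)) == 2L) S_jj <- array(S_jj, c(dim(S_jj), 1L))
  s <- dim(S_jj)[1L]; nf <- dim(S_jj)[3L]
  if (is.null(support)) support <- matrix(TRUE, s, nf)
  if (is.vector(support)) support <- matrix(support, s, nf)
  Theta <- array(0i, c(s, s, nf))
  for (k in seq_len(nf)) {
    on <- which(support[, k])
    if (!length(on)) stop("empty support at slice ", k)
    Ssub <- S_jj[on, on, k, drop = TRUE]
    if (length(on) == 1L) {
      Theta[on, on, k] <- 1 / Re(Ssub)
      next
    }
    Th <- if (cfg$type2 == "hgridge") hgridge_solve(Ssub, cfg$alpha_graph)
          else hglasso_solve(Ssub, cfg$alpha_graph)
    Theta[on, on, k] <- Th
  }
  structure(list(precision = Theta, support = support, config = cfg,
                 method = "two_step"), class = "higgs_fit")
}

.higgs_objective <- function(S_vv, Lm, Theta, sigma2, m, alpha, type2) {
  Sigma <- Lm %*% solve(Theta, Conj(t(Lm))) + diag(sigma2, nrow(Lm))
  Si <- solve(Sigma)
  logdet <- sum(log(pmax(Re(eigen(Sigma, symmetric = TRUE,
                                  only.values = TRUE)$values), 1e-300)))
  ll <- -m * (logdet + Re(sum(diag(Si %*% S_vv))))
  pen <- if (type2 == "hglasso") {
    Om <- Mod(Theta); diag(Om) <- 0
    alpha * sum(Om)
  } else (alpha / 2) * sum(Mod(Theta)^2)
  ll - pen
}

#' One-step HIGGS: EM on the sensor cross-spectrum
#'
#' EM-style iteration per frequency on the support-restricted model
#' v ~ CN(0, L Theta^-1 L^H + sigma^2 I): the E-step forms the posterior
#' source cross-spectrum under the current precision, the M-step fits
#' HGLASSO/HGRidge to it. Returns the precision tensor and the
#' quasilinear operator T = Theta^-1 L^H (L Theta^-1 L^H + sigma^2 I)^-1.
#' The penalized marginal likelihood is tracked; five consecutive
#' decreases abort with an error trace.
#'
#' @param S_vv `cross_spectrum` or N x N x F array.
#' @param L constrained [lead_field()] or matrix.
#' @param support logical S x F (or S) sparse support from SSSBL.
#' @param cfg a [solver_config()].
#' @param m effective sample count.
#' @return `higgs_fit` with `precision` (S x S x F), `operator`
#'   (S x N x F), `objective` trace per slice.
#' @export
higgs_one_step <- function(S_vv, L, support, cfg = solver_config(), m = NULL) {
  Sarr <- if (inherits(S_vv, "cross_spectrum")) S_vv$S else S_vv
  if (length(dim(Sarr)) == 2L) Sarr <- array(Sarr, c(dim(Sarr), 1L))
  if (is.null(m)) m <- if (inherits(S_vv, "cross_spectrum")) S_vv$m else 1L
  Lm <- if (inherits(L, "lead_field")) L$matrix else as.matrix(L)
  n <- nrow(Lm); s <- ncol(Lm); nf <- dim(Sarr)[3L]
  if (is.vector(support)) support <- matrix(support, s, nf)
  Theta_out <- array(0i, c(s, s, nf))
  T_out <- array(0i, c(s, n, nf))
  obj_trace <- vector("list", nf)
  for (k in seq_len(nf)) {
    Sk <- Sarr[, , k]
    on <- which(support[, k])
    if (!length(on)) stop("empty support at slice ", k)
    Ls <- Lm[, on, drop = FALSE]
    p <- length(on)
    sigma2 <- if (is.na(cfg$noise_variance)) .estimate_noise_variance(Sk)
              else cfg$noise_variance
    Theta <- diag(p) + 0i
    objs <- numeric(0)
    bad <- 0L
    for (it in seq_len(cfg$max_iter)) {
      Gam <- solve(Theta)
      Sigma <- Ls %*% Gam %*% Conj(t(Ls)) + diag(sigma2, n)
      Si <- solve(Sigma)
      TT <- Gam %*% Conj(t(Ls)) %*% Si
      S_post <- TT %*% Sk %*% Conj(t(TT)) + Gam - TT %*% Ls %*% Gam
      S_post <- (S_post + Conj(t(S_post))) / 2
      # ensure a positive diagonal for the graph step
      dshift <- max(0, -min(Re(diag(S_post)))) + 1e-15 * max(Re(diag(S_post)))
      if (dshift > 0) S_post <- S_post + diag(dshift, p)
      Theta_new <- if (cfg$type2 == "hgridge")
        hgridge_solve(S_post, cfg$alpha_graph / max(m, 1))
      else hglasso_solve(S_post, cfg$alpha_graph / max(m, 1))
      obj <- .higgs_objective(Sk, Ls, Theta_new, sigma2, m,
                              cfg$alpha_graph, cfg$type2)
      if (length(objs) && obj < objs[length(objs)] - 1e-9 * abs(objs[length(objs)]))
        bad <- bad + 1L else bad <- 0L
      if (bad >= 5L)
        stop(sprintf("higgs_one_step diverging at slice %d: objective trace %s",
                     k, paste(signif(utils::tail(c(objs, obj), 6), 6),
                              collapse = ", ")))
      rel <- sqrt(sum(Mod(Theta_new - Theta)^2)) /
        max(sqrt(sum(Mod(Theta)^2)), 1e-300)
      Theta <- Theta_new
      objs <- c(objs, obj)
      if (rel < cfg$tolerance) break
    }
    Gam <- solve(Theta)
    Sigma <- Ls %*% Gam %*% Conj(t(Ls)) + diag(sigma2, n)
    TT <- Gam %*% Conj(t(Ls)) %*% solve(Sigma)
    Theta_out[on, on, k] <- Theta
    T_out[on, , k] <- TT
    obj_trace[[k]] <- objs
  }
  structure(list(precision = Theta_out, operator = T_out, support = support,
                 objective = obj_trace, config = cfg, method = "one_step"),
            class = "higgs_fit")
}

#' eLORETA inverse operator
#'
#' Weighted minimum-norm with the exact low-resolution tomography weight
#' fixed point: w_i = sqrt(l_i^T M l_i) with
#' M = (L W^-1 L^T + reg I)^+, iterated to tolerance; the operator is
#' T = W^-1 L^T M. For noise-free point sources and vanishing
#' regularization the estimated power attains its maximum at the true
#' source (zero localization error).
#'
#' @param C_vv sensor covariance/cross-spectral slice (used only to apply
#'   the operator; the weights depend on the lead field and `reg`).
#' @param L constrained [lead_field()] or N x S matrix.
#' @param reg regularization added to L W^-1 L^T (default 0: pseudoinverse).
#' @param max_iter,tol fixed-point controls.
#' @return List of class `quasilinear_op`: `T` (S x N), `weights`,
#'   `iterations`, `converged`.
#' @export
eloreta_solve <- function(C_vv = NULL, L, reg = 0, max_iter = 200L,
                          tol = 1e-8) {
  Lm <- if (inherits(L, "lead_field")) L$matrix else as.matrix(L)
  n <- nrow(Lm); s <- ncol(Lm)
  w <- rep(1, s)
  pinv_reg <- function(A) {
    ee <- eigen((A + t(A)) / 2, symmetric = TRUE)
    pos <- ee$values > 1e-12 * max(ee$values)
    ee$vectors[, pos, drop = FALSE] %*%
      (t(ee$vectors[, pos, drop = FALSE]) / ee$values[pos])
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Lw <- sweep(Lm, 2L, w, "/")
    G <- Lw %*% t(Lm)           # L W^-1 L^T
    M <- pinv_reg(G + diag(reg, n))
    w_new <- sqrt(pmax(colSums(Lm * (M %*% Lm)), 0))
    w_new <- w_new / mean(w_new)          # fix the scale indeterminacy
    rel <- max(abs(w_new - w)) / max(w)
    w <- w_new
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("eLORETA weights did not reach tolerance; using last iterate")
  Lw <- sweep(Lm, 2L, w, "/")
  M <- pinv_reg(Lw %*% t(Lm) + diag(reg, n))
  T <- sweep(t(Lm) %*% M, 1L, w, "/")
  structure(list(T = T, weights = w, iterations = it, converged = converged,
                 method = "eloreta", reg = reg),
            class = "quasilinear_op")
}

#' LCMV beamformer operator
#'
#' Unit-gain linearly constrained minimum-variance filter per source:
#' row i = l_i^H C^-1 / (l_i^H C^-1 l_i), with `reg` added to the sensor
#' covariance diagonal before inversion.
#'
#' @param C_vv Hermitian positive-definite sensor covariance.
#' @param L constrained [lead_field()] or matrix.
#' @param reg diagonal loading.
#' @return `quasilinear_op` with `T` (S x N).
#' @export
lcmv_solve <- function(C_vv, L, reg = 0) {
  Lm <- if (inherits(L, "lead_field")) L$matrix else as.matrix(L)
  C <- C_vv + diag(reg, nrow(C_vv))
  Ci <- tryCatch(solve(C), error = function(e)
    stop("regularized covariance is singular; increase reg"))
  num <- Conj(t(Lm)) %*% Ci                 # s x n
  den <- Re(rowSums(num * t(Lm)))           # l_i^H C^-1 l_i
  structure(list(T = num / den, method = "lcmv", reg = reg),
            class = "quasilinear_op")
}

#' Apply a quasilinear operator to a data metric
#'
#' Coefficient vectors/matrices map as T z; cross-spectral matrices or
#' tensors map as T S T^H per frequency slice (Hermitian PSD is
#' preserved). Applying the stored operator to the stored data tensor
#' reproduces the solver's source tensor, which is why only the operator
#' and the data metrics need archiving.
#'
#' @param op a `quasilinear_op`, `sssbl_fit`, `higgs_fit`, or S x N
#'   matrix / S x N x F array.
#' @param x data metric: coefficients (N x m) or cross-spectrum
#'   (N x N or N x N x F array / `cross_spectrum`).
#' @param metric "coefficients" or "cross_spectrum".
#' @return The analogous source metric.
#' @export
apply_operator <- function(op, x, metric = c("cross_spectrum", "coefficients")) {
  metric <- match.arg(metric)
  Tarr <- if (inherits(op, "quasilinear_op")) op$T
          else if (inherits(op, c("sssbl_fit", "higgs_fit"))) op$operator
          else op
  xarr <- if (inherits(x, "cross_spectrum")) x$S else x
  if (metric == "coefficients") {
    if (length(dim(Tarr)) == 3L) {
      nf <- dim(Tarr)[3L]
      if (length(dim(xarr)) != 3L || dim(xarr)[3L] != nf)
        stop("frequency axes of operator and data do not match")
      out <- array(0i, c(dim(Tarr)[1L], dim(xarr)[2L], nf))
      for (k in seq_len(nf)) out[, , k] <- Tarr[, , k] %*% xarr[, , k]
      return(out)
    }
    return(Tarr %*% xarr)
  }
  if (length(dim(Tarr)) == 2L && length(dim(xarr)) == 2L) {
    out <- Tarr %*% xarr %*% Conj(t(Tarr))
    return((out + Conj(t(out))) / 2)
  }
  if (length(dim(Tarr)) == 2L && length(dim(xarr)) == 3L) {
    nf <- dim(xarr)[3L]
    out <- array(0i, c(nrow(Tarr), nrow(Tarr), nf))
    for (k in seq_len(nf)) {
      o <- Tarr %*% xarr[, , k] %*% Conj(t(Tarr))
      out[, , k] <- (o + Conj(t(o))) / 2
    }
    return(out)
  }
  nf <- dim(Tarr)[3L]
  if (length(dim(xarr)) != 3L || dim(xarr)[3L] != nf)
    stop("frequency axes of operator and data do not match")
  s <- dim(Tarr)[1L]
  out <- array(0i, c(s, s, nf))
  for (k in seq_len(nf)) {
    o <- Tarr[, , k] %*% xarr[, , k] %*% Conj(t(Tarr[, , k]))
    out[, , k] <- (o + Conj(t(o))) / 2
  }
  out
}
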