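test_that("HGRidge closed form: frozen value, inverse limit, optimality", {
  Th <- hgridge_solve(diag(3) + 0i, 1)
  expect_equal(Re(diag(Th)), rep((sqrt(5) - 1) / 2, 3), tolerance = 1e-12)
  expect_lt(max(Mod(Th - diag(Re(diag(Th))[1L], 3))), 1e-12)
  # alpha -> 0 recovers the inverse
  S <- random_hermitian_psd(4, seed = 41) + diag(4)
  Th0 <- hgridge_solve(S, 1e-8)
  expect_lt(max(Mod(Th0 - solve(S))), 1e-5)
  expect_error(hgridge_solve(S, 0), "alpha")
  # objective at the closed form beats random Hermitian PD perturbations
  obj <- function(Th, S, a) {
    ev <- Re(eigen(Th, symmetric = TRUE, only.values = TRUE)$values)
    -sum(log(ev)) + Re(sum(diag(S %*% Th))) + (a / 2) * sum(Mod(Th)^2)
  }
  a <- 0.5
  Ths <- hgridge_solve(S, a)
  o0 <- obj(Ths, S, a)
  set.seed(42)
  for (r in 1:100) {
    P <- random_hermitian_psd(4) * 0.05
    expect_gt(obj(Ths + P, S, a), o0)
  }
})

test_that("HGRidge closed form matches a generic numerical optimizer", {
  for (seed in c(1, 2, 3)) {
    S <- random_hermitian_psd(5, seed = seed) + diag(0.5, 5)
    a <- 0.3
    Th <- hgridge_solve(S, a)
    # independent route: numerical minimization over the eigenvalues of S
    # is insufficientlly general, so optimize the full Hermitian
    # parameterization (real + imaginary parts)
    pack <- function(M) c(Re(M[upper.tri(M, diag = TRUE)]),
                          Im(M[upper.tri(M)]))
    unpack <- function(p) {
      M <- matrix(0i, 5, 5)
      ut <- upper.tri(M, diag = TRUE)
      M[ut] <- p[seq_len(sum(ut))]
      M[upper.tri(M)] <- M[upper.tri(M)] +
        1i * p[(sum(ut) + 1):length(p)]
      M + Conj(t(M)) - diag(Re(diag(M)))
    }
    fobj <- function(p) {
      M <- unpack(p)
      ev <- Re(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
      if (min(ev) <= 1e-9) return(1e10)
      -sum(log(ev)) + Re(sum(diag(S %*% M))) + (a / 2) * sum(Mod(M)^2)
    }
    opt <- optim(pack(Th), fobj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_lt(max(Mod(unpack(opt$par) - Th)), 1e-4)
    expect_lte(fobj(pack(Th)), opt$value + 1e-8)
  }
})

test_that("HGLASSO: unpenalized inverse, exact saturation, edge recovery at oracle alpha", {
  S <- random_hermitian_psd(4, seed = 43) + diag(4)
  expect_lt(max(Mod(hglasso_solve(S, 0) - solve(S))), 1e-6)
  amax <- max(Mod(S - diag(diag(S))))
  Th <- hglasso_solve(S, amax * 1.0001)
  off <- Th; diag(off) <- 0
  expect_identical(max(Mod(off)), 0)   # exact zeros from the sparse iterate
  expect_equal(Re(diag(Th)), 1 / Re(diag(S)), tolerance = 1e-6)
  # planted Hermitian graph (ring + chords), m = 2000 samples
  fx <- hermitian_graph_fixture(m = 2000L, seed = 21L)
  est <- hglasso_solve(fx$S_hat, 0.15)
  expect_gte(edge_f1(est, fx$truth_edges), 0.8)
  # edge set is monotone non-increasing in the penalty
  sizes <- vapply(c(0.05, 0.15, 0.5), function(a) {
    E <- hglasso_solve(fx$S_hat, a)
    sum(Mod(E) > 1e-9 & !diag(TRUE, 10)) / 2
  }, 1)
  expect_true(all(diff(sizes) <= 0))
  expect_error(hglasso_solve(S - diag(10, 4), 0.1), "diagonal")
})

test_that("SSSBL reduces to the data in the noiseless identity problem", {
  Svv <- random_hermitian_psd(6, seed = 44)
  fit <- sssbl_solve(array(Svv, c(6, 6, 1)), diag(6), m = 100,
                     cfg = solver_config(alpha1 = 0, alpha2 = 0,
                                         noise_variance = 1e-10,
                                         max_iter = 500L,
                                         tolerance = 1e-10))
  expect_lt(max(Mod(fit$S_jj[, , 1] - Svv)) / max(Mod(Svv)), 1e-6)
})

test_that("SSSBL localizes three planted alpha-band sources on the sphere fixture", {
  sc <- solver_alpha_csd()
  scn <- solver_scene()
  fit <- sssbl_solve(array(sc$S_alpha, c(19, 19, 1)), scn$L, m = sc$m,
                     cfg = solver_config(alpha1 = 0.1, alpha2 = 0.1,
                                         max_iter = 300L, tolerance = 1e-7))
  spectra <- Re(diag(fit$S_jj[, , 1]))
  top10 <- order(spectra, decreasing = TRUE)[1:10]
  for (a in scn$active)
    expect_true(any(top10 %in% scn$ring1[[a]]))
  .fixture_cache$sssbl_alpha_fit <- fit
})

test_that("SSSBL support thresholds behave and sparsity is monotone in alpha1", {
  sc <- solver_alpha_csd()
  scn <- solver_scene()
  fit <- .fixture_cache$sssbl_alpha_fit
  expect_identical(sum(sssbl_support(fit, threshold = 0)), 500L)
  expect_lte(sum(sssbl_support(fit, threshold = 1)), 500L)
  expect_true(all(fit$support_prob >= 0 & fit$support_prob <= 1))
  s_lo <- fit
  s_hi <- sssbl_solve(array(sc$S_alpha, c(19, 19, 1)), scn$L, m = sc$m,
                      cfg = solver_config(alpha1 = 1, alpha2 = 0.1,
                                          max_iter = 300L, tolerance = 1e-7))
  expect_lte(sum(s_hi$support), sum(s_lo$support))
  # joint union/intersection modes on a two-slice fit
  two <- array(c(sc$S_alpha, sc$S_alpha), c(19, 19, 2))
  f2 <- sssbl_solve(two, scn$L, m = sc$m,
                    cfg = solver_config(alpha1 = 0.1, alpha2 = 0.1,
                                        max_iter = 100L))
  ju <- sssbl_support(f2, threshold = 0.9, joint = "union")
  ji <- sssbl_support(f2, threshold = 0.9, joint = "intersection")
  expect_true(all(ji[ju == FALSE] == FALSE))
})

test_that("two-step HIGGS: scalar support, identity input, edge recovery", {
  S1 <- array(2 + 0i, c(1, 1, 1))
  th <- higgs_two_step(S1, support = TRUE, cfg = solver_config())
  expect_equal(Re(th$precision[1, 1, 1]), 0.5, tolerance = 1e-12)
  Sid <- array(diag(5) + 0i, c(5, 5, 1))
  th2 <- higgs_two_step(Sid, support = rep(TRUE, 5),
                        cfg = solver_config(type2 = "hgridge",
                                            alpha_graph = 0.1))
  off <- th2$precision[, , 1]; diag(off) <- 0
  expect_lt(max(Mod(off)), 1e-10)
  fx <- hermitian_graph_fixture(m = 2000L, seed = 21L)
  Sjj <- array(fx$S_hat, c(10, 10, 1))
  thg <- higgs_two_step(Sjj, support = rep(TRUE, 10),
                        cfg = solver_config(type2 = "hglasso",
                                            alpha_graph = 0.15))
  expect_gte(edge_f1(thg$precision[, , 1], fx$truth_edges), 0.8)
  expect_error(higgs_two_step(Sid, support = rep(FALSE, 5)), "empty support")
})

test_that("one-step HIGGS: identity reduction, monotone objective, two-step agreement", {
  fx <- hermitian_graph_fixture(m = 2000L, seed = 21L)
  n <- 10L
  cfgl <- solver_config(type2 = "hglasso", alpha_graph = 100,
                        noise_variance = 1e-8, max_iter = 50L)
  one <- higgs_one_step(array(fx$S_hat, c(n, n, 1)), diag(n),
                        support = rep(TRUE, n), cfg = cfgl, m = fx$m)
  direct <- hglasso_solve(fx$S_hat, 100 / fx$m)
  expect_lt(max(Mod(one$precision[, , 1] - direct)) / max(Mod(direct)), 1e-4)
  # penalized likelihood is non-decreasing along the EM trace
  objs <- one$objective[[1L]]
  expect_true(all(diff(objs) >= -1e-6 * abs(objs[-length(objs)])))
  # low-noise mixed problem: one-step and two-step edge patterns agree
  set.seed(45)
  Lmix <- diag(n) + 0.1 * matrix(rnorm(n * n), n)
  Smix <- Lmix %*% fx$S_hat %*% t(Lmix) + diag(1e-6, n)
  one2 <- higgs_one_step(array(Smix, c(n, n, 1)), Lmix,
                         support = rep(TRUE, n),
                         cfg = solver_config(type2 = "hglasso",
                                             alpha_graph = 0.15 * fx$m,
                                             noise_variance = 1e-6,
                                             max_iter = 50L), m = fx$m)
  two <- higgs_two_step(array(fx$S_hat, c(n, n, 1)), rep(TRUE, n),
                        cfg = solver_config(type2 = "hglasso",
                                            alpha_graph = 0.15))
  e1 <- Mod(one2$precision[, , 1]) > 1e-9 & !diag(TRUE, n)
  e2 <- Mod(two$precision[, , 1]) > 1e-9 & !diag(TRUE, n)
  jac <- sum(e1 & e2) / max(sum(e1 | e2), 1L)
  expect_gte(jac, 0.7)
})

test_that("eLORETA: exact localization, convergence, and power homogeneity", {
  scn <- solver_scene()
  el <- eloreta_solve(NULL, scn$L, reg = 0)
  expect_true(el$converged)
  P <- (el$T %*% scn$L$matrix)^2
  hits <- apply(P, 2L, which.max)
  expect_identical(hits, seq_len(500L))    # zero localization error
  # scaling the data by c scales estimated power by c^2
  C <- random_hermitian_psd(19, seed = 46)
  p1 <- Re(diag(apply_operator(el, C)))
  p2 <- Re(diag(apply_operator(el, 4 * C)))
  expect_equal(p2, 4 * p1, tolerance = 1e-10)
})

test_that("LCMV: unit gain, matched filter limit, interference suppression", {
  scn <- solver_scene()
  L <- scn$L$matrix
  C <- diag(19)
  lc <- lcmv_solve(C, L)
  expect_lt(max(abs(Re(diag(lc$T %*% L)) - 1)), 1e-10)
  # white covariance: rows proportional to l^T / |l|^2
  expect_equal(unname(Re(lc$T[3L, ])), L[, 3L] / sum(L[, 3L]^2),
               tolerance = 1e-10)
  # two uncorrelated sources: filter 1 suppresses source 2 by >= 20 dB
  a <- scn$active[1L]; b <- scn$active[2L]
  Cs <- L[, a] %o% L[, a] + L[, b] %o% L[, b] + 1e-8 * diag(19)
  f <- lcmv_solve(Cs, L[, c(a, b)])
  gain_own <- abs(sum(f$T[1L, ] * L[, a]))
  gain_other <- abs(sum(f$T[1L, ] * L[, b]))
  expect_gt(20 * log10(gain_own / gain_other), 20)
  expect_error(lcmv_solve(matrix(0, 19, 19), L), "singular")
})

test_that("apply_operator preserves Hermitian PSD and matches stored solutions", {
  sc <- solver_alpha_csd()
  fit <- .fixture_cache$sssbl_alpha_fit
  S_src <- apply_operator(fit, array(sc$S_alpha, c(19, 19, 1)))
  expect_hermitian_psd(S_src[, , 1])
  # compression consistency: operator x data = stored tensor minus the
  # posterior-covariance correction on the diagonal
  direct <- fit$operator[, , 1] %*% sc$S_alpha %*% Conj(t(fit$operator[, , 1]))
  off_stored <- fit$S_jj[, , 1]; diag(off_stored) <- 0
  off_direct <- direct; diag(off_direct) <- 0
  expect_lt(max(Mod(off_stored - off_direct)), 1e-10 * max(Mod(direct)))
  # identity operator leaves the metric unchanged
  id <- structure(list(T = diag(19) + 0i, method = "identity"),
                  class = "quasilinear_op")
  expect_equal(apply_operator(id, sc$S_alpha), sc$S_alpha, tolerance = 1e-12)
  z <- matrix(complex(real = rnorm(19 * 5), imaginary = rnorm(19 * 5)), 19)
  expect_equal(apply_operator(id, z, metric = "coefficients"), z,
               tolerance = 1e-12)
  expect_error(apply_operator(fit, array(0i, c(19, 19, 7))), "frequency axes")
})
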