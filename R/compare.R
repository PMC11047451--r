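#' Spectra tensor
#'
#' Strictly positive source spectra indexed sources x frequencies x
#' cases, one tensor per modality.
#'
#' @param values numeric S x F x C array, > 0 (before log transform).
#' @param modality label ("meg"/"eeg").
#' @param frequencies optional frequency grid, Hz.
#' @param logged whether values are already log-transformed.
#' @return Object of class `spectra_tensor`.
#' @export
spectra_tensor <- function(values, modality, frequencies = NULL,
                           logged = FALSE) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("spectra tensor must be S x F x C")
  structure(list(values = values, modality = modality,
                 frequencies = frequencies, logged = logged),
            class = "spectra_tensor")
}

#' Natural-log transform of a spectra tensor
#'
#' @param spectra a [spectra_tensor()] with strictly positive values.
#' @return The log-transformed tensor (`logged = TRUE`).
#' @export
log_transform <- function(spectra) {
  if (spectra$logged) stop("tensor is already log-transformed")
  bad <- which(spectra$values <= 0)
  if (length(bad)) {
    ix <- arrayInd(bad[1L], dim(spectra$values))
    stop(sprintf("nonpositive spectrum at [source %d, frequency %d, case %d]",
                 ix[1L], ix[2L], ix[3L]))
  }
  spectra_tensor(log(spectra$values), spectra$modality,
                 spectra$frequencies, logged = TRUE)
}

#' Per-frequency scaling regression between MEG and EEG log spectra
#'
#' For each frequency f, ordinary least squares of the MEG log spectra on
#' the EEG log spectra pooling sources and cases:
#' meg[s,f,c] = a_f + b_f * eeg[s,f,c] + E[s,f,c]. The intercept a_f is
#' the frequency-dependent scale difference between the modalities; the
#' slope b_f the exponential contraction of the EEG source spectra.
#'
#' @param meg_log,eeg_log log-transformed [spectra_tensor()]s of matched
#'   shape.
#' @return List of class `scaling_fit`: `a` (F), `b` (F), `r_squared`
#'   (F), `residuals_meg` (S x F x C), `n_pooled`.
#' @export
fit_scaling_model <- function(meg_log, eeg_log) {
  M <- meg_log$values; E <- eeg_log$values
  if (!all(dim(M) == dim(E))) stop("MEG/EEG tensor shapes differ")
  if (!meg_log$logged || !eeg_log$logged)
    stop("apply log_transform() before fitting the scaling model")
  dm <- dim(M)
  a <- b <- r2 <- numeric(dm[2L])
  Eres <- array(0, dm)
  for (f in seq_len(dm[2L])) {
    x <- as.vector(E[, f, ]); y <- as.vector(M[, f, ])
    vx <- stats::var(x)
    if (vx == 0) stop(sprintf("zero-variance EEG regressor at frequency %d", f))
    b[f] <- stats::cov(x, y) / vx
    a[f] <- mean(y) - b[f] * mean(x)
    res <- y - a[f] - b[f] * x
    r2[f] <- 1 - sum(res^2) / sum((y - mean(y))^2)
    Eres[, f, ] <- res
  }
  structure(list(a = a, b = b, r_squared = r2, residuals_meg = Eres,
                 n_pooled = dm[1L] * dm[3L],
                 frequencies = meg_log$frequencies),
            class = "scaling_fit")
}

.group_stats <- function(X, ind) {
  # X: cells x cases_total; ind: cases_total x P logical/0-1 group-1 design
  C1 <- colSums(ind)
  C2 <- nrow(ind) - C1
  m1 <- (X %*% ind) / matrix(C1, nrow(X), ncol(ind), byrow = TRUE)
  m2 <- (X %*% (1 - ind)) / matrix(C2, nrow(X), ncol(ind), byrow = TRUE)
  X2 <- X^2
  v1 <- (X2 %*% ind) / matrix(C1, nrow(X), ncol(ind), byrow = TRUE) - m1^2
  v2 <- (X2 %*% (1 - ind)) / matrix(C2, nrow(X), ncol(ind), byrow = TRUE) - m2^2
  # unbiased pooled SE of the mean difference
  v1 <- sweep(v1, 2L, C1 / pmax(C1 - 1, 1), "*")
  v2 <- sweep(v2, 2L, C2 / pmax(C2 - 1, 1), "*")
  se <- sqrt(sweep(v1, 2L, C1, "/") + sweep(v2, 2L, C2, "/"))
  (m1 - m2) / pmax(se, .Machine$double.xmin)
}

#' Max-statistic random permutation test on source spectra
#'
#' Two-sample comparison of regression-corrected log spectra on the full
#' (source, frequency) grid with family-wise error control by the
#' permutation distribution of the maximum absolute statistic. The
#' statistic per cell is the between-modality difference of case means
#' standardized by the pooled standard error; the null is built by
#' randomly reassigning the 2C cases to modalities. A cell is significant
#' when its permutation p-value (observed included in the null) is at or
#' below `alpha`.
#'
#' @param meg_corrected,eeg_corrected S x F x C arrays (or
#'   [spectra_tensor()]s) on matched grids, regression-corrected.
#' @param n_perm number of random permutations (must be >= 1/alpha).
#' @param alpha family-wise significance level (default 0.01).
#' @param seed RNG seed for the permutation draws.
#' @return List of class `perm_test`: `statistic` (S x F), `significant`
#'   (S x F logical), `null_max` (n_perm), `threshold`, `alpha`,
#'   `n_permutations`.
#' @export
permutation_max_test <- function(meg_corrected, eeg_corrected, n_perm = 500L,
                                 alpha = 0.01, seed = NULL) {
  M <- if (inherits(meg_corrected, "spectra_tensor")) meg_corrected$values
       else meg_corrected
  E <- if (inherits(eeg_corrected, "spectra_tensor")) eeg_corrected$values
       else eeg_corrected
  if (!all(dim(M)[1:2] == dim(E)[1:2]))
    stop("source/frequency grids do not match")
  if (n_perm < 1 / alpha)
    stop(sprintf("n_perm = %d is insufficient for alpha = %g (need >= %d)",
                 n_perm, alpha, ceiling(1 / alpha)))
  if (!is.null(seed)) set.seed(seed)
  dm <- dim(M)
  s <- dm[1L]; f <- dm[2L]
  cm <- dim(M)[3L]; ce <- dim(E)[3L]
  X <- cbind(matrix(M, s * f, cm), matrix(E, s * f, ce))
  ntot <- cm + ce
  obs_ind <- matrix(c(rep(1, cm), rep(0, ce)), ntot, 1L)
  stat <- matrix(.group_stats(X, obs_ind), s, f)
  ind <- matrix(0, ntot, n_perm)
  for (p in seq_len(n_perm)) ind[sample.int(ntot, cm), p] <- 1
  null_stat <- .group_stats(X, ind)
  null_max <- apply(abs(null_stat), 2L, max)
  obs_max_p <- (1 + colSums(outer(null_max, as.vector(abs(stat)), `>=`)))
  # p-value per cell against the max null, observed included
  pval <- matrix(obs_max_p / (n_perm + 1), s, f)
  significant <- pval <= alpha
  threshold <- stats::quantile(null_max, 1 - alpha, names = FALSE, type = 1)
  structure(list(statistic = stat, significant = significant,
                 p_values = pval, null_max = null_max, threshold = threshold,
                 alpha = alpha, n_permutations = n_perm),
            class = "perm_test")
}

#' Per-band source indicator maps of significant differences
#'
#' A source is marked in a band when it shows a significant difference at
#' any frequency within the band.
#'
#' @param significant S x F logical matrix (or `perm_test`).
#' @param frequencies frequency grid, Hz (length F).
#' @param bands named list of `c(lo, hi)` Hz; default [default_bands()]
#'   with gamma capped at the grid maximum.
#' @return Named list of logical source masks, one per band.
#' @export
band_indicator_map <- function(significant, frequencies, bands = NULL) {
  if (inherits(significant, "perm_test")) significant <- significant$significant
  if (is.null(bands)) {
    bands <- default_bands(NA)
    bands$gamma[2L] <- max(frequencies)
  }
  if (length(frequencies) != ncol(significant))
    stop("frequency grid length does not match the significance matrix")
  lapply(bands, function(b) {
    inb <- frequencies >= b[1L] & frequencies <= b[2L]
    if (!any(inb)) stop("band lies outside the frequency grid")
    apply(significant[, inb, drop = FALSE], 1L, any)
  })
}
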