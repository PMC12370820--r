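# Shared fixtures, all generated in code.

# Whole-brain cohort parameters: one pseudo-region sampled in everyone, so
# rows are subjects and the LMM operates at the whole-brain level.
wb_params <- function(..., seed = 1L) {
  simulation_params(rois = data.frame(roi = "whole_brain", prob = 1),
                    seed = seed, ...)
}

# Compact mirrored cohort over a few regions for regional-map tests.
regional_params <- function(..., seed = 1L) {
  simulation_params(rois = data.frame(
    roi = c("middle_temporal", "hippocampus", "frontal_pole"),
    prob = c(0.9, 0.6, 0.2)), seed = seed, ...)
}

# Independent dense multivariate-normal log-likelihood for the
# random-intercept model, built from the marginal covariance by direct
# linear algebra (solve/determinant): the grid-search oracle.
oracle_loglik_ml <- function(y, X, g, beta, sigma2_u, sigma2_e) {
  Z <- outer(g, unique(g), `==`) * 1
  V <- sigma2_e * diag(length(y)) + sigma2_u * tcrossprod(Z)
  r <- y - X %*% beta
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            t(r) %*% solve(V, r) + length(y) * log(2 * pi))[1]
}

# Restricted likelihood over the variance components only, with beta
# integrated out (Harville), again by direct dense algebra.
oracle_loglik_reml <- function(y, X, g, sigma2_u, sigma2_e) {
  Z <- outer(g, unique(g), `==`) * 1
  V <- sigma2_e * diag(length(y)) + sigma2_u * tcrossprod(Z)
  Vi_X <- solve(V, X)
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(Vi_X, y))
  r <- y - X %*% beta
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XtViX, logarithm = TRUE)$modulus +
            t(r) %*% solve(V, r) +
            (length(y) - ncol(X)) * log(2 * pi))[1]
}

# Amplitude of a sinusoid at f0 in x, by projection over whole periods
# (avoids FFT scalloping).
proj_amp <- function(x, f0, fs) {
  nper <- floor(length(x) * f0 / fs)
  n <- floor(nper * fs / f0)
  tt <- seq_len(n) / fs
  2 * Mod(mean(x[seq_len(n)] * exp(-2i * pi * f0 * tt)))
}

# A flat unit-density PSD on a 0.5 Hz grid up to 100 Hz.
flat_psd <- function(value = 1, fmax = 100, nch = 1) {
  freq <- seq(0, fmax, by = 0.5)
  structure(list(freq = freq,
                 density = matrix(value, nch, length(freq)),
                 window = 2, overlap = 1, fs = 2 * fmax),
            class = "psd_estimate")
}
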