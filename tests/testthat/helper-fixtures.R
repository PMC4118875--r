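# shared fixtures: coarse grid + cheap simulated datasets

tiny_grid <- function(step = 2) seq(400, 900, by = step)

# default study conditions on a coarse grid, for speed
sim_default <- function(n = 10, seed = 1, grid = tiny_grid(), ...) {
  simulate_dataset(default_formulation_profiles(), n, grid = grid,
                   noise = noise_model(...), seed = seed)
}

# notch + reference-line normalization
prep <- function(set, cfg = preprocess_config()) {
  set |> apply_notch_mask(cfg) |> normalize_to_reference_line(cfg)
}

# three well-separated classes: large line-amplitude differences, mild noise
separable_profiles <- function() {
  p <- list(
    formulation_profile("alpha", list(
      line_spec(479.45, 4.0, 1.1, "Cl"), line_spec(656.3, 5.0, 1.2, "H"),
      line_spec(777.0, 0.5, 1.2, "O")), continuum_spec(1.0)),
    formulation_profile("beta", list(
      line_spec(479.45, 0.5, 1.1, "Cl"), line_spec(656.3, 5.0, 1.2, "H"),
      line_spec(777.0, 4.0, 1.2, "O")), continuum_spec(1.0)),
    formulation_profile("gamma", list(
      line_spec(567.0, 3.0, 1.0, "N"), line_spec(656.3, 5.0, 1.2, "H"),
      line_spec(868.0, 2.5, 1.5, "O")), continuum_spec(0.5, center = 600))
  )
  stats::setNames(p, vapply(p, `[[`, "", "name"))
}

sim_separable <- function(n = 12, seed = 1, grid = tiny_grid(),
                          noise = noise_model()) {
  simulate_dataset(separable_profiles(), n, grid = grid, noise = noise,
                   seed = seed)
}

# ---- independent oracles -------------------------------------------------

# modified-polyfit baseline via lm() on orthogonal polynomials; shares no
# numerics with the package's Vandermonde/QR implementation
oracle_modpoly <- function(x, y, order = 6, max_iter = 100, tol = 1e-4) {
  work <- y
  fit_old <- NULL
  for (it in seq_len(max_iter)) {
    f <- unname(stats::fitted(stats::lm(work ~ stats::poly(x, order))))
    if (!is.null(fit_old) &&
        max(abs(f - fit_old)) / max(abs(fit_old)) < tol) {
      return(f)
    }
    fit_old <- f
    work <- pmin(work, f)
  }
  fit_old
}

# PCA via brute-force eigendecomposition of the covariance matrix
oracle_pca <- function(X, k) {
  e <- eigen(stats::cov(X), symmetric = TRUE)
  list(fractions = e$values / sum(e$values),
       loadings = t(e$vectors[, seq_len(k), drop = FALSE]))
}

# SIMCA orthogonal residual by explicit reconstruction, one row at a time
oracle_residual <- function(pca, X) {
  vapply(seq_len(nrow(X)), function(i) {
    xc <- X[i, ] - pca$mean_spectrum
    recon <- drop(t(pca$loadings) %*% (pca$loadings %*% xc))
    sqrt(sum((xc - recon)^2))
  }, 0)
}

# Welch t from summary statistics (closed form)
oracle_welch_p <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(tstat), df)
}
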