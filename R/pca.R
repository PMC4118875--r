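#' Principal component analysis of a spectra set
#'
#' Mean-centred PCA over the valid channels (no unit-variance scaling:
#' spectra are already normalized to the hydrogen reference line, and
#' centring-only is the chemometric default for spectral data).
#' Component signs are fixed so that the largest-magnitude loading entry
#' of each component is positive, making runs reproducible.
#'
#' @param set A [spectra_set()], `n >= 2` rows.
#' @param k Number of components to retain (default 3);
#'   `k <= min(n - 1, number of valid channels)`.
#' @return An object of class `libs_pca` with fields `mean_spectrum`
#'   (over valid channels), `loadings` (`k x channels` orthonormal rows),
#'   `variance_fractions` (all `min(n-1, p)` fractions; the first `k`
#'   belong to the retained components), `k`, and the grid/mask for
#'   compatibility checks.
#' @export
fit_pca <- function(set, k = 3) {
  stopifnot(inherits(set, "spectra_set"))
  X <- valid_matrix(set)
  n <- nrow(X)
  if (n < 2) stop("PCA requires at least two spectra", call. = FALSE)
  kmax <- min(n - 1L, ncol(X))
  if (k < 1 || k > kmax) {
    stop(sprintf("k must be between 1 and %d (min(n - 1, valid channels))", kmax),
         call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  fractions <- if (sum(ev) > 0) ev / sum(ev) else rep(0, length(ev))
  loadings <- unname(t(pc$rotation[, seq_len(k), drop = FALSE]))
  for (i in seq_len(k)) {
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) loadings[i, ] <- -loadings[i, ]
  }
  structure(
    list(mean_spectrum = unname(pc$center), loadings = loadings,
         variance_fractions = fractions[seq_len(min(kmax, length(fractions)))],
         k = as.integer(k), n = n,
         wavelengths = set$wavelengths, valid_mask = set$valid_mask),
    class = "libs_pca"
  )
}

#' @export
print.libs_pca <- function(x, ...) {
  cat(sprintf("<libs_pca> %d components over %d valid channels (n = %d)\n",
              x$k, ncol(x$loadings), x$n))
  cat(sprintf("cumulative variance of retained components: %.1f%%\n",
              100 * sum(x$variance_fractions[seq_len(x$k)])))
  invisible(x)
}

#' Cumulative variance explained by the first j components
#'
#' @param model A `libs_pca` model.
#' @param j Component count, `1 <= j <= k`.
#' @return Fraction in `[0, 1]`.
#' @export
variance_explained <- function(model, j) {
  stopifnot(inherits(model, "libs_pca"))
  if (j < 1 || j > model$k) {
    stop(sprintf("j must be between 1 and k = %d", model$k), call. = FALSE)
  }
  sum(model$variance_fractions[seq_len(j)])
}

#' Project spectra onto a fitted PCA model
#'
#' `scores = (rows - mean_spectrum) %*% t(loadings)` over valid channels.
#'
#' @param model A `libs_pca` model.
#' @param set A [spectra_set()] on the same grid and mask.
#' @return Score matrix, `n x k`, columns named `PC1..PCk`.
#' @export
project <- function(model, set) {
  stopifnot(inherits(model, "libs_pca"), inherits(set, "spectra_set"))
  check_same_grid(model$wavelengths, model$valid_mask,
                  set$wavelengths, set$valid_mask)
  X <- sweep(valid_matrix(set), 2, model$mean_spectrum)
  scores <- X %*% t(model$loadings)
  colnames(scores) <- paste0("PC", seq_len(model$k))
  scores
}

#' @method tidy libs_pca
#' @export
tidy.libs_pca <- function(x, ...) {
  fr <- x$variance_fractions[seq_len(x$k)]
  tibble::tibble(component = seq_len(x$k),
                 variance_fraction = fr,
                 cumulative = cumsum(fr))
}

#' @method glance libs_pca
#' @export
glance.libs_pca <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, n_channels = ncol(x$loadings),
                 cumulative_variance = sum(x$variance_fractions[seq_len(x$k)]))
}

#' Score plot for a fitted PCA model
#'
#' @param object A `libs_pca` model.
#' @param data The [spectra_set()] to project (typically the training set).
#' @param components Two component indices to plot (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot libs_pca
#' @export
autoplot.libs_pca <- function(object, data, components = c(1, 2), ...) {
  sc <- project(object, data)
  df <- tibble::tibble(x = sc[, components[1]], y = sc[, components[2]],
                       class = data$labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1],
                  100 * object$variance_fractions[components[1]]),
      y = sprintf("PC%d (%.1f%%)", components[2],
                  100 * object$variance_fractions[components[2]]),
      colour = "formulation") +
    ggplot2::theme_minimal()
}
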