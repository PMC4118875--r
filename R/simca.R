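#' SIMCA configuration
#'
#' Soft independent modelling of class analogy builds one PCA submodel
#' per class and accepts a spectrum into a class when its orthogonal
#' residual distance to that class's subspace falls below
#' `residual_mean + sigma_multiplier * residual_sd` of the class's
#' training residuals — the "3-sigma unclassification threshold" at the
#' default multiplier. A spectrum accepted by no class is unclassified;
#' one accepted by several is assigned to the accepted class with the
#' smallest standardized distance.
#'
#' @param sigma_multiplier Acceptance threshold in training-residual
#'   standard deviations (default 3).
#' @param variance_target Cumulative-variance target for choosing each
#'   submodel's rank (default 0.95).
#' @param rank_cap Upper bound on any submodel rank (default 10).
#' @return A list of class `simca_config`.
#' @export
simca_config <- function(sigma_multiplier = 3, variance_target = 0.95,
                         rank_cap = 10) {
  stopifnot(sigma_multiplier > 0, variance_target > 0, variance_target <= 1,
            rank_cap >= 1)
  structure(list(sigma_multiplier = sigma_multiplier,
                 variance_target = variance_target,
                 rank_cap = as.integer(rank_cap)),
            class = "simca_config")
}

#' Fit a SIMCA model
#'
#' For each class: a mean-centred PCA submodel of rank `k_c` — the
#' smallest rank reaching the cumulative-variance target, capped at
#' `min(rank_cap, n_c - 2)` so the residual spread is estimable — then
#' the mean and standard deviation of the training rows' orthogonal
#' residual distances — inflated by `sqrt((n_c - 1) / (n_c - 1 - k_c))` to
#' undo the in-sample shrinkage caused by the fitted components, as in
#' classical SIMCA residual-variance accounting — and the acceptance
#' threshold `mean + sigma_multiplier * sd`.
#'
#' @param train A [spectra_set()] with at least 3 rows per class.
#' @param config A [simca_config()].
#' @return An object of class `simca_model`.
#' @export
fit_simca <- function(train, config = simca_config()) {
  stopifnot(inherits(train, "spectra_set"))
  submodels <- lapply(class_levels(train), function(cl) {
    rows <- which(train$labels == cl)
    n_c <- length(rows)
    if (n_c < 3) {
      stop(sprintf("class '%s' has only %d training spectra (need >= 3)", cl, n_c),
           call. = FALSE)
    }
    sub <- train[rows]
    kmax <- min(config$rank_cap, n_c - 2L, sum(train$valid_mask))
    full <- fit_pca(sub, k = kmax)
    tot <- sum(full$variance_fractions)
    k_c <- if (tot <= .Machine$double.eps) 1L else {
      cum <- cumsum(full$variance_fractions[seq_len(kmax)]) / tot
      hit <- which(cum >= config$variance_target - 1e-12)
      if (length(hit)) min(hit) else kmax
    }
    pca <- fit_pca(sub, k = k_c)
    d <- residual_distance(list(pca = pca), sub)
    # in-sample residuals are shrunk by the k_c + 1 degrees of freedom the
    # submodel absorbs (mean + components); inflate them back, as in
    # classical SIMCA residual-variance bookkeeping, so the threshold is
    # calibrated for out-of-sample distances
    d <- d * sqrt((n_c - 1) / max(n_c - 1 - k_c, 1))
    res_mean <- mean(d)
    res_sd <- stats::sd(d)
    list(class = cl, pca = pca, k = k_c, residual_mean = res_mean,
         residual_sd = res_sd,
         threshold = res_mean + config$sigma_multiplier * res_sd)
  })
  names(submodels) <- class_levels(train)
  structure(list(submodels = submodels, config = config,
                 classes = class_levels(train)),
            class = "simca_model")
}

#' Orthogonal residual distance to a SIMCA submodel
#'
#' Euclidean norm, over valid channels, of the part of a centred spectrum
#' orthogonal to the submodel's principal subspace:
#' `|| (x - mean) - P (x - mean) ||`.
#'
#' @param submodel One element of `simca_model$submodels` (anything
#'   carrying a `pca` field).
#' @param set A [spectra_set()] on the same grid and mask.
#' @return Nonnegative distance vector, one entry per row of `set`.
#' @export
residual_distance <- function(submodel, set) {
  pca <- submodel$pca
  check_same_grid(pca$wavelengths, pca$valid_mask,
                  set$wavelengths, set$valid_mask)
  X <- sweep(valid_matrix(set), 2, pca$mean_spectrum)
  S <- X %*% t(pca$loadings)
  resid <- X - S %*% pca$loadings
  sqrt(rowSums(resid^2))
}

#' Classify spectra with a fitted SIMCA model
#'
#' Each spectrum is tested against every class's acceptance threshold.
#' The verdict is `"unclassified"` when no class accepts it,
#' `"correct"` when the assigned class (the accepted class with the
#' smallest standardized distance `(d - residual_mean) / residual_sd`)
#' matches the true label, and `"misclassified"` otherwise.
#'
#' @param object A `simca_model`.
#' @param newdata A [spectra_set()] to classify.
#' @param ... Unused.
#' @return A tibble with one row per spectrum: `row`, `true_class`,
#'   `n_accepted`, `assigned_class` (`NA` when unclassified) and
#'   `verdict`.
#' @export
predict.simca_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spectra_set"))
  eps <- 1e-8
  dists <- vapply(object$submodels, residual_distance, set = newdata,
                  numeric(n_spectra(newdata)))
  dists <- matrix(dists, nrow = n_spectra(newdata),
                  dimnames = list(NULL, object$classes))
  thr <- vapply(object$submodels, `[[`, 0, "threshold")
  mu <- vapply(object$submodels, `[[`, 0, "residual_mean")
  sg <- pmax(vapply(object$submodels, `[[`, 0, "residual_sd"), eps)
  accepted <- sweep(dists, 2, thr, `<=`)
  std <- sweep(sweep(dists, 2, mu), 2, sg, `/`)
  assigned <- rep(NA_character_, nrow(dists))
  for (i in seq_len(nrow(dists))) {
    acc <- which(accepted[i, ])
    if (length(acc)) assigned[i] <- object$classes[acc[which.min(std[i, acc])]]
  }
  verdict <- dplyr::case_when(
    is.na(assigned) ~ "unclassified",
    assigned == newdata$labels ~ "correct",
    TRUE ~ "misclassified"
  )
  tibble::tibble(row = seq_len(nrow(dists)),
                 true_class = newdata$labels,
                 n_accepted = rowSums(accepted),
                 assigned_class = assigned,
                 verdict = verdict)
}

#' @method tidy simca_model
#' @export
tidy.simca_model <- function(x, ...) {
  purrr::map_dfr(x$submodels, function(s) {
    tibble::tibble(class = s$class, rank = s$k,
                   residual_mean = s$residual_mean,
                   residual_sd = s$residual_sd,
                   threshold = s$threshold)
  })
}

#' @method glance simca_model
#' @export
glance.simca_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$submodels),
                 sigma_multiplier = x$config$sigma_multiplier,
                 variance_target = x$config$variance_target)
}

#' @export
print.simca_model <- function(x, ...) {
  cat(sprintf("<simca_model> %d classes, %g-sigma acceptance threshold\n",
              length(x$submodels), x$config$sigma_multiplier))
  print(tidy.simca_model(x))
  invisible(x)
}
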