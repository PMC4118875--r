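#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares discriminant analysis: PLS2 regression of
#' mean-centred spectra (valid channels) on mean-centred one-hot class
#' indicators, computed with the NIPALS algorithm, giving a single
#' "global" model for all classes at once. Prediction is the argmax of
#' the predicted class scores — there is no rejection option, so the
#' unclassification rate is structurally zero.
#'
#' When `n_latent` is `NULL`, the number of latent variables is chosen by
#' stratified 5-fold cross-validation on the training set (smallest count
#' within half a held-out misclassification of the best mean accuracy,
#' capped at `max_latent`).
#'
#' @param train A [spectra_set()] with at least two classes.
#' @param n_latent Number of latent variables, or `NULL` to select by
#'   cross-validation.
#' @param max_latent Cap on the latent-variable count (default 10).
#' @param cv_folds Folds for the internal selection (default 5).
#' @param cv_seed Seed for the fold assignment (default 1).
#' @return An object of class `plsda_model`.
#' @export
fit_plsda <- function(train, n_latent = NULL, max_latent = 10, cv_folds = 5,
                      cv_seed = 1) {
  stopifnot(inherits(train, "spectra_set"))
  classes <- class_levels(train)
  if (length(classes) < 2) stop("PLS-DA needs at least two classes", call. = FALSE)
  X <- valid_matrix(train)
  if (nrow(X) < 2) stop("PLS-DA needs at least two spectra", call. = FALSE)
  if (all(abs(sweep(X, 2, colMeans(X))) < .Machine$double.eps)) {
    stop("design matrix has zero variance", call. = FALSE)
  }
  Y <- one_hot(train$labels, classes)
  cap <- min(max_latent, nrow(X) - 1L, ncol(X))
  if (is.null(n_latent)) {
    n_latent <- select_n_latent(X, train$labels, classes, cap, cv_folds, cv_seed)
  }
  if (n_latent > cap) {
    stop(sprintf("n_latent must be at most %d here", cap), call. = FALSE)
  }
  core <- nipals_pls2(X, Y, n_latent)
  structure(c(core, list(classes = classes,
                         wavelengths = train$wavelengths,
                         valid_mask = train$valid_mask)),
            class = "plsda_model")
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

# NIPALS PLS2 on raw X, Y (centres them internally)
nipals_pls2 <- function(X, Y, a, tol = 1e-10, max_iter = 200) {
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  E <- sweep(X, 2, x_mean)
  F0 <- sweep(Y, 2, y_mean)
  n <- nrow(E)
  W <- P <- matrix(0, ncol(E), 0)
  C <- matrix(0, ncol(F0), 0)
  Fh <- F0
  for (h in seq_len(a)) {
    u <- Fh[, which.max(apply(Fh, 2, stats::var))]
    if (sum(u^2) < .Machine$double.eps) break
    tt <- t_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(E, u))
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) break
      w <- w / nw
      tt <- drop(E %*% w)
      cc <- drop(crossprod(Fh, tt)) / sum(tt^2)
      u <- drop(Fh %*% cc) / sum(cc^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * max(sqrt(sum(tt^2)), 1)) break
      t_old <- tt
    }
    if (sum(tt^2) < .Machine$double.eps) break
    p <- drop(crossprod(E, tt)) / sum(tt^2)
    E <- E - tcrossprod(tt, p)
    Fh <- Fh - tcrossprod(tt, cc)
    W <- cbind(W, w)
    P <- cbind(P, p)
    C <- cbind(C, cc)
  }
  if (ncol(W) == 0) stop("NIPALS extracted no latent variables", call. = FALSE)
  B <- W %*% solve(crossprod(P, W), t(C))
  list(x_mean = x_mean, y_mean = y_mean, weights = W, x_loadings = P,
       y_loadings = C, coef = B, n_latent = ncol(W))
}

select_n_latent <- function(X, labels, classes, cap, folds, seed) {
  n <- nrow(X)
  fold_id <- with_seed_local(seed, {
    id <- integer(n)
    for (cl in classes) {
      rows <- which(labels == cl)
      id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    id
  })
  acc <- matrix(NA_real_, folds, cap)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    if (!length(te) || length(unique(labels[tr])) < length(classes)) next
    cap_f <- min(cap, length(tr) - 1L)
    core <- nipals_pls2(X[tr, , drop = FALSE], one_hot(labels[tr], classes),
                        cap_f)
    for (a in seq_len(core$n_latent)) {
      Ba <- core$weights[, 1:a, drop = FALSE] %*%
        solve(crossprod(core$x_loadings[, 1:a, drop = FALSE],
                        core$weights[, 1:a, drop = FALSE]),
              t(core$y_loadings[, 1:a, drop = FALSE]))
      Yh <- sweep(X[te, , drop = FALSE], 2, core$x_mean) %*% Ba
      Yh <- sweep(Yh, 2, core$y_mean, `+`)
      pred <- classes[max.col(Yh, ties.method = "first")]
      acc[f, a] <- mean(pred == labels[te])
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  if (all(!is.finite(mean_acc))) return(min(2L, cap))
  best <- max(mean_acc, na.rm = TRUE)
  # parsimony: smallest count within half a test-fold misclassification of best
  slack <- 0.5 / max(1, floor(nrow(X) / folds))
  min(which(mean_acc >= best - slack))
}

#' Predict classes with a fitted PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata A [spectra_set()] on the same grid.
#' @param type `"class"` for assigned labels (argmax of predicted class
#'   scores; ties break to the lowest-index class), `"score"` for the raw
#'   predicted indicator matrix.
#' @param ... Unused.
#' @return Character vector of class labels, or a score matrix.
#' @export
predict.plsda_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "spectra_set"))
  check_same_grid(object$wavelengths, object$valid_mask,
                  newdata$wavelengths, newdata$valid_mask)
  Yh <- sweep(valid_matrix(newdata), 2, object$x_mean) %*% object$coef
  Yh <- sweep(Yh, 2, object$y_mean, `+`)
  colnames(Yh) <- object$classes
  if (type == "score") return(Yh)
  object$classes[max.col(Yh, ties.method = "first")]
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d classes, %d latent variables, %d channels\n",
              length(x$classes), x$n_latent, length(x$x_mean)))
  invisible(x)
}

#' @method glance plsda_model
#' @export
glance.plsda_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), n_latent = x$n_latent,
                 n_channels = length(x$x_mean))
}
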