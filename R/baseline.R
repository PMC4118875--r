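#' Configuration for iterative polynomial continuum removal
#'
#' The continuum background of a non-gated LIBS spectrum is broad and
#' featureless, so it can be approximated by a low-order polynomial fitted
#' iteratively: after each least-squares fit the working vector is clipped
#' to the fitted curve (`min(working, fit)`), which progressively excludes
#' the emission peaks from the fit until the curve converges onto the
#' background.
#'
#' @param order Polynomial order (default 6).
#' @param max_iter Maximum number of fit/clip iterations (default 100).
#' @param tol Convergence threshold on the maximum relative change of the
#'   fitted curve between iterations (default 1e-4).
#' @param clip_negative_residual Clip negative values of the corrected
#'   spectrum to zero (default `TRUE`) — the non-negativity constraint.
#'
#' @return A list of class `baseline_config`.
#' @export
baseline_config <- function(order = 6, max_iter = 100, tol = 1e-4,
                            clip_negative_residual = TRUE) {
  stopifnot(order >= 0, max_iter >= 1, tol > 0)
  structure(list(order = as.integer(order), max_iter = as.integer(max_iter),
                 tol = tol, clip_negative_residual = clip_negative_residual),
            class = "baseline_config")
}

#' Estimate and remove the continuum of one spectrum
#'
#' Iterative constrained polynomial fit: (1) least-squares polynomial of
#' the configured order over the valid channels, with wavelengths rescaled
#' to \[-1, 1\] for numerical conditioning; (2) working vector replaced by
#' its pointwise minimum with the fitted curve; (3) repeat until the
#' maximum relative change of the fitted curve drops below `tol` or
#' `max_iter` is reached (non-convergence raises a warning and returns the
#' last iterate). The corrected spectrum is `original - baseline`,
#' clipped at zero when `clip_negative_residual`. Masked channels are
#' excluded from the fit; their corrected values pass through unchanged.
#'
#' @param wavelengths Channel centres, nm.
#' @param intensities Intensity vector (a.u.).
#' @param valid_mask Logical channel mask (default all valid).
#' @param cfg A [baseline_config()].
#' @return A list with `baseline` (fitted continuum, full length; `NA` on
#'   masked channels), `corrected` (intensity vector), `iterations`, and
#'   `converged`.
#' @examples
#' wl <- seq(400, 900, by = 1)
#' y <- 1 + 0.002 * (wl - 650) + 8 * exp(-(wl - 656.3)^2 / 2)
#' fit <- iterative_polyfit_baseline(wl, y)
#' max(fit$corrected)  # close to the planted peak height 8
#' @export
iterative_polyfit_baseline <- function(wavelengths, intensities,
                                       valid_mask = NULL,
                                       cfg = baseline_config()) {
  p <- length(wavelengths)
  stopifnot(length(intensities) == p)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, p)
  idx <- which(valid_mask)
  if (length(idx) < cfg$order + 1L) {
    stop(sprintf("need at least %d valid channels for an order-%d fit, have %d",
                 cfg$order + 1L, cfg$order, length(idx)), call. = FALSE)
  }
  wl <- wavelengths[idx]
  y <- intensities[idx]
  x <- if (diff(range(wl)) > 0) 2 * (wl - min(wl)) / diff(range(wl)) - 1 else wl * 0
  V <- outer(x, 0:cfg$order, `^`)
  qrV <- qr(V)

  work <- y
  fit_old <- NULL
  converged <- FALSE
  iter <- 0L
  scale_ref <- max(abs(y), .Machine$double.eps)
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    fit <- drop(V %*% qr.coef(qrV, work))
    if (!is.null(fit_old)) {
      rel <- max(abs(fit - fit_old)) / max(max(abs(fit_old)), scale_ref * 1e-12,
                                           .Machine$double.eps)
      if (rel < cfg$tol) {
        converged <- TRUE
        fit_old <- fit
        break
      }
    }
    fit_old <- fit
    work <- pmin(work, fit)
  }
  if (!converged && iter >= cfg$max_iter) {
    warning(sprintf("baseline fit did not converge within %d iterations",
                    cfg$max_iter), call. = FALSE)
  }
  baseline <- rep(NA_real_, p)
  baseline[idx] <- fit_old
  corrected <- intensities
  res <- y - fit_old
  if (cfg$clip_negative_residual) res <- pmax(res, 0)
  corrected[idx] <- res
  list(baseline = baseline, corrected = corrected, iterations = iter,
       converged = converged)
}

#' Continuum-correct every spectrum of a set
#'
#' Row-wise application of [iterative_polyfit_baseline()]; labels, grid
#' and mask are preserved. Per-row failures are collected and reported
#' together with their row indices.
#'
#' @param set A [spectra_set()].
#' @param cfg A [baseline_config()].
#' @return The corrected [spectra_set()], with the estimated baselines
#'   attached as attribute `"baselines"` (matrix, `NA` on masked channels).
#' @export
batch_correct <- function(set, cfg = baseline_config()) {
  stopifnot(inherits(set, "spectra_set"))
  n <- n_spectra(set)
  corrected <- set$intensities
  baselines <- matrix(NA_real_, n, n_channels(set))
  failures <- character(0)
  for (i in seq_len(n)) {
    out <- tryCatch(
      iterative_polyfit_baseline(set$wavelengths, set$intensities[i, ],
                                 set$valid_mask, cfg),
      error = function(e) e
    )
    if (inherits(out, "error")) {
      failures <- c(failures, sprintf("row %d: %s", i, conditionMessage(out)))
    } else {
      corrected[i, ] <- out$corrected
      baselines[i, ] <- out$baseline
    }
  }
  if (length(failures)) {
    stop(paste(c("baseline correction failed for:", failures), collapse = "\n"),
         call. = FALSE)
  }
  set$intensities <- corrected
  attr(set, "baselines") <- baselines
  set
}
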