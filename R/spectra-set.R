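#' Construct a set of LIBS spectra on a shared wavelength grid
#'
#' A `spectra_set` bundles an intensity matrix (rows = individual laser
#' shots / spectra, columns = wavelength channels), the common wavelength
#' grid in nanometres, a shared channel validity mask, a class label per
#' row, and an optional free-text provenance string per row (e.g. pellet
#' and location id). Channels with `valid_mask = FALSE` (such as the band
#' blanked around the excitation laser line) are excluded from every
#' downstream computation: normalization, baselines, distances, PCA and
#' classification.
#'
#' Class order is first-appearance order of `labels` and is kept stable
#' throughout the pipeline. Labels are case-sensitive.
#'
#' @param wavelengths Numeric vector of channel centres in nm, strictly
#'   increasing.
#' @param intensities Numeric matrix, `n_spectra x n_channels`, arbitrary
#'   intensity units. A single spectrum may be given as a vector.
#' @param labels Character vector of class names, one per row.
#' @param valid_mask Logical vector marking usable channels; defaults to
#'   all valid.
#' @param provenance Optional character vector of per-row annotations.
#'
#' @return An object of class `spectra_set`.
#' @examples
#' grid <- seq(400, 900, by = 1)
#' mat <- matrix(runif(2 * length(grid)), nrow = 2)
#' s <- spectra_set(grid, mat, labels = c("a", "b"))
#' s
#' @export
spectra_set <- function(wavelengths, intensities, labels,
                        valid_mask = NULL, provenance = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (is.null(dim(intensities))) {
    intensities <- matrix(as.numeric(intensities), nrow = 1)
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  p <- ncol(intensities)
  if (n < 1L) stop("spectra_set requires at least one spectrum", call. = FALSE)
  if (length(wavelengths) != p) {
    stop(sprintf("wavelength grid has %d channels but intensity matrix has %d columns",
                 length(wavelengths), p), call. = FALSE)
  }
  if (anyDuplicated(wavelengths)) {
    stop("duplicate wavelength channels are not allowed", call. = FALSE)
  }
  if (p > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, p)
  valid_mask <- as.logical(valid_mask)
  if (length(valid_mask) != p) {
    stop("valid_mask length must match the number of channels", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) == 1L && n > 1L) labels <- rep(labels, n)
  if (length(labels) != n) {
    stop("need one class label per spectrum", call. = FALSE)
  }
  if (!all(is.finite(intensities[, valid_mask, drop = FALSE]))) {
    stop("intensity matrix contains non-finite values on valid channels",
         call. = FALSE)
  }
  if (is.null(provenance)) provenance <- rep(NA_character_, n)
  provenance <- as.character(provenance)
  if (length(provenance) != n) {
    stop("need one provenance entry per spectrum", call. = FALSE)
  }
  structure(
    list(
      wavelengths = wavelengths,
      intensities = unname(intensities),
      labels = labels,
      valid_mask = valid_mask,
      provenance = provenance,
      class_levels = unique(labels)
    ),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d channels (%d valid), %.1f-%.1f nm\n",
              n_spectra(x), n_channels(x), sum(x$valid_mask),
              min(x$wavelengths), max(x$wavelengths)))
  tab <- table(factor(x$labels, levels = x$class_levels))
  cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of spectra / channels in a set
#' @param set A `spectra_set`.
#' @return Integer count.
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' @rdname n_spectra
#' @export
n_channels <- function(set) ncol(set$intensities)

#' Class labels in first-appearance order
#' @param set A `spectra_set`.
#' @return Character vector of class names.
#' @export
class_levels <- function(set) set$class_levels

#' Subset rows of a spectra set
#'
#' @param x A `spectra_set`.
#' @param i Row index (integer or logical).
#' @param ... Unused.
#' @return A `spectra_set` containing the selected rows; class order of the
#'   parent set is preserved for classes that survive the subset.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  out <- spectra_set(x$wavelengths, x$intensities[i, , drop = FALSE],
                     labels = x$labels[i], valid_mask = x$valid_mask,
                     provenance = x$provenance[i])
  out$class_levels <- x$class_levels[x$class_levels %in% out$labels]
  out
}

# intensity submatrix restricted to valid channels
valid_matrix <- function(set) {
  set$intensities[, set$valid_mask, drop = FALSE]
}

valid_wavelengths <- function(set) set$wavelengths[set$valid_mask]

# check two sets / a model and a set share a grid + mask
check_same_grid <- function(a_wl, a_mask, b_wl, b_mask, what = "spectra") {
  if (length(a_wl) != length(b_wl) ||
      max(abs(a_wl - b_wl)) > 1e-9 ||
      !identical(as.logical(a_mask), as.logical(b_mask))) {
    stop(sprintf("wavelength grid or validity mask mismatch between model and %s", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Coerce a spectra set to a wide tibble
#'
#' One row per spectrum: a `class` column, a `provenance` column, then one
#' column per wavelength channel named by its centre in nm. Masked channels
#' are included (their values are carried but ignored by the pipeline).
#'
#' @param x A `spectra_set`.
#' @param ... Unused.
#' @return A tibble with `n_spectra(x)` rows.
#' @method as_tibble spectra_set
#' @export
as_tibble.spectra_set <- function(x, ...) {
  mat <- x$intensities
  colnames(mat) <- format_wavelength(x$wavelengths)
  dplyr::bind_cols(
    tibble::tibble(class = x$labels, provenance = x$provenance),
    tibble::as_tibble(mat)
  )
}

format_wavelength <- function(wl) {
  formatC(wl, format = "fg", digits = 10)
}

#' Tidy a spectra set into long format
#'
#' @param x A `spectra_set`.
#' @param ... Unused.
#' @return A tibble with columns `spectrum` (row index), `class`,
#'   `wavelength` (nm), `intensity` and `valid`.
#' @method tidy spectra_set
#' @export
tidy.spectra_set <- function(x, ...) {
  n <- n_spectra(x)
  p <- n_channels(x)
  tibble::tibble(
    spectrum = rep(seq_len(n), each = p),
    class = rep(x$labels, each = p),
    wavelength = rep(x$wavelengths, times = n),
    intensity = as.vector(t(x$intensities)),
    valid = rep(x$valid_mask, times = n)
  )
}

#' Plot spectra coloured by class
#'
#' Masked channels (e.g. the band around the excitation laser line) are
#' dropped, producing the characteristic gap in the wavelength axis.
#'
#' @param object A `spectra_set`.
#' @param max_per_class Spectra drawn per class (default 3) to keep the
#'   figure readable.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectra_set
#' @export
autoplot.spectra_set <- function(object, max_per_class = 3, ...) {
  long <- tidy.spectra_set(object)
  keep <- unlist(lapply(split(seq_len(n_spectra(object)), object$labels),
                        utils::head, max_per_class), use.names = FALSE)
  long <- dplyr::filter(long, .data$valid, .data$spectrum %in% keep)
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$intensity,
                                     group = .data$spectrum,
                                     colour = .data$class)) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.8) +
    ggplot2::labs(x = "wavelength (nm)", y = "intensity (a.u.)",
                  colour = "formulation") +
    ggplot2::theme_minimal()
}
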