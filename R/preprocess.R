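#' Preprocessing configuration
#'
#' Parameters for the two preprocessing steps applied to every non-gated
#' LIBS spectrum before modelling: blanking the band around the excitation
#' laser wavelength, and normalizing each spectrum to its hydrogen
#' Balmer-alpha emission peak.
#'
#' @param notch_center Centre of the blanked band, nm. Default 532 (the
#'   frequency-doubled Nd:YAG excitation line).
#' @param notch_width Full width of the blanked band, nm (default 30, i.e.
#'   +/- 15 nm about the centre).
#' @param reference_line Wavelength of the normalization reference peak,
#'   nm. Default 656.3 (H-alpha).
#' @param reference_window Half-width of the search window around
#'   `reference_line` in which the peak maximum is located, nm (default 2).
#'
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(notch_center = 532, notch_width = 30,
                              reference_line = 656.3, reference_window = 2) {
  stopifnot(notch_width > 0, reference_window > 0)
  if (abs(reference_line - notch_center) <= notch_width / 2) {
    stop("reference_line lies inside the notch band", call. = FALSE)
  }
  structure(list(notch_center = notch_center, notch_width = notch_width,
                 reference_line = reference_line,
                 reference_window = reference_window),
            class = "preprocess_config")
}

#' Mask the band around the excitation laser line
#'
#' Channels whose centre falls in the closed interval
#' `[notch_center - notch_width/2, notch_center + notch_width/2]` are
#' marked invalid; their intensity values are disregarded by all
#' downstream analysis. Masking a grid that does not cover the interval is
#' a no-op, and the operation is idempotent.
#'
#' @param set A [spectra_set()].
#' @param cfg A [preprocess_config()].
#' @return The set with an updated validity mask.
#' @export
apply_notch_mask <- function(set, cfg = preprocess_config()) {
  stopifnot(inherits(set, "spectra_set"))
  lo <- cfg$notch_center - cfg$notch_width / 2
  hi <- cfg$notch_center + cfg$notch_width / 2
  inside <- set$wavelengths >= lo & set$wavelengths <= hi
  set$valid_mask <- set$valid_mask & !inside
  set
}

#' Normalize each spectrum to its reference-line peak
#'
#' Every row is divided by the maximum valid intensity found within
#' `reference_line +/- reference_window`; after normalization that maximum
#' is exactly 1. This emulates normalization to the characteristic
#' hydrogen emission peak near 656 nm, which all the formulations share.
#' The operation is idempotent and scale-invariant.
#'
#' @param set A [spectra_set()].
#' @param cfg A [preprocess_config()].
#' @return The normalized set.
#' @export
normalize_to_reference_line <- function(set, cfg = preprocess_config()) {
  stopifnot(inherits(set, "spectra_set"))
  win <- abs(set$wavelengths - cfg$reference_line) <= cfg$reference_window &
    set$valid_mask
  if (!any(win)) {
    stop("reference window contains no valid channel", call. = FALSE)
  }
  ref <- apply(set$intensities[, win, drop = FALSE], 1, max)
  bad <- which(!is.finite(ref) | ref <= 0)
  if (length(bad)) {
    stop(sprintf("reference peak maximum is not positive for spectra: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  set$intensities <- set$intensities / ref
  set
}
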