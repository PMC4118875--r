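#' Building blocks of the LIBS forward model
#'
#' `line_spec()` describes one atomic emission line as a unit-peak
#' Gaussian: `amplitude` is the peak height in arbitrary units, `fwhm` the
#' full width at half maximum in nm (emulating a Czerny-Turner
#' spectrograph's instrumental width), `element` a tag such as `"H"` or
#' `"F"`. `continuum_spec()` describes the broad featureless continuum
#' emission of a non-gated measurement as a wide Gaussian bump plus a
#' constant offset. `noise_model()` collects the three stochastic
#' components: shot noise (sd = `shot_scale * sqrt(intensity)` per
#' channel), static fixed-pattern detector gain non-uniformity
#' (multiplicative per-channel gains with sd `fixed_pattern_sd`, drawn
#' once per dataset), and per-spectrum lognormal scatter of each line
#' amplitude with sd `line_scatter_sd`, modelling pellet inhomogeneity.
#' `formulation_profile()` bundles a class label with its line list and
#' continuum.
#'
#' @param center Line / continuum centre, nm.
#' @param amplitude Peak height (a.u.), `>= 0`.
#' @param fwhm Full width at half maximum, nm, `> 0`.
#' @param element Element tag.
#' @return A list of the corresponding class.
#' @name forward-model
NULL

#' @rdname forward-model
#' @export
line_spec <- function(center, amplitude, fwhm = 1.0, element = "") {
  stopifnot(amplitude >= 0, fwhm > 0)
  structure(list(center = center, amplitude = amplitude, fwhm = fwhm,
                 element = element), class = "line_spec")
}

#' @rdname forward-model
#' @param width Gaussian width parameter of the continuum bump, nm.
#' @param offset Constant continuum floor, a.u.
#' @export
continuum_spec <- function(amplitude, center = 480, width = 130, offset = 0.2) {
  stopifnot(amplitude >= 0, width >= 0, offset >= 0)
  structure(list(amplitude = amplitude, center = center, width = width,
                 offset = offset), class = "continuum_spec")
}

#' @rdname forward-model
#' @param shot_scale Shot-noise scale (dimensionless, `>= 0`).
#' @param fixed_pattern_sd Sd of the per-channel multiplicative gains.
#' @param line_scatter_sd Sd of the per-spectrum lognormal line-amplitude
#'   multiplier.
#' @param seed Integer seed; identical seed implies an identical dataset.
#' @export
noise_model <- function(shot_scale = 0.02, fixed_pattern_sd = 0.05,
                        line_scatter_sd = 0.15, seed = 1L) {
  stopifnot(shot_scale >= 0, fixed_pattern_sd >= 0, line_scatter_sd >= 0)
  structure(list(shot_scale = shot_scale, fixed_pattern_sd = fixed_pattern_sd,
                 line_scatter_sd = line_scatter_sd, seed = as.integer(seed)),
            class = "noise_model")
}

#' @rdname forward-model
#' @param name Class label.
#' @param lines List of [line_spec()] objects (nonempty).
#' @param continuum A [continuum_spec()].
#' @export
formulation_profile <- function(name, lines, continuum) {
  stopifnot(length(lines) >= 1, inherits(continuum, "continuum_spec"))
  structure(list(name = name, lines = lines, continuum = continuum),
            class = "formulation_profile")
}

#' Default wavelength grid
#'
#' 2068 uniformly spaced channels spanning 350-900 nm, emulating a
#' compact CCD spectrometer of the Maya2000 class.
#'
#' @return Numeric vector of channel centres (nm).
#' @export
default_wavelength_grid <- function() {
  seq(350, 900, length.out = 2068)
}

#' Default registry of four pharmaceutical formulation profiles
#'
#' Four classes named after the formulations studied: all share
#' characteristic emission lines at 479.45 nm (Cl), 500, 567 and 747 nm
#' (N), 656.3 nm (H-alpha), and 777 and 868 nm (O) — the elements every
#' formulation exposes in ambient air — with class-specific amplitude
#' ratios. The two ciprofloxacin-family classes additionally carry two
#' fluorine-tagged lines (685.6 and 690.2 nm), since only their active
#' ingredient contains fluorine. The Metformin and Cetirizine analogues
#' form the designated hard pair: their line amplitudes and continuum
#' amplitude differ by at most 10 percent relative, so discrimination
#' hinges on subtle intensity ratios, as observed for the real pellets.
#'
#' @return Named list of four [formulation_profile()] objects.
#' @export
default_formulation_profiles <- function() {
  shared <- function(cl, n500, n567, n747, o777, o868) {
    list(
      line_spec(479.45, cl, 1.1, "Cl"),
      line_spec(500.0, n500, 1.0, "N"),
      line_spec(567.0, n567, 1.0, "N"),
      line_spec(656.3, 5.0, 1.2, "H"),
      line_spec(747.0, n747, 1.3, "N"),
      line_spec(777.0, o777, 1.2, "O"),
      line_spec(868.0, o868, 1.5, "O")
    )
  }
  f_lines <- function(a1, a2) {
    list(line_spec(685.6, a1, 0.9, "F"), line_spec(690.2, a2, 0.9, "F"))
  }
  profiles <- list(
    formulation_profile(
      "Cetirizine dihydrochloride",
      shared(2.0, 1.00, 0.80, 1.20, 1.60, 0.90),
      continuum_spec(1.4, center = 470, width = 130, offset = 0.25)
    ),
    formulation_profile(
      "Cipro pure",
      c(shared(1.2, 1.50, 1.10, 0.90, 2.00, 1.30), f_lines(0.9, 0.7)),
      continuum_spec(1.1, center = 500, width = 150, offset = 0.20)
    ),
    formulation_profile(
      "Metformin hydrochloride",
      shared(1.9, 1.08, 0.85, 1.28, 1.50, 0.96),
      continuum_spec(1.5, center = 470, width = 130, offset = 0.25)
    ),
    formulation_profile(
      "Ciprofloxacin hydrochloride",
      c(shared(2.6, 1.30, 0.90, 1.10, 1.80, 1.10), f_lines(0.8, 0.6)),
      continuum_spec(1.8, center = 450, width = 120, offset = 0.30)
    )
  )
  stats::setNames(profiles, vapply(profiles, `[[`, "", "name"))
}

#' Two profiles whose only difference is the continuum
#'
#' A minimal registry for probing whether class information carried purely
#' by the broad continuum background survives a classification pipeline:
#' both classes share an identical line list; only the continuum amplitude
#' differs (by `amplitude_delta` a.u.).
#'
#' @param amplitude_delta Continuum-amplitude difference between the two
#'   classes, a.u.
#' @return Named list of two [formulation_profile()] objects.
#' @export
continuum_pair_profiles <- function(amplitude_delta = 0.5) {
  lines <- list(
    line_spec(479.45, 2.0, 1.1, "Cl"),
    line_spec(500.0, 1.0, 1.0, "N"),
    line_spec(656.3, 5.0, 1.2, "H"),
    line_spec(777.0, 1.6, 1.2, "O")
  )
  profiles <- list(
    formulation_profile("continuum_lo", lines,
                        continuum_spec(1.2, center = 480, width = 140, offset = 0.25)),
    formulation_profile("continuum_hi", lines,
                        continuum_spec(1.2 + amplitude_delta, center = 480,
                                       width = 140, offset = 0.25))
  )
  stats::setNames(profiles, vapply(profiles, `[[`, "", "name"))
}

#' Evaluate a continuum specification on a grid
#'
#' `offset + amplitude * exp(-(lambda - center)^2 / (2 width^2))`.
#'
#' @param spec A [continuum_spec()].
#' @param grid Wavelengths (nm), nonempty.
#' @return Intensity vector, strictly positive whenever `offset > 0`.
#' @export
continuum_curve <- function(spec, grid) {
  stopifnot(inherits(spec, "continuum_spec"), length(grid) >= 1)
  if (spec$width == 0) {
    return(rep(spec$offset, length(grid)) +
             ifelse(grid == spec$center, spec$amplitude, 0))
  }
  spec$offset + spec$amplitude * exp(-(grid - spec$center)^2 / (2 * spec$width^2))
}

# unit-peak Gaussian line profile
gaussian_line <- function(grid, center, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(grid - center)^2 / (2 * sigma^2))
}

# noiseless line + continuum forward model, with per-line amplitude multipliers
clean_spectrum <- function(profile, grid, scatter = NULL) {
  y <- continuum_curve(profile$continuum, grid)
  if (is.null(scatter)) scatter <- rep(1, length(profile$lines))
  for (i in seq_along(profile$lines)) {
    ln <- profile$lines[[i]]
    y <- y + ln$amplitude * scatter[i] * gaussian_line(grid, ln$center, ln$fwhm)
  }
  y
}

#' Simulate one LIBS spectrum
#'
#' Intensities are `(continuum + sum of scattered Gaussian lines) * gains
#' + shot noise`, clipped at zero. `gains` is the fixed-pattern detector
#' gain vector; when `NULL` it is drawn here (one fresh pattern), but for
#' a dataset the pattern should be drawn once and shared across rows —
#' [simulate_dataset()] does this.
#'
#' @param profile A [formulation_profile()].
#' @param grid Wavelength grid (nm), strictly increasing, nonempty.
#' @param noise A [noise_model()].
#' @param gains Optional per-channel gain vector.
#' @param seed Optional seed applied locally (default: use the current RNG
#'   stream).
#' @return A single-row [spectra_set()] is not returned; this low-level
#'   routine returns the raw intensity vector.
#' @export
simulate_spectrum <- function(profile, grid, noise = noise_model(),
                              gains = NULL, seed = NULL) {
  if (length(grid) < 1) stop("empty wavelength grid", call. = FALSE)
  if (length(grid) > 1 && any(diff(grid) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  draw <- function() {
    if (is.null(gains)) {
      gains <- draw_gains(length(grid), noise$fixed_pattern_sd)
    }
    nl <- length(profile$lines)
    scatter <- if (noise$line_scatter_sd > 0) {
      stats::rlnorm(nl, meanlog = -noise$line_scatter_sd^2 / 2,
                    sdlog = noise$line_scatter_sd)
    } else {
      rep(1, nl)
    }
    y <- clean_spectrum(profile, grid, scatter) * gains
    if (noise$shot_scale > 0) {
      y <- y + stats::rnorm(length(grid), 0, noise$shot_scale * sqrt(pmax(y, 0)))
    }
    pmax(y, 0)
  }
  if (is.null(seed)) draw() else with_seed_local(seed, draw())
}

draw_gains <- function(p, sd) {
  if (sd <= 0) return(rep(1, p))
  pmax(1 + stats::rnorm(p, 0, sd), 0)
}

#' Simulate a labelled LIBS dataset
#'
#' `n_per_class` spectra per formulation on a shared grid. One
#' fixed-pattern gain vector is drawn for the whole dataset (it models
#' constant detector structure); line-amplitude scatter and shot noise are
#' drawn per spectrum. Fully reproducible under `seed`.
#'
#' @param registry Named list of [formulation_profile()] objects, e.g.
#'   [default_formulation_profiles()].
#' @param n_per_class Spectra per class (scalar or one per class).
#' @param grid Wavelength grid (nm).
#' @param noise A [noise_model()].
#' @param seed Seed (defaults to `noise$seed`).
#' @return A [spectra_set()] with `sum(n_per_class)` rows.
#' @examples
#' s <- simulate_dataset(default_formulation_profiles(), n_per_class = 3,
#'                       grid = seq(400, 900, by = 5), seed = 1)
#' table(s$labels)
#' @export
simulate_dataset <- function(registry, n_per_class, grid = default_wavelength_grid(),
                             noise = noise_model(), seed = noise$seed) {
  stopifnot(length(registry) >= 1, all(n_per_class >= 1))
  n_per_class <- rep_len(as.integer(n_per_class), length(registry))
  with_seed_local(seed, {
    gains <- draw_gains(length(grid), noise$fixed_pattern_sd)
    rows <- list()
    labels <- character(0)
    prov <- character(0)
    for (ci in seq_along(registry)) {
      prof <- registry[[ci]]
      for (r in seq_len(n_per_class[ci])) {
        rows[[length(rows) + 1L]] <- simulate_spectrum(prof, grid, noise, gains)
        labels <- c(labels, prof$name)
        prov <- c(prov, sprintf("%s/shot%03d", prof$name, r))
      }
    }
    spectra_set(grid, do.call(rbind, rows), labels = labels, provenance = prov)
  })
}

#' Ground-truth sidecar for a simulated dataset
#'
#' Returns the noiseless quantities behind [simulate_dataset()]: the true
#' continuum curve and line table per class, for use as an oracle when
#' testing baseline recovery.
#'
#' @param registry Profile registry.
#' @param grid Wavelength grid (nm).
#' @return A list with `continuum` (tibble: class, wavelength, intensity)
#'   and `lines` (tibble: class, element, center, amplitude, fwhm).
#' @export
simulation_ground_truth <- function(registry, grid = default_wavelength_grid()) {
  cont <- purrr::map_dfr(registry, function(p) {
    tibble::tibble(class = p$name, wavelength = grid,
                   intensity = continuum_curve(p$continuum, grid))
  })
  lines <- purrr::map_dfr(registry, function(p) {
    purrr::map_dfr(p$lines, function(ln) {
      tibble::tibble(class = p$name, element = ln$element, center = ln$center,
                     amplitude = ln$amplitude, fwhm = ln$fwhm)
    })
  })
  list(continuum = cont, lines = lines)
}
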