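#' Configuration of the resampled evaluation protocol
#'
#' The protocol: stratified 70/30 train/test splits, re-drawn
#' `n_iterations` times (default 100), fitting the chosen classifier on
#' each training split and scoring the held-out spectra with the
#' trichotomy correct / misclassified / unclassified. The
#' `baseline_removed` variant continuum-corrects every spectrum (after
#' reference-line normalization) before any splitting, so the comparison
#' between raw and background-removed runs isolates the effect of
#' continuum removal.
#'
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.7).
#' @param n_iterations Number of independent re-splits (default 100).
#' @param base_seed Base seed; iteration `i` uses `base_seed + i`.
#' @param classifier `"simca"`, `"plsda"` or `"ann"`.
#' @param classifier_args Named list of extra arguments for the
#'   classifier (e.g. `sigma_multiplier`, `n_latent`, `width`).
#' @param variant `"raw"` or `"baseline_removed"`.
#' @param baseline A [baseline_config()] for the corrected variant.
#' @return A list of class `evaluation_config`.
#' @export
evaluation_config <- function(train_fraction = 0.7, n_iterations = 100,
                              base_seed = 1,
                              classifier = c("simca", "plsda", "ann"),
                              classifier_args = list(),
                              variant = c("raw", "baseline_removed"),
                              baseline = baseline_config()) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_iterations >= 1)
  classifier <- match.arg(classifier)
  variant <- match.arg(variant)
  structure(list(train_fraction = train_fraction,
                 n_iterations = as.integer(n_iterations),
                 base_seed = as.integer(base_seed),
                 classifier = classifier, classifier_args = classifier_args,
                 variant = variant, baseline = baseline),
            class = "evaluation_config")
}

#' Stratified train/test split
#'
#' Per class, `round(n_c * train_fraction)` rows (round half up) go to
#' training — at least one row on each side — and the remainder to test.
#' The split is disjoint, exhaustive, and reproducible under `seed`.
#'
#' @param set A [spectra_set()]; every class needs at least 2 rows.
#' @param train_fraction Training fraction.
#' @param seed Seed for the shuffle (default: current RNG stream).
#' @return A list with sorted integer vectors `train` and `test`.
#' @export
stratified_split <- function(set, train_fraction = 0.7, seed = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  do_split <- function() {
    train <- integer(0)
    for (cl in class_levels(set)) {
      rows <- which(set$labels == cl)
      n_c <- length(rows)
      if (n_c < 2) {
        stop(sprintf("class '%s' has a single spectrum and cannot be split", cl),
             call. = FALSE)
      }
      n_tr <- min(max(floor(n_c * train_fraction + 0.5), 1L), n_c - 1L)
      train <- c(train, sample(rows, n_tr))
    }
    list(train = sort(train),
         test = sort(setdiff(seq_len(n_spectra(set)), train)))
  }
  if (is.null(seed)) do_split() else with_seed_local(seed, do_split())
}

#' Trichotomy rates from classification outcomes
#'
#' @param outcomes A tibble with columns `true_class` and `verdict`
#'   (values `correct`, `misclassified`, `unclassified`), as produced by
#'   [predict.simca_model()]; at least one outcome per class.
#' @param classes Class order (default: first appearance).
#' @return A tibble with one row per class plus an unweighted `"Average"`
#'   row; columns `class`, `correct`, `misclassified`, `unclassified`,
#'   `n`. Each rate triple sums to exactly 1.
#' @export
rates_from_outcomes <- function(outcomes, classes = unique(outcomes$true_class)) {
  per <- purrr::map_dfr(classes, function(cl) {
    v <- outcomes$verdict[outcomes$true_class == cl]
    if (!length(v)) stop(sprintf("no outcomes for class '%s'", cl), call. = FALSE)
    tibble::tibble(class = cl,
                   correct = mean(v == "correct"),
                   misclassified = mean(v == "misclassified"),
                   unclassified = mean(v == "unclassified"),
                   n = length(v))
  })
  avg <- tibble::tibble(class = "Average",
                        correct = mean(per$correct),
                        misclassified = mean(per$misclassified),
                        unclassified = mean(per$unclassified),
                        n = sum(per$n))
  dplyr::bind_rows(per, avg)
}

# fit the configured classifier on the training rows and return an
# outcomes tibble (true_class, verdict) for the test rows
evaluate_split <- function(set, split, classifier, args, iter_seed) {
  train <- set[split$train]
  test <- set[split$test]
  if (classifier == "simca") {
    cfg_args <- args[intersect(names(args),
                               names(formals(simca_config)))]
    model <- fit_simca(train, do.call(simca_config, cfg_args))
    out <- predict(model, test)
    return(out[, c("true_class", "verdict")])
  }
  assigned <- if (classifier == "plsda") {
    model <- fit_plsda(train, n_latent = args$n_latent %||% NULL,
                       max_latent = args$max_latent %||% 10,
                       cv_seed = iter_seed)
    predict(model, test)
  } else {
    k <- args$k %||% NULL
    cap <- min(10L, n_spectra(train) - 1L, sum(train$valid_mask))
    pca <- fit_pca(train, k = cap)
    if (is.null(k)) {
      cum <- cumsum(pca$variance_fractions[seq_len(cap)])
      k <- min(which(cum >= 0.99), cap)
      pca <- fit_pca(train, k = k)
    } else {
      pca <- fit_pca(train, k = k)
    }
    net <- suppressWarnings(
      fit_ann(project(pca, train), train$labels,
              width = args$width %||% 8,
              seed = args$seed %||% iter_seed,
              maxit = args$maxit %||% 300))
    predict(net, project(pca, test))
  }
  tibble::tibble(true_class = test$labels,
                 verdict = ifelse(assigned == test$labels,
                                  "correct", "misclassified"))
}

#' Run the resampled evaluation protocol
#'
#' For each iteration `i`: split with seed `base_seed + i`, fit the
#' configured classifier on the training rows, classify the held-out
#' rows, and record the per-class trichotomy rates. Reports means and
#' standard deviations over iterations, plus the per-iteration average
#' correct rate used by [compare_reports()]. Bit-reproducible under
#' `base_seed`.
#'
#' @param set A preprocessed [spectra_set()].
#' @param cfg An [evaluation_config()].
#' @return An object of class `evaluation_report`.
#' @export
run_iterations <- function(set, cfg = evaluation_config()) {
  stopifnot(inherits(set, "spectra_set"), inherits(cfg, "evaluation_config"))
  if (cfg$variant == "baseline_removed") {
    set <- batch_correct(set, cfg$baseline)
  }
  classes <- class_levels(set)
  per_iter <- vector("list", cfg$n_iterations)
  for (i in seq_len(cfg$n_iterations)) {
    iter_seed <- cfg$base_seed + i
    res <- tryCatch({
      split <- stratified_split(set, cfg$train_fraction, seed = iter_seed)
      out <- with_seed_local(iter_seed,
                             evaluate_split(set, split, cfg$classifier,
                                            cfg$classifier_args, iter_seed))
      rates_from_outcomes(out, classes)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      stop(sprintf("iteration %d failed: %s", i, conditionMessage(res)),
           call. = FALSE)
    }
    per_iter[[i]] <- dplyr::mutate(res, iteration = i)
  }
  all_rates <- dplyr::bind_rows(per_iter)
  summ <- all_rates |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      correct_mean = mean(.data$correct), correct_sd = sd0(.data$correct),
      misclassified_mean = mean(.data$misclassified),
      misclassified_sd = sd0(.data$misclassified),
      unclassified_mean = mean(.data$unclassified),
      unclassified_sd = sd0(.data$unclassified),
      .groups = "drop") |>
    dplyr::arrange(match(.data$class, c(classes, "Average")))
  per_iteration <- all_rates |>
    dplyr::filter(.data$class == "Average") |>
    dplyr::transmute(iteration = .data$iteration,
                     average_correct = .data$correct)
  structure(list(rates = summ, per_iteration = per_iteration,
                 classes = classes, config = cfg,
                 n_spectra = n_spectra(set)),
            class = "evaluation_report")
}

sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s / %s variant, %d iterations, %d spectra\n",
              x$config$classifier, x$config$variant,
              x$config$n_iterations, x$n_spectra))
  print(x$rates)
  invisible(x)
}

#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$rates

#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  avg <- x$rates[x$rates$class == "Average", ]
  tibble::tibble(classifier = x$config$classifier, variant = x$config$variant,
                 n_iterations = x$config$n_iterations,
                 average_correct = avg$correct_mean,
                 average_misclassified = avg$misclassified_mean,
                 average_unclassified = avg$unclassified_mean,
                 average_correct_sd = avg$correct_sd)
}

#' Bar chart of trichotomy rates per class
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  long <- object$rates |>
    tidyr::pivot_longer(cols = dplyr::ends_with("_mean"),
                        names_to = "rate", values_to = "mean") |>
    dplyr::mutate(rate = sub("_mean$", "", .data$rate))
  ggplot2::ggplot(long, ggplot2::aes(.data$class, .data$mean,
                                     fill = .data$rate)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "rate over iterations", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Compare two evaluation reports
#'
#' Welch two-sample t test (unequal variances) on the two reports'
#' per-iteration average correct rates; returns the two-tailed p-value.
#' When both vectors are constant, p is 1 for equal means and 0
#' otherwise, by convention.
#'
#' @param a,b `evaluation_report` objects.
#' @return Two-tailed p-value in `[0, 1]`.
#' @export
compare_reports <- function(a, b) {
  stopifnot(inherits(a, "evaluation_report"), inherits(b, "evaluation_report"))
  x <- a$per_iteration$average_correct
  y <- b$per_iteration$average_correct
  if (sd0(x) == 0 && sd0(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  unname(stats::t.test(x, y, var.equal = FALSE)$p.value)
}

#' Compare two evaluation report files
#'
#' Reads two JSON reports written by [write_report()] and applies the
#' same Welch comparison as [compare_reports()] to their per-iteration
#' average correct rates.
#'
#' @param path_a,path_b Report JSON files.
#' @return Two-tailed p-value in `[0, 1]`.
#' @export
compare_report_files <- function(path_a, path_b) {
  skeleton <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    v <- obj$per_iteration_average_correct
    if (is.null(v)) {
      stop(sprintf("%s does not contain per-iteration rates", path),
           call. = FALSE)
    }
    structure(list(per_iteration = tibble::tibble(
      iteration = seq_along(v), average_correct = as.numeric(v))),
      class = "evaluation_report")
  }
  compare_reports(skeleton(path_a), skeleton(path_b))
}

# plain-list view of a report, for JSON serialization
report_to_list <- function(report) {
  list(
    classifier = report$config$classifier,
    variant = report$config$variant,
    n_iterations = report$config$n_iterations,
    n_spectra = report$n_spectra,
    rates = lapply(seq_len(nrow(report$rates)), function(i) {
      as.list(report$rates[i, ])
    }),
    per_iteration_average_correct = report$per_iteration$average_correct
  )
}
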