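#' Assemble / read a pipeline configuration
#'
#' A single configuration drives the whole pipeline: where the data come
#' from (a CSV/XLSX file, or the simulator), the preprocessing, outlier
#' and baseline settings, and the evaluation protocol. Configurations
#' round-trip losslessly through YAML (JSON is valid YAML and is accepted
#' too).
#'
#' @param x Named list of overrides; unknown keys raise an error naming
#'   them.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list()) {
  defaults <- list(
    data = NULL,
    output_dir = "libsclass-output",
    simulate = list(n_per_class = 100, seed = 7,
                    grid = list(from = 350, to = 900, n = 2068),
                    noise = list(shot_scale = 0.02, fixed_pattern_sd = 0.05,
                                 line_scatter_sd = 0.15)),
    preprocess = list(notch_center = 532, notch_width = 30,
                      reference_line = 656.3, reference_window = 2),
    outliers = list(height_factor = 3, max_branch_size = 2, per_class = TRUE),
    baseline = list(order = 6, max_iter = 100, tol = 1e-4,
                    clip_negative_residual = TRUE),
    evaluation = list(classifier = "simca", variant = "raw",
                      train_fraction = 0.7, n_iterations = 100, base_seed = 1,
                      classifier_args = list()),
    pca = list(k = 3)
  )
  bad <- setdiff(names(x), names(defaults))
  if (length(bad)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, x)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML or JSON configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  pipeline_config(yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

cfg_grid <- function(cfg) {
  g <- cfg$simulate$grid
  seq(g$from, g$to, length.out = g$n)
}

cfg_noise <- function(cfg) {
  do.call(noise_model, c(cfg$simulate$noise, list(seed = cfg$simulate$seed)))
}

cfg_preprocess <- function(cfg) do.call(preprocess_config, cfg$preprocess)

cfg_baseline <- function(cfg) do.call(baseline_config, cfg$baseline)

stage_log <- function(stage, t0, ...) {
  message(sprintf("[libsclass] %-12s %6.2fs  %s", stage,
                  as.numeric(Sys.time()) - t0, sprintf(...)))
}

#' Simulate a dataset and write it (with its ground truth) to disk
#'
#' Writes `spectra.csv` (wide format, readable by [read_spectra()]),
#' `ground_truth_continuum.csv` and `ground_truth_lines.csv` (the
#' noiseless per-class continuum curves and line tables, for oracle
#' checks), and a `config.yaml` echo. Re-running with the same seed
#' reproduces the files bit for bit.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (default `cfg$output_dir`).
#' @return Named character vector of the written paths, invisibly.
#' @export
cmd_simulate <- function(cfg = pipeline_config(), out_dir = cfg$output_dir) {
  t0 <- as.numeric(Sys.time())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- default_formulation_profiles()
  grid <- cfg_grid(cfg)
  set <- simulate_dataset(registry, cfg$simulate$n_per_class, grid,
                          cfg_noise(cfg), seed = cfg$simulate$seed)
  truth <- simulation_ground_truth(registry, grid)
  paths <- c(
    spectra = file.path(out_dir, "spectra.csv"),
    continuum = file.path(out_dir, "ground_truth_continuum.csv"),
    lines = file.path(out_dir, "ground_truth_lines.csv"),
    config = file.path(out_dir, "config.yaml")
  )
  write_spectra(set, paths[["spectra"]])
  readr::write_csv(truth$continuum, paths[["continuum"]], progress = FALSE)
  readr::write_csv(truth$lines, paths[["lines"]], progress = FALSE)
  write_pipeline_config(cfg, paths[["config"]])
  stage_log("simulate", t0, "%d spectra x %d channels -> %s",
            n_spectra(set), n_channels(set), out_dir)
  invisible(paths)
}

# shared front end: load or simulate, then notch -> normalize -> outliers
load_and_preprocess <- function(cfg) {
  t0 <- as.numeric(Sys.time())
  set <- if (!is.null(cfg$data)) {
    read_spectra(cfg$data)
  } else {
    simulate_dataset(default_formulation_profiles(), cfg$simulate$n_per_class,
                     cfg_grid(cfg), cfg_noise(cfg), seed = cfg$simulate$seed)
  }
  stage_log("load", t0, "%d spectra, %d classes", n_spectra(set),
            length(class_levels(set)))
  t0 <- as.numeric(Sys.time())
  pp <- cfg_preprocess(cfg)
  set <- set |> apply_notch_mask(pp) |> normalize_to_reference_line(pp)
  rule <- outlier_rule(cfg$outliers$height_factor, cfg$outliers$max_branch_size)
  flagged <- detect_outliers_by_class(set, rule,
                                      per_class = isTRUE(cfg$outliers$per_class))
  n_in <- n_spectra(set)
  if (length(flagged)) set <- set[-flagged]
  stage_log("preprocess", t0,
            "notch + normalize; outliers flagged %d of %d, %d spectra retained",
            length(flagged), n_in, n_spectra(set))
  list(set = set, flagged = flagged, n_input = n_in)
}

#' Run the classification experiments end to end
#'
#' Executes notch masking, reference-line normalization, per-class
#' dendrogram outlier removal, then the resampled evaluation for the raw
#' and/or background-removed variants, writing one JSON report per
#' variant (and, when both run, a comparison JSON with the Welch
#' two-tailed p-value on the per-iteration average correct rates).
#'
#' @param cfg A [pipeline_config()]. Set `cfg$evaluation$variant` to
#'   `"raw"`, `"baseline_removed"` or `"both"`.
#' @return A list with the `evaluation_report` objects, the comparison
#'   p-value (when both variants run), outlier counts and written paths.
#' @export
cmd_run <- function(cfg = pipeline_config()) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  front <- load_and_preprocess(cfg)
  variants <- if (identical(cfg$evaluation$variant, "both")) {
    c("raw", "baseline_removed")
  } else {
    cfg$evaluation$variant
  }
  reports <- list()
  paths <- character(0)
  for (v in variants) {
    t0 <- as.numeric(Sys.time())
    ecfg <- evaluation_config(
      train_fraction = cfg$evaluation$train_fraction,
      n_iterations = cfg$evaluation$n_iterations,
      base_seed = cfg$evaluation$base_seed,
      classifier = cfg$evaluation$classifier,
      classifier_args = cfg$evaluation$classifier_args,
      variant = v, baseline = cfg_baseline(cfg)
    )
    rep <- run_iterations(front$set, ecfg)
    p <- file.path(cfg$output_dir, sprintf("report_%s_%s.json",
                                           cfg$evaluation$classifier, v))
    write_report(rep, p)
    paths <- c(paths, p)
    reports[[v]] <- rep
    stage_log(paste0("evaluate/", v), t0, "average correct %.3f",
              rep$rates$correct_mean[rep$rates$class == "Average"])
  }
  p_value <- NULL
  if (length(reports) == 2) {
    p_value <- compare_reports(reports[["raw"]], reports[["baseline_removed"]])
    cmp_path <- file.path(cfg$output_dir, "comparison.json")
    write_report(list(
      raw_average_correct = mean(reports$raw$per_iteration$average_correct),
      baseline_removed_average_correct =
        mean(reports$baseline_removed$per_iteration$average_correct),
      welch_two_tailed_p = p_value
    ), cmp_path)
    paths <- c(paths, cmp_path)
  }
  invisible(list(reports = reports, p_value = p_value,
                 flagged = front$flagged, n_input = front$n_input,
                 n_retained = n_spectra(front$set), paths = paths))
}

#' Exploratory analysis: PCA summary and class dendrogram
#'
#' After preprocessing and outlier removal, fits a global PCA, and
#' builds the class-mean similarity dendrogram. Writes
#' `pca_variance.csv`, `pca_scores.csv`, `class_dendrogram.json` and
#' `class_dendrogram.nwk`.
#'
#' @param cfg A [pipeline_config()] (`cfg$pca$k` components).
#' @return A list with the `libs_pca` model, score matrix, dendrogram and
#'   written paths, invisibly.
#' @export
cmd_explore <- function(cfg = pipeline_config()) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  front <- load_and_preprocess(cfg)
  t0 <- as.numeric(Sys.time())
  pca <- fit_pca(front$set, k = cfg$pca$k)
  scores <- project(pca, front$set)
  means <- class_mean_spectra(front$set)
  dend <- class_similarity_dendrogram(means)
  paths <- c(
    variance = file.path(cfg$output_dir, "pca_variance.csv"),
    scores = file.path(cfg$output_dir, "pca_scores.csv"),
    dendro_json = file.path(cfg$output_dir, "class_dendrogram.json"),
    dendro_nwk = file.path(cfg$output_dir, "class_dendrogram.nwk")
  )
  readr::write_csv(tidy(pca), paths[["variance"]], progress = FALSE)
  readr::write_csv(dplyr::bind_cols(tibble::tibble(class = front$set$labels),
                                    tibble::as_tibble(scores)),
                   paths[["scores"]], progress = FALSE)
  write_report(list(leaves = dend$leaf_labels,
                    merges = lapply(seq_len(nrow(dendrogram_merges(dend))),
                                    function(i) as.list(dendrogram_merges(dend)[i, ]))),
               paths[["dendro_json"]])
  writeLines(dendrogram_to_newick(dend), paths[["dendro_nwk"]])
  stage_log("explore", t0, "PC1-%d cumulative variance %.1f%%",
            pca$k, 100 * variance_explained(pca, pca$k))
  invisible(list(pca = pca, scores = scores, dendrogram = dend, paths = paths))
}
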