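test_that("stratified split sizes follow round-half-up per class", {
  grid <- seq(400, 418, by = 2)
  n_c <- c(100, 100, 100, 103)
  labs <- rep(c("a", "b", "c", "d"), times = n_c)
  s <- spectra_set(grid, matrix(rnorm(sum(n_c) * 10), sum(n_c), 10), labs)
  split <- stratified_split(s, 0.7, seed = 1)
  tr_sizes <- vapply(c("a", "b", "c", "d"),
                     function(cl) sum(s$labels[split$train] == cl), 0L)
  expect_equal(unname(tr_sizes), c(70L, 70L, 70L, 72L))
  # disjoint and exhaustive
  expect_length(intersect(split$train, split$test), 0)
  expect_setequal(c(split$train, split$test), seq_len(sum(n_c)))
  # reproducible
  expect_identical(stratified_split(s, 0.7, seed = 1), split)
  # singleton class refuses to split
  one <- spectra_set(grid, matrix(rnorm(30), 3, 10), c("a", "a", "b"))
  expect_error(stratified_split(one, 0.7, seed = 1), "single spectrum")
})

test_that("rates are fractions of verdicts with an unweighted average", {
  out <- tibble::tibble(true_class = rep("a", 10),
                        verdict = rep("correct", 10))
  r <- rates_from_outcomes(out)
  expect_equal(r$correct, c(1, 1))
  out2 <- tibble::tibble(
    true_class = c(rep("a", 10), rep("b", 4)),
    verdict = c(rep("correct", 8), rep("unclassified", 2), rep("correct", 4)))
  r2 <- rates_from_outcomes(out2)
  expect_equal(r2$correct[r2$class == "a"], 0.8)
  expect_equal(r2$unclassified[r2$class == "a"], 0.2)
  # unweighted class mean, not pooled: (0.8 + 1)/2
  expect_equal(r2$correct[r2$class == "Average"], 0.9)
  expect_equal(r2$correct + r2$misclassified + r2$unclassified, rep(1, 3))
  expect_error(rates_from_outcomes(out, classes = c("a", "ghost")), "ghost")
})

test_that("per-class rates averaging matches the published-table convention", {
  # four per-class correct rates average like a printed summary row
  expect_equal(mean(c(1.00, 0.86, 0.82, 0.96)), 0.91)
  out <- tibble::tibble(
    true_class = rep(c("w", "x", "y", "z"), each = 50),
    verdict = c(rep("correct", 50),
                rep(c("correct", "unclassified"), times = c(43, 7)),
                rep(c("correct", "unclassified"), times = c(41, 9)),
                rep(c("correct", "unclassified"), times = c(48, 2))))
  r <- rates_from_outcomes(out)
  expect_equal(r$correct[r$class == "Average"],
               mean(r$correct[r$class != "Average"]))
})

test_that("the iteration protocol is reproducible bit for bit", {
  s <- prep(sim_default(n = 12, seed = 40, grid = tiny_grid(4)))
  cfg <- evaluation_config(n_iterations = 3, base_seed = 9,
                           classifier = "simca")
  r1 <- run_iterations(s, cfg)
  r2 <- run_iterations(s, cfg)
  expect_identical(r1$rates, r2$rates)
  expect_identical(r1$per_iteration, r2$per_iteration)
  r3 <- run_iterations(s, evaluation_config(n_iterations = 3, base_seed = 10,
                                            classifier = "simca"))
  expect_false(identical(r1$per_iteration, r3$per_iteration))
})

test_that("a single iteration on separable data is perfect for PLS-DA", {
  s <- prep(sim_separable(n = 12, seed = 41))
  cfg <- evaluation_config(n_iterations = 1, classifier = "plsda",
                           classifier_args = list(n_latent = 3))
  r <- run_iterations(s, cfg)
  expect_equal(r$rates$correct_mean[r$rates$class == "Average"], 1)
  expect_equal(r$rates$misclassified_mean[r$rates$class == "Average"], 0)
  # single iteration: sds are zero
  expect_true(all(r$rates$correct_sd == 0))
})

test_that("rate conservation holds per class in every iteration", {
  s <- prep(sim_default(n = 10, seed = 42, grid = tiny_grid(4)))
  r <- run_iterations(s, evaluation_config(n_iterations = 4,
                                           classifier = "simca"))
  sums <- r$rates$correct_mean + r$rates$misclassified_mean +
    r$rates$unclassified_mean
  expect_equal(sums, rep(1, nrow(r$rates)), tolerance = 1e-12)
})

test_that("report comparison is a symmetric Welch test with sane conventions", {
  s <- prep(sim_default(n = 12, seed = 43, grid = tiny_grid(4)))
  cfg <- evaluation_config(n_iterations = 4, classifier = "simca")
  r1 <- run_iterations(s, cfg)
  expect_equal(compare_reports(r1, r1), 1)
  s2 <- prep(sim_default(n = 12, seed = 44, grid = tiny_grid(4)))
  r2 <- run_iterations(s2, cfg)
  expect_equal(compare_reports(r1, r2), compare_reports(r2, r1))
  p <- compare_reports(r1, r2)
  expect_gte(p, 0)
  expect_lte(p, 1)
})

test_that("summary-statistic Welch oracle: 91% vs 88% at sd 0.005 is p < 1e-4", {
  p <- oracle_welch_p(0.91, 0.005, 100, 0.88, 0.005, 100)
  expect_lt(p, 1e-4)
  # and the package's test agrees with the closed form on real vectors
  set.seed(45)
  x <- rnorm(100, 0.91, 0.005)
  y <- rnorm(100, 0.88, 0.005)
  skel <- function(v) {
    structure(list(per_iteration = tibble::tibble(
      iteration = seq_along(v), average_correct = v)),
      class = "evaluation_report")
  }
  p_pkg <- compare_reports(skel(x), skel(y))
  p_ora <- oracle_welch_p(mean(x), sd(x), 100, mean(y), sd(y), 100)
  expect_equal(p_pkg, p_ora, tolerance = 1e-10)
})

test_that("constant equal reports compare to p = 1 by convention", {
  skel <- function(v) {
    structure(list(per_iteration = tibble::tibble(
      iteration = seq_along(v), average_correct = v)),
      class = "evaluation_report")
  }
  expect_equal(compare_reports(skel(rep(0.9, 5)), skel(rep(0.9, 5))), 1)
  expect_equal(compare_reports(skel(rep(0.9, 5)), skel(rep(0.8, 5))), 0)
})

test_that("continuum-held information is lost by baseline removal", {
  reg <- continuum_pair_profiles(amplitude_delta = 0.5)
  raw_wins <- vapply(1:4, function(i) {
    s <- prep(simulate_dataset(reg, 24, grid = tiny_grid(4),
                               noise = noise_model(), seed = 600 + i))
    base <- evaluation_config(n_iterations = 2, base_seed = i,
                              classifier = "plsda",
                              classifier_args = list(n_latent = 3))
    removed <- base
    removed$variant <- "baseline_removed"
    acc <- function(cfg) {
      r <- run_iterations(s, cfg)
      r$rates$correct_mean[r$rates$class == "Average"]
    }
    acc(base) > acc(removed)
  }, TRUE)
  expect_gte(mean(raw_wins), 0.75)
})
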