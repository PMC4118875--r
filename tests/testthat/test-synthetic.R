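test_that("default registry matches the four-formulation design", {
  reg <- default_formulation_profiles()
  expect_length(reg, 4)
  has_f <- vapply(reg, function(p) {
    any(vapply(p$lines, `[[`, "", "element") == "F")
  }, TRUE)
  expect_equal(sum(has_f), 2)  # only the ciprofloxacin-family classes
  # every profile carries the hydrogen reference line
  expect_true(all(vapply(reg, function(p) {
    any(vapply(p$lines, `[[`, 0, "center") == 656.3)
  }, TRUE)))
  # hard pair differs by at most 10% relative in amplitudes and continuum
  a <- reg[["Cetirizine dihydrochloride"]]
  b <- reg[["Metformin hydrochloride"]]
  amp <- function(p) vapply(p$lines, `[[`, 0, "amplitude")
  rel <- abs(amp(a) - amp(b)) / pmax(amp(a), amp(b))
  expect_lte(max(rel), 0.10)
  expect_lte(abs(a$continuum$amplitude - b$continuum$amplitude) /
               max(a$continuum$amplitude, b$continuum$amplitude), 0.10)
})

test_that("continuum curve has the stated closed form", {
  grid <- seq(-10, 10) + 500
  flat <- continuum_curve(continuum_spec(0, offset = 0.7), grid)
  expect_equal(flat, rep(0.7, length(grid)))
  spec <- continuum_spec(2, center = 500, width = 5, offset = 0.3)
  y <- continuum_curve(spec, grid)
  expect_equal(y[grid == 500], 2.3)                # offset + amplitude at centre
  expect_equal(y, rev(y))                          # symmetric about centre
  expect_true(all(y > 0))
})

test_that("a noiseless single line lands at its centre with its amplitude", {
  grid <- seq(606.3, 706.3, by = 0.25)   # grid hits 656.3 exactly
  prof <- formulation_profile("x", list(line_spec(656.3, 5, 1)),
                              continuum_spec(0, offset = 0))
  quiet <- noise_model(0, 0, 0)
  y <- simulate_spectrum(prof, grid, quiet)
  expect_lt(abs(grid[which.max(y)] - 656.3), 0.25 + 1e-12)
  expect_equal(max(y), 5, tolerance = 1e-9)
  expect_error(simulate_spectrum(prof, numeric(0), quiet), "empty")
})

test_that("the noiseless forward model is linear in amplitudes", {
  grid <- tiny_grid()
  quiet <- noise_model(0, 0, 0)
  prof <- default_formulation_profiles()[[1]]
  doubled <- prof
  doubled$lines <- lapply(prof$lines, function(l) {
    l$amplitude <- 2 * l$amplitude
    l
  })
  doubled$continuum$amplitude <- 2 * doubled$continuum$amplitude
  doubled$continuum$offset <- 2 * doubled$continuum$offset
  y1 <- simulate_spectrum(prof, grid, quiet)
  y2 <- simulate_spectrum(doubled, grid, quiet)
  expect_equal(y2, 2 * y1, tolerance = 1e-12)
})

test_that("datasets are deterministic under seed and correctly labelled", {
  s1 <- sim_default(n = 5, seed = 42)
  s2 <- sim_default(n = 5, seed = 42)
  expect_identical(s1$intensities, s2$intensities)
  expect_identical(s1$labels, s2$labels)
  expect_equal(n_spectra(s1), 20)
  expect_equal(unname(table(s1$labels)[class_levels(s1)]),
               rep(5L, 4), ignore_attr = TRUE)
  s3 <- sim_default(n = 5, seed = 43)
  expect_false(identical(s1$intensities, s3$intensities))
})

test_that("line-amplitude scatter is calibrated (cv of peak height ~ sd)", {
  grid <- seq(470, 490, by = 0.25)
  prof <- formulation_profile("x", list(line_spec(479.45, 3, 1.1, "Cl")),
                              continuum_spec(0, offset = 0))
  nm <- noise_model(shot_scale = 0, fixed_pattern_sd = 0,
                    line_scatter_sd = 0.15)
  s <- simulate_dataset(list(x = prof), 1000, grid = grid, noise = nm, seed = 2)
  peak <- apply(s$intensities, 1, max)
  expect_equal(stats::sd(peak) / mean(peak), 0.15, tolerance = 0.03)
})

test_that("shot-noise magnitude matches its configured scale", {
  grid <- seq(500, 520, by = 0.5)
  prof <- formulation_profile("x", list(line_spec(400, 0, 1)),
                              continuum_spec(0, offset = 4))
  nm <- noise_model(shot_scale = 0.05, fixed_pattern_sd = 0,
                    line_scatter_sd = 0)
  s <- simulate_dataset(list(x = prof), 1000, grid = grid, noise = nm, seed = 3)
  # flat level 4: sd should be shot_scale * sqrt(4) = 0.1
  expect_equal(stats::sd(s$intensities[, 10]), 0.05 * 2, tolerance = 0.05)
})

test_that("fixed-pattern gains are shared across a dataset but differ between seeds", {
  grid <- seq(500, 520, by = 0.5)
  prof <- formulation_profile("x", list(line_spec(400, 0, 1)),
                              continuum_spec(0, offset = 1))
  nm <- noise_model(shot_scale = 0, fixed_pattern_sd = 0.1, line_scatter_sd = 0)
  s <- simulate_dataset(list(x = prof), 5, grid = grid, noise = nm, seed = 4)
  # without per-row noise every row equals the gain vector itself
  for (i in 2:5) expect_equal(s$intensities[i, ], s$intensities[1, ])
  s2 <- simulate_dataset(list(x = prof), 5, grid = grid, noise = nm, seed = 5)
  expect_false(identical(s$intensities[1, ], s2$intensities[1, ]))
})

test_that("zero-noise distinct profiles are perfectly separated by class means", {
  s <- simulate_dataset(separable_profiles(), 6, grid = tiny_grid(),
                        noise = noise_model(0, 0, 0), seed = 1)
  means <- class_mean_spectra(s)
  d <- as.matrix(stats::dist(rbind(s$intensities, means$intensities)))
  n <- n_spectra(s)
  assigned <- apply(d[seq_len(n), n + seq_len(3), drop = FALSE], 1, which.min)
  expect_equal(means$labels[assigned], s$labels)
})

test_that("hard-pair confusion is non-decreasing in the scatter level", {
  reg <- default_formulation_profiles()[c("Cetirizine dihydrochloride",
                                          "Metformin hydrochloride")]
  confusion <- vapply(c(0.02, 0.15, 0.5), function(sc) {
    nm <- noise_model(shot_scale = 0.02, fixed_pattern_sd = 0.05,
                      line_scatter_sd = sc)
    s <- prep(simulate_dataset(reg, 40, grid = tiny_grid(), noise = nm,
                               seed = 77))
    # nearest-class-mean confusion, leave-split: train on first 30, test rest
    idx_tr <- unlist(lapply(class_levels(s),
                            function(cl) which(s$labels == cl)[1:30]))
    means <- class_mean_spectra(s[idx_tr])
    test <- s[-idx_tr]
    d <- vapply(seq_len(n_spectra(means)), function(k) {
      rowSums(sweep(valid_matrix(test), 2, valid_matrix(means)[k, ])^2)
    }, numeric(n_spectra(test)))
    mean(means$labels[apply(d, 1, which.min)] != test$labels)
  }, 0)
  expect_true(all(diff(confusion) >= 0))
})
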