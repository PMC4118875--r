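test_that("constructor enforces the container invariants", {
  expect_error(spectra_set(c(1, 2), matrix(1, 1, 3), "a"), "channels")
  expect_error(spectra_set(c(2, 1, 3), matrix(1, 1, 3), "a"), "increasing")
  expect_error(spectra_set(c(1, 1, 2), matrix(1, 1, 3), "a"), "duplicate")
  expect_error(spectra_set(1:3, matrix(c(1, NA, 3), 1), "a"), "non-finite")
  expect_error(spectra_set(1:3, matrix(0, 0, 3), character(0)), "at least one")
  # non-finite values allowed on masked channels
  s <- spectra_set(1:3, matrix(c(1, NA, 3), 1), "a",
                   valid_mask = c(TRUE, FALSE, TRUE))
  expect_equal(sum(s$valid_mask), 2)
  # class order is first appearance, stable under subsetting
  s2 <- spectra_set(1:3, matrix(1:12, 4, 3), labels = c("z", "a", "z", "b"))
  expect_equal(class_levels(s2), c("z", "a", "b"))
  expect_equal(class_levels(s2[c(4, 2)]), c("a", "b"))
})

test_that("notch masking covers the closed interval and is idempotent", {
  grid <- seq(400, 900, by = 1)
  s <- spectra_set(grid, matrix(1, 1, length(grid)), "a")
  m <- apply_notch_mask(s, preprocess_config())
  masked_wl <- m$wavelengths[!m$valid_mask]
  expect_equal(length(masked_wl), 31)  # 517..547 nm inclusive
  expect_equal(range(masked_wl), c(517, 547))
  expect_identical(apply_notch_mask(m, preprocess_config())$valid_mask,
                   m$valid_mask)
  # disjoint grid: nothing masked
  g2 <- seq(600, 900, by = 1)
  s2 <- spectra_set(g2, matrix(1, 1, length(g2)), "a")
  expect_true(all(apply_notch_mask(s2)$valid_mask))
})

test_that("reference-line normalization scales, is idempotent and scale-invariant", {
  grid <- seq(606.3, 706.3, by = 0.5)    # grid hits 656.3 exactly
  y <- exp(-(grid - 656.3)^2 / 2) * 2    # window max 2.0 at 656.3 nm
  s <- spectra_set(grid, rbind(y, 5 * y), c("a", "a"))
  n1 <- normalize_to_reference_line(s)
  win <- abs(grid - 656.3) <= 2
  expect_equal(max(n1$intensities[1, win]), 1.0)
  expect_equal(n1$intensities[1, ], y / 2)
  # scale invariance: f(c x) = f(x)
  expect_equal(n1$intensities[2, ], n1$intensities[1, ])
  # idempotence
  n2 <- normalize_to_reference_line(n1)
  expect_equal(n2$intensities, n1$intensities)
})

test_that("normalization failures carry the offending row index", {
  grid <- seq(600, 700, by = 1)
  y_ok <- exp(-(grid - 656)^2 / 8)
  s <- spectra_set(grid, rbind(y_ok, 0 * y_ok), c("a", "b"))
  expect_error(normalize_to_reference_line(s), "spectra: 2")
  # window entirely masked
  s2 <- spectra_set(grid, rbind(y_ok), "a",
                    valid_mask = abs(grid - 656.3) > 3)
  expect_error(normalize_to_reference_line(s2), "no valid channel")
})

test_that("simulated reference peak normalizes to exactly 1", {
  s <- prep(sim_default(n = 3, seed = 4))
  win <- abs(s$wavelengths - 656.3) <= 2 & s$valid_mask
  for (i in seq_len(n_spectra(s))) {
    expect_equal(max(s$intensities[i, win]), 1.0)
  }
})

test_that("wide CSV round-trips labels, grid, mask and intensities", {
  s <- sim_default(n = 3, seed = 9) |> apply_notch_mask()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, path)
  r <- read_spectra(path)
  expect_identical(r$labels, s$labels)
  expect_identical(r$valid_mask, s$valid_mask)
  expect_equal(r$wavelengths, s$wavelengths, tolerance = 1e-9)
  expect_equal(r$intensities, s$intensities, tolerance = 1e-12)
})

test_that("reader handles a minimal CSV and rejects bad headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("class,400,410,420,430,440",
               "a,1,2,3,4,5", "a,2,3,4,5,6", "b,1,1,1,1,1"), path)
  s <- read_spectra(path)
  expect_equal(n_spectra(s), 3)
  expect_equal(n_channels(s), 5)
  expect_equal(class_levels(s), c("a", "b"))
  # unparsable wavelength header named in the error
  writeLines(c("class,400,bogus", "a,1,2"), path)
  expect_error(read_spectra(path), "bogus")
  # missing label column
  writeLines(c("400,410", "1,2"), path)
  expect_error(read_spectra(path), "label column")
})

test_that("channel-oriented layout reads with a label sidecar", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength,s1,s2,s3",
               "500,1,2,3", "400,4,5,6", "600,7,8,9"), path)
  side <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,class", "s1,a", "s2,b", "s3,a"), side)
  s <- read_spectra(path, orientation = "channels", labels = side)
  expect_equal(s$wavelengths, c(400, 500, 600))  # sorted ascending
  expect_equal(s$labels, c("a", "b", "a"))
  expect_equal(s$intensities[2, ], c(5, 2, 8))   # columns reordered with grid
  expect_error(read_spectra(path, orientation = "channels"), "labels")
})

test_that("masked channels never influence downstream results", {
  s <- prep(sim_default(n = 8, seed = 3))
  vandal <- s
  vandal$intensities[, !vandal$valid_mask] <- 1e6
  expect_identical(fit_pca(s, 3)$loadings, fit_pca(vandal, 3)$loadings)
  m1 <- fit_simca(s)
  m2 <- fit_simca(vandal)
  expect_identical(predict(m1, s)$verdict, predict(m2, vandal)$verdict)
  t1 <- hierarchical_cluster(s)$hclust$height
  t2 <- hierarchical_cluster(vandal)$hclust$height
  expect_identical(t1, t2)
  b1 <- iterative_polyfit_baseline(s$wavelengths, s$intensities[1, ],
                                   s$valid_mask)
  b2 <- iterative_polyfit_baseline(vandal$wavelengths, vandal$intensities[1, ],
                                   vandal$valid_mask)
  expect_identical(b1$baseline, b2$baseline)
})

test_that("report JSON carries the rates it was given", {
  path <- withr::local_tempfile(fileext = ".json")
  write_report(list(correct = 1, misclassified = 0, unclassified = 0), path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$correct, 1)
  expect_equal(parsed$misclassified, 0)
  expect_equal(parsed$unclassified, 0)
})
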