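test_that("theoretical fragments match an independent mass summation", {
  # independent oracle: explicit residue masses summed per ion span
  mono <- c(A = 71.03711, G = 57.02146, S = 87.03203, I = 113.08406,
            N = 114.04293, F = 147.06841, E = 129.04259, K = 128.09496,
            L = 113.08406)
  proton <- 1.00728; water <- 18.01056
  f <- theoretical_fragments("AG")
  expect_equal(f$mz[f$type == "b" & f$index == 1], mono[["A"]] + proton,
               tolerance = 1e-4)
  expect_equal(f$mz[f$type == "y" & f$index == 1],
               mono[["G"]] + water + proton, tolerance = 1e-4)
  pep <- "SIINFEKL"
  res <- strsplit(pep, "")[[1]]
  f2 <- theoretical_fragments(pep)
  expect_equal(nrow(f2), 2 * (nchar(pep) - 1))
  for (i in 1:7) {
    expect_equal(f2$mz[f2$type == "b" & f2$index == i],
                 sum(mono[res[1:i]]) + proton, tolerance = 1e-4)
    expect_equal(f2$mz[f2$type == "y" & f2$index == i],
                 sum(mono[res[(9 - i):8]]) + water + proton,
                 tolerance = 1e-4)
  }
})

test_that("an isotope label shifts exactly the ions spanning it", {
  n <- 8L
  f <- theoretical_fragments("SIINFEKL", label_shift = 6,
                             label_position = n)
  # label on the C-terminal residue: every y ion shifted, no b ion
  f0 <- theoretical_fragments("SIINFEKL")
  expect_true(all(f$contains_label[f$type == "y"]))
  expect_false(any(f$contains_label[f$type == "b"]))
  expect_equal(f$mz[f$type == "y"], f0$mz[f0$type == "y"] + 6)
  expect_equal(f$mz[f$type == "b"], f0$mz[f0$type == "b"])
  # label at position 3: b_i shifted iff i >= 3, y_i iff i >= n - 2
  f3 <- theoretical_fragments("SIINFEKL", 6, 3)
  expect_equal(f3$contains_label[f3$type == "b"], 1:7 >= 3)
  expect_equal(f3$contains_label[f3$type == "y"], 1:7 >= n - 2)
  expect_error(theoretical_fragments("SIINFEKL", 6, 9),
               "label_position")
})

test_that("encoding picks peaks within tolerance, most intense on ties", {
  f <- theoretical_fragments("AGAG")
  # exact theoretical peaks -> all slots filled
  sp <- fragment_spectrum("AGAG", cbind(mz = f$mz, intensity = rep(10, nrow(f))),
                 precursor_mz = 200)
  e <- encode_spectrum(sp, f)
  expect_true(all(e$intensities > 0))
  expect_equal(sqrt(sum(e$intensities^2)), 1, tolerance = 1e-12)
  # a peak 0.05 Da off with tol 0.02 does not match
  sp2 <- fragment_spectrum("AGAG", cbind(mz = f$mz[1] + 0.05, intensity = 10),
                  precursor_mz = 200)
  e2 <- encode_spectrum(sp2, f, tol = 0.02)
  expect_true(e2$all_zero)
  # two peaks within tol of one slot -> the more intense is taken
  sp3 <- fragment_spectrum("AGAG",
                  cbind(mz = c(f$mz[1] - 0.01, f$mz[1] + 0.01),
                        intensity = c(3, 7)),
                  precursor_mz = 200)
  e3 <- encode_spectrum(sp3, f, normalize = FALSE)
  expect_equal(e3$intensities[1], 7)
})

test_that("spectral angle follows the contrast-angle formula", {
  s_a <- make_encoded(c(1, 0, 0, 0))
  s_b <- make_encoded(c(0, 1, 0, 0))
  expect_equal(spectral_angle(s_a, s_a), 1.0)
  expect_equal(spectral_angle(s_a, s_b), 0.0)
  # dot product cos(pi/4) -> lambda = 0.5
  s_c <- make_encoded(c(cos(pi / 4), sin(pi / 4), 0, 0))
  expect_equal(spectral_angle(s_a, s_c), 0.5, tolerance = 1e-12)
  expect_equal(spectral_angle(s_a, s_c), spectral_angle(s_c, s_a))
  expect_error(spectral_angle(s_a, make_encoded(c(1, 0))), "layout")
  expect_error(spectral_angle(make_encoded(c(0, 0, 0, 0)),
                              make_encoded(c(0, 0, 0, 0))), "all-zero")
})

test_that("lambda decreases monotonically along a shared-signal ramp", {
  set.seed(71)
  base <- rlnorm(14, 10, 0.5)
  noise_a <- rlnorm(14, 10, 0.5)
  noise_b <- rlnorm(14, 10, 0.5)
  mix <- seq(0, 1, by = 0.1)
  lambdas <- vapply(mix, function(w) {
    spectral_angle(make_encoded((1 - w) * base + w * noise_a),
                   make_encoded((1 - w) * base + w * noise_b))
  }, numeric(1))
  expect_equal(lambdas[1], 1, tolerance = 1e-12)
  expect_true(all(diff(lambdas) < 0.05))
  expect_lt(lambdas[length(lambdas)], lambdas[1])
})

test_that("native and labeled encodings agree for noise-free pairs", {
  for (pep in c("SIINFEKL", "AGAGAGAGK", "LLDVPTAAV")) {
    pr <- generate_spectrum_pair(pep, noise = NULL, seed = 72)
    fn <- theoretical_fragments(pep)
    fl <- theoretical_fragments(pep, 6, nchar(pep))
    en <- encode_spectrum(pr$native, fn)
    el <- encode_spectrum(pr$labeled, fl)
    expect_equal(en$intensities, el$intensities, tolerance = 1e-12)
    expect_equal(spectral_angle(en, el), 1.0, tolerance = 1e-12)
  }
})

test_that("null distribution is seeded, cross-peptide, and separates
           matched pairs", {
  set.seed(73)
  peps <- random_peptides(12, 9:11)
  spectra <- unlist(lapply(seq_along(peps), function(i) {
    pr <- generate_spectrum_pair(peps[i], seed = 100 + i)
    list(pr$native, pr$labeled)
  }), recursive = FALSE)
  null1 <- null_distribution(spectra, n_pairs = 200, seed = 7)
  null2 <- null_distribution(spectra, n_pairs = 200, seed = 7)
  expect_identical(null1$lambdas, null2$lambdas)
  expect_true(all(null1$lambdas >= 0 & null1$lambdas <= 1))
  # matched pairs score far above the null
  pairs <- lapply(seq_along(peps), function(i) {
    generate_spectrum_pair(peps[i], seed = 100 + i)
  })
  val <- validate_pairs(pairs, null = null1)
  expect_gt(median(val$lambda), null1$quantile(0.99))
  expect_true(all(val$null_percentile >= 0.9))
  # a pool of one peptide has no valid cross pairs
  mono_pool <- list(spectra[[1]], spectra[[2]])
  expect_error(null_distribution(mono_pool), "distinct")
})

test_that("RT evaluation reports interval width and coverage", {
  pred <- 1:10
  ev <- evaluate_rt(pred, 2 * pred + 3)
  expect_equal(ev$frac, 1.0)
  expect_true(ev$degenerate)
  expect_equal(ev$slope, 2)
  expect_error(evaluate_rt(1:2, 1:2), "at least 3")
  expect_error(evaluate_rt(rep(1, 5), 1:5), "zero variance")
  # 99% interval covers about 99% of noisy points
  set.seed(74)
  pred <- runif(500, 10, 60)
  meas <- 1.05 * pred + 2 + rnorm(500, 0, 1.5)
  ev2 <- evaluate_rt(pred, meas)
  expect_gt(ev2$frac, 0.96)
  expect_gt(ev2$pi, 0)
  expect_gt(ev2$r_squared, 0.9)
})
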