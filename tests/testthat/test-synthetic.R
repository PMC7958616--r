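test_that("the logistic population model interpolates its two regimes", {
  preset <- sugar_presets()$trehalose
  # far below the switch the protein-dominated vector is returned
  lo <- population_model(preset$switch_sp / 2^10, preset)
  expect_equal(unname(lo), unname(preset$p_low), tolerance = 1e-3)
  # steeper presets get there faster; at steepness >= 4 the gap is < 1e-6...
  lo_steep <- population_model(110 / 2^10, sugar_presets()$sucrose)
  expect_equal(unname(lo_steep), unname(sugar_presets()$sucrose$p_low),
               tolerance = 1e-6)
  # at the switch point the blend is the renormalized midpoint
  mid <- population_model(preset$switch_sp, preset)
  want <- (preset$p_low + preset$p_high) / 2
  expect_equal(unname(mid), unname(want / sum(want)), tolerance = 1e-12)
  # protein-free sentinel: sugar-dominated populations with W0a absent
  pf <- population_model(Inf, preset)
  expect_equal(pf[["W0a"]], 0)
  expect_equal(sum(pf), 1, tolerance = 1e-12)
})

test_that("smooth presets change more gradually across the switch", {
  smooth <- sugar_presets()$trehalose
  abrupt <- sugar_presets()$sucrose
  step <- function(preset) {
    sum(abs(population_model(160, preset) - population_model(80, preset)))
  }
  rel_step <- function(preset) {
    total <- sum(abs(preset$p_high / sum(preset$p_high) -
                       preset$p_low / sum(preset$p_low)))
    step(preset) / total
  }
  expect_lt(rel_step(smooth), rel_step(abrupt))
})

test_that("spectrum generation is seed-reproducible and leaves the RNG alone", {
  truth <- synthetic_truth(seven_class_populations(), noise_sd = 0.003,
                           seed = 11)
  set.seed(123)
  before <- .Random.seed
  s1 <- generate_spectrum(truth)
  expect_identical(.Random.seed, before)
  s2 <- generate_spectrum(truth)
  expect_identical(s1$absorbance, s2$absorbance)
  s3 <- generate_spectrum(truth, seed = 12)
  expect_false(identical(s1$absorbance, s3$absorbance))
})

test_that("a noiseless single-class truth round-trips through the fit", {
  truth <- synthetic_truth(c(W2a = 1), noise_sd = 0,
                           background = background_model(0, 2900, 300, 0))
  spec <- generate_spectrum(truth)
  norm <- normalize_area(spec, c(2000, 2500))
  d <- fit_fixed_set(norm, "W2a")
  expect_lt(abs(d$components$center - truth$centers[["W2a"]]), 1e-6)
  expect_lt(abs(d$components$fwhm - truth$fwhms[["W2a"]]), 1e-4)
  expect_equal(unname(d$populations), 1)
})

test_that("synthetic truths validate populations and centers", {
  expect_error(synthetic_truth(c(W2a = 0.6, W4 = 0.3)), "sum to 1")
  expect_error(synthetic_truth(c(W2a = 1), centers = c(W2a = 2130)),
               "outside")
  expect_error(synthetic_truth(stats::setNames(c(0.5, 0.5), c("A", "B"))),
               "named by sub-band")
})

test_that("Dirichlet replicate jitter stays on the simplex, keeping zeros", {
  p <- c(W0a = 0, W0b = 0.2, W1 = 0.1, W2a = 0.4, W2b = 0, W3 = 0.2,
         W4 = 0.1)
  set.seed(4)
  for (i in 1:25) {
    q <- wabdecomp:::dirichlet_jitter(p, 400)
    expect_equal(sum(q), 1, tolerance = 1e-12)
    expect_true(all(q >= 0))
    expect_equal(unname(q[c("W0a", "W2b")]), c(0, 0))
  }
  expect_identical(wabdecomp:::dirichlet_jitter(p, Inf), p)
})

test_that("jitter-free studies reproduce the population model exactly", {
  st <- generate_study(sugar_presets()["trehalose"],
                       design = c(20, 160), replicates = 3, seed = 7,
                       jitter_conc = Inf, center_jitter_sd = 0,
                       noise_sd = 0)
  for (sp in c(20, 160)) {
    want <- population_model(sp, sugar_presets()$trehalose)
    rows <- st$truth[st$truth$sp_ratio == sp, ]
    got <- tapply(rows$population, rows$class, mean)[names(want)]
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
    expect_true(all(tapply(rows$population, rows$class, stats::sd) == 0))
  }
})

test_that("study generation is deterministic with substream independence", {
  st1 <- generate_study(sugar_presets()["sucrose"], design = c(40, 320),
                        replicates = 2, seed = 3)
  st2 <- generate_study(sugar_presets()["sucrose"], design = c(40, 320),
                        replicates = 2, seed = 3)
  expect_identical(st1, st2)

  # a different master seed changes the data but not the manifest
  st3 <- generate_study(sugar_presets()["sucrose"], design = c(40, 320),
                        replicates = 2, seed = 4)
  expect_identical(st3$manifest, st1$manifest)
  expect_false(identical(st3$spectra[[1]]$absorbance,
                         st1$spectra[[1]]$absorbance))

  # adding a sugar leaves the draws of the existing one untouched
  st4 <- generate_study(sugar_presets()[c("sucrose", "maltose")],
                        design = c(40, 320), replicates = 2, seed = 3)
  key <- names(st1$spectra)[1]
  expect_identical(st4$spectra[[key]]$absorbance,
                   st1$spectra[[key]]$absorbance)
})

test_that("the full pipeline returns planted populations for clean truths", {
  # well-separated active classes, default background, no noise
  pops <- c(W0b = 0.15, W1 = 0.20, W2a = 0.30, W3 = 0.20, W4 = 0.15)
  centers <- c(W0b = 2016, W1 = 2056, W2a = 2103, W3 = 2180, W4 = 2250)
  truth <- synthetic_truth(pops, centers = centers, noise_sd = 0)
  d <- process_spectrum(generate_spectrum(truth))
  got <- full_populations(d)
  want <- stats::setNames(numeric(7), subband_classes()$name)
  want[names(pops)] <- pops
  expect_true(all(abs(got - want) < 1e-3))
})

test_that("replicate jitter averages out across many seeds", {
  preset <- sugar_presets()$trehalose
  want <- population_model(80, preset)
  set.seed(1)
  draws <- replicate(200, {
    as.numeric(wabdecomp:::dirichlet_jitter(want, 400))
  })
  expect_true(all(abs(rowMeans(draws) - want) < 0.02))
})
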