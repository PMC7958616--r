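test_that("a single planted component is recovered identically", {
  spec <- normalized_gaussians(2100, 60, 1)
  d <- fit_fixed_set(spec, "W2a")
  expect_lt(abs(d$components$center - 2100), 1e-6)
  expect_equal(unname(d$populations), 1)
})

test_that("populations reproduce planted analytic area ratios", {
  # equal widths, amplitude ratio 2:1 -> populations 2/3 and 1/3
  spec <- normalized_gaussians(c(2100, 2250), c(60, 60), c(2, 1))
  d <- fit_fixed_set(spec, c("W2a", "W4"))
  expect_equal(unname(d$populations), c(2 / 3, 1 / 3), tolerance = 1e-6)

  # seven equal-area components at the window midpoints
  cls <- subband_classes()
  mids <- (cls$lo + cls$hi) / 2
  spec7 <- normalized_gaussians(mids, rep(50, 7), rep(1, 7))
  d7 <- fit_fixed_set(spec7, cls$name)
  expect_true(all(abs(d7$populations - 1 / 7) < 1e-4))
})

test_that("noiseless well-separated truths are recovered to machine level", {
  cases <- list(
    list(classes = c("W0b", "W1", "W2a", "W3", "W4"),
         centers = c(2018, 2058, 2098, 2182, 2248),
         fwhms = c(48, 62, 75, 66, 55),
         pops = c(0.10, 0.15, 0.35, 0.22, 0.18)),
    list(classes = c("W1", "W2a", "W3", "W4"),
         centers = c(2050, 2110, 2175, 2265),
         fwhms = c(55, 85, 72, 58),
         pops = c(0.20, 0.40, 0.25, 0.15)),
    list(classes = c("W2a", "W2b", "W4"), # adjacent pair, 40 cm-1 apart
         centers = c(2100, 2140, 2245),
         fwhms = c(70, 75, 60),
         pops = c(0.45, 0.30, 0.25))
  )
  for (cs in cases) {
    spec <- normalized_gaussians(cs$centers, cs$fwhms,
                                 amps_for_areas(cs$pops, cs$fwhms))
    d <- fit_fixed_set(spec, cs$classes)
    expect_true(all(abs(d$components$center - cs$centers) < 0.1))
    expect_true(all(abs(unname(d$populations) - cs$pops) < 1e-4))
  }
})

test_that("populations always sum to one", {
  pops7 <- seven_class_populations()
  specs <- list(
    normalized_gaussians(2100, 60, 1),
    normalized_gaussians(c(2030, 2190), c(50, 70), c(1, 2)),
    generate_spectrum(synthetic_truth(pops7, noise_sd = 0.003, seed = 42))
  )
  classes <- list("W2a", c("W0b", "W3"), subband_classes()$name)
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (max(s$wavenumbers) > 2500) {
      s <- normalize_area(subtract_background(s, fit_background(s)),
                          c(2000, 2500))
    }
    d <- fit_fixed_set(s, classes[[i]])
    expect_equal(sum(d$populations), 1, tolerance = 1e-9)
  }
})

test_that("adding a class to a warm-started fit never increases the RSS", {
  pops <- five_mandatory_populations()
  base_spec <- generate_spectrum(synthetic_truth(pops, noise_sd = 0.003,
                                                 seed = 9))
  norm <- normalize_area(subtract_background(base_spec,
                                             fit_background(base_spec)),
                         c(2000, 2500))
  small <- fit_fixed_set(norm, mandatory_classes())
  for (extra in list("W0a", "W2b", c("W0a", "W2b"))) {
    big <- fit_fixed_set(norm, c(mandatory_classes(), extra),
                         start = small$components)
    expect_lte(big$rss, small$rss + 1e-12)
  }
})

test_that("identical inputs and config give bit-identical decompositions", {
  spec <- generate_spectrum(synthetic_truth(seven_class_populations(),
                                            noise_sd = 0.003, seed = 5))
  norm <- normalize_area(subtract_background(spec, fit_background(spec)),
                         c(2000, 2500))
  d1 <- select_minimal_model(norm)
  d2 <- select_minimal_model(norm)
  expect_identical(d1$components, d2$components)
  expect_identical(d1$rss, d2$rss)
  expect_identical(d1$bic, d2$bic)
})

test_that("minimal-model selection keeps five and finds seven components", {
  for (s in 1:3) {
    d5 <- process_spectrum(generate_spectrum(
      synthetic_truth(five_mandatory_populations(), noise_sd = 0.003,
                      seed = s)))
    expect_equal(nrow(d5$components), 5L)
    d7 <- process_spectrum(generate_spectrum(
      synthetic_truth(seven_class_populations(), noise_sd = 0.003,
                      seed = 100 + s)))
    expect_equal(nrow(d7$components), 7L)
  }
})

test_that("fit preconditions are enforced", {
  short <- wab_spectrum(seq(2050, 2300), rep(0.01, 251))
  expect_error(fit_fixed_set(short, c("W0b", "W4")), "does not cover")
  spec <- normalized_gaussians(2100, 60, 1)
  expect_error(fit_fixed_set(spec, character(0)), "non-empty")
  expect_error(fit_fixed_set(spec, c("W2a", "W2a")), "duplicated")
  expect_error(fit_fixed_set(spec, "W9"), "unknown")
  # an empty band cannot be normalized upstream
  zero <- wab_spectrum(wab_grid(2000, 2500), rep(0, 501))
  expect_error(normalize_area(zero, c(2000, 2500)), "non-positive")
})

test_that("replicate aggregation averages populations and centers correctly", {
  mk <- function(pops, id = "s") {
    fwhms <- rep(60, length(pops))
    spec <- normalized_gaussians(
      c(W2a = 2100, W4 = 2250, W2b = 2140)[names(pops)],
      fwhms, amps_for_areas(pops, fwhms))
    spec$meta <- sample_meta(id, "sucrose", 160, 1L)
    fit_fixed_set(spec, names(pops))
  }
  d1 <- mk(c(W2a = 0.5, W4 = 0.5))
  d2 <- mk(c(W2a = 0.3, W4 = 0.7))
  summ <- as.data.frame(unclass(aggregate_replicates(list(d1, d2))))
  expect_equal(summ$mean_population[summ$class == "W2a"], 0.4,
               tolerance = 1e-6)
  expect_equal(summ$mean_population[summ$class == "W4"], 0.6,
               tolerance = 1e-6)
  expect_equal(summ$sd_population, rep(stats::sd(c(0.5, 0.3)), 2),
               tolerance = 1e-6)

  # single replicate: SDs are zero
  s1 <- as.data.frame(unclass(aggregate_replicates(list(d1))))
  expect_true(all(s1$sd_population == 0))
  expect_true(all(s1$sd_center == 0))
  expect_true(all(s1$n_replicates == 1L))

  # a replicate lacking W2b contributes population 0 but no center
  da <- mk(c(W2a = 0.4, W2b = 0.3, W4 = 0.3))
  db <- mk(c(W2a = 0.4, W2b = 0.2, W4 = 0.4))
  dc <- mk(c(W2a = 0.6, W4 = 0.4))
  s3 <- as.data.frame(unclass(aggregate_replicates(list(da, db, dc))))
  w2b <- s3[s3$class == "W2b", ]
  expect_equal(w2b$mean_population, mean(c(0.3, 0.2, 0)), tolerance = 1e-6)
  ctrs <- c(da$components$center[da$components$class == "W2b"],
            db$components$center[db$components$class == "W2b"])
  expect_equal(w2b$mean_center, mean(ctrs), tolerance = 1e-9)

  # mixed samples are a usage error
  dz <- mk(c(W2a = 0.5, W4 = 0.5), id = "other")
  expect_error(aggregate_replicates(list(d1, dz)), "mixed sample_ids")
})

test_that("decomposition JSON serialization carries the fit", {
  spec <- normalized_gaussians(c(2100, 2250), c(60, 60), c(2, 1))
  spec$meta <- sample_meta("js", "lactose", 40, 1L)
  d <- fit_fixed_set(spec, c("W2a", "W4"))
  path <- withr::local_tempfile(fileext = ".json")
  decomposition_json(d, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$sample_id, "js")
  expect_equal(nrow(back$components), 2L)
  expect_equal(back$populations$W2a, 2 / 3, tolerance = 1e-6)
  expect_equal(back$rss, d$rss, tolerance = 1e-12)
})
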