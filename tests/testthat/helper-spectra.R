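# shared fixtures: all synthetic, built in code

wab_grid <- function(lo = 2000, hi = 2600) seq(lo, hi, by = 1)

# raw (unnormalized) spectrum from explicit gaussian components
gaussian_spectrum <- function(centers, fwhms, amplitudes,
                              grid = wab_grid(2000, 2500),
                              meta = sample_meta()) {
  y <- numeric(length(grid))
  for (i in seq_along(centers)) {
    sigma <- fwhms[i] / (2 * sqrt(2 * log(2)))
    y <- y + amplitudes[i] * exp(-((grid - centers[i])^2) / (2 * sigma^2))
  }
  wab_spectrum(grid, y, meta)
}

# normalized single/multi-gaussian WAB spectrum over (2000, 2500)
normalized_gaussians <- function(centers, fwhms, amplitudes,
                                 grid = wab_grid(2000, 2500)) {
  normalize_area(gaussian_spectrum(centers, fwhms, amplitudes, grid),
                 c(2000, 2500))
}

gauss_area <- function(fwhm, amplitude) {
  amplitude * (fwhm / (2 * sqrt(2 * log(2)))) * sqrt(2 * pi)
}

# amplitudes realizing target analytic areas
amps_for_areas <- function(areas, fwhms) areas / gauss_area(fwhms, 1)

# planted truths used by several files
seven_class_populations <- function() {
  stats::setNames(c(0.07, 0.08, 0.10, 0.25, 0.15, 0.20, 0.15),
                  subband_classes()$name)
}

five_mandatory_populations <- function() {
  stats::setNames(c(0.12, 0.13, 0.35, 0.22, 0.18), mandatory_classes())
}

# full decomposition populations as a named length-7 vector (absent = 0)
full_populations <- function(decomp) {
  p <- stats::setNames(numeric(7), subband_classes()$name)
  p[names(decomp$populations)] <- decomp$populations
  p
}
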