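#' Background model: constant plus Gaussian tail
#'
#' The WAB sits on a background formed by a constant offset plus the
#' low-frequency tail of the very strong CH-stretching bands (2800-3000 cm-1).
#' That tail is modeled as a single Gaussian centered on the CH-stretch side
#' (>= 2700 cm-1); only its wing enters the WAB range.
#'
#' @param offset Constant absorbance offset.
#' @param tail_center Gaussian center in cm-1 (>= 2700).
#' @param tail_fwhm Full width at half maximum in cm-1 (> 0).
#' @param tail_amplitude Peak amplitude (>= 0).
#' @return A list of class `"wab_background"`.
#' @export
background_model <- function(offset, tail_center, tail_fwhm, tail_amplitude) {
  stopifnot(is.numeric(offset), is.numeric(tail_center),
            is.numeric(tail_fwhm), is.numeric(tail_amplitude))
  if (tail_fwhm <= 0) stop("tail_fwhm must be > 0", call. = FALSE)
  if (tail_amplitude < 0) stop("tail_amplitude must be >= 0", call. = FALSE)
  if (tail_center < 2700) {
    stop("tail_center must be >= 2700 cm-1 (CH-stretch side)", call. = FALSE)
  }
  structure(list(offset = offset, tail_center = tail_center,
                 tail_fwhm = tail_fwhm, tail_amplitude = tail_amplitude),
            class = "wab_background")
}

#' Evaluate a background model
#' @param bg A [background_model()].
#' @param x Wavenumbers (cm-1).
#' @return Absorbance values of the model at `x`.
#' @export
eval_background <- function(bg, x) {
  stopifnot(inherits(bg, "wab_background"))
  bg$offset + gaussian_profile(x, bg$tail_center, bg$tail_fwhm,
                               bg$tail_amplitude)
}

#' Fit the constant + Gaussian-tail background
#'
#' Least-squares fit of [background_model()] to the spectrum over the anchor
#' region (high-wavenumber side of the WAB, where the CH-stretch wing
#' dominates and sub-band wings are negligible). Optionally the `n_edge`
#' lowest-wavenumber points of the WAB region can be added to the support;
#' this is off by default because the strongly-destructured sub-bands (W0a,
#' W0b) sit directly at that edge and bias the fitted offset whenever they
#' are populated. The tail center is box-constrained to
#' `tail_center_bounds`.
#'
#' @param spectrum A [wab_spectrum()] spanning both regions.
#' @param wab_region Numeric `c(lo, hi)` of the WAB window (default
#'   `c(2000, 2500)` cm-1).
#' @param anchor_region Numeric `c(lo, hi)` on the high-wavenumber side
#'   (default `c(2400, 2600)` cm-1).
#' @param tail_center_bounds Allowed tail-center interval (default
#'   `c(2700, 3100)` cm-1).
#' @param n_edge Number of low-edge WAB points added to the fit support
#'   (default 0).
#' @param max_iterations Optimizer iteration cap.
#' @return A fitted [background_model()] with attribute `"rss"`.
#' @export
fit_background <- function(spectrum, wab_region = c(2000, 2500),
                           anchor_region = c(2400, 2600),
                           tail_center_bounds = c(2700, 3100),
                           n_edge = 0L, max_iterations = 500L) {
  stopifnot(inherits(spectrum, "wab_spectrum"))
  check_region(wab_region)
  check_region(anchor_region)
  if (anchor_region[1] < wab_region[1]) {
    stop("anchor_region must lie on the high-wavenumber side of wab_region",
         call. = FALSE)
  }
  w <- spectrum$wavenumbers
  rng <- range(w)
  if (rng[1] > wab_region[1] || rng[2] < anchor_region[2]) {
    stop(sprintf(
      "spectrum span [%g, %g] does not cover wab_region + anchor_region",
      rng[1], rng[2]), call. = FALSE)
  }
  in_anchor <- w >= anchor_region[1] & w <= anchor_region[2]
  in_wab <- which(w >= wab_region[1] & w <= wab_region[2])
  edge <- utils::head(in_wab, n_edge)
  sel <- sort(unique(c(which(in_anchor), edge)))
  x <- w[sel]
  y <- spectrum$absorbance[sel]

  if (max(y) - min(y) < .Machine$double.eps * 100 * max(1, abs(y[1]))) {
    # flat spectrum: degenerate tail
    return(structure(background_model(y[[1]], mean(tail_center_bounds),
                                      140, 0),
                     rss = 0))
  }

  c0 <- 2900
  c0 <- min(max(c0, tail_center_bounds[1]), tail_center_bounds[2])
  f0 <- 200
  off0 <- min(y)
  top <- mean(utils::tail(y[order(x)], 5L))
  wing0 <- gaussian_profile(max(x), c0, f0, 1)
  a0 <- max((top - off0) / max(wing0, 1e-12), 0)
  a0 <- min(a0, (max(y) - min(y)) * 1e6)

  par0 <- c(offset = off0, center = c0, fwhm = f0, amplitude = a0)
  lower <- c(-Inf, tail_center_bounds[1], 10, 0)
  upper <- c(Inf, tail_center_bounds[2], 2000, Inf)
  resid_fn <- function(p) {
    y - (p[1] + gaussian_profile(x, p[2], p[3], p[4]))
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = min(1024L, max_iterations),
      maxfev = 20000L, ftol = 1e-13, ptol = 1e-12, gtol = 0))
  if (!fit$info %in% 1:4) {
    stop(sprintf(
      "background fit did not converge (info=%d, %s; rss=%.3g after %d iterations)",
      fit$info, fit$message, fit$deviance, fit$niter), call. = FALSE)
  }
  p <- fit$par
  structure(background_model(p[[1]], p[[2]], p[[3]], p[[4]]),
            rss = fit$deviance)
}

#' Subtract a background model from a spectrum
#'
#' Pointwise subtraction of the evaluated model; negative values are kept
#' (not clipped). Metadata is preserved.
#'
#' @param spectrum A [wab_spectrum()].
#' @param bg A [background_model()].
#' @return The background-subtracted [wab_spectrum()].
#' @export
subtract_background <- function(spectrum, bg) {
  stopifnot(inherits(spectrum, "wab_spectrum"))
  wab_spectrum(spectrum$wavenumbers,
               spectrum$absorbance - eval_background(bg, spectrum$wavenumbers),
               spectrum$meta)
}

#' Normalize a spectrum to unit area over a region
#'
#' Divides the absorbance by the trapezoidal integral over `region`, so the
#' study object becomes the relative fraction of sub-bands rather than raw
#' intensity. Signed area is used; a non-positive area is a data error
#' (empty or negative band).
#'
#' @param spectrum A [wab_spectrum()].
#' @param region Numeric `c(lo, hi)` integration window (cm-1).
#' @return The normalized [wab_spectrum()].
#' @export
normalize_area <- function(spectrum, region = c(2000, 2500)) {
  a <- region_area(spectrum, region)
  if (!is.finite(a) || a <= 0) {
    stop(sprintf("non-positive area (%.3g) over [%g, %g]: cannot normalize",
                 a, region[1], region[2]), call. = FALSE)
  }
  wab_spectrum(spectrum$wavenumbers, spectrum$absorbance / a, spectrum$meta)
}

#' Baseline-corrected band area
#'
#' Trapezoidal integral over `region` after subtracting the straight line
#' through the spectrum values at the two region endpoints. Used e.g. to
#' monitor the water combination band near 5200 cm-1 during drying.
#'
#' @param spectrum A [wab_spectrum()] spanning `region`.
#' @param region Numeric `c(lo, hi)` (cm-1).
#' @return Area in absorbance * cm-1.
#' @export
band_area <- function(spectrum, region) {
  stopifnot(inherits(spectrum, "wab_spectrum"))
  check_region(region)
  rng <- range(spectrum$wavenumbers)
  if (region[1] < rng[1] || region[2] > rng[2]) {
    stop(sprintf("region [%g, %g] outside spectrum span [%g, %g]",
                 region[1], region[2], rng[1], rng[2]), call. = FALSE)
  }
  sub <- resample_region(spectrum, region)
  y_end <- sub$y[c(1L, length(sub$y))]
  baseline <- stats::approx(range(sub$x), y_end, xout = sub$x)$y
  trapz(sub$x, sub$y - baseline)
}

#' Stabilization check for successive band-area scans
#'
#' Water-content monitoring acquires repeated scans until the monitored band
#' area stops drifting; the band is declared stable when the relative change
#' between successive scans drops below `tol`.
#'
#' @param area_prev,area_curr Band areas from successive scans.
#' @param tol Relative-change tolerance (default 0.005, i.e. 0.5%).
#' @return Logical.
#' @export
band_stabilized <- function(area_prev, area_curr, tol = 0.005) {
  stopifnot(is.numeric(area_prev), is.numeric(area_curr), tol > 0)
  if (area_prev == 0) return(area_curr == 0)
  abs(area_curr - area_prev) / abs(area_prev) < tol
}

## ---- internal geometry helpers ----

# Gaussian peak profile parameterized by center / FWHM / peak amplitude.
gaussian_profile <- function(x, center, fwhm, amplitude) {
  amplitude * exp(-4 * log(2) * ((x - center) / fwhm)^2)
}

# Analytic area of that profile: amplitude * sigma * sqrt(2*pi),
# sigma = fwhm / (2*sqrt(2*log(2))) (~fwhm/2.3548).
gaussian_area <- function(fwhm, amplitude) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  amplitude * sigma * sqrt(2 * pi)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

check_region <- function(region) {
  if (!(is.numeric(region) && length(region) == 2L && region[1] < region[2])) {
    stop("a region must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  invisible(region)
}

# points of the spectrum inside [lo, hi], with exact interpolated endpoints
# so areas over a region are well defined on any grid
resample_region <- function(spectrum, region) {
  w <- spectrum$wavenumbers
  a <- spectrum$absorbance
  keep <- w > region[1] & w < region[2]
  x <- c(region[1], w[keep], region[2])
  y <- stats::approx(w, a, xout = x, ties = "ordered")$y
  list(x = x, y = y)
}

region_area <- function(spectrum, region) {
  stopifnot(inherits(spectrum, "wab_spectrum"))
  check_region(region)
  rng <- range(spectrum$wavenumbers)
  if (region[1] < rng[1] || region[2] > rng[2]) {
    stop(sprintf("region [%g, %g] outside spectrum span [%g, %g]",
                 region[1], region[2], rng[1], rng[2]), call. = FALSE)
  }
  sub <- resample_region(spectrum, region)
  trapz(sub$x, sub$y)
}
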