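#' Fit configuration for the sub-band decomposition
#'
#' @param fwhm_bounds Allowed component FWHM interval in cm-1. The whole WAB
#'   is only ~300 cm-1 wide, so no sub-band may approach that scale; the
#'   lower bound excludes spike-fitting of noise.
#' @param selection_threshold Minimum BIC improvement required to admit an
#'   optional sub-band (strong-evidence convention).
#' @param max_iterations Optimizer iteration cap per candidate model.
#' @param tolerance Relative RSS-change convergence tolerance.
#' @param ridge_kappa Strength of the noise-adaptive shape regularization.
#'   Overlapping sub-bands make populations ill-determined exactly at the
#'   measurement-noise scale, so a mild Tikhonov penalty pulls centers
#'   toward the window midpoints and FWHMs toward the canonical class
#'   widths ([canonical_fwhm()]), weighted by `ridge_kappa` times the noise
#'   level estimated from an unpenalized pilot fit. The penalty therefore
#'   vanishes for noiseless data (recovery of well-separated components
#'   stays exact) and only stabilizes directions the data cannot resolve.
#'   Set to 0 to disable.
#' @param ridge_kappa_fwhm Strength of the width part of the penalty,
#'   applied to log(FWHM / canonical FWHM). Deliberately much stronger than
#'   the center part: peak positions are physical observables reported per
#'   sample, whereas widths are treated as class properties, and leaving
#'   them effectively free lets a five-band model absorb a genuine
#'   duplication by broadening, which defeats parsimony-based selection.
#'   Like `ridge_kappa` it is scaled by the estimated noise and vanishes
#'   for noiseless data.
#' @param seed Integer seed used only by the optional multistart
#'   perturbations.
#' @param multistart Number of additional randomized starts (0 = purely
#'   deterministic initialization).
#' @return A list of class `"wab_fit_config"`.
#' @export
fit_config <- function(fwhm_bounds = c(20, 200), selection_threshold = 10,
                       max_iterations = 2000L, tolerance = 1e-12,
                       ridge_kappa = 15, ridge_kappa_fwhm = 200,
                       seed = 1L, multistart = 0L) {
  stopifnot(length(fwhm_bounds) == 2L, all(fwhm_bounds > 0),
            fwhm_bounds[1] < fwhm_bounds[2],
            selection_threshold >= 0, max_iterations >= 1,
            tolerance > 0, ridge_kappa >= 0, ridge_kappa_fwhm >= 0,
            multistart >= 0)
  structure(list(fwhm_bounds = as.numeric(fwhm_bounds),
                 selection_threshold = selection_threshold,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, ridge_kappa = ridge_kappa,
                 ridge_kappa_fwhm = ridge_kappa_fwhm,
                 seed = as.integer(seed), multistart = as.integer(multistart)),
            class = "wab_fit_config")
}

#' Canonical per-class component widths
#'
#' Reference FWHM for each sub-band class (cm-1), used as the shape prior of
#' the regularized fit and as the generator's default component widths. The
#' values sit in the 50-90 cm-1 range so a full seven-component composite
#' approaches the ~300 cm-1 width of the whole band.
#'
#' @return Named numeric vector over the seven classes.
#' @export
canonical_fwhm <- function() {
  stats::setNames(c(50, 55, 60, 80, 80, 70, 60), subband_classes()$name)
}

#' Fit a fixed set of sub-bands to a normalized spectrum
#'
#' Bounded nonlinear least squares over (center, FWHM, amplitude) for each
#' requested class, initialized at the window midpoints and canonical class
#' widths with amplitudes read off the spectrum (rescaled to the band area).
#' Centers are box-constrained to the class windows
#' (half-open at the upper edge except W4, so the 2120 cm-1 boundary belongs
#' to W2a), amplitudes are non-negative, and FWHMs respect
#' `config$fwhm_bounds`. Fractional populations are the analytic component
#' areas divided by their sum. The fit is deterministic given
#' (spectrum, classes, config).
#'
#' @param spectrum A background-subtracted, area-normalized [wab_spectrum()]
#'   covering all requested class windows.
#' @param classes Character vector of class names (subset of
#'   `subband_classes()$name`).
#' @param config A [fit_config()].
#' @param start Optional warm start: a components data.frame from a previous
#'   (nested) decomposition; classes absent from it start at amplitude 0.
#' @param sigma Optional known noise level (same units as the absorbance).
#'   When supplied the internal pilot fit is skipped and the regularization
#'   weight is taken as `ridge_kappa * sigma`; [select_minimal_model()] uses
#'   this to estimate the noise once per spectrum and share it across all
#'   candidate models so their BICs are comparable.
#' @return A list of class `"wab_decomposition"` with elements `components`
#'   (data.frame: class, center, fwhm, amplitude, area, population),
#'   `populations` (named vector), `rss`, `n_points`, `bic`, `meta`.
#' @export
fit_fixed_set <- function(spectrum, classes, config = fit_config(),
                          start = NULL, sigma = NULL) {
  stopifnot(inherits(spectrum, "wab_spectrum"),
            inherits(config, "wab_fit_config"))
  taxonomy <- subband_classes()
  classes <- as.character(classes)
  if (length(classes) == 0L) stop("`classes` must be non-empty", call. = FALSE)
  if (!all(classes %in% taxonomy$name)) {
    stop("unknown sub-band class(es): ",
         paste(setdiff(classes, taxonomy$name), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(classes)) stop("duplicated class names", call. = FALSE)
  tax <- taxonomy[match(classes, taxonomy$name), ]
  rng <- range(spectrum$wavenumbers)
  if (rng[1] > min(tax$lo) || rng[2] < max(tax$hi)) {
    stop(sprintf("spectrum span [%g, %g] does not cover all class windows",
                 rng[1], rng[2]), call. = FALSE)
  }

  x <- spectrum$wavenumbers
  y <- spectrum$absorbance
  k <- nrow(tax)

  # upper center bound: half-open windows except W4 (closed)
  eps <- 1e-9
  c_hi <- ifelse(tax$name == "W4", tax$hi, tax$hi - eps)
  lower <- as.numeric(rbind(tax$lo, config$fwhm_bounds[1], 0))
  upper <- as.numeric(rbind(c_hi, config$fwhm_bounds[2], Inf))

  prior_ctr <- (tax$lo + tax$hi) / 2
  prior_fwhm <- unname(canonical_fwhm()[tax$name])
  prior_fwhm <- pmin(pmax(prior_fwhm, config$fwhm_bounds[1]),
                     config$fwhm_bounds[2])
  halfw <- (tax$hi - tax$lo) / 2

  default_start <- function() {
    amp <- pmax(stats::approx(x, y, xout = prior_ctr, ties = "ordered")$y, 0)
    # overlapping neighbors inflate the read-off heights; rescale so the
    # implied total analytic area matches the observed band area
    implied <- sum(gaussian_area(prior_fwhm, amp))
    observed <- trapz(x, pmax(y, 0))
    if (implied > 0 && observed > 0) amp <- amp * observed / implied
    as.numeric(rbind(prior_ctr, prior_fwhm, amp))
  }
  par0 <- if (is.null(start)) default_start() else {
    stopifnot(is.data.frame(start))
    p <- default_start()
    for (i in seq_len(k)) {
      j <- match(tax$name[i], start$class)
      if (!is.na(j)) {
        p[3 * i - 2] <- min(max(start$center[j], tax$lo[i]), c_hi[i])
        p[3 * i - 1] <- min(max(start$fwhm[j], config$fwhm_bounds[1]),
                            config$fwhm_bounds[2])
        p[3 * i] <- max(start$amplitude[j], 0)
      } else {
        p[3 * i] <- 0 # new component enters at zero amplitude
      }
    }
    p
  }

  idx_c <- seq(1, 3 * k, by = 3)
  model_fn <- function(p) {
    out <- numeric(length(x))
    for (i in seq_len(k)) {
      out <- out + gaussian_profile(x, p[3 * i - 2], p[3 * i - 1], p[3 * i])
    }
    out
  }
  # analytic Jacobian of the residuals (data rows, then penalty rows)
  jac_fn <- function(p, lam_c, lam_f) {
    pen <- lam_c > 0 || lam_f > 0
    J <- matrix(0, length(x) + if (pen) 2L * k else 0L, 3 * k)
    for (i in seq_len(k)) {
      ctr <- p[3 * i - 2]; fw <- p[3 * i - 1]; amp <- p[3 * i]
      u <- (x - ctr) / fw
      e <- exp(-4 * log(2) * u^2)
      J[seq_along(x), 3 * i - 2] <- -amp * e * 8 * log(2) * u / fw
      J[seq_along(x), 3 * i - 1] <- -amp * e * 8 * log(2) * u^2 / fw
      J[seq_along(x), 3 * i] <- -e
    }
    if (pen) {
      for (i in seq_len(k)) {
        J[length(x) + i, 3 * i - 2] <- lam_c / halfw[i]
        J[length(x) + k + i, 3 * i - 1] <- lam_f / p[3 * i - 1]
      }
    }
    J
  }
  resid_fn <- function(p, lam_c, lam_f) {
    r <- y - model_fn(p)
    if (lam_c > 0 || lam_f > 0) {
      ctr <- p[idx_c]; fw <- p[idx_c + 1]
      r <- c(r, lam_c * (ctr - prior_ctr) / halfw,
             lam_f * log(fw / prior_fwhm))
    }
    r
  }
  run_fit <- function(p0, lam_c, lam_f, maxiter, lo = lower, hi = upper) {
    # nls.lm caps a single call at 1024 iterations; restart from the last
    # parameters (fresh damping) until the configured budget is spent
    left <- maxiter
    fit <- NULL
    repeat {
      fit <- suppressWarnings(minpack.lm::nls.lm(
        par = p0, lower = lo, upper = hi,
        fn = function(p) resid_fn(p, lam_c, lam_f),
        jac = function(p) jac_fn(p, lam_c, lam_f),
        control = minpack.lm::nls.lm.control(
          maxiter = min(1024L, left),
          maxfev = 100000L, ftol = config$tolerance, ptol = 1e-10, gtol = 0)))
      left <- left - fit$niter
      if (fit$info != -1 || left <= 0) break
      p0 <- fit$par
    }
    fit
  }
  # frozen-center descent: fit only (fwhm, amplitude) with centers held at
  # `ctr`; a reduced parameterization, since box-constraining a parameter to
  # a zero-width interval degrades the LM step
  run_fit_frozen <- function(p0, maxiter) {
    ctr <- p0[idx_c]
    q0 <- as.numeric(rbind(p0[idx_c + 1], p0[idx_c + 2]))
    lo2 <- as.numeric(rbind(rep(config$fwhm_bounds[1], k), rep(0, k)))
    hi2 <- as.numeric(rbind(rep(config$fwhm_bounds[2], k), rep(Inf, k)))
    expand <- function(q) as.numeric(rbind(ctr, q[seq(1, 2 * k, 2)],
                                           q[seq(2, 2 * k, 2)]))
    jac2 <- function(q) {
      J <- matrix(0, length(x), 2 * k)
      for (i in seq_len(k)) {
        fw <- q[2 * i - 1]; amp <- q[2 * i]
        u <- (x - ctr[i]) / fw
        e <- exp(-4 * log(2) * u^2)
        J[, 2 * i - 1] <- -amp * e * 8 * log(2) * u^2 / fw
        J[, 2 * i] <- -e
      }
      J
    }
    f <- suppressWarnings(minpack.lm::nls.lm(
      par = q0, lower = lo2, upper = hi2,
      fn = function(q) y - model_fn(expand(q)),
      jac = jac2,
      control = minpack.lm::nls.lm.control(
        maxiter = min(1024L, maxiter),
        maxfev = 100000L, ftol = config$tolerance, ptol = 1e-10, gtol = 0)))
    f$par_full <- expand(f$par)
    f
  }
  # unpenalized fit via two deterministic routes: a staged descent (centers
  # frozen at their start values first, then everything free) and a direct
  # descent; the overlapping-Gaussian surface is multimodal enough that
  # either alone can stall above the true floor
  best_unpenalized <- function(p0, maxiter) {
    fA <- run_fit_frozen(p0, maxiter)
    fB <- run_fit(fA$par_full, 0, 0, maxiter)
    fS <- run_fit(p0, 0, 0, maxiter)
    if (fB$deviance <= fS$deviance) fB else fS
  }
  noise_floor <- 1e-4 * sqrt(mean(y^2))
  data_rss <- function(p) sum((y - model_fn(p))^2)

  # pilot (unpenalized) fit estimates the noise floor; the final fit adds a
  # ridge toward the taxonomy shape, scaled to that noise level, so that
  # directions flatter than the noise are pinned instead of wandering
  if (config$ridge_kappa > 0 || config$ridge_kappa_fwhm > 0) {
    sigma_hat <- sigma
    pilot <- NULL
    if (is.null(sigma_hat)) {
      pilot <- best_unpenalized(par0, min(512L, config$max_iterations))
      sigma_hat <- sqrt(pilot$deviance / max(length(x) - 3 * k, 1))
    }
    # a residual below 0.01% of the signal rms is numerical, not
    # measurement noise: treat the data as noiseless and skip the penalty
    if (sigma_hat <= noise_floor) {
      lam_c <- lam_f <- 0
      fit <- if (is.null(pilot)) {
        best_unpenalized(par0, config$max_iterations)
      } else pilot
    } else {
      lam_c <- config$ridge_kappa * sigma_hat
      lam_f <- config$ridge_kappa_fwhm * sigma_hat
      fit <- run_fit(par0, lam_c, lam_f, config$max_iterations)
    }
  } else {
    sigma_hat <- NA_real_
    lam_c <- lam_f <- 0
    fit <- best_unpenalized(par0, config$max_iterations)
  }
  if (config$multistart > 0L) {
    rs <- restore_rng_on_exit()
    set.seed(config$seed)
    best_obj <- sum(resid_fn(fit$par, lam_c, lam_f)^2)
    for (m in seq_len(config$multistart)) {
      p0 <- default_start()
      span <- (c_hi - tax$lo)
      p0[idx_c] <- pmin(pmax(p0[idx_c] + stats::rnorm(k, 0, span / 4),
                             tax$lo), c_hi)
      p0[idx_c + 1] <- pmin(pmax(p0[idx_c + 1] * stats::runif(k, 0.5, 1.5),
                                 config$fwhm_bounds[1]), config$fwhm_bounds[2])
      cand <- run_fit(p0, lam_c, lam_f, config$max_iterations)
      obj <- sum(resid_fn(cand$par, lam_c, lam_f)^2)
      if (cand$info %in% 1:4 && obj < best_obj) {
        fit <- cand
        best_obj <- obj
      }
    }
  }
  if (!fit$info %in% 1:4 &&
      !(fit$info == -1 && isTRUE(config$.allow_maxiter))) {
    stop(sprintf(
      "sub-band fit did not converge (info=%d, %s; rss=%.3g, %d iterations, classes: %s)",
      fit$info, fit$message, fit$deviance, fit$niter,
      paste(classes, collapse = ",")), call. = FALSE)
  }

  p <- fit$par
  # warm-started nested fits must never lose ground on the data residual:
  # fall back to the start point if the penalty trade made it worse
  if (!is.null(start) && data_rss(p) > data_rss(par0) + 1e-12) {
    p <- par0
  }
  comp <- data.frame(
    class = tax$name,
    center = p[seq(1, 3 * k, by = 3)],
    fwhm = p[seq(2, 3 * k, by = 3)],
    amplitude = p[seq(3, 3 * k, by = 3)],
    stringsAsFactors = FALSE
  )
  comp <- comp[order(match(comp$class, taxonomy$name)), ]
  rownames(comp) <- NULL
  comp$area <- gaussian_area(comp$fwhm, comp$amplitude)
  total <- sum(comp$area)
  if (total <= 0) {
    stop("degenerate fit: total component area is zero", call. = FALSE)
  }
  comp$population <- comp$area / total
  n <- length(x)
  rss <- data_rss(p) # data residual only; the shape penalty is reported apart
  bic <- n * log(rss / n) + (3 * k) * log(n)
  populations <- stats::setNames(comp$population, comp$class)
  structure(list(components = comp, populations = populations,
                 rss = rss, n_points = n, bic = bic,
                 sigma_hat = sigma_hat,
                 ridge_lambda = c(center = lam_c, fwhm = lam_f),
                 niter = fit$niter, info = fit$info,
                 meta = spectrum$meta),
            class = "wab_decomposition")
}

#' @export
print.wab_decomposition <- function(x, ...) {
  cat(sprintf("<wab_decomposition> %s: %d components, rss=%.3g, bic=%.1f\n",
              x$meta$sample_id, nrow(x$components), x$rss, x$bic))
  print(x$components, digits = 4)
  invisible(x)
}

# Noise level of a normalized spectrum, from the unpenalized residual of the
# richest candidate model (all seven classes): sqrt(rss / (n - p)).
estimate_noise <- function(spectrum, classes, config) {
  cfg0 <- config
  cfg0$ridge_kappa <- 0
  cfg0$ridge_kappa_fwhm <- 0
  cfg0$max_iterations <- min(512L, config$max_iterations)
  cfg0$.allow_maxiter <- TRUE # the residual level, not convergence, matters
  d <- fit_fixed_set(spectrum, classes, cfg0)
  sqrt(d$rss / max(d$n_points - 3 * length(classes), 1))
}

#' Minimal-model selection over optional sub-bands
#'
#' The band profile is described with the lowest possible number of Gaussian
#' curves: the five mandatory sub-bands are always fitted, and the optional
#' duplications W0a and W2b are admitted — singly or together — only when
#' they improve the BIC by at least `config$selection_threshold`. All four
#' candidate class sets ({mandatory}, +W0a, +W2b, +both) are fitted, each
#' warm-started from the accepted smaller model, and candidates are examined
#' in order of increasing size so that ties resolve to the fewest components.
#'
#' @inheritParams fit_fixed_set
#' @return The accepted `"wab_decomposition"`, with attribute `"candidates"`
#'   holding the per-candidate RSS/BIC table.
#' @export
select_minimal_model <- function(spectrum, config = fit_config()) {
  base_classes <- mandatory_classes()
  all_classes <- subband_classes()$name
  # noise level estimated once, from the richest model's unpenalized
  # residual, and shared by every candidate fit
  sigma <- estimate_noise(spectrum, all_classes, config)
  base <- fit_fixed_set(spectrum, base_classes, config, sigma = sigma)
  candidates <- list(
    list(classes = c("W0a", base_classes)),
    list(classes = c(base_classes[1:4], "W2b", base_classes[5])),
    list(classes = c("W0a", base_classes[1:4], "W2b", base_classes[5]))
  )
  accepted <- base
  log <- data.frame(classes = paste(sort(base_classes), collapse = "+"),
                    k = length(base_classes), rss = base$rss, bic = base$bic,
                    accepted = TRUE, stringsAsFactors = FALSE)
  for (cand in candidates) {
    cl <- cand$classes
    # fit twice: warm-started from the accepted nested model (guarantees
    # RSS monotonicity) and from the default initialization; keep the better
    warm <- tryCatch(fit_fixed_set(spectrum, cl, config,
                                   start = accepted$components,
                                   sigma = sigma),
                     error = function(e) NULL)
    cold <- tryCatch(fit_fixed_set(spectrum, cl, config, sigma = sigma),
                     error = function(e) NULL)
    fit <- if (is.null(warm)) cold
           else if (!is.null(cold) && cold$rss < warm$rss) cold else warm
    if (is.null(fit)) next # candidate unfittable: cannot improve the model
    ok <- fit$bic <= accepted$bic - config$selection_threshold
    log <- rbind(log, data.frame(classes = paste(sort(cl), collapse = "+"),
                                 k = length(cl), rss = fit$rss, bic = fit$bic,
                                 accepted = ok, stringsAsFactors = FALSE))
    if (ok) accepted <- fit
  }
  attr(accepted, "candidates") <- log
  accepted
}

#' Aggregate replicate decompositions into per-class summaries
#'
#' Populations and peak frequencies of a sample are reported as means over
#' all replicate measurements with sample (n-1) standard deviations. A class
#' absent from a replicate's accepted model contributes population 0 to the
#' population statistics, while center statistics are taken only over the
#' replicates where the class is present. Instrumental-resolution
#' uncertainty is not added to the SDs.
#'
#' @param decomps List of `"wab_decomposition"` objects from replicates of
#'   one sample (same `sample_id`).
#' @return A list of class `"wab_replicate_summary"`: a per-class table with
#'   columns `sample_id`, `sugar`, `sp_ratio`, `class`, `n_replicates`,
#'   `mean_population`, `sd_population`, `mean_center`, `sd_center`.
#' @export
aggregate_replicates <- function(decomps) {
  if (inherits(decomps, "wab_decomposition")) decomps <- list(decomps)
  stopifnot(is.list(decomps), length(decomps) >= 1L)
  lapply(decomps, function(d) stopifnot(inherits(d, "wab_decomposition")))
  ids <- vapply(decomps, function(d) d$meta$sample_id, character(1))
  if (length(unique(ids)) != 1L) {
    stop("mixed sample_ids in aggregate_replicates(): ",
         paste(unique(ids), collapse = ", "), call. = FALSE)
  }
  n <- length(decomps)
  meta <- decomps[[1]]$meta
  all_classes <- subband_classes()$name
  present_any <- all_classes[all_classes %in%
                               unlist(lapply(decomps,
                                             function(d) d$components$class))]
  sd0 <- function(v) if (length(v) >= 2L) stats::sd(v) else 0
  rows <- lapply(present_any, function(cl) {
    pops <- vapply(decomps, function(d) {
      j <- match(cl, d$components$class)
      if (is.na(j)) 0 else d$components$population[j]
    }, numeric(1))
    ctrs <- unlist(lapply(decomps, function(d) {
      j <- match(cl, d$components$class)
      if (is.na(j)) NULL else d$components$center[j]
    }))
    data.frame(sample_id = meta$sample_id, sugar = meta$sugar,
               sp_ratio = meta$sp_ratio, class = cl, n_replicates = n,
               mean_population = mean(pops), sd_population = sd0(pops),
               mean_center = mean(ctrs), sd_center = sd0(ctrs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("wab_replicate_summary", class(out))
  out
}

#' Serialize a decomposition to JSON
#'
#' @param decomp A `"wab_decomposition"`.
#' @param path Optional file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
decomposition_json <- function(decomp, path = NULL) {
  stopifnot(inherits(decomp, "wab_decomposition"))
  obj <- list(
    sample_id = decomp$meta$sample_id,
    sugar = decomp$meta$sugar,
    sp_ratio = if (is.infinite(decomp$meta$sp_ratio)) "inf"
               else decomp$meta$sp_ratio,
    replicate = decomp$meta$replicate,
    components = decomp$components,
    populations = as.list(decomp$populations),
    rss = decomp$rss, n_points = decomp$n_points, bic = decomp$bic
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
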