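#' Sugar presets for the synthetic-study generator
#'
#' Each preset encodes, qualitatively, how a sugar's sub-band populations
#' move from a protein-dominated regime (`p_low`: low-frequency components
#' prevail) to a sugar-dominated regime (`p_high`: high-frequency components
#' prevail) as S/P grows. The changeover is a logistic in log2(S/P) centered
#' at `switch_sp` with slope `steepness`: trehalose is remarkably smooth
#' (low steepness), sucrose abrupt, maltose and lactose intermediate, with
#' lactose already carrying W2b weight at low S/P, and raffinose never
#' developing W2b. The switch is placed at S/P = 110, between the last
#' low-family point (80) and the first high-family point (160); the labeled
#' transition ratio of the resulting designs is therefore 80. The numbers
#' are this package's encodings of those qualitative shapes, not
#' measurements.
#'
#' @return Named list of `"wab_sugar_preset"` objects with fields `name`,
#'   `p_low`, `p_high`, `switch_sp`, `steepness`.
#' @export
sugar_presets <- function() {
  cls <- subband_classes()$name
  pv <- function(...) {
    v <- c(...)
    stopifnot(length(v) == 7L, all(v >= 0))
    stats::setNames(v / sum(v), cls)
  }
  #          W0a   W0b   W1    W2a   W2b   W3    W4
  p_low  <- pv(0.08, 0.12, 0.05, 0.45, 0.00, 0.18, 0.12)
  p_high <- pv(0.00, 0.05, 0.15, 0.20, 0.25, 0.20, 0.15)
  mk <- function(name, p_low, p_high, steepness, switch_sp = 110) {
    structure(list(name = name, p_low = p_low, p_high = p_high,
                   switch_sp = switch_sp, steepness = steepness),
              class = "wab_sugar_preset")
  }
  list(
    trehalose = mk("trehalose", p_low, p_high, steepness = 1.5),
    sucrose = mk("sucrose", p_low,
                 pv(0.00, 0.04, 0.16, 0.15, 0.35, 0.10, 0.20),
                 steepness = 6),
    maltose = mk("maltose",
                 pv(0.06, 0.12, 0.04, 0.38, 0.10, 0.18, 0.12),
                 p_high, steepness = 2.5),
    lactose = mk("lactose",
                 pv(0.07, 0.11, 0.04, 0.30, 0.18, 0.17, 0.13),
                 pv(0.00, 0.04, 0.14, 0.12, 0.30, 0.22, 0.18),
                 steepness = 3),
    raffinose = mk("raffinose",
                   pv(0.08, 0.12, 0.05, 0.45, 0.00, 0.18, 0.12),
                   pv(0.00, 0.06, 0.08, 0.40, 0.00, 0.26, 0.20),
                   steepness = 5)
  )
}

#' Composition-dependent sub-band populations
#'
#' Logistic blend between the preset's protein-dominated and
#' sugar-dominated population vectors:
#' p(sp) = p_low + sigma(steepness * (log2 sp - log2 switch_sp)) *
#' (p_high - p_low), renormalized to sum 1. The protein-free sentinel
#' (`Inf`) returns `p_high` with W0a forced to 0 (W0a is tied to the protein
#' surface).
#'
#' @param sp S/P ratio (> 0) or `Inf`.
#' @param preset A `"wab_sugar_preset"` from [sugar_presets()].
#' @return Named population vector over the seven classes, summing to 1.
#' @export
population_model <- function(sp, preset) {
  stopifnot(inherits(preset, "wab_sugar_preset"),
            is.numeric(sp), length(sp) == 1L, sp > 0)
  if (is.infinite(sp)) {
    p <- preset$p_high
    p[["W0a"]] <- 0
    return(p / sum(p))
  }
  sig <- stats::plogis(preset$steepness * (log2(sp) - log2(preset$switch_sp)))
  p <- preset$p_low + sig * (preset$p_high - preset$p_low)
  p / sum(p)
}

#' Planted ground truth for one synthetic spectrum
#'
#' @param populations Named population vector over (a subset of) the seven
#'   classes; non-negative, summing to 1. Zero entries mean the class is
#'   absent.
#' @param centers Named vector of component centers; defaults to the window
#'   midpoints. Must lie inside the class windows.
#' @param fwhms Named vector of component FWHMs (cm-1); defaults span
#'   50-90 cm-1 so the composite approaches the ~300 cm-1 full-band width.
#' @param background A [background_model()]. The default tail reaches into
#'   the anchor region the way real CH-stretch wings do.
#' @param noise_sd Measurement-noise SD as a fraction of the maximum
#'   noiseless signal (default 0.003).
#' @param total_area Total WAB area in absorbance*cm-1 before normalization.
#' @param seed Integer seed for the noise draw.
#' @return A list of class `"wab_truth"`.
#' @export
synthetic_truth <- function(populations,
                            centers = NULL, fwhms = NULL,
                            background = default_background(),
                            noise_sd = 0.003, total_area = 25,
                            seed = 1L) {
  cls <- subband_classes()
  if (is.null(names(populations)) ||
      !all(names(populations) %in% cls$name)) {
    stop("populations must be named by sub-band class", call. = FALSE)
  }
  if (any(populations < 0) || abs(sum(populations) - 1) > 1e-9) {
    stop("populations must be >= 0 and sum to 1", call. = FALSE)
  }
  mid <- stats::setNames((cls$lo + cls$hi) / 2, cls$name)
  defw <- canonical_fwhm()
  nm <- names(populations)
  ctr <- mid[nm]
  if (!is.null(centers)) ctr[names(centers)] <- centers
  fw <- defw[nm]
  if (!is.null(fwhms)) fw[names(fwhms)] <- fwhms
  win <- cls[match(nm, cls$name), ]
  active <- populations > 0
  bad <- active & (ctr < win$lo | ctr > win$hi)
  if (any(bad)) {
    stop("centers outside class windows: ", paste(nm[bad], collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(fw > 0), noise_sd >= 0, total_area > 0)
  structure(list(populations = populations, centers = ctr, fwhms = fw,
                 background = background, noise_sd = noise_sd,
                 total_area = total_area, seed = as.integer(seed)),
            class = "wab_truth")
}

#' Default synthetic background
#'
#' A small constant offset plus a broad CH-stretch tail whose wing is an
#' appreciable fraction of the signal at the high end of the anchor region,
#' so background fitting is genuinely exercised.
#' @return A [background_model()].
#' @export
default_background <- function() {
  background_model(offset = 0.02, tail_center = 2900, tail_fwhm = 300,
                   tail_amplitude = 1.0)
}

#' Generate a synthetic spectrum from planted truth
#'
#' Sum of class Gaussians with analytic areas proportional to the planted
#' populations (total area `truth$total_area`), plus the background model,
#' plus i.i.d. zero-mean Gaussian noise with SD `noise_sd` times the maximum
#' noiseless signal. Reproducible per seed; the global RNG state is left
#' untouched.
#'
#' @param truth A [synthetic_truth()].
#' @param grid Wavenumber grid; the default `seq(2000, 2600)` covers the WAB
#'   plus the background anchor region at 1 cm-1 resolution.
#' @param seed Seed for the noise draw (defaults to `truth$seed`).
#' @param meta Metadata to attach.
#' @return A [wab_spectrum()].
#' @export
generate_spectrum <- function(truth, grid = seq(2000, 2600, by = 1),
                              seed = truth$seed, meta = sample_meta()) {
  stopifnot(inherits(truth, "wab_truth"))
  signal <- eval_background(truth$background, grid)
  nm <- names(truth$populations)
  for (i in seq_along(nm)) {
    pop <- truth$populations[[i]]
    if (pop <= 0) next
    area <- pop * truth$total_area
    amp <- area / gaussian_area(truth$fwhms[[i]], 1)
    signal <- signal + gaussian_profile(grid, truth$centers[[i]],
                                        truth$fwhms[[i]], amp)
  }
  if (truth$noise_sd > 0) {
    restore <- restore_rng_on_exit()
    set.seed(seed)
    signal <- signal + stats::rnorm(length(grid),
                                    sd = truth$noise_sd * max(signal))
  }
  wab_spectrum(grid, signal, meta)
}

#' Generate a whole synthetic study with planted truth
#'
#' For each (sugar, S/P) cell of the design, draws `replicates` replicate
#' spectra: replicate populations jitter around [population_model()] via a
#' Dirichlet perturbation (concentration `jitter_conc`; larger = tighter),
#' centers jitter inside their windows (truncated normal, SD
#' `center_jitter_sd`), and each spectrum gets fresh measurement noise. All
#' randomness derives from the single `seed` through per-(sugar, S/P,
#' replicate) substreams, so adding a sugar does not change the draws of the
#' others, and the manifest is seed-independent.
#'
#' @param presets Named list from [sugar_presets()] (subset allowed).
#' @param design Numeric vector of S/P values (may include `Inf`).
#' @param replicates Replicates per sample (the study design uses 3-8).
#' @param seed Single integer master seed.
#' @param jitter_conc Dirichlet concentration (default 400, giving
#'   population SDs of a few percent); `Inf` disables population jitter.
#' @param center_jitter_sd SD of center jitter in cm-1 (0 disables).
#' @param noise_sd Measurement-noise fraction (see [synthetic_truth()]).
#' @param out_dir Optional directory; when given, spectra, `manifest.csv`
#'   and `truth.csv` are written there.
#' @return A list with `spectra` (named list of [wab_spectrum()]),
#'   `manifest` (data.frame), `truth` (data.frame of planted populations and
#'   centers per replicate and class).
#' @export
generate_study <- function(presets = sugar_presets(),
                           design = c(20, 40, 80, 160, 320, 640),
                           replicates = 4L, seed = 1L,
                           jitter_conc = 400, center_jitter_sd = 2,
                           noise_sd = 0.003, out_dir = NULL) {
  stopifnot(length(design) >= 1L, replicates >= 1L)
  spectra <- list()
  manifest <- list()
  truth_rows <- list()
  for (sugar in names(presets)) {
    preset <- presets[[sugar]]
    for (sp in design) {
      p0 <- population_model(sp, preset)
      sid <- sprintf("%s_sp%s", sugar, format(sp))
      for (r in seq_len(replicates)) {
        sseed <- substream_seed(seed, sugar, sp, r)
        restore <- restore_rng_on_exit()
        set.seed(sseed)
        p <- dirichlet_jitter(p0, jitter_conc)
        ctr <- jitter_centers(names(p0), center_jitter_sd)
        tr <- synthetic_truth(p, centers = ctr, noise_sd = noise_sd,
                              seed = sseed)
        meta <- sample_meta(sample_id = sid, sugar = sugar, sp_ratio = sp,
                            replicate = r)
        spec_seed <- substream_seed(seed, sugar, sp, r, "noise")
        spec <- generate_spectrum(tr, seed = spec_seed, meta = meta)
        key <- sprintf("%s_r%d", sid, r)
        spectra[[key]] <- spec
        manifest[[key]] <- data.frame(
          sample_id = sid, sugar = sugar, sp_ratio = sp, replicate = r,
          path = paste0(key, ".csv"), stringsAsFactors = FALSE)
        truth_rows[[key]] <- data.frame(
          sample_id = sid, sugar = sugar, sp_ratio = sp, replicate = r,
          class = names(p0), population = as.numeric(p),
          center = as.numeric(ctr[names(p0)]),
          fwhm = as.numeric(tr$fwhms[names(p0)]),
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(spectra)) {
      write_spectrum(spectra[[key]], file.path(out_dir, paste0(key, ".csv")))
    }
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(spectra = spectra, manifest = manifest, truth = truth)
}

## ---- randomness plumbing ----

# Deterministic substream seed in [1, 2^31 - 2]: polynomial rolling hash of
# the key components, so each (sugar, sp, replicate) gets an independent,
# stable stream.
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
               collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 17
  m <- 2147483647 # 2^31 - 1
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h + 1)
}

# Save the global RNG state and restore it when the calling frame exits.
restore_rng_on_exit <- function(envir = parent.frame()) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  expr <- if (had) {
    bquote(assign(".Random.seed", .(old), globalenv()))
  } else {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    })
  }
  do.call(on.exit, list(expr, TRUE), envir = envir)
  invisible(old)
}

# Dirichlet perturbation around p with concentration conc; zero entries stay
# exactly zero (gamma with shape 0), so the support of the planted model is
# preserved. conc = Inf returns p unchanged.
dirichlet_jitter <- function(p, conc) {
  if (is.infinite(conc)) return(p)
  stopifnot(conc > 0)
  g <- stats::setNames(numeric(length(p)), names(p))
  pos <- p > 0
  g[pos] <- stats::rgamma(sum(pos), shape = conc * p[pos])
  g / sum(g)
}

# Truncated-normal jitter of component centers around the window midpoints,
# clamped a small margin inside each window.
jitter_centers <- function(class_names, sd) {
  cls <- subband_classes()
  idx <- match(class_names, cls$name)
  mid <- (cls$lo[idx] + cls$hi[idx]) / 2
  if (sd <= 0) return(stats::setNames(mid, class_names))
  lo <- cls$lo[idx] + 0.5
  hi <- cls$hi[idx] - 0.5
  out <- mid + stats::rnorm(length(mid), 0, sd)
  stats::setNames(pmin(pmax(out, lo), hi), class_names)
}
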