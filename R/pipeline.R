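#' Pipeline configuration
#'
#' Bundles every tunable of the analysis in one validated object. Unknown
#' keys are rejected.
#'
#' @param wab_region WAB observation window, default `c(2000, 2500)` cm-1.
#' @param anchor_region Background anchor window, default `c(2400, 2600)`.
#' @param tail_center_bounds Allowed background tail center interval.
#' @param n_edge Low-edge WAB points added to the background fit support.
#' @param stabilization_tol Relative tolerance of [band_stabilized()].
#' @param fit A [fit_config()].
#' @param reliability_threshold Separation-score threshold of
#'   [cluster_families()].
#' @param rho_threshold Rank-correlation threshold of [population_trend()].
#' @param seed Master seed for anything stochastic downstream.
#' @return A list of class `"wab_config"`.
#' @export
wab_config <- function(wab_region = c(2000, 2500),
                       anchor_region = c(2400, 2600),
                       tail_center_bounds = c(2700, 3100),
                       n_edge = 0L, stabilization_tol = 0.005,
                       fit = fit_config(),
                       reliability_threshold = 2, rho_threshold = 0.7,
                       seed = 1L) {
  check_region(wab_region)
  check_region(anchor_region)
  check_region(tail_center_bounds)
  stopifnot(inherits(fit, "wab_fit_config"), n_edge >= 0,
            stabilization_tol > 0, reliability_threshold > 0,
            rho_threshold > 0, rho_threshold <= 1)
  structure(list(wab_region = wab_region, anchor_region = anchor_region,
                 tail_center_bounds = tail_center_bounds,
                 n_edge = as.integer(n_edge),
                 stabilization_tol = stabilization_tol, fit = fit,
                 reliability_threshold = reliability_threshold,
                 rho_threshold = rho_threshold, seed = as.integer(seed)),
            class = "wab_config")
}

#' Decompose one raw spectrum
#'
#' The per-spectrum pipeline: fit and subtract the constant + Gaussian-tail
#' background, area-normalize over the WAB region, and run minimal-model
#' sub-band selection.
#'
#' @param spectrum A raw [wab_spectrum()] covering the WAB and anchor
#'   regions.
#' @param config A [wab_config()].
#' @return A `"wab_decomposition"`.
#' @export
process_spectrum <- function(spectrum, config = wab_config()) {
  stopifnot(inherits(config, "wab_config"))
  bg <- fit_background(spectrum, wab_region = config$wab_region,
                       anchor_region = config$anchor_region,
                       tail_center_bounds = config$tail_center_bounds,
                       n_edge = config$n_edge)
  flat <- subtract_background(spectrum, bg)
  norm <- normalize_area(flat, config$wab_region)
  select_minimal_model(norm, config$fit)
}

#' Run the full batch pipeline over a manifest
#'
#' Reads every spectrum listed in the manifest, decomposes it, aggregates
#' replicates per sample, and (per sugar, when at least three finite-S/P
#' samples exist) computes the family split and per-class trends. Outputs:
#' per-spectrum decomposition JSONs, a per-(sample, class) summary table,
#' and a per-sugar trend report JSON. Deterministic for fixed inputs and
#' config.
#'
#' @param manifest A manifest data.frame or path to `manifest.csv`
#'   (see [read_manifest()]); relative spectrum paths resolve against the
#'   manifest's directory.
#' @param out_dir Output directory (created if needed).
#' @param config A [wab_config()].
#' @return Invisibly, a list with `decompositions`, `summaries` (data.frame),
#'   `trends`, `families`.
#' @export
run_pipeline <- function(manifest, out_dir, config = wab_config()) {
  base_dir <- "."
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "decompositions"), showWarnings = FALSE)

  decomps <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    path <- row$path
    if (!file.exists(path)) path <- file.path(base_dir, row$path)
    if (!file.exists(path)) {
      stop(sprintf("sample %s (replicate %d): spectrum file not found: %s",
                   row$sample_id, row$replicate, row$path), call. = FALSE)
    }
    meta <- sample_meta(row$sample_id, row$sugar, row$sp_ratio,
                        row$replicate)
    spec <- read_spectrum(path, meta = meta)
    d <- tryCatch(process_spectrum(spec, config), error = function(e) {
      stop(sprintf("sample %s (replicate %d): %s",
                   row$sample_id, row$replicate, conditionMessage(e)),
           call. = FALSE)
    })
    decomps[[i]] <- d
    decomposition_json(
      d, file.path(out_dir, "decompositions",
                   sprintf("%s_r%d.json", row$sample_id, row$replicate)))
  }

  by_sample <- split(decomps, manifest$sample_id)
  summaries <- lapply(by_sample, aggregate_replicates)
  summary_tab <- do.call(rbind, lapply(summaries, as.data.frame))
  rownames(summary_tab) <- NULL
  write_decomposition_table(unname(summaries),
                            file.path(out_dir, "summary.csv"))

  trends <- list()
  families <- list()
  for (sugar in unique(manifest$sugar)) {
    sub <- summary_tab[summary_tab$sugar == sugar &
                         is.finite(summary_tab$sp_ratio), ]
    sps <- sort(unique(sub$sp_ratio))
    if (length(sps) >= 3L) {
      profiles <- lapply(sps, function(sp) {
        idx <- which(manifest$sugar == sugar & manifest$sp_ratio == sp)
        mean_normalized_profile(decomps[idx], config)
      })
      names(profiles) <- sps
      families[[sugar]] <- cluster_families(
        profiles, reliability_threshold = config$reliability_threshold)
    }
    if (length(sps) >= 4L) trends[[sugar]] <- trend_report(summary_tab, sugar)
  }
  report <- list(
    families = lapply(families, function(f) {
      list(low_family = f$low_family, high_family = f$high_family,
           transition_sp = f$transition_sp,
           separation_score = f$separation_score, reliable = f$reliable)
    }),
    trends = trends
  )
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "trends.json"))
  invisible(list(decompositions = decomps, summaries = summary_tab,
                 trends = trends, families = families))
}

# mean normalized WAB profile of a sample, reconstructed on the WAB grid from
# the replicate decompositions' fitted components (decomposition-space mean,
# so the profile is noise-free and grid-consistent)
mean_normalized_profile <- function(decomps, config) {
  grid <- seq(config$wab_region[1], config$wab_region[2], by = 1)
  mats <- vapply(decomps, function(d) {
    y <- numeric(length(grid))
    for (j in seq_len(nrow(d$components))) {
      y <- y + gaussian_profile(grid, d$components$center[j],
                                d$components$fwhm[j],
                                d$components$amplitude[j])
    }
    y
  }, numeric(length(grid)))
  wab_spectrum(grid, rowMeans(mats), decomps[[1]]$meta)
}
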