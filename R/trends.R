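#' Two-family clustering of WAB profiles across S/P
#'
#' WAB profiles form two families as the sugar/protein ratio grows: a
#' low-S/P family dominated by low-frequency components and a high-S/P
#' family resembling protein-free samples. The split is located by ordering
#' the profiles by S/P, computing the L2 distance between each consecutive
#' pair of area-normalized profiles, and placing the transition at the S/P
#' immediately below the largest consecutive gap. The separation score
#' (largest gap over the mean of the other gaps) flags whether the split is
#' reliable.
#'
#' @param profiles Named list of [wab_spectrum()] objects on a common grid;
#'   names are finite S/P values.
#' @param reliability_threshold Minimum separation score for a reliable
#'   split (default 2).
#' @return A list of class `"wab_family_split"` with elements `low_family`,
#'   `high_family`, `transition_sp`, `separation_score`, `reliable`, `gaps`.
#' @export
cluster_families <- function(profiles, reliability_threshold = 2) {
  if (!is.list(profiles) || length(profiles) < 3L) {
    stop("need at least 3 profiles to split into families", call. = FALSE)
  }
  sp <- suppressWarnings(as.numeric(names(profiles)))
  if (anyNA(sp) || any(!is.finite(sp))) {
    stop("profile names must be finite S/P values", call. = FALSE)
  }
  ord <- order(sp)
  sp <- sp[ord]
  profiles <- profiles[ord]
  grids <- lapply(profiles, function(s) s$wavenumbers)
  if (!all(vapply(grids[-1], function(g) isTRUE(all.equal(g, grids[[1]])),
                  logical(1)))) {
    stop("profiles must share a common wavenumber grid", call. = FALSE)
  }
  # re-normalize internally so the split is invariant to common rescaling
  mats <- vapply(profiles, function(s) {
    a <- region_area(s, range(s$wavenumbers))
    if (a <= 0) stop("profile with non-positive area", call. = FALSE)
    s$absorbance / a
  }, numeric(length(grids[[1]])))
  gaps <- vapply(seq_len(ncol(mats) - 1L), function(i) {
    sqrt(sum((mats[, i + 1L] - mats[, i])^2))
  }, numeric(1))
  imax <- which.max(gaps)
  others <- gaps[-imax]
  score <- if (max(gaps) == 0) 1
           else if (mean(others) == 0) Inf
           else gaps[imax] / mean(others)
  structure(list(
    low_family = sp[seq_len(imax)],
    high_family = sp[seq(imax + 1L, length(sp))],
    transition_sp = sp[imax],
    separation_score = score,
    reliable = is.finite(score) && score >= reliability_threshold ||
      is.infinite(score),
    gaps = stats::setNames(gaps, paste(sp[-length(sp)], sp[-1], sep = "->"))
  ), class = "wab_family_split")
}

#' @export
print.wab_family_split <- function(x, ...) {
  cat(sprintf(
    "<wab_family_split> transition S/P = %g (score %.2f%s)\n  low:  {%s}\n  high: {%s}\n",
    x$transition_sp, x$separation_score,
    if (x$reliable) "" else ", unreliable",
    paste(x$low_family, collapse = ", "),
    paste(x$high_family, collapse = ", ")))
  invisible(x)
}

#' Monotonic trend of a sub-band population across S/P
#'
#' Spearman rank correlation of population against log2(S/P) (the design is
#' log-spaced in S/P). Direction is `"increasing"` for rho >= 0.7,
#' `"decreasing"` for rho <= -0.7, else `"flat"`; constant populations give
#' rho = 0.
#'
#' @param sp Numeric vector of finite S/P values (>= 4 points).
#' @param population Population fractions at each S/P.
#' @param rho_threshold Absolute correlation needed to call a direction.
#' @return A list with `direction`, `rank_correlation`.
#' @export
population_trend <- function(sp, population, rho_threshold = 0.7) {
  stopifnot(is.numeric(sp), is.numeric(population),
            length(sp) == length(population))
  if (length(sp) < 4L) stop("need at least 4 S/P points", call. = FALSE)
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("S/P values must be finite and positive", call. = FALSE)
  }
  rho <- if (stats::sd(population) == 0) 0 else
    suppressWarnings(stats::cor(log2(sp), population, method = "spearman"))
  direction <- if (rho >= rho_threshold) "increasing"
               else if (rho <= -rho_threshold) "decreasing"
               else "flat"
  list(direction = direction, rank_correlation = rho)
}

#' Red/blue classification of a sub-band peak shift across S/P
#'
#' Compares the peak frequency at the lowest and highest S/P. A shift is
#' declared only when the endpoint difference exceeds the combined standard
#' deviation sqrt(sd1^2 + sd2^2); otherwise the peak is taken as constant
#' within the errors. Red = frequency decreases with S/P, blue = increases.
#'
#' @param sp Numeric vector of S/P values (>= 2 points).
#' @param center Mean peak frequencies (cm-1) at each S/P.
#' @param sd Standard deviations of the peak frequencies; missing values are
#'   treated as 0 and flagged.
#' @return A list with `shift` (`"red"`, `"blue"`, `"none"`),
#'   `shift_magnitude` (cm-1), `combined_sd`, `sd_imputed`.
#' @export
peak_shift <- function(sp, center, sd = NULL) {
  stopifnot(is.numeric(sp), is.numeric(center),
            length(sp) == length(center))
  if (length(sp) < 2L) stop("need at least 2 S/P points", call. = FALSE)
  imputed <- FALSE
  if (is.null(sd)) {
    sd <- rep(0, length(sp))
    imputed <- TRUE
  } else {
    stopifnot(length(sd) == length(sp))
    if (anyNA(sd)) {
      sd[is.na(sd)] <- 0
      imputed <- TRUE
    }
  }
  if (imputed) {
    warning("missing peak-frequency SDs treated as 0", call. = FALSE)
  }
  ord <- order(sp)
  c1 <- center[ord][1L]
  c2 <- center[ord][length(sp)]
  s1 <- sd[ord][1L]
  s2 <- sd[ord][length(sp)]
  delta <- c2 - c1
  combined <- sqrt(s1^2 + s2^2)
  shift <- if (abs(delta) > combined) {
    if (delta < 0) "red" else "blue"
  } else "none"
  list(shift = shift, shift_magnitude = abs(delta),
       combined_sd = combined, sd_imputed = imputed)
}

#' Per-sugar trend report from a replicate-summary table
#'
#' Convenience wrapper applying [population_trend()] and [peak_shift()] to
#' every sub-band class of one sugar in a summary table (as produced by
#' [aggregate_replicates()] / [write_decomposition_table()]), using finite
#' S/P rows only.
#'
#' @param summary_table Data.frame with columns `sugar`, `sp_ratio`, `class`,
#'   `mean_population`, `mean_center`, `sd_center`.
#' @param sugar Sugar to report on.
#' @return A list keyed by class: each entry has `population_trend` and
#'   `peak_shift` results.
#' @export
trend_report <- function(summary_table, sugar) {
  df <- summary_table[summary_table$sugar == sugar &
                        is.finite(summary_table$sp_ratio), ]
  if (nrow(df) == 0L) stop("no finite-S/P rows for sugar ", sugar,
                           call. = FALSE)
  out <- list()
  for (cl in unique(df$class)) {
    sub <- df[df$class == cl, ]
    sub <- sub[order(sub$sp_ratio), ]
    pt <- if (nrow(sub) >= 4L) {
      population_trend(sub$sp_ratio, sub$mean_population)
    } else NULL
    ps <- if (nrow(sub) >= 2L) {
      suppressWarnings(peak_shift(sub$sp_ratio, sub$mean_center,
                                  sub$sd_center))
    } else NULL
    out[[cl]] <- list(population_trend = pt, peak_shift = ps)
  }
  out
}
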