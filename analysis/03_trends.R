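#!/usr/bin/env Rscript
# Cross-composition analysis of the decomposed studies: the two-family
# split of WAB profiles with its transition S/P, per-class population
# trends (Spearman rank against log2 S/P) and red/blue peak-shift calls.
# Reads results/pipeline/<sugar>/; writes results/trends_summary.csv.

library(wabdecomp)

out_root <- file.path("results", "pipeline")
sugars <- list.dirs(out_root, recursive = FALSE, full.names = FALSE)
if (length(sugars) == 0L) stop("run analysis/02_decompose.R first")

rows <- list()
for (sugar in sugars) {
  tab <- read_decomposition_table(file.path(out_root, sugar, "summary.csv"))
  report <- trend_report(tab, sugar)
  trend_json <- jsonlite::fromJSON(file.path(out_root, sugar, "trends.json"))
  fam <- trend_json$families[[sugar]]
  cat(sprintf("%s: transition S/P = %s (score %.2f%s)\n", sugar,
              fam$transition_sp, fam$separation_score,
              if (isTRUE(fam$reliable)) "" else ", unreliable"))
  for (cl in names(report)) {
    pt <- report[[cl]]$population_trend
    ps <- report[[cl]]$peak_shift
    rows[[paste(sugar, cl)]] <- data.frame(
      sugar = sugar, class = cl,
      transition_sp = fam$transition_sp,
      direction = if (is.null(pt)) NA else pt$direction,
      rank_correlation = if (is.null(pt)) NA else pt$rank_correlation,
      shift = if (is.null(ps)) NA else ps$shift,
      shift_magnitude = if (is.null(ps)) NA else ps$shift_magnitude)
    cat(sprintf("  %-3s population %-10s (rho % .2f)  peak %-4s (%.1f cm-1)\n",
                cl, rows[[paste(sugar, cl)]]$direction,
                rows[[paste(sugar, cl)]]$rank_correlation,
                rows[[paste(sugar, cl)]]$shift,
                rows[[paste(sugar, cl)]]$shift_magnitude))
  }
}
out <- do.call(rbind, rows)
rownames(out) <- NULL
utils::write.csv(out, file.path("results", "trends_summary.csv"),
                 row.names = FALSE)
cat("wrote results/trends_summary.csv\n")
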