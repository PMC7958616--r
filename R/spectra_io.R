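#' Sample metadata
#'
#' Metadata attached to every spectrum: sample identity, sugar, the
#' monosaccharide-units-per-protein molar ratio (S/P) and the replicate index.
#' Protein-free (binary sugar-water) samples carry `sp_ratio = Inf`.
#'
#' @param sample_id Character scalar identifying the sample (replicates of the
#'   same formulation share a `sample_id`).
#' @param sugar One of `"trehalose"`, `"sucrose"`, `"maltose"`, `"lactose"`,
#'   `"raffinose"`, `"none"`.
#' @param sp_ratio Positive number, or `Inf` for protein-free samples.
#' @param replicate Positive integer replicate index.
#' @return A list of class `"wab_meta"`.
#' @export
sample_meta <- function(sample_id = "sample", sugar = "none",
                        sp_ratio = Inf, replicate = 1L) {
  sugar <- match.arg(sugar, wab_sugars())
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!(is.numeric(sp_ratio) && length(sp_ratio) == 1L &&
        (is.infinite(sp_ratio) || sp_ratio > 0))) {
    stop("`sp_ratio` must be a positive number or Inf (protein-free)",
         call. = FALSE)
  }
  replicate <- as.integer(replicate)
  stopifnot(length(replicate) == 1L, !is.na(replicate), replicate >= 1L)
  structure(list(sample_id = sample_id, sugar = sugar,
                 sp_ratio = as.numeric(sp_ratio), replicate = replicate),
            class = "wab_meta")
}

#' Closed vocabulary of sugars
#' @return Character vector of recognized sugar labels.
#' @export
wab_sugars <- function() {
  c("none", "trehalose", "sucrose", "maltose", "lactose", "raffinose")
}

#' Construct a spectrum
#'
#' The universal carrier of the pipeline: a wavenumber grid (cm-1, strictly
#' increasing) with dimensionless absorbance values and sample metadata.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm-1, length >= 2.
#' @param absorbance Numeric vector of the same length, all finite.
#' @param meta A [sample_meta()] object.
#' @return A list of class `"wab_spectrum"` with elements `wavenumbers`,
#'   `absorbance`, `meta`.
#' @export
wab_spectrum <- function(wavenumbers, absorbance, meta = sample_meta()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) < 2L) {
    stop("spectrum needs at least 2 points", call. = FALSE)
  }
  if (length(absorbance) != length(wavenumbers)) {
    stop("`wavenumbers` and `absorbance` must have equal length",
         call. = FALSE)
  }
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers))) {
    stop("non-finite wavenumbers", call. = FALSE)
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly increasing (duplicates not allowed)",
         call. = FALSE)
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    stop("non-finite absorbance values", call. = FALSE)
  }
  if (!inherits(meta, "wab_meta")) stop("`meta` must be a sample_meta()",
                                        call. = FALSE)
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 meta = meta),
            class = "wab_spectrum")
}

#' @export
print.wab_spectrum <- function(x, ...) {
  cat(sprintf("<wab_spectrum> %s (%s, S/P=%s, rep %d): %d points, %.1f-%.1f cm-1\n",
              x$meta$sample_id, x$meta$sugar,
              format(x$meta$sp_ratio), x$meta$replicate,
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Read a spectrum from disk
#'
#' Reads a two-column (wavenumber, absorbance) spectrum in either a delimited
#' text dialect (`"csv2col"`: comma, tab or whitespace separated, optional
#' single header line) or a restricted JCAMP-DX-style dialect (`"jcamp"`:
#' a single `##XYDATA=(X++(Y..Y))` or `##XYPOINTS=(XY..XY)` block). Rows are
#' sorted by ascending wavenumber; duplicated wavenumbers are rejected.
#'
#' @param path File to read.
#' @param dialect `"csv2col"` (default) or `"jcamp"`.
#' @param meta Metadata to attach (see [sample_meta()]).
#' @return A [wab_spectrum()].
#' @export
read_spectrum <- function(path, dialect = c("csv2col", "jcamp"),
                          meta = sample_meta()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  xy <- switch(dialect,
               csv2col = read_csv2col(path),
               jcamp = read_jcamp_xy(path))
  ord <- order(xy$x)
  x <- xy$x[ord]
  y <- xy$y[ord]
  if (anyDuplicated(x)) {
    stop("duplicated wavenumbers in ", path, call. = FALSE)
  }
  wab_spectrum(x, y, meta)
}

read_csv2col <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty spectrum file: ", path, call. = FALSE)
  parse_line <- function(ln) {
    fields <- strsplit(trimws(ln), "[,\t ]+")[[1]]
    suppressWarnings(as.numeric(fields))
  }
  first <- parse_line(lines[[1]])
  has_header <- anyNA(first)
  body <- if (has_header) lines[-1] else lines
  if (length(body) == 0L) stop("no data rows in ", path, call. = FALSE)
  vals <- lapply(body, parse_line)
  ncol_ok <- vapply(vals, function(v) length(v) >= 2 && !anyNA(v[1:2]),
                    logical(1))
  if (!all(ncol_ok)) {
    stop("unparsable rows in ", path,
         " (expected two numeric columns)", call. = FALSE)
  }
  list(x = vapply(vals, `[`, numeric(1), 1L),
       y = vapply(vals, `[`, numeric(1), 2L))
}

# Restricted JCAMP-DX reader: one data block of either (X++(Y..Y)) with
# FIRSTX/DELTAX (or FIRSTX/LASTX/NPOINTS) and optional X/Y factors, or
# (XY..XY) pairs. Anything else is a format error.
read_jcamp_xy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines, ignore.case = TRUE,
                value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    sub(paste0("^##", name, "="), "", hit[[1]], ignore.case = TRUE)
  }
  num_ldr <- function(name, default = NA_real_) {
    v <- suppressWarnings(as.numeric(ldr(name)))
    if (is.na(v)) default else v
  }
  start <- grep("^##(XYDATA|XYPOINTS)=", lines, ignore.case = TRUE)
  if (length(start) != 1L) {
    stop("unsupported JCAMP file (need exactly one XYDATA/XYPOINTS block): ",
         path, call. = FALSE)
  }
  header <- toupper(lines[[start]])
  stop_at <- grep("^##", lines)
  stop_at <- stop_at[stop_at > start]
  end <- if (length(stop_at)) min(stop_at) - 1L else length(lines)
  body <- lines[seq(start + 1L, end)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("empty JCAMP data block: ", path, call. = FALSE)
  xf <- num_ldr("XFACTOR", 1)
  yf <- num_ldr("YFACTOR", 1)
  if (grepl("XYPOINTS", header) || grepl("\\(XY\\.\\.XY\\)", header)) {
    toks <- unlist(strsplit(trimws(body), "[;,\t ]+"))
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals) || length(vals) %% 2L != 0L) {
      stop("unparsable JCAMP XY pairs in ", path, call. = FALSE)
    }
    idx <- seq_along(vals)
    return(list(x = vals[idx %% 2L == 1L] * xf, y = vals[idx %% 2L == 0L] * yf))
  }
  # (X++(Y..Y)): each line starts with an X value followed by Y values
  firstx <- num_ldr("FIRSTX")
  lastx <- num_ldr("LASTX")
  npoints <- num_ldr("NPOINTS")
  deltax <- num_ldr("DELTAX")
  if (is.na(deltax)) {
    if (is.na(firstx) || is.na(lastx) || is.na(npoints) || npoints < 2) {
      stop("JCAMP XYDATA block lacks DELTAX and FIRSTX/LASTX/NPOINTS: ",
           path, call. = FALSE)
    }
    deltax <- (lastx - firstx) / (npoints - 1)
  }
  xs <- numeric(0)
  ys <- numeric(0)
  for (ln in body) {
    toks <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[,\t ]+")[[1]]))
    if (anyNA(toks) || length(toks) < 2L) {
      stop("unparsable JCAMP XYDATA line in ", path, call. = FALSE)
    }
    x0 <- toks[[1]] * xf
    yv <- toks[-1] * yf
    xs <- c(xs, x0 + deltax * (seq_along(yv) - 1L))
    ys <- c(ys, yv)
  }
  list(x = xs, y = ys)
}

#' Write a spectrum as two-column delimited text
#'
#' Values are written with 17 significant digits so that a write/read round
#' trip reproduces the spectrum to 1e-12.
#'
#' @param spectrum A [wab_spectrum()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "wab_spectrum"))
  rows <- paste(format(spectrum$wavenumbers, digits = 17, trim = TRUE,
                       scientific = FALSE),
                format(spectrum$absorbance, digits = 17, trim = TRUE),
                sep = ",")
  ok <- tryCatch(suppressWarnings({
    writeLines(c("wavenumber,absorbance", rows), path)
    TRUE
  }), error = function(e) FALSE)
  if (!ok) stop("cannot write spectrum to ", path, call. = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation; no extrapolation outside the spectrum span.
#'
#' @param spectrum A [wab_spectrum()].
#' @param grid Target wavenumber grid, within the spectrum span.
#' @return A [wab_spectrum()] on `grid` with metadata preserved.
#' @export
resample <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "wab_spectrum"))
  grid <- as.numeric(grid)
  rng <- range(spectrum$wavenumbers)
  if (any(grid < rng[1]) || any(grid > rng[2])) {
    stop(sprintf("grid [%g, %g] outside spectrum span [%g, %g]: no extrapolation",
                 min(grid), max(grid), rng[1], rng[2]), call. = FALSE)
  }
  y <- stats::approx(spectrum$wavenumbers, spectrum$absorbance,
                     xout = grid, method = "linear", ties = "ordered")$y
  wab_spectrum(grid, y, spectrum$meta)
}

#' Read and write batch manifests
#'
#' A manifest is a delimited table with columns `sample_id`, `sugar`,
#' `sp_ratio`, `replicate`, `path`; protein-free samples use the sentinel
#' `"inf"` in `sp_ratio`.
#'
#' @param path Manifest file.
#' @return A data.frame with `sp_ratio` numeric (`Inf` for protein-free).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sp_ratio = "character"))
  need <- c("sample_id", "sugar", "sp_ratio", "replicate", "path")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sp <- tolower(trimws(df$sp_ratio))
  df$sp_ratio <- ifelse(sp %in% c("inf", "infinity"), Inf,
                        suppressWarnings(as.numeric(sp)))
  if (anyNA(df$sp_ratio)) stop("unparsable sp_ratio in manifest", call. = FALSE)
  df$replicate <- as.integer(df$replicate)
  df[need]
}

#' @rdname read_manifest
#' @param manifest Data.frame with the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("sample_id", "sugar", "sp_ratio", "replicate", "path")
  stopifnot(all(need %in% names(manifest)))
  out <- manifest[need]
  out$sp_ratio <- ifelse(is.infinite(out$sp_ratio), "inf",
                         format(out$sp_ratio, digits = 15, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write replicate summaries as a delimited table
#'
#' One row per (sample, sub-band class) with mean/SD population and mean/SD
#' center, in a fixed column order.
#'
#' @param results A single replicate summary or a list of them
#'   (see [aggregate_replicates()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_decomposition_table <- function(results, path) {
  if (inherits(results, "wab_replicate_summary")) results <- list(results)
  if (!is.list(results) || length(results) == 0L) {
    stop("`results` must be a non-empty list of replicate summaries",
         call. = FALSE)
  }
  tabs <- lapply(results, function(r) {
    stopifnot(inherits(r, "wab_replicate_summary"))
    as.data.frame(unclass(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  cols <- c("sample_id", "sugar", "sp_ratio", "class", "n_replicates",
            "mean_population", "sd_population", "mean_center", "sd_center")
  out <- out[cols]
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) out[[j]] <- format_full(out[[j]])
  ok <- tryCatch(suppressWarnings({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }), error = function(e) FALSE)
  if (!ok) stop("cannot write table to ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_decomposition_table
#' @export
read_decomposition_table <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sp_ratio = "character"))
  sp <- tolower(trimws(df$sp_ratio))
  df$sp_ratio <- ifelse(sp %in% c("inf", "infinity"), Inf,
                        suppressWarnings(as.numeric(sp)))
  df
}

# full-precision numeric formatting for delimited outputs (round-trips to
# 1e-12; keeps "inf" sentinel out of numeric columns)
format_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA"
    else if (is.infinite(v)) ifelse(v > 0, "inf", "-inf")
    else format(v, digits = 17, trim = TRUE)
  }, character(1))
}
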