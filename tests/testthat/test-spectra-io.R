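test_that("two-column files read back exactly, regardless of row order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("2000,0.10", "2001,0.11", "2002,0.12"), path)
  s <- read_spectrum(path)
  expect_length(s$wavenumbers, 3L)
  expect_equal(diff(s$wavenumbers), c(1, 1))
  expect_equal(s$absorbance, c(0.10, 0.11, 0.12))

  desc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("2002,0.12", "2001,0.11", "2000,0.10"), desc)
  s2 <- read_spectrum(desc)
  expect_equal(s2$wavenumbers, s$wavenumbers)
  expect_equal(s2$absorbance, s$absorbance)

  # tab separation and a header line are accepted too
  tabbed <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("wavenumber\tabsorbance", "2000\t0.10", "2001\t0.11"), tabbed)
  expect_equal(read_spectrum(tabbed)$absorbance, c(0.10, 0.11))
})

test_that("duplicated wavenumbers and unparsable files are rejected", {
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("2100,0.1", "2101,0.2", "2100,0.3"), dup)
  expect_error(read_spectrum(dup), "duplicated")

  junk <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("2000,0.1", "not,a,number", "2002,0.2"), junk)
  expect_error(read_spectrum(junk), "unparsable|two numeric")

  expect_error(read_spectrum(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("the JCAMP XYDATA dialect matches the plain two-column reader", {
  grid <- seq(2000, 2019)
  y <- sin(grid / 50) + 2
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(grid, format(y, digits = 17), sep = ","), csv)

  jdx <- withr::local_tempfile(fileext = ".jdx")
  rows <- vapply(seq(1, 20, by = 5), function(i) {
    paste(c(grid[i], format(y[i:(i + 4)], digits = 17)), collapse = " ")
  }, character(1))
  writeLines(c("##TITLE=synthetic", "##XUNITS=1/CM", "##FIRSTX=2000",
               "##LASTX=2019", "##NPOINTS=20", "##DELTAX=1",
               "##XYDATA=(X++(Y..Y))", rows, "##END="), jdx)
  a <- read_spectrum(csv)
  b <- read_spectrum(jdx, dialect = "jcamp")
  expect_equal(b$wavenumbers, a$wavenumbers)
  expect_equal(b$absorbance, a$absorbance, tolerance = 1e-12)

  # XY pairs block
  jdx2 <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=synthetic", "##XYPOINTS=(XY..XY)",
               "2000,0.5; 2001,0.6", "2002,0.7", "##END="), jdx2)
  s2 <- read_spectrum(jdx2, dialect = "jcamp")
  expect_equal(s2$absorbance, c(0.5, 0.6, 0.7))

  # anything without a single data block is a format error
  bad <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=nope", "##END="), bad)
  expect_error(read_spectrum(bad, dialect = "jcamp"), "unsupported")
})

test_that("write_spectrum / read_spectrum round-trips to 1e-12", {
  s <- gaussian_spectrum(2150, 80, 0.123456789012345,
                         meta = sample_meta("x", "trehalose", 80, 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  r <- read_spectrum(path)
  expect_equal(r$wavenumbers, s$wavenumbers, tolerance = 1e-12)
  expect_equal(r$absorbance, s$absorbance, tolerance = 1e-12)
})

test_that("resample is exact on affine absorbance and refuses extrapolation", {
  s <- wab_spectrum(seq(2000, 2010), 0.01 * seq(2000, 2010) - 19)
  mids <- seq(2000.5, 2009.5)
  r <- resample(s, mids)
  expect_equal(r$absorbance, 0.01 * mids - 19, tolerance = 1e-12)

  same <- resample(s, s$wavenumbers)
  expect_equal(same$absorbance, s$absorbance)
  expect_identical(same$meta, s$meta)

  expect_error(resample(s, seq(1990, 2005)), "outside")
})

test_that("spectrum invariants are enforced at construction", {
  expect_error(wab_spectrum(2000, 0.1), "at least 2")
  expect_error(wab_spectrum(c(2000, 2000), c(0.1, 0.2)), "increasing")
  expect_error(wab_spectrum(c(2000, 2001), c(0.1, NA)), "finite")
  expect_error(wab_spectrum(c(2000, 2001), 0.1), "equal length")
  expect_error(sample_meta(sugar = "glucose"), "arg")
  expect_error(sample_meta(sp_ratio = -1), "positive")
})

test_that("manifests round-trip, including the protein-free sentinel", {
  m <- data.frame(sample_id = c("a", "b"), sugar = c("trehalose", "sucrose"),
                  sp_ratio = c(80, Inf), replicate = c(1L, 2L),
                  path = c("a.csv", "b.csv"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, path)
  expect_match(readLines(path)[3], "inf")
  r <- read_manifest(path)
  expect_equal(r$sp_ratio, c(80, Inf))
  expect_equal(r$sample_id, m$sample_id)
})

test_that("decomposition tables have fixed layout and round-trip", {
  mk_decomp <- function(id, pops) {
    cls <- names(pops)
    spec <- normalized_gaussians(c(2100, 2250), c(60, 60),
                                 amps_for_areas(pops, c(60, 60)))
    spec$meta <- sample_meta(id, "trehalose", 80, 1L)
    fit_fixed_set(spec, cls)
  }
  d1 <- mk_decomp("s1", c(W2a = 0.6, W4 = 0.4))
  d2 <- mk_decomp("s1", c(W2a = 0.5, W4 = 0.5))
  summ <- aggregate_replicates(list(d1, d2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_decomposition_table(summ, path)
  tab <- read_decomposition_table(path)
  expect_equal(nrow(tab), 2L) # one row per (sample, class)
  expect_equal(names(tab),
               c("sample_id", "sugar", "sp_ratio", "class", "n_replicates",
                 "mean_population", "sd_population", "mean_center",
                 "sd_center"))
  expect_equal(tab$mean_population, unclass(summ)$mean_population,
               tolerance = 1e-12)
  expect_equal(tab$sd_center, unclass(summ)$sd_center, tolerance = 1e-12)

  expect_error(write_decomposition_table(list(), path), "non-empty")
  expect_error(write_decomposition_table(summ, "/nonexistent/dir/x.csv"),
               "cannot write")
})
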