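test_that("TextGrid round trip preserves intervals and skips silence labels", {
  a <- annotation_set(onset = c(0.0, 0.2), offset = c(0.1, 0.5),
                      element_class = c("click", "noisy"),
                      individual = "b1", recording = "r1")
  tg <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(a, tg)
  b <- read_textgrid(tg, "elements", individual = "b1", recording = "r1")
  expect_equal(nrow(b), 2L)
  expect_lt(max(abs(b$onset - a$onset)), 1e-9)
  expect_lt(max(abs(b$offset - a$offset)), 1e-9)
  expect_identical(b$element_class, a$element_class)
})

test_that("short-dialect and UTF-16 TextGrids parse identically to long UTF-8", {
  short_lines <- c('File type = "ooTextFile"', 'Object class = "TextGrid"',
                   "", "0", "0.5", "<exists>", "1", '"IntervalTier"',
                   '"elements"', "0", "0.5", "3",
                   "0", "0.1", '"click"',
                   "0.1", "0.2", '""',
                   "0.2", "0.5", '"noisy"')
  sf <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(short_lines, sf)
  s <- read_textgrid(sf, "elements")
  expect_equal(s$onset, c(0.0, 0.2))
  expect_equal(s$offset, c(0.1, 0.5))
  expect_identical(s$element_class, c("click", "noisy"))

  # same content, long dialect, UTF-16LE with BOM (as Praat writes)
  a <- annotation_set(onset = c(0.0, 0.2), offset = c(0.1, 0.5),
                      element_class = c("click", "noisy"))
  lf <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(a, lf)
  uf <- withr::local_tempfile(fileext = ".TextGrid")
  con <- file(uf, open = "wb")
  writeBin(as.raw(c(0xFF, 0xFE)), con)
  body <- paste0(paste(readLines(lf), collapse = "\n"), "\n")
  writeBin(iconv(body, to = "UTF-16LE", toRaw = TRUE)[[1]], con)
  close(con)
  u <- read_textgrid(uf, "elements")
  expect_equal(u$onset, s$onset, tolerance = 1e-12)
  expect_identical(u$element_class, s$element_class)
})

test_that("TextGrid reader rejects missing tiers and point tiers", {
  a <- annotation_set(0, 0.1, "click")
  tg <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(a, tg)
  expect_error(read_textgrid(tg, "no_such_tier"), "not found")

  point_lines <- c('File type = "ooTextFile"', 'Object class = "TextGrid"',
                   "", "0", "1", "<exists>", "1", '"TextTier"', '"pts"',
                   "0", "1", "2", "0.25", '"a"', "0.5", '"b"')
  pf <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(point_lines, pf)
  expect_error(read_textgrid(pf, "pts"), "IntervalTier")
})

test_that("element tables are read, re-sorted, validated and re-written", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("onset,offset,class,individual",
               "0.5,0.7,a,i1", "0.0,0.2,b,i1", "0.3,0.4,c,i1"), csv)
  e <- read_element_table(csv)
  expect_equal(nrow(e), 3L)
  expect_true(all(diff(e$onset) > 0))
  expect_identical(e$element_class, c("b", "c", "a"))

  # zero-duration rows are rejected with row numbers
  writeLines(c("onset,offset,class,individual", "0.1,0.1,a,i1"), csv)
  expect_error(read_element_table(csv), "offset must exceed onset")

  # custom column names, TSV, missing class -> sentinel
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("start\tstop\tbird", "0.0\t0.1\tb1", "0.2\t0.4\tb1"), tsv)
  f <- read_element_table(tsv, cols = c(onset = "start", offset = "stop",
                                        class = "type", individual = "bird"))
  expect_identical(unique(f$element_class), "unlabeled")
  expect_identical(unique(f$individual), "b1")

  out <- withr::local_tempfile(fileext = ".csv")
  write_element_table(e, out)
  e2 <- read_element_table(out)
  expect_equal(e2$onset, e$onset, tolerance = 1e-12)
  expect_identical(e2$element_class, e$element_class)
})

test_that("WAV files survive a 16-bit round trip and float32 reads back", {
  x <- 0.5 * sin(2 * pi * 440 * seq(0, 0.05, by = 1 / 8000))
  wf <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 8000, wf)
  w <- read_wav(wf)
  expect_identical(w$rate, 8000L)
  expect_lt(max(abs(w$samples - x)), 1 / 32000)

  # hand-built IEEE float32 WAV
  ff <- withr::local_tempfile(fileext = ".wav")
  con <- file(ff, "wb")
  nb <- length(x) * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nb), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(3L, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(8000L, con, size = 4L, endian = "little")
  writeBin(32000L, con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(32L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nb, con, size = 4L, endian = "little")
  writeBin(x, con, size = 4L, endian = "little")
  close(con)
  wfl <- read_wav(ff)
  expect_lt(max(abs(wfl$samples - x)), 1e-7)
})

test_that("result documents round-trip exactly and are seed-deterministic", {
  ds <- build_dataset(
    generate_null_dataset(synthetic_spec(bout_count = 30, rng_seed = 3)))
  cfg <- inference_config(n_permutations = 100, rng_seed = 4)
  res <- run_rhythm_test(ds, cfg)
  jf <- withr::local_tempfile(fileext = ".json")
  write_results(res, jf)
  r2 <- read_results(jf)
  expect_identical(r2$observed_max, res$observed_max)
  expect_identical(r2$test_statistic, res$test_statistic)
  expect_identical(r2$significant, res$significant)
  expect_identical(r2$perm_maxima, res$perm_maxima)
  expect_identical(r2$profile$deviation, res$profile$deviation)
  expect_identical(r2$profile$ci_high, res$profile$ci_high)
  expect_true(file.exists(sub("\\.json$", "_grid.csv", jf)))
  expect_true(file.exists(sub("\\.json$", "_peaks.csv", jf)))

  # identical seed + input => byte-identical payloads
  jf_a <- withr::local_tempfile(fileext = ".json")
  jf_b <- withr::local_tempfile(fileext = ".json")
  write_results(run_rhythm_test(ds, cfg), jf_a, tables = FALSE)
  write_results(run_rhythm_test(ds, cfg), jf_b, tables = FALSE)
  expect_identical(readLines(jf_a), readLines(jf_b))
})

test_that("a result with zero peaks still writes a valid, empty peak table", {
  ds <- single_stratum_dataset(rep(0.2, 6))  # fully degenerate: no peaks
  res <- run_rhythm_test(ds, inference_config(n_permutations = 100))
  expect_equal(nrow(res$peaks), 0L)
  jf <- withr::local_tempfile(fileext = ".json")
  write_results(res, jf)
  r2 <- read_results(jf)
  expect_equal(nrow(r2$peaks), 0L)
  pk <- utils::read.csv(sub("\\.json$", "_peaks.csv", jf))
  expect_equal(nrow(pk), 0L)
})
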