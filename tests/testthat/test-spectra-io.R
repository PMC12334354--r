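# Readers, writers, normalization and the peak-table cache.

fixture_table <- function(file_id = "fx") {
  ms1 <- do.call(rbind, lapply(1:3, function(s) {
    mk_ms1(scan = s, mz = seq(100, 550, length.out = 10) + s,
           i = c(5, 10, 3, 8, 10, 2, 7, 1, 9, 4) * 100,
           rt = s / 2, file_id = file_id)
  }))
  ms2 <- do.call(rbind, lapply(4:5, function(s) {
    mk_ms2(scan = s, mz = seq(80, 300, length.out = 5) + s,
           i = c(50, 200, 125, 400, 10), precmz = 488.1 + s, rt = s / 2,
           charge = 2L, ms1scan = 3L, file_id = file_id)
  }))
  peak_table(ms1 = ms1, ms2 = ms2)
}

test_that("mzML export/import reproduces the fixture peak lists", {
  tab <- fixture_table()
  path <- withr::local_tempfile(fileext = ".mzML")
  export_spectra(tab, data.frame(file_id = "fx", scan = 1:5), path, "mzml")
  back <- load_spectra(path, file_id = "fx")
  expect_identical(nrow(back$ms1), 30L)
  expect_identical(nrow(back$ms2), 10L)
  expect_equal(back$ms1$mz, tab$ms1$mz, tolerance = 1e-6)
  expect_equal(back$ms1$i, tab$ms1$i, tolerance = 1e-6)
  expect_equal(back$ms2$precmz, tab$ms2$precmz, tolerance = 1e-6)
  expect_equal(back$ms2$charge, tab$ms2$charge)
  expect_equal(back$ms2$ms1scan, tab$ms2$ms1scan)
  expect_equal(back$ms1$rt, tab$ms1$rt, tolerance = 1e-6)  # minutes both ways
  # structurally an mzML document
  doc <- xml2::read_xml(path)
  expect_match(xml2::xml_name(doc), "mzML", ignore.case = TRUE)
  expect_gt(length(xml2::xml_find_all(doc, "//*[local-name()='spectrum']")), 0)
})

test_that("MGF carries MS2 only, with defaults for missing metadata", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=demo", "PEPMASS=488.1",
               "100.1 10", "200.2 40", "300.3 20", "400.4 5", "END IONS"), path)
  expect_warning(tab <- load_spectra(path), "polarity")
  expect_identical(nrow(tab$ms1), 0L)
  expect_identical(nrow(tab$ms2), 4L)
  expect_equal(unique(tab$ms2$precmz), 488.1)
  expect_equal(unique(tab$ms2$charge), 1L)   # +1 default in positive mode
  expect_equal(unique(tab$ms2$polarity), 1L)
  expect_equal(unique(tab$ms2$scan), 1L)     # block order
  p <- withr::local_tempfile(fileext = ".csv")
  expect_error(load_spectra(p), "file not found")
  file.create(p)
  expect_error(load_spectra(p), "unsupported")
})

test_that("per-scan normalization: one unit base peak (ties included), TIC sums to one", {
  tab <- fixture_table()
  for (grp in split(tab$ms1, tab$ms1$scan)) {
    expect_equal(max(grp$i_norm), 1)
    expect_identical(sum(grp$i_norm == 1), sum(grp$i == max(grp$i)))  # ties all at 1
    expect_equal(sum(grp$i_tic_norm), 1, tolerance = 1e-9)
  }
  set.seed(5)
  rt <- rand_table()
  for (grp in split(rt$ms2, rt$ms2$scan)) {
    expect_equal(max(grp$i_norm), 1)
    expect_equal(sum(grp$i_tic_norm), 1, tolerance = 1e-9)
  }
})

test_that("cache round trip is bit-exact; corruption and staleness are detected", {
  tab <- fixture_table()
  src <- withr::local_tempfile(fileext = ".mzML")
  export_spectra(tab, data.frame(file_id = "fx", scan = 1:5), src, "mzml")
  cdir <- withr::local_tempdir()
  cache <- spectra_cache(cdir)

  cold <- load_spectra(src, cache = cache)
  key <- cache_key(src)
  cached <- load_cache(key, cache)
  expect_identical(cached, cold)                       # bit-exact round trip
  warm <- load_spectra(src, cache = cache)
  expect_identical(warm, cold)

  # truncated blob -> checksum error, not wrong data
  blob <- file.path(cdir, paste0(key, ".rds"))
  raw <- readBin(blob, "raw", file.size(blob))
  writeBin(raw[1:(length(raw) %/% 2)], blob)
  expect_error(load_cache(key, cache), class = "massql_cache_corrupt")

  # version mismatch -> regenerate signal (miss), never a silent misread
  cache2 <- spectra_cache(cdir, version = 99L)
  save_cache(tab, cache2, key = key)
  expect_error(load_cache(key, cache), class = "massql_cache_miss")
  refreshed <- load_spectra(src, cache = cache)        # falls back to re-parse
  expect_identical(refreshed, cold)
})

test_that("result tables write as TSV with stable header and as JSON that reparses", {
  res <- execute_query("QUERY scaninfo(MS1DATA)", fixture_table())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(res, tsv, "tsv")
  lines <- readLines(tsv)
  expect_identical(length(lines), nrow(res) + 1L)
  expect_identical(strsplit(lines[1], "\t")[[1]], names(res))

  empty <- res[0, , drop = FALSE]
  write_result_table(empty, tsv, "tsv")
  expect_identical(length(readLines(tsv)), 1L)

  js <- withr::local_tempfile(fileext = ".json")
  write_result_table(res, js, "json")
  back <- jsonlite::fromJSON(js)
  expect_identical(nrow(back), nrow(res))
  expect_equal(back$rt, res$rt, tolerance = 1e-12)
  expect_identical(back$scan, res$scan)
})

test_that("spectrum export round-trips through MGF and JSON", {
  tab <- fixture_table()
  mgf <- withr::local_tempfile(fileext = ".mgf")
  export_spectra(tab, data.frame(file_id = "fx", scan = 4:5), mgf, "mgf")
  expect_identical(sum(grepl("^BEGIN IONS", readLines(mgf))), 2L)
  back <- load_spectra(mgf, file_id = "fx")
  expect_identical(nrow(back$ms2), 10L)
  expect_equal(sort(back$ms2$mz), sort(tab$ms2$mz), tolerance = 1e-6)
  expect_equal(sort(back$ms2$i), sort(tab$ms2$i), tolerance = 1e-6)
  expect_setequal(back$ms2$scan, 4:5)                   # SCANS preserved

  # empty selection -> empty but valid file
  export_spectra(tab, data.frame(file_id = character(0), scan = integer(0)),
                 mgf, "mgf")
  expect_identical(nrow(load_spectra(mgf)$ms2), 0L)

  js <- withr::local_tempfile(fileext = ".json")
  export_spectra(tab, data.frame(file_id = "fx", scan = c(1L, 4L)), js, "json")
  obj <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_length(obj, 2L)
  lv <- vapply(obj, function(x) x$mslevel, numeric(1))
  expect_setequal(lv, c(1, 2))
  expect_error(export_spectra(tab, data.frame(file_id = "fx", scan = 99L), js, "json"),
               "absent")
})

test_that("the same spectra written as mzML and MGF give identical MS2 query results", {
  set.seed(21)
  dir <- withr::local_tempdir()
  gen <- generate_dataset(dir, n_files = 1, k_iron = 2, k_phosphate = 4,
                          n_decoy_ms1 = 10, n_decoy_ms2 = 30, seed = 7)
  q <- reference_queries()[["phosphate"]]
  from_mzml <- execute_query(q, load_spectra(gen$files$mzml[1]))
  from_mgf <- execute_query(q, load_spectra(gen$files$mgf[1]))
  expect_setequal(from_mzml$scan, from_mgf$scan)
  expect_gt(nrow(from_mzml), 0L)
})
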