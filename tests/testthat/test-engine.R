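# Peak matching arithmetic, variable bindings, metadata filters, EXCLUDED
# semantics and engine/oracle equivalence properties.

test_that("peak matching applies tolerance windows and intensity gates", {
  pk <- data.frame(mz = c(98.9847, 98.9900), i = c(800, 900),
                   i_norm = c(0.8, 0.9), i_tic_norm = c(0.4, 0.45))
  q <- list(tolerance_ppm = 50, intensity_percent = 50)
  m <- peak_matches(pk, 98.9847, q)
  # 50 ppm of 98.9847 is ~0.00495 Da: the 98.99 peak (delta 0.0053) is out
  expect_identical(m, c(TRUE, FALSE))
  expect_identical(peak_matches(pk, 98.9847, list(tolerance_ppm = 50,
                                                  intensity_percent = 95)),
                   c(FALSE, FALSE))
  # default tolerance 0.1 Da captures both
  expect_identical(peak_matches(pk, 98.9847, list()), c(TRUE, TRUE))
  # ppm window computed on the target m/z, so the window is order-independent
  expect_identical(peak_matches(pk, 98.9900, list(tolerance_ppm = 50)),
                   c(FALSE, TRUE))
})

test_that("relative-intensity matching accepts ratios inside the band", {
  # anchor Y = 1e6; expected ratio 0.063 within 25%: band [0.04725, 0.07875]
  pk <- data.frame(mz = rep(498.007, 3), i = c(5e4, 4.6e4, 8e4),
                   i_norm = 1, i_tic_norm = 0.3)
  q <- list(tolerance_mz = 0.01, intensity_match = 0.063,
            intensity_match_percent = 25)
  b <- list(X = 500, Y = 1e6)
  m <- peak_matches(pk, list(kind = "var", offset = -1.993), q,
                    execution_config(), b)
  expect_identical(m, c(TRUE, FALSE, FALSE))  # 0.05 in band; 0.046 and 0.08 out
  expect_error(peak_matches(pk, list(kind = "var", offset = -1.993), q),
               "binding")
})

test_that("mass-defect windows are inclusive on fractional m/z", {
  pk <- data.frame(mz = c(163.15, 163.25, 163.12, 163.20),
                   i = 1, i_norm = 1, i_tic_norm = 0.25)
  m <- peak_matches(pk, 163.2, list(tolerance_mz = 0.5,
                                    mass_defect = c(min = 0.1, max = 0.2)))
  expect_identical(m, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("binding enumeration requires every variable condition to co-occur", {
  iron <- parse_massql(reference_queries()[["iron"]])
  conds <- massql:::.collect_leaves(iron$where)

  one <- plant_iron_pattern(500, 1e6)
  pk <- peak_table(ms1 = mk_ms1(1, one$mz, one$i))$ms1
  b <- enumerate_bindings(pk, conds)
  expect_identical(nrow(b), 1L)
  expect_equal(b$X, 500, tolerance = 1e-9)
  expect_equal(b$Y, 1e6)

  noapo <- plant_iron_pattern(500, 1e6, apo_fraction = 0)
  expect_identical(nrow(noapo), 3L)
  pk2 <- peak_table(ms1 = mk_ms1(1, noapo$mz, noapo$i))$ms1
  expect_identical(nrow(enumerate_bindings(pk2, conds)), 0L)

  two <- rbind(plant_iron_pattern(400, 1e6), plant_iron_pattern(700, 5e5))
  pk3 <- peak_table(ms1 = mk_ms1(1, two$mz, two$i))$ms1
  b3 <- enumerate_bindings(pk3, conds)
  expect_equal(b3$X, c(400, 700), tolerance = 1e-9)
})

test_that("metadata filters are inclusive and polarity/charge are exact", {
  ms1 <- rbind(mk_ms1(1, 200, 10, rt = 4.9), mk_ms1(2, 200, 10, rt = 5.0),
               mk_ms1(3, 200, 10, rt = 5.1, polarity = -1L),
               mk_ms1(5, 200, 10, rt = 9))
  ms2 <- rbind(mk_ms2(6, 150, 10, precmz = 300, charge = 2L),
               mk_ms2(7, 150, 10, precmz = 300, charge = -2L, polarity = -1L),
               mk_ms2(8, 150, 10, precmz = 300, charge = 1L))
  tab <- peak_table(ms1 = ms1, ms2 = ms2)

  q <- parse_massql("QUERY scaninfo(MS1DATA) WHERE RTMIN=5")
  expect_identical(filter_metadata(q, tab)$scan, c(2L, 3L, 5L))  # rt=5.0 retained

  qp <- parse_massql("QUERY scaninfo(MS1DATA) WHERE POLARITY=Positive")
  expect_identical(filter_metadata(qp, tab)$scan, c(1L, 2L, 5L))

  qs <- parse_massql("QUERY scaninfo(MS1DATA) WHERE SCANMIN=5 AND SCANMAX=5")
  expect_identical(filter_metadata(qs, tab)$scan, 5L)

  qc <- parse_massql("QUERY scaninfo(MS2DATA) WHERE CHARGE=2")
  expect_identical(filter_metadata(qc, tab)$scan, c(6L, 7L))  # |charge| compared
})

test_that("EXCLUDED retains exactly the scans with zero qualifying matches", {
  set.seed(31)
  tab <- rand_table(n_ms2 = 12, max_peaks = 10)
  pos <- "QUERY scannum(MS2DATA) WHERE MS2PROD=200:TOLERANCEMZ=50"
  neg <- "QUERY scannum(MS2DATA) WHERE MS2PROD=200:TOLERANCEMZ=50:EXCLUDED"
  a <- execute_query(pos, tab)$scan
  b <- execute_query(neg, tab)$scan
  expect_length(intersect(a, b), 0L)
  expect_setequal(c(a, b), unique(tab$ms2$scan))

  # sub-threshold peaks do not count as matches
  tb <- peak_table(ms2 = mk_ms2(1, c(98.9847, 200), c(10, 1000), precmz = 300))
  r <- execute_query(
    "QUERY scannum(MS2DATA) WHERE MS2PROD=98.9847:TOLERANCEPPM=50:INTENSITYPERCENT=50:EXCLUDED",
    tb)
  expect_identical(r$scan, 1L)

  cond <- parse_massql("QUERY scaninfo(MS2DATA) WHERE MS2PROD=200:TOLERANCEMZ=50:EXCLUDED")
  keep <- apply_excluded(cond$where$cond, tab, "MS2DATA")
  expect_setequal(keep$scan, b)
})

test_that("neutral-loss conditions match where the equivalent product-ion query does", {
  set.seed(41)
  for (k in 1:20) {
    tab <- rand_table(n_ms1 = 1, n_ms2 = 1, max_peaks = 6)
    s <- tab$ms2[tab$ms2$scan == tab$ms2$scan[1], ]
    loss <- max(round(s$precmz[1] - sample(s$mz, 1) + runif(1, -0.02, 0.02), 3), 0.5)
    rnl <- execute_query(sprintf(
      "QUERY scannum(MS2DATA) WHERE MS2NL=%.4f:TOLERANCEMZ=0.05", loss), tab)
    rpr <- execute_query(sprintf(
      "QUERY scannum(MS2DATA) WHERE MS2PROD=%.6f:TOLERANCEMZ=0.05",
      s$precmz[1] - loss), tab)
    expect_identical(rnl$scan, rpr$scan)
  }
})

test_that("widening tolerances or relaxing intensity gates never shrinks results", {
  set.seed(51)
  for (k in 1:15) {
    tab <- rand_table(n_ms2 = 8, max_peaks = 10)
    target <- round(sample(tab$ms2$mz, 1), 2)
    scans <- function(q) execute_query(q, tab)$scan
    narrow <- scans(sprintf("QUERY scannum(MS2DATA) WHERE MS2PROD=%s:TOLERANCEPPM=5", target))
    wide <- scans(sprintf("QUERY scannum(MS2DATA) WHERE MS2PROD=%s:TOLERANCEPPM=50", target))
    expect_true(all(narrow %in% wide))
    tight <- scans(sprintf("QUERY scannum(MS2DATA) WHERE MS2PROD=%s:TOLERANCEMZ=0.01", target))
    loose <- scans(sprintf("QUERY scannum(MS2DATA) WHERE MS2PROD=%s:TOLERANCEMZ=0.1", target))
    expect_true(all(tight %in% loose))
    hi <- scans(sprintf("QUERY scannum(MS2DATA) WHERE MS2PROD=%s:TOLERANCEMZ=0.1:INTENSITYPERCENT=80", target))
    lo <- scans(sprintf("QUERY scannum(MS2DATA) WHERE MS2PROD=%s:TOLERANCEMZ=0.1:INTENSITYPERCENT=10", target))
    expect_true(all(hi %in% lo))
  }
})

test_that("execution is deterministic: repeated runs serialize byte-identically", {
  set.seed(61)
  tab <- rand_table(n_ms1 = 6, n_ms2 = 6)
  q <- "QUERY scaninfo(MS2DATA) WHERE MS2PROD=200:TOLERANCEMZ=60 OR RTMIN=5"
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_result_table(execute_query(q, tab), f1, "tsv")
  write_result_table(execute_query(q, tab), f2, "tsv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("scansum aggregates matched intensity over retained scans", {
  tb <- peak_table(ms2 = rbind(
    mk_ms2(1, c(163.1, 163.15, 300), c(500, 700, 100), precmz = 400),
    mk_ms2(2, c(163.1, 200), c(250, 999), precmz = 400),
    mk_ms2(3, c(50, 60), c(10, 20), precmz = 400)))
  r <- execute_query("QUERY scansum(MS2DATA) WHERE MS2PROD=163.1:TOLERANCEMZ=0.1", tb)
  expect_identical(r$n_scans, 2L)
  # per scan the most intense matching peak: 700 (scan 1) + 250 (scan 2)
  expect_equal(r$total_intensity, 950)
})

test_that("an MS2-only condition on a table with no MS2 data returns empty, not an error", {
  tab <- peak_table(ms1 = mk_ms1(1, c(100, 200), c(5, 10)))
  r <- execute_query("QUERY scaninfo(MS2DATA) WHERE MS2PROD=163.1", tab)
  expect_identical(nrow(r), 0L)
  expect_error(execute_query("QUERY scaninfo(MS1DATA) WHERE RTMIN=10 AND RTMAX=5", tab),
               class = "massql_parse_error")
})

test_that("engine output equals the brute-force oracle on random query/data pairs", {
  set.seed(71)
  hits <- 0L
  for (k in 1:40) {
    tab <- rand_table(n_ms1 = sample(2:5, 1), n_ms2 = sample(2:5, 1))
    q <- rand_query(tab)
    hits <- hits + expect_engine_matches_oracle(q, tab)
  }
  expect_gt(hits, 0L)  # the pairs exercise non-empty results too
})
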