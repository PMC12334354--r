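# Grammar, parser, canonical serialization, validation and description.

test_that("the diagnostic product-ion query parses into the expected AST", {
  q <- parse_massql(
    "QUERY scaninfo(MS2DATA) WHERE MS2PROD=98.9847:TOLERANCEPPM=50:INTENSITYPERCENT=50")
  expect_s3_class(q, "massql_query")
  expect_identical(q$fun, "scaninfo")
  expect_identical(q$datatype, "MS2DATA")
  expect_identical(q$where$kind, "LEAF")
  cond <- q$where$cond
  expect_identical(cond$type, "MS2PROD")
  expect_equal(cond$value$mz, 98.9847)
  expect_equal(cond$qualifiers$tolerance_ppm, 50)
  expect_equal(cond$qualifiers$intensity_percent, 50)
})

test_that("range-valued and match-all queries parse", {
  q <- parse_massql("QUERY scaninfo(MS1DATA) WHERE MOBILITY=range(min=1, max=2)")
  expect_identical(q$where$cond$type, "MOBILITY")
  expect_equal(unname(q$where$cond$value), c(1, 2))

  q2 <- parse_massql("QUERY scaninfo(MS1DATA)")
  expect_null(q2$where)

  q3 <- parse_massql(
    "QUERY scaninfo(MS1DATA) WHERE MS1MZ=301.1:MASSDEFECT=massdefect(min=0.1, max=0.2)")
  expect_equal(unname(q3$where$cond$qualifiers$mass_defect), c(0.1, 0.2))
})

test_that("parse errors carry the offset of the earliest failure", {
  err <- tryCatch(parse_massql("QUERY scaninfo(MS1DATA) WHERE MS1MZ="),
                  massql_parse_error = identity)
  expect_s3_class(err, "massql_parse_error")
  expect_identical(err$offset, nchar("QUERY scaninfo(MS1DATA) WHERE MS1MZ=") + 1L)
  expect_match(conditionMessage(err), "at character")

  e2 <- tryCatch(parse_massql("QUERY scaninfo(MS1DATA) WHERE FOO=1"),
                 massql_parse_error = identity)
  expect_identical(e2$offset, 31L)
  expect_error(parse_massql("QUERY scaninfo(MS1DATA) WHERE (MS1MZ=100"),
               class = "massql_parse_error")
  expect_error(parse_massql("QUERY scaninfo(MS1DATA) WHERE MS1MZ=X*2"),
               "limited to X")
  expect_error(parse_massql("QUERY scaninfo(MS1DATA) WHERE MS1MZ=1e5"),
               class = "massql_parse_error")
})

test_that("keywords are case-insensitive and AND binds tighter than OR", {
  a <- parse_massql("query SCANINFO(ms2data) where ms2prod=163.1")
  b <- parse_massql("QUERY scaninfo(MS2DATA) WHERE MS2PROD=163.1")
  expect_identical(massql:::.strip_positions(a), massql:::.strip_positions(b))

  q <- parse_massql(
    "QUERY scaninfo(MS1DATA) WHERE MS1MZ=100 OR MS1MZ=200 AND MS1MZ=300")
  expect_identical(q$where$kind, "OR")
  expect_identical(q$where$children[[2]]$kind, "AND")
  qp <- parse_massql(
    "QUERY scaninfo(MS1DATA) WHERE (MS1MZ=100 OR MS1MZ=200) AND MS1MZ=300")
  expect_identical(qp$where$kind, "AND")
  expect_identical(qp$where$children[[1]]$kind, "OR")
})

test_that("serialize/parse round trip is structurally exact over the corpus", {
  for (s in corpus_queries()) {
    q <- parse_massql(s)
    r <- parse_massql(serialize_massql(q))
    expect_identical(massql:::.strip_positions(r), massql:::.strip_positions(q),
                     label = s)
    # canonical text is a fixed point
    expect_identical(serialize_massql(r), serialize_massql(q))
  }
})

test_that("serialization preserves child order and uses canonical casing", {
  q <- parse_massql("query scaninfo(ms1data) where ms1mz=200.5 and ms1mz=100.1")
  s <- serialize_massql(q)
  expect_identical(s, "QUERY scaninfo(MS1DATA) WHERE MS1MZ=200.5 AND MS1MZ=100.1")
})

test_that("every random token soup parses or fails with one offset-bearing error", {
  set.seed(99)
  vocab <- c("QUERY", "scaninfo", "(", ")", "MS1DATA", "WHERE", "MS1MZ", "=",
             "163.1", ":", "TOLERANCEPPM", "AND", "OR", "X", "+", "-", "range",
             "min", "max", ",", "#", "$", "banana", "1.2.3")
  for (k in 1:200) {
    s <- paste(sample(vocab, sample(1:12, 1), replace = TRUE), collapse = " ")
    res <- tryCatch(parse_massql(s), condition = identity)
    if (inherits(res, "massql_query")) succeed()
    else {
      expect_s3_class(res, "massql_parse_error")
      expect_true(is.integer(res$offset) && res$offset >= 1L, label = s)
    }
  }
})

test_that("validation flags inverted ranges, exclusive tolerances and missing anchors", {
  q <- parse_massql("QUERY scaninfo(MS1DATA) WHERE RTMIN=10 AND RTMAX=5", check = FALSE)
  d <- validate_massql(q)
  expect_identical(nrow(d[d$level == "error", ]), 1L)
  expect_match(d$message[1], "RTMIN")

  q2 <- parse_massql(
    "QUERY scaninfo(MS2DATA) WHERE MS2PROD=163.1:TOLERANCEMZ=0.1:TOLERANCEPPM=50",
    check = FALSE)
  d2 <- validate_massql(q2)
  expect_identical(nrow(d2[d2$level == "error", ]), 1L)
  expect_match(d2$message[1], "mutually exclusive")

  q3 <- parse_massql("QUERY scaninfo(MS1DATA) WHERE MS1MZ=X+1.003", check = FALSE)
  expect_match(validate_massql(q3)$message[1], "anchor")

  q4 <- parse_massql("QUERY scaninfo(MS1DATA) WHERE MS2PROD=163.1", check = FALSE)
  expect_match(validate_massql(q4)$message[1], "MS2DATA")

  q5 <- parse_massql("QUERY scaninfo(MS2DATA) WHERE MS2PREC=488.1:INTENSITYPERCENT=10",
                     check = FALSE)
  expect_match(validate_massql(q5)$message[1], "does not apply")

  ok <- parse_massql(
    "QUERY scaninfo(MS2DATA) WHERE MS2PROD=98.9847:TOLERANCEPPM=50:INTENSITYPERCENT=50")
  expect_identical(nrow(validate_massql(ok)), 0L)
  for (s in corpus_queries()) {
    expect_identical(nrow(validate_massql(parse_massql(s))), 0L, label = s)
  }
})

test_that("English description names the level, constraints and negation", {
  ope <- describe_massql(parse_massql(
    "QUERY scaninfo(MS2DATA) WHERE MS2PROD=98.9847:TOLERANCEPPM=50:INTENSITYPERCENT=50"))
  expect_match(ope, "product ion")
  expect_match(ope, "98.9847")
  expect_match(ope, "50 ppm")
  expect_match(ope, "50% of the base peak")

  expect_identical(describe_massql(parse_massql("QUERY scaninfo(MS1DATA)")),
                   "Return information for all MS1 scans.")

  excl <- describe_massql(parse_massql(
    "QUERY scaninfo(MS2DATA) WHERE MS2PROD=163.1:EXCLUDED"))
  expect_match(excl, "not contain")
})
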