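# Query grammar and parser.
#
# A query has the shape
#
#   QUERY <function>(<datatype>) [ WHERE <condition tree> ]
#
# where <function> is scaninfo | scannum | scansum, <datatype> is
# MS1DATA | MS2DATA, and the condition tree combines conditions with AND/OR
# and parentheses (AND binds tighter than OR). Each condition is
# NAME=value[:QUALIFIER[=value]]*. Keywords are case-insensitive; numeric
# literals are plain decimals (no scientific notation). m/z-valued conditions
# accept a variable expression X, X+<offset> or X-<offset>; at most one
# variable symbol per query, and an un-offset X (the anchor) must appear in
# at least one condition.

.CONDITION_VALUE_KIND <- c(
  MS1MZ = "mz", MS2PREC = "mz", MS2PROD = "mz", MS2NL = "mz",
  CHARGE = "number", POLARITY = "polarity",
  RTMIN = "number", RTMAX = "number",
  SCANMIN = "number", SCANMAX = "number",
  MOBILITY = "range"
)

.QUALIFIER_FIELDS <- c(
  TOLERANCEMZ = "tolerance_mz", TOLERANCEPPM = "tolerance_ppm",
  INTENSITYVALUE = "intensity_value", INTENSITYPERCENT = "intensity_percent",
  INTENSITYTICPERCENT = "intensity_tic_percent",
  INTENSITYMATCH = "intensity_match",
  INTENSITYMATCHPERCENT = "intensity_match_percent",
  MASSDEFECT = "mass_defect", EXCLUDED = "excluded"
)

# which condition types each qualifier may be attached to
.QUALIFIER_APPLIES <- list(
  tolerance_mz = c("MS1MZ", "MS2PREC", "MS2PROD", "MS2NL"),
  tolerance_ppm = c("MS1MZ", "MS2PREC", "MS2PROD", "MS2NL"),
  intensity_value = c("MS1MZ", "MS2PROD"),
  intensity_percent = c("MS1MZ", "MS2PROD"),
  intensity_tic_percent = c("MS1MZ", "MS2PROD"),
  intensity_match = c("MS1MZ", "MS2PROD"),
  intensity_match_percent = c("MS1MZ", "MS2PROD"),
  mass_defect = c("MS1MZ", "MS2PREC", "MS2PROD"),
  excluded = c("MS1MZ", "MS2PREC", "MS2PROD")
)

.parse_error <- function(message, offset) {
  stop(structure(
    class = c("massql_parse_error", "error", "condition"),
    list(message = sprintf("%s (at character %d)", message, offset),
         call = NULL, offset = offset)
  ))
}

# tokenizer: IDENT, NUMBER, PUNCT; each token carries its 1-based start offset
.tokenize <- function(text) {
  n <- nchar(text)
  toks <- list()
  i <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (grepl("^[A-Za-z]$", ch)) {
      j <- i
      while (j < n && grepl("^[A-Za-z0-9_]$", substr(text, j + 1L, j + 1L))) j <- j + 1L
      toks[[length(toks) + 1L]] <- list(type = "IDENT", text = substr(text, i, j), pos = i)
      i <- j + 1L
    } else if (grepl("^[0-9.]$", ch)) {
      j <- i
      while (j < n && grepl("^[0-9.]$", substr(text, j + 1L, j + 1L))) j <- j + 1L
      num <- substr(text, i, j)
      if (!grepl("^([0-9]+\\.?[0-9]*|\\.[0-9]+)$", num)) {
        .parse_error(sprintf("malformed number '%s'", num), i)
      }
      toks[[length(toks) + 1L]] <- list(type = "NUMBER", text = num, pos = i)
      i <- j + 1L
    } else if (ch %in% c("(", ")", "=", ":", ",", "+", "-", "*")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, pos = i)
      i <- i + 1L
    } else {
      .parse_error(sprintf("unexpected character '%s'", ch), i)
    }
  }
  toks[[length(toks) + 1L]] <- list(type = "EOF", text = "", pos = n + 1L)
  toks
}

#' Parse a query string
#'
#' Parses query text into a structured abstract syntax tree of class
#' `"massql_query"`. Keywords are case-insensitive. With `check = TRUE`
#' (default) the parsed query is also validated (see [validate_massql()]) and
#' the first error-level diagnostic is raised; with `check = FALSE` the raw
#' AST is returned so diagnostics can be inspected.
#'
#' @param text A single query string.
#' @param check Run semantic validation after parsing?
#' @return A `massql_query` object with elements `fun` (output function),
#'   `datatype` (`"MS1DATA"` or `"MS2DATA"`), `where` (condition tree or
#'   `NULL` for match-all) and `source` (the input text).
#' @examples
#' q <- parse_massql(
#'   "QUERY scaninfo(MS2DATA) WHERE MS2PROD=98.9847:TOLERANCEPPM=50:INTENSITYPERCENT=50")
#' print(q)
#' @export
parse_massql <- function(text, check = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) .parse_error("empty query", 1L)
  toks <- .tokenize(text)
  pos <- 1L

  peek <- function() toks[[pos]]
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect_kw <- function(kw) {
    t <- peek()
    if (t$type != "IDENT" || toupper(t$text) != kw) {
      .parse_error(sprintf("expected '%s'", kw), t$pos)
    }
    advance()
  }
  expect_type <- function(type, what) {
    t <- peek()
    if (t$type != type) .parse_error(sprintf("expected %s", what), t$pos)
    advance()
  }
  expect_number <- function(what) {
    t <- peek()
    if (t$type != "NUMBER") .parse_error(sprintf("missing %s", what), t$pos)
    as.numeric(advance()$text)
  }

  parse_range <- function(keyword) {
    t <- peek()
    if (t$type != "IDENT" || toupper(t$text) != toupper(keyword)) {
      .parse_error(sprintf("expected '%s(min=..., max=...)'", keyword), t$pos)
    }
    advance()
    expect_type("(", "'('")
    expect_kw("MIN"); expect_type("=", "'='")
    lo <- expect_number("range minimum")
    expect_type(",", "','")
    expect_kw("MAX"); expect_type("=", "'='")
    hi <- expect_number("range maximum")
    expect_type(")", "')'")
    c(min = lo, max = hi)
  }

  parse_mz_value <- function() {
    t <- peek()
    if (t$type == "NUMBER") {
      return(list(kind = "const", mz = as.numeric(advance()$text)))
    }
    if (t$type == "IDENT" && toupper(t$text) == "X") {
      advance()
      nxt <- peek()
      if (nxt$type %in% c("+", "-")) {
        op <- advance()$type
        mult <- peek()
        if (mult$type == "*") .parse_error("variable arithmetic is limited to X +/- constant", mult$pos)
        off <- expect_number("offset after X")
        return(list(kind = "var", offset = if (op == "+") off else -off))
      }
      if (nxt$type == "*") .parse_error("variable arithmetic is limited to X +/- constant", nxt$pos)
      return(list(kind = "var", offset = 0))
    }
    .parse_error("missing m/z value", t$pos)
  }

  parse_condition <- function() {
    t <- peek()
    if (t$type != "IDENT") .parse_error("expected a condition name", t$pos)
    name <- toupper(t$text)
    kindv <- .CONDITION_VALUE_KIND[name]
    if (is.na(kindv)) .parse_error(sprintf("unknown condition '%s'", t$text), t$pos)
    cond_pos <- t$pos
    advance()
    expect_type("=", "'='")
    value <- switch(unname(kindv),
      mz = parse_mz_value(),
      number = expect_number(sprintf("value for %s", name)),
      polarity = {
        v <- peek()
        if (v$type != "IDENT" || !(toupper(v$text) %in% c("POSITIVE", "NEGATIVE"))) {
          .parse_error("missing polarity value (Positive or Negative)", v$pos)
        }
        if (toupper(advance()$text) == "POSITIVE") "Positive" else "Negative"
      },
      range = parse_range("range")
    )
    quals <- list()
    while (peek()$type == ":") {
      advance()
      qt <- peek()
      if (qt$type != "IDENT") .parse_error("expected a qualifier name", qt$pos)
      qname <- toupper(qt$text)
      field <- .QUALIFIER_FIELDS[qname]
      if (is.na(field)) .parse_error(sprintf("unknown qualifier '%s'", qt$text), qt$pos)
      field <- unname(field)
      if (field %in% names(quals)) {
        .parse_error(sprintf("duplicate qualifier '%s'", qname), qt$pos)
      }
      advance()
      if (field == "excluded") {
        quals[[field]] <- TRUE
      } else if (field == "mass_defect") {
        expect_type("=", "'='")
        quals[[field]] <- parse_range("massdefect")
      } else {
        expect_type("=", "'='")
        quals[[field]] <- expect_number(sprintf("value for %s", qname))
      }
    }
    list(kind = "LEAF",
         cond = list(type = name, value = value, qualifiers = quals, pos = cond_pos))
  }

  parse_primary <- function() {
    if (peek()$type == "(") {
      advance()
      node <- parse_or()
      expect_type(")", "')'")
      return(node)
    }
    parse_condition()
  }

  parse_and <- function() {
    children <- list(parse_primary())
    while (peek()$type == "IDENT" && toupper(peek()$text) == "AND") {
      advance()
      children[[length(children) + 1L]] <- parse_primary()
    }
    if (length(children) == 1L) children[[1L]] else list(kind = "AND", children = children)
  }

  parse_or <- function() {
    children <- list(parse_and())
    while (peek()$type == "IDENT" && toupper(peek()$text) == "OR") {
      advance()
      children[[length(children) + 1L]] <- parse_and()
    }
    if (length(children) == 1L) children[[1L]] else list(kind = "OR", children = children)
  }

  expect_kw("QUERY")
  fn <- peek()
  if (fn$type != "IDENT" || !(tolower(fn$text) %in% c("scaninfo", "scannum", "scansum"))) {
    .parse_error("expected an output function (scaninfo, scannum or scansum)", fn$pos)
  }
  fun <- tolower(advance()$text)
  expect_type("(", "'('")
  dt <- peek()
  if (dt$type != "IDENT" || !(toupper(dt$text) %in% c("MS1DATA", "MS2DATA"))) {
    .parse_error("expected a data level (MS1DATA or MS2DATA)", dt$pos)
  }
  datatype <- toupper(advance()$text)
  expect_type(")", "')'")

  where <- NULL
  if (peek()$type == "IDENT" && toupper(peek()$text) == "WHERE") {
    advance()
    where <- parse_or()
  }
  eof <- peek()
  if (eof$type != "EOF") .parse_error(sprintf("unexpected input '%s'", eof$text), eof$pos)

  q <- structure(
    list(fun = fun, datatype = datatype, where = where, source = text),
    class = "massql_query"
  )
  if (check) {
    d <- validate_massql(q)
    err <- d[d$level == "error", , drop = FALSE]
    if (nrow(err) > 0L) .parse_error(err$message[1L], err$position[1L])
  }
  q
}
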