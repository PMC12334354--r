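# AST utilities: canonical serialization, semantic validation, English
# description and printing of parsed queries.

# collect all LEAF conditions of a tree, depth-first, source order
.collect_leaves <- function(node) {
  if (is.null(node)) return(list())
  if (identical(node$kind, "LEAF")) return(list(node$cond))
  do.call(c, lapply(node$children, .collect_leaves))
}

.is_peak_condition <- function(type) type %in% c("MS1MZ", "MS2PREC", "MS2PROD", "MS2NL")

.is_var_value <- function(value) is.list(value) && identical(value$kind, "var")

# plain-decimal number formatting used by the canonical serializer
.fmt_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, digits = 15)
}

# canonical qualifier order in serialized text
.QUALIFIER_ORDER <- c("tolerance_mz", "tolerance_ppm", "intensity_value",
                      "intensity_percent", "intensity_tic_percent",
                      "intensity_match", "intensity_match_percent",
                      "mass_defect", "excluded")

.serialize_value <- function(type, value) {
  kind <- .CONDITION_VALUE_KIND[[type]]
  switch(kind,
    mz = if (.is_var_value(value)) {
      if (value$offset == 0) "X"
      else if (value$offset > 0) paste0("X+", .fmt_num(value$offset))
      else paste0("X-", .fmt_num(-value$offset))
    } else .fmt_num(value$mz),
    number = .fmt_num(value),
    polarity = value,
    range = sprintf("range(min=%s, max=%s)", .fmt_num(value[["min"]]), .fmt_num(value[["max"]]))
  )
}

.serialize_condition <- function(cond) {
  out <- paste0(cond$type, "=", .serialize_value(cond$type, cond$value))
  kw <- stats::setNames(names(.QUALIFIER_FIELDS), unname(.QUALIFIER_FIELDS))
  for (field in intersect(.QUALIFIER_ORDER, names(cond$qualifiers))) {
    v <- cond$qualifiers[[field]]
    out <- if (field == "excluded") {
      paste0(out, ":", kw[[field]])
    } else if (field == "mass_defect") {
      paste0(out, sprintf(":%s=massdefect(min=%s, max=%s)",
                          kw[[field]], .fmt_num(v[["min"]]), .fmt_num(v[["max"]])))
    } else {
      paste0(out, ":", kw[[field]], "=", .fmt_num(v))
    }
  }
  out
}

.serialize_node <- function(node, parent = "OR") {
  if (identical(node$kind, "LEAF")) return(.serialize_condition(node$cond))
  sep <- if (identical(node$kind, "AND")) " AND " else " OR "
  body <- paste(vapply(node$children, .serialize_node, character(1), parent = node$kind),
                collapse = sep)
  # minimal parentheses: an OR node nested under AND needs grouping
  if (identical(node$kind, "OR") && identical(parent, "AND")) paste0("(", body, ")") else body
}

#' Serialize a query to canonical text
#'
#' Produces a canonical textual form (upper-case keywords, fixed qualifier
#' order, minimal parentheses preserving grouping). Re-parsing the output
#' yields a structurally identical query.
#'
#' @param query A `massql_query` object.
#' @return A single query string.
#' @export
serialize_massql <- function(query) {
  stopifnot(inherits(query, "massql_query"))
  head <- sprintf("QUERY %s(%s)", query$fun, query$datatype)
  if (is.null(query$where)) head
  else paste(head, "WHERE", .serialize_node(query$where))
}

#' @export
format.massql_query <- function(x, ...) serialize_massql(x)

#' @export
print.massql_query <- function(x, ...) {
  cat("<massql query>\n")
  cat("  ", serialize_massql(x), "\n", sep = "")
  d <- validate_massql(x)
  if (nrow(d) > 0L) {
    cat("  diagnostics:\n")
    for (i in seq_len(nrow(d))) {
      cat(sprintf("    [%s] %s\n", d$level[i], d$message[i]))
    }
  }
  invisible(x)
}

# structural comparison helper used by round-trip tests: drop source text and
# character offsets, which legitimately differ after serialization
.strip_positions <- function(q) {
  strip_node <- function(node) {
    if (is.null(node)) return(NULL)
    if (identical(node$kind, "LEAF")) {
      node$cond$pos <- NULL
      return(node)
    }
    node$children <- lapply(node$children, strip_node)
    node
  }
  q$source <- NULL
  q$where <- strip_node(q$where)
  unclass(q)
}

.diag <- function(level, position, message) {
  data.frame(level = level, position = as.integer(position), message = message,
             stringsAsFactors = FALSE)
}

#' Validate a parsed query
#'
#' Checks semantic rules that the grammar alone cannot enforce: qualifier
#' applicability per condition type, mutual exclusivity of the Da and ppm
#' tolerances, retention-time range sanity, variable-anchor presence, and
#' data-level consistency (MS2-specific conditions require an MS2 query).
#'
#' @param query A `massql_query` object (typically from
#'   `parse_massql(text, check = FALSE)`).
#' @return A data frame of diagnostics with columns `level` (`"error"` or
#'   `"warning"`), `position` (character offset in the source) and `message`.
#'   Zero rows means the query is executable.
#' @export
validate_massql <- function(query) {
  stopifnot(inherits(query, "massql_query"))
  out <- .diag(character(0), integer(0), character(0))
  leaves <- .collect_leaves(query$where)

  for (cond in leaves) {
    pos <- if (is.null(cond$pos)) 1L else cond$pos
    for (field in names(cond$qualifiers)) {
      ok_types <- .QUALIFIER_APPLIES[[field]]
      if (!(cond$type %in% ok_types)) {
        out <- rbind(out, .diag("error", pos, sprintf(
          "qualifier %s does not apply to %s",
          names(.QUALIFIER_FIELDS)[.QUALIFIER_FIELDS == field], cond$type)))
      }
      if (field != "excluded" && field != "mass_defect") {
        if (any(cond$qualifiers[[field]] < 0)) {
          out <- rbind(out, .diag("error", pos, sprintf(
            "qualifier values must be non-negative on %s", cond$type)))
        }
      }
    }
    q <- cond$qualifiers
    if (!is.null(q$tolerance_mz) && !is.null(q$tolerance_ppm)) {
      out <- rbind(out, .diag("error", pos, sprintf(
        "TOLERANCEMZ and TOLERANCEPPM are mutually exclusive on %s", cond$type)))
    }
    if (!is.null(q$intensity_match) && is.null(q$intensity_match_percent)) {
      out <- rbind(out, .diag("error", pos,
        "INTENSITYMATCH requires INTENSITYMATCHPERCENT"))
    }
    if (!is.null(q$intensity_match_percent) && is.null(q$intensity_match)) {
      out <- rbind(out, .diag("error", pos,
        "INTENSITYMATCHPERCENT requires INTENSITYMATCH"))
    }
    if (!is.null(q$mass_defect) && q$mass_defect[["min"]] > q$mass_defect[["max"]]) {
      out <- rbind(out, .diag("error", pos, "mass defect range has min > max"))
    }
    if (cond$type == "MOBILITY" && cond$value[["min"]] > cond$value[["max"]]) {
      out <- rbind(out, .diag("error", pos, "mobility range has min > max"))
    }
    if (cond$type %in% c("MS2PREC", "MS2PROD", "MS2NL") && query$datatype != "MS2DATA") {
      out <- rbind(out, .diag("error", pos, sprintf(
        "%s requires an MS2DATA query", cond$type)))
    }
    if (cond$type == "CHARGE" && query$datatype != "MS2DATA") {
      out <- rbind(out, .diag("error", pos, "CHARGE requires an MS2DATA query"))
    }
  }

  rtmins <- Filter(function(c) c$type == "RTMIN", leaves)
  rtmaxs <- Filter(function(c) c$type == "RTMAX", leaves)
  if (length(rtmins) && length(rtmaxs)) {
    lo <- max(vapply(rtmins, function(c) c$value, numeric(1)))
    hi <- min(vapply(rtmaxs, function(c) c$value, numeric(1)))
    if (lo > hi) {
      out <- rbind(out, .diag("error", rtmins[[1L]]$pos,
        sprintf("RTMIN (%s) exceeds RTMAX (%s)", .fmt_num(lo), .fmt_num(hi))))
    }
  }

  var_leaves <- Filter(function(c) .is_var_value(c$value), leaves)
  if (length(var_leaves)) {
    anchors <- Filter(function(c) c$value$offset == 0, var_leaves)
    if (!length(anchors)) {
      out <- rbind(out, .diag("error", var_leaves[[1L]]$pos,
        "variable query lacks an anchor condition (an X term with zero offset)"))
    }
  } else {
    im <- Filter(function(c) !is.null(c$qualifiers$intensity_match), leaves)
    if (length(im)) {
      out <- rbind(out, .diag("error", im[[1L]]$pos,
        "INTENSITYMATCH requires a variable-anchored query"))
    }
  }

  out
}

.describe_tolerance <- function(q) {
  if (!is.null(q$tolerance_ppm)) sprintf(" (tolerance %s ppm)", .fmt_num(q$tolerance_ppm))
  else if (!is.null(q$tolerance_mz)) sprintf(" (tolerance %s Da)", .fmt_num(q$tolerance_mz))
  else ""
}

.describe_value <- function(value) {
  if (.is_var_value(value)) {
    if (value$offset == 0) "X"
    else if (value$offset > 0) paste0("X + ", .fmt_num(value$offset))
    else paste0("X - ", .fmt_num(-value$offset))
  } else .fmt_num(value$mz)
}

.describe_condition <- function(cond) {
  q <- cond$qualifiers
  neg <- isTRUE(q$excluded)
  noun <- switch(cond$type,
    MS1MZ = "an MS1 peak", MS2PROD = "a product ion",
    MS2PREC = "a precursor ion", MS2NL = "a neutral loss", NULL)
  if (!is.null(noun)) {
    s <- sprintf("%s %s at m/z %s%s",
                 if (neg) "do not contain" else "contain",
                 noun, .describe_value(cond$value), .describe_tolerance(q))
    extras <- character(0)
    if (!is.null(q$intensity_value)) {
      extras <- c(extras, sprintf("intensity at least %s", .fmt_num(q$intensity_value)))
    }
    if (!is.null(q$intensity_percent)) {
      extras <- c(extras, sprintf("intensity at least %s%% of the base peak",
                                  .fmt_num(q$intensity_percent)))
    }
    if (!is.null(q$intensity_tic_percent)) {
      extras <- c(extras, sprintf("intensity at least %s%% of the TIC",
                                  .fmt_num(q$intensity_tic_percent)))
    }
    if (!is.null(q$intensity_match)) {
      extras <- c(extras, sprintf(
        "expected intensity %s times the anchor peak (within %s%%)",
        .fmt_num(q$intensity_match), .fmt_num(q$intensity_match_percent)))
    }
    if (!is.null(q$mass_defect)) {
      extras <- c(extras, sprintf("mass defect between %s and %s",
                                  .fmt_num(q$mass_defect[["min"]]),
                                  .fmt_num(q$mass_defect[["max"]])))
    }
    if (length(extras)) s <- paste0(s, " with ", paste(extras, collapse = " and "))
    return(s)
  }
  switch(cond$type,
    CHARGE = sprintf("have precursor charge %s", .fmt_num(cond$value)),
    POLARITY = sprintf("were acquired in %s mode", tolower(cond$value)),
    RTMIN = sprintf("have retention time at least %s minutes", .fmt_num(cond$value)),
    RTMAX = sprintf("have retention time at most %s minutes", .fmt_num(cond$value)),
    SCANMIN = sprintf("have scan number at least %s", .fmt_num(cond$value)),
    SCANMAX = sprintf("have scan number at most %s", .fmt_num(cond$value)),
    MOBILITY = sprintf("have ion mobility between %s and %s",
                       .fmt_num(cond$value[["min"]]), .fmt_num(cond$value[["max"]]))
  )
}

.describe_node <- function(node, parent = "OR") {
  if (identical(node$kind, "LEAF")) return(.describe_condition(node$cond))
  sep <- if (identical(node$kind, "AND")) " and " else " or "
  body <- paste(vapply(node$children, .describe_node, character(1), parent = node$kind),
                collapse = sep)
  if (identical(node$kind, "OR") && identical(parent, "AND")) paste0("(", body, ")") else body
}

#' Describe a query in English
#'
#' Renders a deterministic English sentence naming the data level, each
#' condition with its tolerances and intensity constraints, and the Boolean
#' structure.
#'
#' @param query A `massql_query` object.
#' @return A single character string.
#' @examples
#' describe_massql(parse_massql("QUERY scaninfo(MS1DATA)"))
#' @export
describe_massql <- function(query) {
  stopifnot(inherits(query, "massql_query"))
  verb <- switch(query$fun,
    scaninfo = "Return information for",
    scannum = "Return the scan numbers of",
    scansum = "Return the summed matched intensity over")
  level <- if (query$datatype == "MS1DATA") "MS1 scans" else "MS2 scans"
  if (is.null(query$where)) {
    return(sprintf("%s all %s.", verb, level))
  }
  sprintf("%s all %s that %s.", verb, level, .describe_node(query$where))
}
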