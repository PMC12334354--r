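# Query engine: evaluates a parsed query against a peak table.
#
# Semantics in brief: a scan of the query's data level is retained when its
# condition tree evaluates true under at least one variable binding. AND
# across peak conditions means "same scan, each condition satisfied by at
# least one (possibly different) peak", under a single consistent binding of
# the variable X when one is used. A peak satisfies an m/z condition when it
# falls within the condition's tolerance window (Da tolerance, ppm tolerance
# computed on the target m/z, or the configured default) and passes every
# intensity/mass-defect qualifier. EXCLUDED retains scans with zero matching
# peaks, qualifiers applied first. All range comparisons are inclusive.

#' Engine configuration
#'
#' @param default_tolerance_mz m/z half-window in Da applied when a condition
#'   names neither `TOLERANCEMZ` nor `TOLERANCEPPM`. Default 0.1 Da.
#' @return An object of class `"massql_config"`.
#' @export
execution_config <- function(default_tolerance_mz = 0.1) {
  stopifnot(is.numeric(default_tolerance_mz), default_tolerance_mz > 0)
  structure(list(default_tolerance_mz = default_tolerance_mz),
            class = "massql_config")
}

.resolve_target <- function(value, binding) {
  if (!.is_var_value(value)) return(value$mz)
  if (is.null(binding)) {
    stop("variable m/z expression evaluated without a binding", call. = FALSE)
  }
  binding$X + value$offset
}

.mz_tolerance <- function(target, qualifiers, config) {
  if (!is.null(qualifiers$tolerance_mz)) qualifiers$tolerance_mz
  else if (!is.null(qualifiers$tolerance_ppm)) qualifiers$tolerance_ppm * target * 1e-6
  else config$default_tolerance_mz
}

# qualifier checks that do not depend on the target m/z
.intrinsic_mask <- function(peaks, qualifiers) {
  m <- rep(TRUE, nrow(peaks))
  q <- qualifiers
  if (!is.null(q$intensity_value)) m <- m & peaks$i >= q$intensity_value
  if (!is.null(q$intensity_percent)) m <- m & peaks$i_norm >= q$intensity_percent / 100
  if (!is.null(q$intensity_tic_percent)) m <- m & peaks$i_tic_norm >= q$intensity_tic_percent / 100
  if (!is.null(q$mass_defect)) {
    frac <- peaks$mz - floor(peaks$mz)
    m <- m & frac >= q$mass_defect[["min"]] & frac <= q$mass_defect[["max"]]
  }
  m & !is.na(m)
}

#' Match peaks against one m/z condition
#'
#' A peak matches when `|mz - target| <= tol` (with `tol` the Da tolerance,
#' the ppm tolerance computed on the target m/z, or the configured default)
#' and every intensity and mass-defect qualifier holds; when
#' `INTENSITYMATCH = r` is set, additionally `|i / Y - r| <= r * p / 100`
#' where `Y` is the anchor-peak intensity of the supplied binding and `p` is
#' `INTENSITYMATCHPERCENT`.
#'
#' @param peaks Data frame with columns `mz`, `i`, `i_norm`, `i_tic_norm`.
#' @param target Target m/z: a number, or a value expression from a parsed
#'   condition (resolved against `binding` when it involves X).
#' @param qualifiers Named list of qualifier values (as stored on a parsed
#'   condition).
#' @param config An [execution_config()].
#' @param binding Optional list with elements `X` (anchor m/z) and `Y`
#'   (anchor intensity); required for variable targets or `INTENSITYMATCH`.
#' @return Logical vector, one element per peak row.
#' @export
peak_matches <- function(peaks, target, qualifiers = list(),
                         config = execution_config(), binding = NULL) {
  if (is.list(target)) target <- .resolve_target(target, binding)
  stopifnot(is.numeric(target), length(target) == 1L)
  if (nrow(peaks) == 0L) return(logical(0))
  tol <- .mz_tolerance(target, qualifiers, config)
  m <- abs(peaks$mz - target) <= tol
  m <- m & .intrinsic_mask(peaks, qualifiers)
  if (!is.null(qualifiers$intensity_match)) {
    if (is.null(binding)) {
      stop("INTENSITYMATCH requires an anchor binding", call. = FALSE)
    }
    r <- qualifiers$intensity_match
    p <- qualifiers$intensity_match_percent
    m <- m & abs(peaks$i / binding$Y - r) <= r * p / 100
  }
  m & !is.na(m)
}

# per-scan metadata comparison for one condition; meta is a one-row list
.metadata_ok <- function(cond, meta) {
  v <- cond$value
  ok <- switch(cond$type,
    RTMIN = meta$rt >= v,
    RTMAX = meta$rt <= v,
    SCANMIN = meta$scan >= v,
    SCANMAX = meta$scan <= v,
    POLARITY = meta$polarity == (if (v == "Positive") 1L else -1L),
    CHARGE = !is.null(meta$charge) && !is.na(meta$charge) && abs(meta$charge) == v,
    MOBILITY = !is.na(meta$mobility) &&
      meta$mobility >= v[["min"]] && meta$mobility <= v[["max"]]
  )
  isTRUE(ok)
}

.META_TYPES <- c("RTMIN", "RTMAX", "SCANMIN", "SCANMAX", "POLARITY", "CHARGE", "MOBILITY")

# Scan context: peaks (target-level), meta (scalars), ms1peaks (linked MS1
# peaks for MS2-level queries; zero-row frame when absent).
.leaf_peaks <- function(cond, ctx, level) {
  switch(cond$type,
    MS1MZ = if (level == 1L) ctx$peaks else ctx$ms1peaks,
    MS2PROD = ctx$peaks,
    MS2NL = ctx$peaks,
    MS2PREC = data.frame(mz = ctx$meta$precmz, i = NA_real_,
                         i_norm = NA_real_, i_tic_norm = NA_real_)
  )
}

.eval_leaf <- function(cond, ctx, level, binding, config, acc) {
  if (cond$type %in% .META_TYPES) return(.metadata_ok(cond, ctx$meta))
  peaks <- .leaf_peaks(cond, ctx, level)
  target <- if (cond$type == "MS2NL") {
    ctx$meta$precmz - .resolve_target(cond$value, binding)
  } else {
    .resolve_target(cond$value, binding)
  }
  m <- peak_matches(peaks, target, cond$qualifiers, config, binding)
  if (isTRUE(cond$qualifiers$excluded)) return(!any(m))
  if (!any(m)) return(FALSE)
  hit <- peaks$i[m]
  hit <- hit[!is.na(hit)]
  if (length(hit)) acc$matched <- c(acc$matched, max(hit))
  TRUE
}

.eval_node <- function(node, ctx, level, binding, config, acc) {
  if (identical(node$kind, "LEAF")) {
    return(.eval_leaf(node$cond, ctx, level, binding, config, acc))
  }
  vals <- vapply(node$children, .eval_node, logical(1),
                 ctx = ctx, level = level, binding = binding,
                 config = config, acc = acc)
  if (identical(node$kind, "AND")) all(vals) else any(vals)
}

.empty_result <- function(has_var, fun) {
  df <- data.frame(file_id = character(0), scan = integer(0), rt = numeric(0),
                   polarity = integer(0), mslevel = integer(0),
                   precmz = numeric(0), charge = integer(0),
                   ms1scan = integer(0), matched_intensity = numeric(0),
                   stringsAsFactors = FALSE)
  if (has_var) { df$X <- numeric(0); df$Y <- numeric(0) }
  if (fun == "scannum") df <- df[, c("file_id", "scan")]
  if (fun == "scansum") {
    df <- data.frame(file_id = character(0), n_scans = integer(0),
                     total_intensity = numeric(0), stringsAsFactors = FALSE)
  }
  class(df) <- c("massql_result", "data.frame")
  df
}

#' Execute a query over a peak table
#'
#' Returns every scan of the query's data level whose condition tree holds
#' under at least one binding of the variable X (one result row per
#' scan/binding for variable queries). The output function controls the
#' shape: `scaninfo` returns scan metadata rows, `scannum` returns scan
#' identifiers, and `scansum` returns one row per file with the number of
#' retained scans and their summed matched intensity.
#'
#' @param query Query text or a `massql_query` from [parse_massql()].
#' @param table A `massql_peaks` object.
#' @param config An [execution_config()].
#' @return A data frame of class `"massql_result"`, sorted by
#'   `(file_id, scan, X)`. Metadata rows carry `rt` (minutes), `polarity`,
#'   `mslevel`, `precmz`/`charge`/`ms1scan` (MS2 level), `matched_intensity`
#'   (intensity of the most intense condition-matching peak) and, for
#'   variable queries, the bound anchor m/z `X` and anchor intensity `Y`.
#' @examples
#' tb <- peak_table(ms2 = data.frame(
#'   file_id = "a", scan = 1L, mz = c(98.9847, 150), i = c(80, 100),
#'   rt = 1, polarity = 1L, precmz = 300.1, charge = 1L))
#' execute_query(
#'   "QUERY scaninfo(MS2DATA) WHERE MS2PROD=98.9847:TOLERANCEPPM=50:INTENSITYPERCENT=50",
#'   tb)
#' @export
execute_query <- function(query, table, config = execution_config()) {
  if (is.character(query)) query <- parse_massql(query)
  stopifnot(inherits(query, "massql_query"), inherits(table, "massql_peaks"),
            inherits(config, "massql_config"))
  d <- validate_massql(query)
  if (any(d$level == "error")) {
    stop("invalid query: ", d$message[d$level == "error"][1], call. = FALSE)
  }

  level <- if (query$datatype == "MS1DATA") 1L else 2L
  df <- if (level == 1L) table$ms1 else table$ms2
  leaves <- .collect_leaves(query$where)
  var_leaves <- Filter(function(c) .is_var_value(c$value), leaves)
  has_var <- length(var_leaves) > 0L
  if (nrow(df) == 0L) return(.empty_result(has_var, query$fun))

  ms1_index <- if (level == 2L && any(vapply(leaves, function(c) c$type == "MS1MZ", logical(1)))) {
    split(table$ms1, paste(table$ms1$file_id, table$ms1$scan, sep = "\r"))
  } else NULL
  empty_peaks <- .empty_peak_df(.MS1_COLS)

  anchor <- if (has_var) Filter(function(c) c$value$offset == 0, var_leaves)[[1]] else NULL

  rows <- list()
  for (grp in .split_scans(df)) {
    meta <- list(
      file_id = grp$file_id[1], scan = grp$scan[1], rt = grp$rt[1],
      polarity = grp$polarity[1], mobility = grp$mobility[1],
      precmz = if (level == 2L) grp$precmz[1] else NA_real_,
      charge = if (level == 2L) grp$charge[1] else NA_integer_,
      ms1scan = if (level == 2L) grp$ms1scan[1] else NA_integer_
    )
    ctx <- list(peaks = grp, meta = meta, ms1peaks = empty_peaks)
    if (!is.null(ms1_index) && !is.na(meta$ms1scan)) {
      linked <- ms1_index[[paste(meta$file_id, meta$ms1scan, sep = "\r")]]
      if (!is.null(linked)) ctx$ms1peaks <- linked
    }

    emit <- function(binding, matched) {
      row <- data.frame(
        file_id = meta$file_id, scan = meta$scan, rt = meta$rt,
        polarity = meta$polarity, mslevel = level, precmz = meta$precmz,
        charge = meta$charge, ms1scan = meta$ms1scan,
        matched_intensity = if (length(matched)) max(matched) else NA_real_,
        stringsAsFactors = FALSE
      )
      if (has_var) { row$X <- binding$X; row$Y <- binding$Y }
      rows[[length(rows) + 1L]] <<- row
    }

    if (!has_var) {
      acc <- new.env(parent = emptyenv()); acc$matched <- numeric(0)
      ok <- if (is.null(query$where)) TRUE
            else .eval_node(query$where, ctx, level, NULL, config, acc)
      if (ok) emit(NULL, acc$matched)
    } else {
      cand <- .leaf_peaks(anchor, ctx, level)
      keep <- .intrinsic_mask(cand, anchor$qualifiers)
      cand <- cand[keep, , drop = FALSE]
      cand <- cand[!duplicated(cand$mz), , drop = FALSE]
      cand <- cand[order(cand$mz), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        binding <- list(X = cand$mz[k], Y = cand$i[k])
        acc <- new.env(parent = emptyenv()); acc$matched <- numeric(0)
        if (.eval_node(query$where, ctx, level, binding, config, acc)) {
          emit(binding, acc$matched)
        }
      }
    }
  }

  if (length(rows) == 0L) return(.empty_result(has_var, query$fun))
  res <- do.call(rbind, rows)
  ord <- if (has_var) order(res$file_id, res$scan, res$X) else order(res$file_id, res$scan)
  res <- res[ord, , drop = FALSE]
  if (has_var) res <- res[!duplicated(res[, c("file_id", "scan", "X")]), , drop = FALSE]
  rownames(res) <- NULL

  if (query$fun == "scannum") {
    res <- unique(res[, c("file_id", "scan")])
    rownames(res) <- NULL
  } else if (query$fun == "scansum") {
    per_scan <- res[!duplicated(res[, c("file_id", "scan")]), , drop = FALSE]
    agg <- stats::aggregate(
      cbind(total_intensity = ifelse(is.na(per_scan$matched_intensity), 0,
                                     per_scan$matched_intensity)) ~ file_id,
      data = per_scan, FUN = sum)
    cnt <- stats::aggregate(cbind(n_scans = per_scan$scan) ~ file_id,
                            data = per_scan, FUN = length)
    res <- merge(cnt, agg, by = "file_id", sort = TRUE)
  }
  class(res) <- c("massql_result", "data.frame")
  attr(res, "query") <- serialize_massql(query)
  res
}

#' Enumerate variable bindings for one scan
#'
#' Candidate values of X are the m/z of peaks matching the anchor condition's
#' intrinsic qualifiers (the anchor is the X term with zero offset); a
#' binding is emitted when every variable condition has at least one matching
#' peak under it. Bindings are sorted by X ascending.
#'
#' @param peaks Data frame of one scan's peaks (`mz`, `i`, `i_norm`,
#'   `i_tic_norm`).
#' @param conditions List of parsed conditions with variable-valued m/z
#'   expressions, one of which must be the anchor.
#' @param config An [execution_config()].
#' @return Data frame with columns `X` and `Y`.
#' @export
enumerate_bindings <- function(peaks, conditions, config = execution_config()) {
  var_conds <- Filter(function(c) .is_var_value(c$value), conditions)
  anchors <- Filter(function(c) c$value$offset == 0, var_conds)
  if (!length(anchors)) stop("no anchor condition (X with zero offset)", call. = FALSE)
  anchor <- anchors[[1]]
  cand <- peaks[.intrinsic_mask(peaks, anchor$qualifiers), , drop = FALSE]
  cand <- cand[!duplicated(cand$mz), , drop = FALSE]
  cand <- cand[order(cand$mz), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    binding <- list(X = cand$mz[k], Y = cand$i[k])
    keep[k] <- all(vapply(var_conds, function(cond) {
      any(peak_matches(peaks, cond$value, cond$qualifiers, config, binding))
    }, logical(1)))
  }
  data.frame(X = cand$mz[keep], Y = cand$i[keep])
}

#' Filter scans on metadata conditions
#'
#' Applies retention-time, scan-number, polarity, charge and mobility
#' conditions (all bounds inclusive; charge compared as absolute value) and
#' returns the retained scan keys.
#'
#' @param conditions A `massql_query`, or a list of parsed metadata
#'   conditions combined with AND.
#' @param table A `massql_peaks` object.
#' @param datatype `"MS1DATA"` or `"MS2DATA"`; ignored when `conditions` is a
#'   query.
#' @return Data frame with columns `file_id` and `scan`.
#' @export
filter_metadata <- function(conditions, table, datatype = "MS1DATA") {
  if (inherits(conditions, "massql_query")) {
    datatype <- conditions$datatype
    conditions <- Filter(function(c) c$type %in% .META_TYPES,
                         .collect_leaves(conditions$where))
  }
  level <- if (datatype == "MS1DATA") 1L else 2L
  df <- if (level == 1L) table$ms1 else table$ms2
  out <- list()
  for (grp in .split_scans(df)) {
    meta <- list(scan = grp$scan[1], rt = grp$rt[1], polarity = grp$polarity[1],
                 mobility = grp$mobility[1],
                 charge = if (level == 2L) grp$charge[1] else NA_integer_)
    if (all(vapply(conditions, .metadata_ok, logical(1), meta = meta))) {
      out[[length(out) + 1L]] <- data.frame(file_id = grp$file_id[1],
                                            scan = grp$scan[1],
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(file_id = character(0), scan = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$file_id, res$scan), , drop = FALSE]
}

#' Apply an EXCLUDED condition
#'
#' A scan is retained when zero peaks match the condition, all non-EXCLUDED
#' qualifiers applied first (so a peak below an intensity threshold does not
#' count as a match).
#'
#' @param condition A parsed peak condition (the `excluded` flag itself is
#'   ignored here; retention is always by absence of matches).
#' @param table A `massql_peaks` object.
#' @param datatype `"MS1DATA"` or `"MS2DATA"`.
#' @param config An [execution_config()].
#' @return Data frame with columns `file_id` and `scan`.
#' @export
apply_excluded <- function(condition, table, datatype = "MS1DATA",
                           config = execution_config()) {
  level <- if (datatype == "MS1DATA") 1L else 2L
  df <- if (level == 1L) table$ms1 else table$ms2
  out <- list()
  for (grp in .split_scans(df)) {
    target <- if (condition$type == "MS2NL") grp$precmz[1] - condition$value$mz
              else condition$value$mz
    peaks <- if (condition$type == "MS2PREC") {
      data.frame(mz = grp$precmz[1], i = NA_real_, i_norm = NA_real_,
                 i_tic_norm = NA_real_)
    } else grp
    q <- condition$qualifiers
    q$excluded <- NULL
    if (!any(peak_matches(peaks, target, q, config))) {
      out[[length(out) + 1L]] <- data.frame(file_id = grp$file_id[1],
                                            scan = grp$scan[1],
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(file_id = character(0), scan = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$file_id, res$scan), , drop = FALSE]
}
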