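# Naive brute-force query evaluator, independent of the engine's vectorized
# path: scalar loops over scans x peaks x conditions x candidate bindings.
# Used as the oracle for engine-equivalence checks.

oracle_execute <- function(query, table, default_tol = 0.1) {
  q <- if (is.character(query)) parse_massql(query) else query
  level <- if (q$datatype == "MS1DATA") "ms1" else "ms2"
  df <- table[[level]]
  leaves <- massql:::.collect_leaves(q$where)
  has_var <- any(vapply(leaves, function(c) is.list(c$value) &&
                          identical(c$value$kind, "var"), logical(1)))

  scalar_match <- function(pmz, pi, pinorm, pitic, target, qual, Y) {
    tol <- if (!is.null(qual$tolerance_mz)) qual$tolerance_mz
           else if (!is.null(qual$tolerance_ppm)) qual$tolerance_ppm * target * 1e-6
           else default_tol
    if (abs(pmz - target) > tol) return(FALSE)
    if (!is.null(qual$intensity_value) && !(pi >= qual$intensity_value)) return(FALSE)
    if (!is.null(qual$intensity_percent) && !(pinorm >= qual$intensity_percent / 100)) return(FALSE)
    if (!is.null(qual$intensity_tic_percent) && !(pitic >= qual$intensity_tic_percent / 100)) return(FALSE)
    if (!is.null(qual$mass_defect)) {
      fr <- pmz - floor(pmz)
      if (fr < qual$mass_defect[["min"]] || fr > qual$mass_defect[["max"]]) return(FALSE)
    }
    if (!is.null(qual$intensity_match)) {
      r <- qual$intensity_match
      if (abs(pi / Y - r) > r * qual$intensity_match_percent / 100) return(FALSE)
    }
    TRUE
  }

  out <- list()
  keys <- unique(df[, c("file_id", "scan")])
  for (rr in seq_len(nrow(keys))) {
    fid <- keys$file_id[rr]; sc <- keys$scan[rr]
    sp <- df[df$file_id == fid & df$scan == sc, , drop = FALSE]
    linked <- if (level == "ms2") {
      lk <- sp$ms1scan[1]
      if (!is.na(lk)) table$ms1[table$ms1$file_id == fid & table$ms1$scan == lk, , drop = FALSE]
      else table$ms1[0, , drop = FALSE]
    } else NULL

    leaf_ok <- function(cond, Xv, Yv) {
      meta_scan <- sp[1, ]
      if (cond$type %in% c("RTMIN", "RTMAX", "SCANMIN", "SCANMAX",
                           "POLARITY", "CHARGE", "MOBILITY")) {
        v <- cond$value
        return(switch(cond$type,
          RTMIN = meta_scan$rt >= v, RTMAX = meta_scan$rt <= v,
          SCANMIN = sc >= v, SCANMAX = sc <= v,
          POLARITY = meta_scan$polarity == (if (v == "Positive") 1L else -1L),
          CHARGE = !is.na(meta_scan$charge) && abs(meta_scan$charge) == v,
          MOBILITY = !is.na(meta_scan$mobility) &&
            meta_scan$mobility >= v[["min"]] && meta_scan$mobility <= v[["max"]]))
      }
      resolve <- function(val) {
        if (is.list(val) && identical(val$kind, "var")) Xv + val$offset else val$mz
      }
      target <- if (cond$type == "MS2NL") sp$precmz[1] - resolve(cond$value)
                else resolve(cond$value)
      pk <- switch(cond$type,
        MS1MZ = if (level == "ms1") sp else linked,
        MS2PROD = sp, MS2NL = sp,
        MS2PREC = data.frame(mz = sp$precmz[1], i = NA_real_,
                             i_norm = NA_real_, i_tic_norm = NA_real_))
      n_match <- 0L
      for (p in seq_len(nrow(pk))) {
        hit <- scalar_match(pk$mz[p], pk$i[p], pk$i_norm[p], pk$i_tic_norm[p],
                            target, cond$qualifiers, Yv)
        if (isTRUE(hit)) n_match <- n_match + 1L
      }
      if (isTRUE(cond$qualifiers$excluded)) n_match == 0L else n_match > 0L
    }

    node_ok <- function(node, Xv, Yv) {
      if (identical(node$kind, "LEAF")) return(leaf_ok(node$cond, Xv, Yv))
      vals <- vapply(node$children, function(ch) node_ok(ch, Xv, Yv), logical(1))
      if (identical(node$kind, "AND")) all(vals) else any(vals)
    }

    if (!has_var) {
      ok <- if (is.null(q$where)) TRUE else node_ok(q$where, NA, NA)
      if (ok) out[[length(out) + 1L]] <- data.frame(file_id = fid, scan = sc,
                                                    stringsAsFactors = FALSE)
    } else {
      anchor <- NULL
      for (cond in leaves) {
        if (is.list(cond$value) && identical(cond$value$kind, "var") &&
            cond$value$offset == 0) { anchor <- cond; break }
      }
      apeaks <- switch(anchor$type,
        MS1MZ = if (level == "ms1") sp else linked, MS2PROD = sp)
      seen <- numeric(0)
      for (p in seq_len(nrow(apeaks))) {
        X <- apeaks$mz[p]; Y <- apeaks$i[p]
        if (X %in% seen) next
        q2 <- anchor$qualifiers
        intrinsic <- scalar_match(X, Y, apeaks$i_norm[p], apeaks$i_tic_norm[p],
                                  X, q2[setdiff(names(q2),
                                  c("tolerance_mz", "tolerance_ppm",
                                    "intensity_match", "intensity_match_percent",
                                    "excluded"))], NA)
        if (!intrinsic) next
        seen <- c(seen, X)
        if (node_ok(q$where, X, Y)) {
          out[[length(out) + 1L]] <- data.frame(file_id = fid, scan = sc, X = X,
                                                stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(file_id = character(0), scan = integer(0))
    if (has_var) res$X <- numeric(0)
    return(res)
  }
  res <- do.call(rbind, out)
  ord <- if (has_var) order(res$file_id, res$scan, res$X) else order(res$file_id, res$scan)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# set comparison of engine output vs oracle output
expect_engine_matches_oracle <- function(query, table, config = execution_config()) {
  eng <- execute_query(query, table, config)
  orc <- oracle_execute(query, table, default_tol = config$default_tolerance_mz)
  cols <- intersect(c("file_id", "scan", "X"), intersect(names(orc), names(eng)))
  if (!length(cols)) cols <- c("file_id", "scan")
  eng_keys <- if (nrow(eng)) do.call(paste, c(eng[cols], sep = "|")) else character(0)
  orc_keys <- if (nrow(orc)) do.call(paste, c(orc[cols], sep = "|")) else character(0)
  expect_setequal(eng_keys, orc_keys)
  invisible(length(orc_keys))
}
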