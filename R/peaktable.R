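# Columnar peak-table container: one data frame per MS level, with per-scan
# base-peak- and TIC-normalized intensities.

.MS1_COLS <- c(file_id = "character", scan = "integer", mz = "double",
               i = "double", i_norm = "double", i_tic_norm = "double",
               rt = "double", polarity = "integer", mobility = "double")
.MS2_COLS <- c(.MS1_COLS, precmz = "double", charge = "integer", ms1scan = "integer")

.empty_peak_df <- function(cols) {
  out <- lapply(cols, function(tp) vector(tp, 0L))
  as.data.frame(out, stringsAsFactors = FALSE)
}

# recompute i_norm / i_tic_norm per (file_id, scan)
.normalize_scans <- function(df) {
  if (nrow(df) == 0L) return(df)
  key <- paste(df$file_id, df$scan, sep = "\r")
  mx <- stats::ave(df$i, key, FUN = max)
  tic <- stats::ave(df$i, key, FUN = sum)
  df$i_norm <- ifelse(mx > 0, df$i / mx, 0)
  df$i_tic_norm <- ifelse(tic > 0, df$i / tic, 0)
  df
}

.coerce_peak_df <- function(df, cols, what) {
  if (is.null(df)) df <- .empty_peak_df(cols)
  missing_cols <- setdiff(names(cols), names(df))
  for (nm in missing_cols) {
    df[[nm]] <- vector(cols[[nm]], 1L)[0][rep(NA, nrow(df))]
    if (nm %in% c("i_norm", "i_tic_norm")) df[[nm]] <- rep(NA_real_, nrow(df))
  }
  df <- df[, names(cols), drop = FALSE]
  df$file_id <- as.character(df$file_id)
  df$scan <- as.integer(df$scan)
  for (nm in names(cols)[cols == "double"]) df[[nm]] <- as.numeric(df[[nm]])
  df$polarity <- as.integer(df$polarity)
  if ("charge" %in% names(df)) df$charge <- as.integer(df$charge)
  if ("ms1scan" %in% names(df)) df$ms1scan <- as.integer(df$ms1scan)
  if (nrow(df) > 0L) {
    if (any(is.na(df$mz)) || any(df$mz <= 0)) stop(what, ": mz must be positive", call. = FALSE)
    if (any(df$i < 0)) stop(what, ": intensities must be non-negative", call. = FALSE)
  }
  if (anyNA(df$i_norm) || anyNA(df$i_tic_norm)) df <- .normalize_scans(df)
  rownames(df) <- NULL
  df
}

#' Construct a peak table
#'
#' A peak table holds centroided peaks of one or more files in two data
#' frames, `ms1` and `ms2`, with columns `file_id`, `scan`, `mz`, `i`,
#' `i_norm` (fraction of the scan base peak), `i_tic_norm` (fraction of the
#' scan TIC), `rt` (minutes), `polarity` (+1/-1) and `mobility`; `ms2`
#' additionally carries `precmz`, `charge` and `ms1scan` (the most recent
#' preceding MS1 scan, `NA` if none). Normalized columns are recomputed when
#' absent.
#'
#' @param ms1,ms2 Data frames (may be `NULL` for empty).
#' @return An object of class `"massql_peaks"`.
#' @export
peak_table <- function(ms1 = NULL, ms2 = NULL) {
  out <- structure(
    list(ms1 = .coerce_peak_df(ms1, .MS1_COLS, "ms1"),
         ms2 = .coerce_peak_df(ms2, .MS2_COLS, "ms2")),
    class = "massql_peaks"
  )
  if (nrow(out$ms2) > 0L && any(is.na(out$ms2$precmz) | out$ms2$precmz <= 0)) {
    stop("ms2: precmz must be positive", call. = FALSE)
  }
  out
}

#' @export
print.massql_peaks <- function(x, ...) {
  n1 <- length(unique(paste(x$ms1$file_id, x$ms1$scan)))
  n2 <- length(unique(paste(x$ms2$file_id, x$ms2$scan)))
  cat(sprintf("<peak table: %d MS1 scan(s) / %d peaks; %d MS2 scan(s) / %d peaks; %d file(s)>\n",
              n1, nrow(x$ms1), n2, nrow(x$ms2),
              length(unique(c(x$ms1$file_id, x$ms2$file_id)))))
  invisible(x)
}

# rbind the per-level frames of several peak tables
.bind_peak_tables <- function(tables) {
  peak_table(
    ms1 = do.call(rbind, lapply(tables, `[[`, "ms1")),
    ms2 = do.call(rbind, lapply(tables, `[[`, "ms2"))
  )
}
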