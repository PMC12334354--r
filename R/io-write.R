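# Writers: result tables as TSV/JSON; retrieved spectra as MGF, mzML or JSON.

#' Write a result table
#'
#' @param result A data frame, typically a `massql_result` from
#'   [execute_query()].
#' @param path Output file path.
#' @param format `"tsv"` (header row, tab-separated, stable column order) or
#'   `"json"` (array of row objects). Numbers are written at full precision.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(result))
  df <- as.data.frame(result)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA, na = "null")
  }
  invisible(path)
}

# Resolve a scan selection to data.frame(file_id, scan). Accepts a data frame
# carrying file_id/scan columns (e.g. a result table) or an integer vector
# (applied to every file in the table).
.resolve_selection <- function(table, scans) {
  if (is.data.frame(scans)) {
    stopifnot(all(c("file_id", "scan") %in% names(scans)))
    sel <- unique(scans[, c("file_id", "scan")])
  } else {
    fids <- unique(c(table$ms1$file_id, table$ms2$file_id))
    sel <- expand.grid(file_id = fids, scan = as.integer(scans),
                       stringsAsFactors = FALSE)
  }
  sel$scan <- as.integer(sel$scan)
  known <- unique(rbind(table$ms1[, c("file_id", "scan")],
                        table$ms2[, c("file_id", "scan")]))
  missing <- !(paste(sel$file_id, sel$scan) %in% paste(known$file_id, known$scan))
  if (any(missing)) {
    stop("selection includes scan(s) absent from the peak table: ",
         paste(sel$scan[missing], collapse = ", "), call. = FALSE)
  }
  sel
}

.split_scans <- function(df) {
  if (nrow(df) == 0L) return(list())
  split(df, paste(df$file_id, df$scan, sep = "\r"))
}

#' Export selected spectra
#'
#' Writes the selected scans to MGF, mzML or JSON. MGF carries MS2 spectra
#' only (one `BEGIN IONS` block per scan, with precursor m/z, charge,
#' retention time and scan number); mzML and JSON carry both MS levels.
#' An empty selection produces an empty but valid file.
#'
#' @param table A `massql_peaks` object.
#' @param scans Selection: a data frame with `file_id`/`scan` columns or an
#'   integer vector of scan numbers.
#' @param path Output path.
#' @param format `"mgf"`, `"mzml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_spectra <- function(table, scans, path, format = c("mgf", "mzml", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "massql_peaks"))
  sel <- .resolve_selection(table, scans)
  keys <- paste(sel$file_id, sel$scan)
  ms1 <- table$ms1[paste(table$ms1$file_id, table$ms1$scan) %in% keys, , drop = FALSE]
  ms2 <- table$ms2[paste(table$ms2$file_id, table$ms2$scan) %in% keys, , drop = FALSE]
  switch(format,
    mgf = .write_mgf(ms2, path),
    mzml = .write_mzml(ms1, ms2, path),
    json = .write_spectra_json(ms1, ms2, path)
  )
  invisible(path)
}

.write_mgf <- function(ms2, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (grp in .split_scans(ms2)) {
    g <- grp[order(grp$mz), , drop = FALSE]
    writeLines(c(
      "BEGIN IONS",
      sprintf("TITLE=%s scan=%d", g$file_id[1], g$scan[1]),
      sprintf("PEPMASS=%.*g", 12, g$precmz[1]),
      sprintf("CHARGE=%d%s", abs(g$charge[1]), if (g$charge[1] < 0) "-" else "+"),
      sprintf("RTINSECONDS=%.*g", 12, g$rt[1] * 60),
      sprintf("SCANS=%d", g$scan[1]),
      sprintf("%.*g %.*g", 12, g$mz, 12, g$i),
      "END IONS", ""
    ), con)
  }
  invisible(path)
}

# assemble the full mzR header data frame mzR::writeMSData expects
.mzr_header <- function(n) {
  data.frame(
    seqNum = integer(n), acquisitionNum = integer(n), msLevel = integer(n),
    polarity = integer(n), peaksCount = integer(n), totIonCurrent = numeric(n),
    retentionTime = numeric(n), basePeakMZ = numeric(n),
    basePeakIntensity = numeric(n), collisionEnergy = rep(NA_real_, n),
    ionisationEnergy = numeric(n), lowMZ = numeric(n), highMZ = numeric(n),
    precursorScanNum = rep(NA_integer_, n), precursorMZ = rep(NA_real_, n),
    precursorCharge = rep(NA_integer_, n), precursorIntensity = rep(NA_real_, n),
    mergedScan = rep(NA_integer_, n), mergedResultScanNum = rep(NA_integer_, n),
    mergedResultStartScanNum = rep(NA_integer_, n),
    mergedResultEndScanNum = rep(NA_integer_, n), injectionTime = numeric(n),
    filterString = rep(NA_character_, n), spectrumId = character(n),
    centroided = rep(TRUE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(NA_real_, n), scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
}

.write_mzml <- function(ms1, ms2, path) {
  groups <- c(
    lapply(.split_scans(ms1), function(g) list(level = 1L, df = g)),
    lapply(.split_scans(ms2), function(g) list(level = 2L, df = g))
  )
  if (length(groups) == 0L) {
    # empty but well-formed: write a header-only mzML via mzR is not possible,
    # so emit a minimal valid document directly
    writeLines(paste0(
      '<?xml version="1.0" encoding="utf-8"?>\n',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
      '<run id="empty"><spectrumList count="0"></spectrumList></run>\n</mzML>'), path)
    return(invisible(path))
  }
  # acquisition order: sort by (file, scan) with MS level interleaved by scan
  ord <- order(vapply(groups, function(g) g$df$file_id[1], character(1)),
               vapply(groups, function(g) g$df$scan[1], integer(1)))
  groups <- groups[ord]
  n <- length(groups)
  hdr <- .mzr_header(n)
  pks <- vector("list", n)
  scans <- vapply(groups, function(g) g$df$scan[1], integer(1))
  renumber <- anyDuplicated(scans) > 0L
  acq <- if (renumber) seq_len(n) else scans
  for (k in seq_len(n)) {
    g <- groups[[k]]$df[order(groups[[k]]$df$mz), , drop = FALSE]
    lvl <- groups[[k]]$level
    hdr$seqNum[k] <- k
    hdr$acquisitionNum[k] <- acq[k]
    hdr$msLevel[k] <- lvl
    hdr$polarity[k] <- if (g$polarity[1] < 0) 0L else 1L
    hdr$peaksCount[k] <- nrow(g)
    hdr$totIonCurrent[k] <- sum(g$i)
    hdr$retentionTime[k] <- g$rt[1] * 60
    hdr$basePeakMZ[k] <- g$mz[which.max(g$i)]
    hdr$basePeakIntensity[k] <- max(g$i)
    hdr$lowMZ[k] <- min(g$mz)
    hdr$highMZ[k] <- max(g$mz)
    hdr$spectrumId[k] <- sprintf("scan=%d", acq[k])
    if (lvl == 2L) {
      hdr$precursorMZ[k] <- g$precmz[1]
      hdr$precursorCharge[k] <- abs(g$charge[1])
      hdr$precursorIntensity[k] <- 0
      if (!is.na(g$ms1scan[1]) && !renumber) hdr$precursorScanNum[k] <- g$ms1scan[1]
      hdr$isolationWindowTargetMZ[k] <- g$precmz[1]
      hdr$isolationWindowLowerOffset[k] <- 0.5
      hdr$isolationWindowUpperOffset[k] <- 0.5
    }
    pks[[k]] <- cbind(mz = g$mz, intensity = g$i)
  }
  mzR::writeMSData(object = pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

.write_spectra_json <- function(ms1, ms2, path) {
  scan_obj <- function(g, level) {
    g <- g[order(g$mz), , drop = FALSE]
    obj <- list(
      file_id = g$file_id[1], scan = g$scan[1], mslevel = level,
      rt = g$rt[1], polarity = g$polarity[1],
      mz = g$mz, i = g$i
    )
    if (level == 2L) {
      obj$precmz <- g$precmz[1]
      obj$charge <- g$charge[1]
    }
    obj
  }
  out <- c(lapply(.split_scans(ms1), scan_obj, level = 1L),
           lapply(.split_scans(ms2), scan_obj, level = 2L))
  names(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
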