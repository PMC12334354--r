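# Readers for open MS formats. mzML and mzXML go through mzR (proteowizard);
# MGF (which carries MS/MS only) is parsed directly.

.infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    mzml = "mzml", mzxml = "mzxml", mgf = "mgf",
    stop("unsupported file extension '.", ext, "' for '", path, "'", call. = FALSE)
  )
}

#' Read an MS data file into a peak table
#'
#' Reads centroided spectra from mzML, mzXML or MGF into a [peak_table()].
#' Retention times are converted to minutes regardless of the source unit.
#' MGF files yield MS2 data only. Scans missing polarity metadata default to
#' positive mode with a warning; MS2 scans missing a precursor charge default
#' to +1 in positive and -1 in negative mode. Each MS2 scan is linked to the
#' most recent preceding MS1 scan in acquisition order (column `ms1scan`).
#'
#' @param path Path to the file.
#' @param format `"mzml"`, `"mzxml"` or `"mgf"`; inferred from the extension
#'   when `NULL`.
#' @param file_id Identifier recorded in the `file_id` column; defaults to
#'   `path` as given.
#' @param cache Optional [spectra_cache()]; when supplied, a previously
#'   cached parse of the same file content is reused.
#' @return A `massql_peaks` object.
#' @export
load_spectra <- function(path, format = NULL, file_id = path, cache = NULL) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (is.null(format)) format <- .infer_format(path)
  format <- match.arg(format, c("mzml", "mzxml", "mgf"))
  if (!is.null(cache)) {
    key <- cache_key(path)
    hit <- tryCatch(load_cache(key, cache), massql_cache_miss = function(e) NULL)
    if (!is.null(hit)) return(hit)
  }
  tab <- switch(format,
    mzml = .read_mzr(path, file_id),
    mzxml = .read_mzr(path, file_id),
    mgf = .read_mgf(path, file_id)
  )
  if (!is.null(cache)) save_cache(tab, cache, key = cache_key(path))
  tab
}

.default_polarity <- function(pol, path) {
  if (any(is.na(pol) | pol == 0L)) {
    warning("missing polarity metadata in '", path,
            "'; defaulting to positive mode", call. = FALSE)
    pol[is.na(pol) | pol == 0L] <- 1L
  }
  pol
}

.read_mzr <- function(path, file_id) {
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) return(peak_table())
  pks <- mzR::peaks(handle)
  if (is.matrix(pks)) pks <- list(pks)

  # mzR polarity: 1 positive, 0 negative, -1 unknown
  pol <- ifelse(hdr$polarity == 1L, 1L,
                ifelse(hdr$polarity == 0L, -1L, NA_integer_))
  pol <- .default_polarity(pol, path)
  rt_min <- hdr$retentionTime / 60
  mob <- if ("ionMobilityDriftTime" %in% names(hdr)) hdr$ionMobilityDriftTime else NA_real_

  npk <- vapply(pks, nrow, integer(1))
  per_scan <- function(col) rep(col, npk)
  all_mz <- unlist(lapply(pks, function(p) p[, 1L]), use.names = FALSE)
  all_i <- unlist(lapply(pks, function(p) p[, 2L]), use.names = FALSE)
  if (length(all_mz) == 0L && sum(npk) == 0L && any(npk == 0L)) {
    # scans may legitimately be empty; drop them below
  }
  if (any(npk > 0L) && is.null(all_mz)) stop("scan lacking m/z array in '", path, "'", call. = FALSE)

  base <- data.frame(
    file_id = per_scan(rep(file_id, nrow(hdr))),
    scan = per_scan(as.integer(hdr$acquisitionNum)),
    mz = all_mz, i = all_i,
    rt = per_scan(rt_min), polarity = per_scan(pol),
    mobility = per_scan(as.numeric(mob)),
    mslevel = per_scan(as.integer(hdr$msLevel)),
    stringsAsFactors = FALSE
  )

  ms1 <- base[base$mslevel == 1L, setdiff(names(base), "mslevel"), drop = FALSE]

  is2 <- hdr$msLevel >= 2L
  ms2 <- base[base$mslevel >= 2L, setdiff(names(base), "mslevel"), drop = FALSE]
  if (nrow(ms2) > 0L) {
    scan2 <- as.integer(hdr$acquisitionNum[is2])
    prec <- hdr$precursorMZ[is2]
    chg <- as.integer(hdr$precursorCharge[is2])
    pol2 <- pol[is2]
    chg[is.na(chg) | chg == 0L] <- 0L
    chg <- ifelse(chg == 0L, ifelse(pol2 < 0, -1L, 1L), abs(chg) * ifelse(pol2 < 0, -1L, 1L))
    # link to most recent preceding MS1 scan in acquisition order
    ms1_nums <- as.integer(hdr$acquisitionNum[hdr$msLevel == 1L])
    link <- vapply(scan2, function(s) {
      prev <- ms1_nums[ms1_nums < s]
      if (length(prev)) max(prev) else NA_integer_
    }, integer(1))
    lut <- stats::setNames(seq_along(scan2), scan2)
    idx <- lut[as.character(ms2$scan)]
    ms2$precmz <- prec[idx]
    ms2$charge <- chg[idx]
    ms2$ms1scan <- link[idx]
  }
  peak_table(ms1 = ms1, ms2 = ms2)
}

.read_mgf <- function(path, file_id) {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^BEGIN IONS[[:space:]]*$", lines)
  end <- grep("^END IONS[[:space:]]*$", lines)
  if (length(begin) != length(end) || any(end < begin)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in '", path, "'", call. = FALSE)
  }
  if (length(begin) == 0L) return(peak_table())
  rows <- vector("list", length(begin))
  warned_pol <- FALSE
  for (b in seq_along(begin)) {
    block <- lines[(begin[b] + 1L):(end[b] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_

    pep <- getv("PEPMASS")
    if (is.na(pep)) stop("MGF spectrum ", b, " lacks PEPMASS in '", path, "'", call. = FALSE)
    precmz <- as.numeric(strsplit(trimws(pep), "[[:space:]]+")[[1]][1])

    chg_raw <- getv("CHARGE")
    if (!is.na(chg_raw)) {
      sign <- if (grepl("-", chg_raw, fixed = TRUE)) -1L else 1L
      zn <- suppressWarnings(as.integer(gsub("[^0-9]", "", chg_raw)))
      charge <- if (is.na(zn) || zn == 0L) sign else sign * zn
      polarity <- sign
    } else {
      charge <- NA_integer_
      polarity <- NA_integer_
    }
    if (is.na(polarity)) {
      if (!warned_pol) {
        warning("missing polarity metadata in '", path,
                "'; defaulting to positive mode", call. = FALSE)
        warned_pol <- TRUE
      }
      polarity <- 1L
    }
    if (is.na(charge)) charge <- if (polarity < 0) -1L else 1L

    rt <- getv("RTINSECONDS")
    rt <- if (is.na(rt)) 0 else as.numeric(rt) / 60
    scan <- getv("SCANS")
    scan <- if (is.na(scan)) b else as.integer(scan)

    pk <- block[!is_kv & nzchar(trimws(block))]
    if (length(pk)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(pk), "[[:space:]]+"), function(x) {
        as.numeric(x[1:2])
      }))
      if (anyNA(mat)) stop("malformed peak line in MGF spectrum ", b, call. = FALSE)
    } else {
      mat <- matrix(numeric(0), ncol = 2)
    }
    if (nrow(mat) == 0L) next
    rows[[b]] <- data.frame(
      file_id = file_id, scan = scan, mz = mat[, 1L], i = mat[, 2L],
      rt = rt, polarity = polarity, mobility = NA_real_,
      precmz = precmz, charge = charge, ms1scan = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  peak_table(ms2 = do.call(rbind, rows))
}
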