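# Multi-file batch querying with deterministic merging, plus the command-line
# entry point. Files are processed independently (no shared mutable state
# between file tasks), so the merged output is invariant to worker count and
# scheduling: results are keyed by file path and sorted after the merge.

#' Run a query over multiple files
#'
#' Loads each input file (through the cache when `cache_dir` is given),
#' executes the query, and merges the per-file results sorted by
#' `(file_id, scan, X)`. The `file_id` column is the input path as given, so
#' identically named files in different directories cannot collide.
#'
#' @param query Query text or a `massql_query`.
#' @param files Character vector of input paths (mzML/mzXML/MGF).
#' @param output Optional path for the merged result table.
#' @param format Result table format, `"tsv"` or `"json"`.
#' @param extract Optional path: export the retrieved spectra here.
#' @param extract_format `"mgf"`, `"mzml"` or `"json"`.
#' @param cache_dir Optional cache directory (see [spectra_cache()]).
#' @param workers Number of parallel workers (forked processes).
#' @param keep_going Continue past per-file failures and report them
#'   (default is fail-fast)?
#' @param config An [execution_config()].
#' @return List with `result` (merged `massql_result`), `failures` (data
#'   frame of skipped files and messages, non-empty only with
#'   `keep_going = TRUE`), and the paths written.
#' @export
run_batch <- function(query, files, output = NULL, format = c("tsv", "json"),
                      extract = NULL, extract_format = c("mgf", "mzml", "json"),
                      cache_dir = NULL, workers = 1L, keep_going = FALSE,
                      config = execution_config()) {
  format <- match.arg(format)
  extract_format <- match.arg(extract_format)
  if (is.character(query)) query <- parse_massql(query)
  d <- validate_massql(query)
  if (any(d$level == "error")) {
    stop("invalid query: ", d$message[d$level == "error"][1], call. = FALSE)
  }
  stopifnot(length(files) >= 1L, workers >= 1L)
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cache <- if (!is.null(cache_dir)) spectra_cache(cache_dir) else NULL

  one_file <- function(path) {
    tab <- load_spectra(path, file_id = path, cache = cache)
    res <- execute_query(query, tab, config)
    hits <- if (nrow(res) > 0L && all(c("file_id", "scan") %in% names(res))) {
      unique(res[, c("file_id", "scan")])
    } else res[0, 0]
    sub <- if (!is.null(extract) && nrow(hits) > 0L) {
      keys <- paste(hits$file_id, hits$scan)
      peak_table(
        ms1 = tab$ms1[paste(tab$ms1$file_id, tab$ms1$scan) %in% keys, , drop = FALSE],
        ms2 = tab$ms2[paste(tab$ms2$file_id, tab$ms2$scan) %in% keys, , drop = FALSE])
    } else NULL
    list(result = res, hits = hits, sub = sub, error = NULL)
  }
  worker <- function(path) {
    if (keep_going) {
      tryCatch(one_file(path),
               error = function(e) list(result = NULL, hits = NULL, sub = NULL,
                                        error = conditionMessage(e)))
    } else one_file(path)
  }

  out <- if (workers > 1L) {
    parallel::mclapply(files, worker, mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(files, worker)
  }
  # mclapply wraps uncaught errors in try-error objects; surface them
  bad <- vapply(out, function(x) inherits(x, "try-error") || !is.list(x), logical(1))
  if (any(bad)) {
    x <- out[[which(bad)[1]]]
    cond <- attr(x, "condition")
    stop(if (!is.null(cond)) conditionMessage(cond) else as.character(x), call. = FALSE)
  }

  failures <- data.frame(file = character(0), message = character(0),
                         stringsAsFactors = FALSE)
  results <- list()
  subs <- list()
  for (k in seq_along(out)) {
    if (!is.null(out[[k]]$error)) {
      failures <- rbind(failures, data.frame(file = files[k],
                                             message = out[[k]]$error,
                                             stringsAsFactors = FALSE))
    } else {
      results[[length(results) + 1L]] <- out[[k]]$result
      if (!is.null(out[[k]]$sub)) subs[[length(subs) + 1L]] <- out[[k]]$sub
    }
  }
  merged <- if (length(results)) do.call(rbind, results) else .empty_result(FALSE, query$fun)
  if (nrow(merged) > 0L) {
    ord <- if ("X" %in% names(merged)) {
      order(merged$file_id, merged$scan, merged$X)
    } else if ("scan" %in% names(merged)) {
      order(merged$file_id, merged$scan)
    } else order(merged$file_id)
    merged <- merged[ord, , drop = FALSE]
    rownames(merged) <- NULL
  }
  class(merged) <- c("massql_result", "data.frame")
  attr(merged, "query") <- serialize_massql(query)

  if (!is.null(output)) write_result_table(merged, output, format)
  if (!is.null(extract)) {
    if (length(subs)) {
      all_sub <- .bind_peak_tables(subs)
      sel <- unique(rbind(all_sub$ms1[, c("file_id", "scan")],
                          all_sub$ms2[, c("file_id", "scan")]))
      export_spectra(all_sub, sel, extract, extract_format)
    } else {
      export_spectra(peak_table(), data.frame(file_id = character(0), scan = integer(0)),
                     extract, extract_format)
    }
  }
  list(result = merged, failures = failures, output = output, extract = extract)
}

#' Command-line entry point
#'
#' Implements the CLI
#' `massql "<QUERY>" <files...> --output results.tsv --format tsv|json
#' --extract hits.mgf --extract-format mgf|mzml|json --cache-dir DIR
#' --workers N [--keep-going]`. Parse and validation failures print a
#' diagnostic with its character offset on standard error and return a
#' nonzero status.
#'
#' @param args Character vector of command-line arguments (typically
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status (0 on success), invisibly.
#' @export
massql_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    usage = "massql \"<QUERY>\" <files...> [options]",
    option_list = list(
      optparse::make_option("--output", type = "character", default = NULL,
                            help = "merged result table path"),
      optparse::make_option("--format", type = "character", default = "tsv",
                            help = "result format: tsv or json [default %default]"),
      optparse::make_option("--extract", type = "character", default = NULL,
                            help = "write retrieved spectra to this path"),
      optparse::make_option("--extract-format", dest = "extract_format",
                            type = "character", default = "mgf",
                            help = "spectrum format: mgf, mzml or json [default %default]"),
      optparse::make_option("--cache-dir", dest = "cache_dir", type = "character",
                            default = NULL, help = "peak-table cache directory"),
      optparse::make_option("--workers", type = "integer", default = 1L,
                            help = "parallel workers [default %default]"),
      optparse::make_option("--keep-going", dest = "keep_going",
                            action = "store_true", default = FALSE,
                            help = "skip and report failing files instead of aborting")
    ))
  parsed <- tryCatch(
    optparse::parse_args(parser, args = args, positional_arguments = TRUE),
    error = function(e) e)
  if (inherits(parsed, "error")) {
    message("argument error: ", conditionMessage(parsed))
    return(invisible(2L))
  }
  pos <- parsed$args
  if (length(pos) < 2L) {
    message("usage: massql \"<QUERY>\" <files...> [options]")
    return(invisible(2L))
  }
  status <- tryCatch({
    job <- run_batch(
      query = pos[1], files = pos[-1],
      output = parsed$options$output, format = parsed$options$format,
      extract = parsed$options$extract,
      extract_format = parsed$options$extract_format,
      cache_dir = parsed$options$cache_dir,
      workers = parsed$options$workers,
      keep_going = parsed$options$keep_going)
    if (nrow(job$failures) > 0L) {
      for (k in seq_len(nrow(job$failures))) {
        message("skipped ", job$failures$file[k], ": ", job$failures$message[k])
      }
    }
    if (is.null(parsed$options$output)) {
      utils::write.table(job$result, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    0L
  },
  massql_parse_error = function(e) { message("query error: ", conditionMessage(e)); 1L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
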