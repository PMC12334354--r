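# Peak-table cache: one serialized blob per source file, keyed by the md5 of
# the source file content. A sidecar checksum guards against corruption and a
# version stamp guards against format drift: a stale version signals a cache
# miss (regenerate), a bad checksum is an error, never a silent misread.

.CACHE_VERSION <- 1L

#' Create a cache handle
#'
#' @param path Cache directory (created if missing).
#' @param version Cache format version; blobs written with a different
#'   version are treated as misses.
#' @return An object of class `"massql_cache"`.
#' @export
spectra_cache <- function(path, version = .CACHE_VERSION) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  structure(list(path = path, version = as.integer(version)),
            class = "massql_cache")
}

#' Content hash of a source file
#'
#' @param path File whose content identifies the cache entry.
#' @return The md5 hex digest of the file content.
#' @export
cache_key <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  unname(tools::md5sum(path))
}

.cache_blob <- function(cache, key) file.path(cache$path, paste0(key, ".rds"))
.cache_sum <- function(cache, key) file.path(cache$path, paste0(key, ".md5"))

#' Save a peak table to a cache
#'
#' @param table A `massql_peaks` object.
#' @param cache A [spectra_cache()].
#' @param key Cache key, typically [cache_key()] of the source file.
#' @return The key, invisibly.
#' @export
save_cache <- function(table, cache, key) {
  stopifnot(inherits(table, "massql_peaks"), inherits(cache, "massql_cache"))
  blob <- .cache_blob(cache, key)
  saveRDS(list(version = cache$version, table = table), blob)
  writeLines(unname(tools::md5sum(blob)), .cache_sum(cache, key))
  invisible(key)
}

#' Load a peak table from a cache
#'
#' Verifies the blob checksum before deserializing. A missing entry or a
#' version mismatch raises a condition of class `"massql_cache_miss"`
#' (callers regenerate); a checksum mismatch raises an error of class
#' `"massql_cache_corrupt"`.
#'
#' @param key Cache key.
#' @param cache A [spectra_cache()].
#' @return The cached `massql_peaks`, column-for-column identical to what was
#'   saved.
#' @export
load_cache <- function(key, cache) {
  stopifnot(inherits(cache, "massql_cache"))
  blob <- .cache_blob(cache, key)
  sumf <- .cache_sum(cache, key)
  miss <- function(msg) {
    stop(structure(class = c("massql_cache_miss", "error", "condition"),
                   list(message = msg, call = NULL)))
  }
  if (!file.exists(blob) || !file.exists(sumf)) miss("cache miss")
  expected <- readLines(sumf, warn = FALSE)[1]
  actual <- unname(tools::md5sum(blob))
  if (!identical(actual, expected)) {
    stop(structure(class = c("massql_cache_corrupt", "error", "condition"),
                   list(message = sprintf("cache blob checksum mismatch for key %s", key),
                        call = NULL)))
  }
  payload <- readRDS(blob)
  if (!identical(payload$version, cache$version)) miss("cache version mismatch")
  payload$table
}
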