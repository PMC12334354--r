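# In-code fixture builders: small peak tables and random (query, dataset)
# pairs for property tests.

mk_ms1 <- function(scan, mz, i, rt = 1, polarity = 1L, file_id = "f1",
                   mobility = NA_real_) {
  data.frame(file_id = file_id, scan = as.integer(scan), mz = mz, i = i,
             rt = rt, polarity = as.integer(polarity), mobility = mobility,
             stringsAsFactors = FALSE)
}

mk_ms2 <- function(scan, mz, i, precmz, rt = 1, polarity = 1L, charge = 1L,
                   file_id = "f1", ms1scan = NA_integer_, mobility = NA_real_) {
  data.frame(file_id = file_id, scan = as.integer(scan), mz = mz, i = i,
             rt = rt, polarity = as.integer(polarity), mobility = mobility,
             precmz = precmz, charge = as.integer(charge),
             ms1scan = as.integer(ms1scan), stringsAsFactors = FALSE)
}

# random small dataset: a few MS1 and MS2 scans with linked precursors
rand_table <- function(n_ms1 = 4L, n_ms2 = 4L, max_peaks = 8L) {
  ms1 <- do.call(rbind, lapply(seq_len(n_ms1), function(s) {
    np <- sample(2:max_peaks, 1)
    mk_ms1(scan = s, mz = round(runif(np, 100, 500), 3),
           i = round(10^runif(np, 2, 5)),
           rt = round(runif(1, 0, 20), 2),
           polarity = sample(c(1L, -1L), 1),
           mobility = if (runif(1) < 0.5) round(runif(1, 0.5, 2), 2) else NA_real_)
  }))
  ms2 <- do.call(rbind, lapply(seq_len(n_ms2), function(s) {
    np <- sample(2:max_peaks, 1)
    mk_ms2(scan = n_ms1 + s, mz = round(runif(np, 100, 500), 3),
           i = round(10^runif(np, 2, 5)),
           precmz = round(runif(1, 200, 600), 3),
           rt = round(runif(1, 0, 20), 2),
           polarity = sample(c(1L, -1L), 1),
           charge = sample(1:3, 1),
           ms1scan = sample(seq_len(n_ms1), 1))
  }))
  peak_table(ms1 = ms1, ms2 = ms2)
}

# random valid query aimed at a table (targets drawn from real peaks so that
# results are often non-empty)
rand_query <- function(table) {
  datatype <- sample(c("MS1DATA", "MS2DATA"), 1)
  df <- if (datatype == "MS1DATA") table$ms1 else table$ms2
  pick_mz <- function() {
    if (runif(1) < 0.7 && nrow(df)) round(sample(df$mz, 1) + runif(1, -0.05, 0.05), 3)
    else round(runif(1, 100, 500), 3)
  }
  tol <- function() sample(c(":TOLERANCEMZ=0.1", ":TOLERANCEMZ=0.02",
                             ":TOLERANCEPPM=200", ":TOLERANCEPPM=2000", ""), 1)
  inten <- function() sample(c(":INTENSITYPERCENT=30", ":INTENSITYTICPERCENT=10",
                               ":INTENSITYVALUE=500", "", ""), 1)
  excl <- function() sample(c(":EXCLUDED", "", "", ""), 1)

  peak_leaf <- function() {
    if (datatype == "MS1DATA") {
      paste0("MS1MZ=", pick_mz(), tol(), inten(), excl())
    } else {
      type <- sample(c("MS2PROD", "MS2PREC", "MS2NL"), 1)
      if (type == "MS2PROD") paste0("MS2PROD=", pick_mz(), tol(), inten(), excl())
      else if (type == "MS2PREC") {
        tgt <- if (runif(1) < 0.7 && nrow(df)) round(sample(df$precmz, 1) + runif(1, -0.05, 0.05), 3)
               else round(runif(1, 200, 600), 3)
        paste0("MS2PREC=", tgt, tol(), excl())
      } else {
        loss <- if (runif(1) < 0.7 && nrow(df)) {
          k <- sample(nrow(df), 1)
          round(df$precmz[k] - df$mz[k] + runif(1, -0.05, 0.05), 3)
        } else round(runif(1, 10, 200), 3)
        paste0("MS2NL=", max(loss, 0.1), tol())
      }
    }
  }
  meta_leaf <- function() {
    sample(c(
      paste0("RTMIN=", round(runif(1, 0, 20), 1)),
      paste0("RTMAX=", round(runif(1, 0, 20), 1)),
      paste0("SCANMIN=", sample(1:8, 1)),
      paste0("SCANMAX=", sample(1:8, 1)),
      paste0("POLARITY=", sample(c("Positive", "Negative"), 1)),
      if (datatype == "MS2DATA") paste0("CHARGE=", sample(1:3, 1)),
      "MOBILITY=range(min=0.4, max=1.8)"
    ), 1)
  }
  var_clause <- function() {
    # variable trio anchored on a real peak pair when possible
    target_type <- if (datatype == "MS1DATA") "MS1MZ" else "MS2PROD"
    off <- if (nrow(df) >= 2 && runif(1) < 0.7) {
      s <- df[df$scan == sample(df$scan, 1), ]
      if (nrow(s) >= 2) round(abs(diff(sample(s$mz, 2))), 3) else round(runif(1, 1, 30), 3)
    } else round(runif(1, 1, 30), 3)
    off <- max(off, 0.5)
    ratio <- sample(c("", ":INTENSITYMATCH=0.5:INTENSITYMATCHPERCENT=400"), 1)
    paste0(target_type, "=X:TOLERANCEMZ=0.05 AND ",
           target_type, "=X-", off, ":TOLERANCEMZ=0.05", ratio)
  }

  fun <- sample(c("scaninfo", "scaninfo", "scannum"), 1)
  head <- paste0("QUERY ", fun, "(", datatype, ")")
  form <- sample(1:5, 1)
  where <- switch(form,
    NULL,
    peak_leaf(),
    paste(peak_leaf(), sample(c("AND", "OR"), 1), meta_leaf()),
    paste0("(", peak_leaf(), " OR ", peak_leaf(), ") AND ", meta_leaf()),
    var_clause())
  if (is.null(where)) head else paste(head, "WHERE", where)
}

corpus_queries <- function() {
  path <- system.file("extdata", "query_corpus.txt", package = "massql")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
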