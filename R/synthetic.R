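# Ground-truth synthetic datasets: planted iron-isotope MS1 patterns, planted
# phosphate-fragment MS2 spectra and random decoy scans, written as mzML and
# MGF with a JSON manifest that exactly predicts the result of the two
# reference queries (iron isotope/adduct pattern; diagnostic phosphate
# product ion).
#
# Planted peak positions use theoretical isotope masses; the reference
# queries use the printed constants (1.993, 52.91, 1.0034, 98.9847), so the
# generated data also exercise the tolerance windows the way real data do.
# Decoy scans are certified pattern-free at generation time by a direct
# checker (resampled on collision, bounded retries), making the manifest an
# exact oracle.

.IRON_54_DELTA <- function() mass_delta("56Fe", "54Fe")      # ~1.99533
.IRON_APO_DELTA <- function() mass_delta("56Fe-3H")          # ~52.91146
.C13_DELTA <- function() mass_delta("13C", "12C")            # ~1.00335
.PHOSPHATE_MZ <- function() ion_mz(monoisotopic_mass("H3PO4"), 1, "protonated")

#' Plant an iron-binding isotope/adduct pattern
#'
#' Builds the four-peak MS1 signature of an iron-bound compound at apex m/z
#' `x`: the monoisotopic peak, the 54Fe isotopologue at `ratio54` of the apex
#' (natural 54Fe/56Fe abundance ratio ~6.3%), the 13C isotopologue, and the
#' metal-free (apo) species at the Fe-3H adduct delta below the apex.
#' Peak positions use theoretical isotope masses.
#'
#' @param x Apex m/z in Da, in \[200, 900\].
#' @param base_intensity Apex peak intensity.
#' @param ratio54 54Fe peak intensity relative to the apex (default 0.063).
#' @param ratio13C 13C peak intensity relative to the apex.
#' @param apo_fraction Apo-species intensity relative to the apex; 0 omits
#'   the apo peak.
#' @return Data frame with columns `mz` and `i` (4 peaks, or 3 when
#'   `apo_fraction = 0`).
#' @export
plant_iron_pattern <- function(x, base_intensity = 1e6, ratio54 = 0.063,
                               ratio13C = 0.27, apo_fraction = 0.5) {
  if (x < 200 || x > 900) stop("apex m/z out of range [200, 900]", call. = FALSE)
  stopifnot(ratio54 > 0, ratio54 < 1, ratio13C > 0, ratio13C < 1,
            apo_fraction >= 0, apo_fraction < 1)
  mz <- c(x, x - .IRON_54_DELTA(), x + .C13_DELTA())
  i <- base_intensity * c(1, ratio54, ratio13C)
  if (apo_fraction > 0) {
    mz <- c(mz, x - .IRON_APO_DELTA())
    i <- c(i, base_intensity * apo_fraction)
  }
  data.frame(mz = mz, i = i)
}

#' Plant a phosphate-fragment MS/MS spectrum
#'
#' Builds an MS2 peak list containing the diagnostic phosphate product ion
#' (H4O4P+) at its theoretical m/z with relative intensity
#' `fragment_rel_intensity` of the scan base peak, plus `n_noise` decoy peaks
#' none of which fall within 50 ppm of the diagnostic m/z. Uses the current
#' RNG state for the decoy peaks.
#'
#' @param precursor_mz Precursor m/z recorded for the scan.
#' @param fragment_rel_intensity Fragment intensity as a fraction of the base
#'   peak, in (0, 1\].
#' @param n_noise Number of decoy peaks.
#' @return List with elements `peaks` (data frame `mz`, `i`) and
#'   `precursor_mz`.
#' @export
plant_phosphate_ms2 <- function(precursor_mz, fragment_rel_intensity = 0.8,
                                n_noise = 20) {
  stopifnot(fragment_rel_intensity > 0, fragment_rel_intensity <= 1)
  frag_mz <- .PHOSPHATE_MZ()
  if (n_noise > 0) {
    mz <- numeric(0)
    while (length(mz) < n_noise) {
      cand <- stats::runif(n_noise - length(mz), 50, max(precursor_mz, 150))
      cand <- cand[abs(cand - frag_mz) > 0.05]
      mz <- c(mz, cand)
    }
    i <- 10^stats::runif(n_noise, 3, 5)
    base <- max(i)
  } else {
    mz <- numeric(0); i <- numeric(0); base <- 1e5
  }
  peaks <- data.frame(mz = c(frag_mz, mz),
                      i = c(fragment_rel_intensity * base, i))
  list(peaks = peaks[order(peaks$mz), , drop = FALSE], precursor_mz = precursor_mz)
}

# --- generation-time pattern checkers (direct loops; certify decoys) -------

.ppm_window <- function(target, ppm) ppm * target * 1e-6

# scans satisfying the diagnostic-phosphate query: a peak within 50 ppm of
# 98.9847 at >= 50% of the base peak
.check_phosphate <- function(peaks) {
  if (nrow(peaks) == 0L) return(FALSE)
  target <- 98.9847
  any(abs(peaks$mz - target) <= .ppm_window(target, 50) &
        peaks$i / max(peaks$i) >= 0.5)
}

# X bindings satisfying the iron query (printed constants, 10 ppm, 25% ratio
# band around 0.063)
.check_iron_bindings <- function(peaks) {
  hits <- numeric(0)
  for (k in seq_len(nrow(peaks))) {
    X <- peaks$mz[k]; Y <- peaks$i[k]
    t54 <- X - 1.993; t13 <- X + 1.0034; tapo <- X - 52.91
    ok54 <- any(abs(peaks$mz - t54) <= .ppm_window(t54, 10) &
                  abs(peaks$i / Y - 0.063) <= 0.063 * 0.25)
    ok13 <- any(abs(peaks$mz - t13) <= .ppm_window(t13, 10))
    okapo <- any(abs(peaks$mz - tapo) <= .ppm_window(tapo, 10))
    if (ok54 && ok13 && okapo) hits <- c(hits, X)
  }
  hits
}

.decoy_peaks <- function(n, mz_range, int_range) {
  data.frame(mz = stats::runif(n, mz_range[1], mz_range[2]),
             i = 10^stats::runif(n, log10(int_range[1]), log10(int_range[2])))
}

#' Noise model for synthetic datasets
#'
#' @param n_decoy_peaks Decoy peaks per scan.
#' @param mz_range m/z range of decoy peaks, Da.
#' @param intensity_range Range of the log-uniform decoy intensity
#'   distribution.
#' @return A list of noise parameters.
#' @export
noise_model <- function(n_decoy_peaks = 30L, mz_range = c(100, 1000),
                        intensity_range = c(1e3, 1e6)) {
  list(n_decoy_peaks = as.integer(n_decoy_peaks), mz_range = mz_range,
       intensity_range = intensity_range)
}

#' Generate a ground-truth dataset
#'
#' Writes `n_files` synthetic files (each as mzML and, for the MS2 content,
#' MGF) containing decoy MS1 and MS2 scans plus planted iron-pattern MS1
#' scans and planted phosphate-fragment MS2 scans, together with a JSON
#' manifest listing every planted pattern. Decoy scans (and the decoy
#' portion of planted scans) are checked against both reference patterns and
#' resampled on collision (at most 100 retries per scan), so the manifest
#' exactly predicts each reference query's result set. Retention times are
#' uniform over \[0, 20\] minutes; scans are numbered 1..N per file in
#' retention-time order. Iron apices are drawn uniformly over \[300, 900\] Da
#' and bases log-uniformly over \[1e5, 1e6\]. Generation is deterministic
#' given `seed` (one derived RNG stream per file).
#'
#' @param dir Output directory (created if needed).
#' @param n_files Number of files.
#' @param k_iron,k_phosphate Total planted iron MS1 scans and phosphate MS2
#'   scans, distributed round-robin over files.
#' @param n_decoy_ms1,n_decoy_ms2 Total decoy MS1/MS2 scans.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return List with `manifest` (also written to `manifest.json` in `dir`)
#'   and `files`, a data frame of the mzML/MGF paths.
#' @export
generate_dataset <- function(dir, n_files = 3L, k_iron = 20L, k_phosphate = 12L,
                             n_decoy_ms1 = 500L, n_decoy_ms2 = 200L,
                             noise = noise_model(), seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  assign_files <- function(k) tabulate(rep(seq_len(n_files), length.out = k), n_files)
  ki <- assign_files(k_iron); kp <- assign_files(k_phosphate)
  d1 <- assign_files(n_decoy_ms1); d2 <- assign_files(n_decoy_ms2)

  manifest <- list(seed = seed, noise = noise, files = list())
  paths <- data.frame(mzml = character(n_files), mgf = character(n_files),
                      stringsAsFactors = FALSE)

  for (f in seq_len(n_files)) {
    set.seed((seed + f) %% .Machine$integer.max)
    fname <- sprintf("synthetic_%02d", f)
    mzml_path <- file.path(dir, paste0(fname, ".mzML"))
    mgf_path <- file.path(dir, paste0(fname, ".mgf"))

    scans <- list()
    retry_cap <- 100L
    sample_until <- function(make, ok) {
      for (r in seq_len(retry_cap)) {
        s <- make()
        if (ok(s)) return(s)
      }
      stop("decoy resampling retry cap exceeded; cannot certify scan", call. = FALSE)
    }

    for (k in seq_len(d1[f])) {
      pk <- sample_until(
        function() .decoy_peaks(noise$n_decoy_peaks, noise$mz_range, noise$intensity_range),
        function(p) length(.check_iron_bindings(p)) == 0L)
      scans[[length(scans) + 1L]] <- list(level = 1L, peaks = pk, planted = NULL)
    }
    for (k in seq_len(ki[f])) {
      x <- stats::runif(1, 300, 900)
      base <- 10^stats::runif(1, 5, 6)
      planted <- plant_iron_pattern(x, base)
      pk <- sample_until(
        function() rbind(planted,
                         .decoy_peaks(noise$n_decoy_peaks, noise$mz_range,
                                      noise$intensity_range)),
        function(p) isTRUE(all.equal(.check_iron_bindings(p), x)))
      scans[[length(scans) + 1L]] <- list(
        level = 1L, peaks = pk,
        planted = list(kind = "iron_ms1", x = x, y = base,
                       peaks = unname(as.matrix(planted))))
    }
    for (k in seq_len(d2[f])) {
      prec <- stats::runif(1, 200, 800)
      pk <- sample_until(
        function() {
          p <- .decoy_peaks(max(noise$n_decoy_peaks %/% 2L, 5L),
                            c(50, prec), noise$intensity_range)
          p[abs(p$mz - 98.9847) > 0.05, , drop = FALSE]
        },
        function(p) nrow(p) > 0L && !.check_phosphate(p))
      scans[[length(scans) + 1L]] <- list(level = 2L, peaks = pk, planted = NULL,
                                          precmz = prec)
    }
    for (k in seq_len(kp[f])) {
      prec <- stats::runif(1, 200, 800)
      sp <- plant_phosphate_ms2(prec, fragment_rel_intensity = 0.8,
                                n_noise = max(noise$n_decoy_peaks %/% 2L, 5L))
      stopifnot(.check_phosphate(sp$peaks))
      scans[[length(scans) + 1L]] <- list(
        level = 2L, peaks = sp$peaks, precmz = prec,
        planted = list(kind = "phosphate_ms2", x = .PHOSPHATE_MZ(),
                       y = sp$peaks$i[which.min(abs(sp$peaks$mz - .PHOSPHATE_MZ()))],
                       peaks = unname(as.matrix(sp$peaks))))
    }

    rts <- sort(stats::runif(length(scans), 0, 20))
    ord <- sample.int(length(scans))  # shuffle scan kinds along the run
    scans <- scans[ord]

    ms1_rows <- list(); ms2_rows <- list(); patterns <- list()
    last_ms1 <- NA_integer_
    for (s in seq_along(scans)) {
      sc <- scans[[s]]
      if (sc$level == 1L) {
        last_ms1 <- s
        ms1_rows[[length(ms1_rows) + 1L]] <- data.frame(
          file_id = mzml_path, scan = s, mz = sc$peaks$mz, i = sc$peaks$i,
          rt = rts[s], polarity = 1L, mobility = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        ms2_rows[[length(ms2_rows) + 1L]] <- data.frame(
          file_id = mzml_path, scan = s, mz = sc$peaks$mz, i = sc$peaks$i,
          rt = rts[s], polarity = 1L, mobility = NA_real_,
          precmz = sc$precmz, charge = 1L, ms1scan = last_ms1,
          stringsAsFactors = FALSE)
      }
      if (!is.null(sc$planted)) {
        patterns[[length(patterns) + 1L]] <- c(
          sc$planted[c("kind", "x", "y")],
          list(scan = s, rt = rts[s], peaks = sc$planted$peaks))
      }
    }
    tab <- peak_table(ms1 = do.call(rbind, ms1_rows), ms2 = do.call(rbind, ms2_rows))
    .write_mzml(tab$ms1, tab$ms2, mzml_path)
    .write_mgf(tab$ms2, mgf_path)
    paths$mzml[f] <- mzml_path
    paths$mgf[f] <- mgf_path
    manifest$files[[f]] <- list(
      mzml = mzml_path, mgf = mgf_path,
      n_ms1_scans = length(ms1_rows), n_ms2_scans = length(ms2_rows),
      patterns = patterns)
  }

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(c(
    sprintf("seed=%d", seed), sprintf("n_files=%d", n_files),
    sprintf("k_iron=%d", k_iron), sprintf("k_phosphate=%d", k_phosphate),
    sprintf("n_decoy_ms1=%d", n_decoy_ms1), sprintf("n_decoy_ms2=%d", n_decoy_ms2),
    sprintf("n_decoy_peaks=%d", noise$n_decoy_peaks)
  ), file.path(dir, "config.txt"))
  list(manifest = manifest, manifest_path = file.path(dir, "manifest.json"),
       files = paths)
}

#' The two reference queries over planted patterns
#'
#' Returns the query strings whose result sets the manifest of
#' [generate_dataset()] predicts exactly: the variable-anchored iron
#' isotope/adduct MS1 pattern (10 ppm tolerance, 6.3% 54Fe intensity ratio
#' within 25%) and the diagnostic phosphate product-ion MS2 pattern (50 ppm,
#' at least 50% of the base peak).
#'
#' @return Named character vector with elements `iron` and `phosphate`.
#' @export
reference_queries <- function() {
  c(iron = paste(
      "QUERY scaninfo(MS1DATA) WHERE MS1MZ=X:TOLERANCEPPM=10",
      "AND MS1MZ=X-1.993:TOLERANCEPPM=10:INTENSITYMATCH=0.063:INTENSITYMATCHPERCENT=25",
      "AND MS1MZ=X+1.0034:TOLERANCEPPM=10",
      "AND MS1MZ=X-52.91:TOLERANCEPPM=10"),
    phosphate = "QUERY scaninfo(MS2DATA) WHERE MS2PROD=98.9847:TOLERANCEPPM=50:INTENSITYPERCENT=50")
}
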