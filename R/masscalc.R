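# Monoisotopic mass arithmetic for formulas, ions and isotope/adduct deltas.
# Atomic masses are AME2020/IUPAC monoisotopic values embedded as literals;
# nothing is looked up at run time.

# Default symbol (no nucleon number) maps to the most abundant isotope.
.ELEMENT_MASSES <- c(
  "H"    = 1.0078250319,
  "1H"   = 1.0078250319,
  "2H"   = 2.0141017781,
  "C"    = 12.0,
  "12C"  = 12.0,
  "13C"  = 13.0033548351,
  "N"    = 14.0030740052,
  "15N"  = 15.0001088989,
  "O"    = 15.9949146221,
  "17O"  = 16.9991317565,
  "18O"  = 17.9991596129,
  "F"    = 18.9984031627,
  "Na"   = 22.9897692820,
  "Mg"   = 23.9850417000,
  "Si"   = 27.9769265350,
  "P"    = 30.9737619984,
  "S"    = 31.9720711744,
  "34S"  = 33.9678670120,
  "Cl"   = 34.9688526820,
  "37Cl" = 36.9659026020,
  "K"    = 38.9637064864,
  "Ca"   = 39.9625909000,
  "Fe"   = 55.9349363300,
  "54Fe" = 53.9396089900,
  "56Fe" = 55.9349363300,
  "57Fe" = 56.9353928410,
  "Cu"   = 62.9295977200,
  "Zn"   = 63.9291420100,
  "Br"   = 78.9183376010,
  "81Br" = 80.9162897120,
  "I"    = 126.9044719000
)

.ELECTRON_MASS <- 0.00054857990907
.PROTON_MASS <- 1.00727646688

#' Atomic and isotope masses
#'
#' Look up the monoisotopic mass of an element (most abundant isotope) or of a
#' specific isotope written with a leading nucleon number, e.g. `"13C"` or
#' `"54Fe"`. The labels `"electron"` and `"proton"` are also recognised.
#'
#' @param label Character vector of element/isotope labels.
#' @return Numeric vector of masses in Da.
#' @examples
#' element_mass(c("C", "13C", "56Fe"))
#' @export
element_mass <- function(label) {
  out <- vapply(label, function(l) {
    if (identical(l, "electron")) return(.ELECTRON_MASS)
    if (identical(l, "proton")) return(.PROTON_MASS)
    m <- .ELEMENT_MASSES[l]
    if (is.na(m)) stop("unknown element or isotope label: '", l, "'", call. = FALSE)
    unname(m)
  }, numeric(1))
  unname(out)
}

#' Parse a molecular formula
#'
#' Parses Hill-like formula strings such as `"C6H12O6"` or `"H4O4P"` into a
#' named count vector. Charge signs and isotope prefixes are not allowed in
#' formulas; use [mass_delta()] for isotope arithmetic.
#'
#' @param x A single formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x, perl = TRUE)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("malformed formula: '", x, "'", call. = FALSE)
  }
  counts <- integer(0)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (is.na(.ELEMENT_MASSES[sym])) {
      stop("unknown element '", sym, "' in formula '", x, "'", call. = FALSE)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts
}

#' Monoisotopic mass of a formula
#'
#' @param f A formula string (see [parse_formula()]) or a named count vector.
#' @return Mass in Da. Summation follows the fixed order of the internal
#'   element table so repeated calls are bit-identical.
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) == 0L) return(0.0)
  if (is.null(names(f)) || any(!nzchar(names(f)))) {
    stop("formula counts must be named by element symbol", call. = FALSE)
  }
  if (any(f < 0)) stop("element counts must be non-negative", call. = FALSE)
  # fixed summation order: order of the element table
  ord <- intersect(names(.ELEMENT_MASSES), names(f))
  if (length(ord) != length(f)) {
    bad <- setdiff(names(f), names(.ELEMENT_MASSES))
    stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sum(unname(.ELEMENT_MASSES[ord]) * as.numeric(f[ord]))
}

#' m/z of a protonated or deprotonated ion
#'
#' Computes `(M + z * m_proton) / z` for protonated species and
#' `(M - z * m_proton) / z` for deprotonated ones, with the proton mass
#' already accounting for the electron.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param z Absolute charge state, a positive integer.
#' @param mode `"protonated"` or `"deprotonated"`.
#' @return m/z in Da per charge.
#' @examples
#' ion_mz(monoisotopic_mass("H3PO4"), 1, "protonated")  # phosphate ion, ~98.9842
#' @export
ion_mz <- function(neutral_mass, z = 1L, mode = c("protonated", "deprotonated")) {
  mode <- match.arg(mode)
  if (length(z) != 1L || is.na(z) || z < 1 || z != round(z)) {
    stop("z must be a positive integer", call. = FALSE)
  }
  z <- as.numeric(z)
  if (mode == "protonated") (neutral_mass + z * .PROTON_MASS) / z
  else (neutral_mass - z * .PROTON_MASS) / z
}

# mass of a species expression: an isotope/element label, "proton"/"electron",
# "0", or a composite like "56Fe-3H" (isotope-table labels take precedence over
# a count prefix, so "2H" is deuterium but "3H" is 3 x hydrogen).
.species_mass <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  label <- gsub("[[:space:]]", "", label)
  if (identical(label, "0") || !nzchar(label)) return(0.0)
  m <- gregexpr("[+-]?[^+-]+", label, perl = TRUE)[[1]]
  parts <- regmatches(label, list(m))[[1]]
  total <- 0.0
  for (p in parts) {
    sign <- if (startsWith(p, "-")) -1 else 1
    p <- sub("^[+-]", "", p)
    if (p %in% c("proton", "electron") || !is.na(.ELEMENT_MASSES[p])) {
      total <- total + sign * element_mass(p)
    } else if (grepl("^[0-9]+[A-Za-z]", p)) {
      # count prefix: "3H" = 3 x H (only when not an isotope-table label)
      n <- as.integer(sub("^([0-9]+).*$", "\\1", p))
      rest <- sub("^[0-9]+", "", p)
      total <- total + sign * n * element_mass(rest)
    } else {
      stop("unknown species label: '", p, "'", call. = FALSE)
    }
  }
  total
}

#' Signed mass difference between two species
#'
#' Labels may be isotope symbols (`"13C"`, `"54Fe"`), plain element symbols,
#' or composites such as `"56Fe-3H"` (iron-56 minus three hydrogen atoms, the
#' Fe(III)-binding adduct delta). `"0"` denotes zero mass, so
#' `mass_delta("56Fe-3H")` is the delta itself.
#'
#' @param a,b Species labels; `b` defaults to `"0"`.
#' @return `mass(a) - mass(b)` in Da.
#' @examples
#' mass_delta("13C", "12C")   # ~1.0034, the 13C isotope spacing
#' mass_delta("56Fe-3H")      # ~52.91, iron binding delta
#' @export
mass_delta <- function(a, b = "0") {
  .species_mass(a) - .species_mass(b)
}
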