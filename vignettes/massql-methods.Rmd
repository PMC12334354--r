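---
title: "Pattern queries over mass spectra: semantics, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern queries over mass spectra: semantics, design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massql)
```

## The querying model

The package treats a mass spectrometry run as two columnar tables of
centroided peaks — survey (MS1) scans and fragmentation (MS2) scans — and a
query as a Boolean tree of *conditions* over one of those levels. A scan is
retrieved when its condition tree evaluates true. Three semantic rules carry
most of the weight:

1. **Per-peak matching.** An m/z condition is satisfied by a scan when at
   least one peak falls inside the condition's tolerance window and passes
   every intensity qualifier. `AND` across peak conditions therefore means
   "same scan, each condition satisfied by at least one, possibly different,
   peak". This is the only reading under which a four-peak isotope/adduct
   envelope is expressible as a conjunction.
2. **Variable binding.** A query may anchor a variable `X` to a peak
   (`MS1MZ=X`) and constrain other peaks relative to it (`MS1MZ=X-1.993`).
   Candidate values of X are the m/z of peaks passing the anchor condition's
   intrinsic qualifiers; the tree is re-evaluated once per candidate, and
   each satisfying binding yields a result row carrying `X` and the anchor
   intensity `Y`. Relative-intensity constraints
   (`INTENSITYMATCH=r:INTENSITYMATCHPERCENT=p`) accept a peak when
   `|i/Y - r| <= r * p/100`.
3. **Negation by exclusion.** `EXCLUDED` retains scans with *zero* matching
   peaks, all other qualifiers applied first — a peak below an intensity
   threshold does not count as a match. For any condition, the plain and
   `EXCLUDED` variants partition the scans of that level (a tested law).
   There is no `NOT` keyword; exclusion is the documented negation form.

MS2 scans additionally expose their precursor (`MS2PREC`), neutral losses
(`MS2NL=L`, evaluated as a product ion at `precursor - L` under a
singly-charged assumption), and — through the link to the most recent
preceding MS1 scan — `MS1MZ` conditions on the survey scan.

### Assumptions

Input spectra are treated as centroided peak lists; profile data are
accepted as-is with each raw point a peak (no centroiding is performed).
Cross-scan chromatographic grouping, similarity scoring and consensus
clustering are out of scope: the engine answers set-membership questions
about single scans.

## Parameters that matter

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `TOLERANCEMZ` / `TOLERANCEPPM` | Da / ppm | 0.1 Da when neither given | common loose default for unit-resolution instruments; configurable via `execution_config()` |
| ppm window | — | computed on the *target* m/z | fixed acceptance window per condition, independent of observation order |
| `INTENSITYPERCENT` | % of scan base peak | unset | base-peak normalization (`i_norm`) is computed per scan at load time |
| `INTENSITYTICPERCENT` | % of scan TIC | unset | TIC normalization (`i_tic_norm`) likewise; both sum/max laws are tested |
| `INTENSITYMATCHPERCENT` | % of the expected ratio | required with `INTENSITYMATCH` | no default tolerance is documented for ratio matching, so omitting it is a validation error rather than a silent guess |
| retention time | minutes | — | mzML/mzXML seconds are divided by 60 at load |
| polarity | +1 / −1 | positive, with a warning, when absent | a stated default beats silent failure; missing MS2 charge defaults to ±1 by mode |
| mobility | dimensionless | compared as stored | no unit is standardized across vendors |

All range comparisons (retention time, scan number, mobility, mass defect)
are inclusive on both ends. Ties among matching peaks are resolved by
reporting the most intense as `matched_intensity`; all matches count for
exclusion logic. `scansum` totals the per-scan matched intensities; it is
defined here because the output-function family names the aggregate but not
its arithmetic.

## Grammar and parser choices

The grammar is deliberately small: keywords are case-insensitive, numeric
literals are plain decimals (no scientific notation), and variable
arithmetic is limited to `X ± constant` — enough to express every anchored
envelope pattern above, while multiplication of X is rejected at parse time.
`AND` binds tighter than `OR`, the conventional precedence, with
parentheses overriding. Every input either parses or fails with exactly one
diagnostic carrying the earliest failing character offset (fuzzed in the
test suite). Parsing is strict by default; `parse_massql(check = FALSE)`
returns the raw tree so `validate_massql()` can report semantic diagnostics
(qualifier applicability, mutually exclusive tolerances, inverted
retention-time ranges, missing variable anchors) as data rather than
errors. Serialization is canonical — fixed keyword case, fixed qualifier
order, minimal parentheses — and `parse(serialize(q))` is structurally
exact, a property exercised over the bundled query corpus.

## What the synthetic data emulate — and what they do not

`generate_dataset()` builds files containing three scan populations:

* **decoy MS1/MS2 scans** — peaks uniform in m/z over 100–1000 Da with
  log-uniform intensities over 10³–10⁶, roughly mimicking the dynamic range
  of an Orbitrap survey scan;
* **planted iron envelopes** — the four-peak signature (apex, ⁵⁴Fe
  isotopologue at 6.3% of the apex, ¹³C isotopologue, apo species at the
  Fe − 3H delta) at theoretical isotope spacings (1.995327, 1.003355,
  52.911461 Da), with apices drawn over 300–900 Da;
* **planted phosphate MS2 spectra** — the H₄O₄P⁺ fragment at 98.984172 Da
  at 80% of the scan base peak plus noise peaks kept clear of its 50 ppm
  window.

Reference queries deliberately use the *printed* constants (1.993, 52.91,
1.0034, 98.9847) against the *theoretical* planted positions, so the suite
also verifies that printed-precision queries tolerate exact data within
their 10–50 ppm windows, as in real use. This is also why apices start at
300 Da: below roughly 235 Da the 10 ppm window around `X - 1.993` no longer
covers the true ⁵⁴Fe spacing, so a correctly planted envelope would be
unfindable by the printed-precision query — a property of the query
constants, not of the engine.

Every decoy scan (and the decoy portion of planted scans) is checked
against both reference patterns by a direct scalar checker and resampled on
collision (at most 100 retries, then a hard error), which makes the JSON
manifest an exact oracle: precision = recall = 1 is a *construction*, and
the tests assert the engine reproduces it. What passing these tests does
**not** show: robustness to chromatographic peak shape, co-elution,
centroiding artifacts, detector saturation, or isotope fine structure —
none of which the generator models.

## Numerical and engineering choices

* **Normalization invariants.** Per scan, every tied base peak has
  `i_norm = 1` and TIC fractions sum to 1 within 1e−9 relative; recomputed
  on load, cached bit-exactly.
* **Float boundaries.** Window and range comparisons use plain `<=`/`>=`;
  values sitting exactly on a boundary are subject to ordinary IEEE
  representation (e.g. the fractional part of 163.10 is fractionally below
  0.1). No epsilon is added — tolerances are the user's instrument to widen.
* **Cache.** One serialized blob per source file keyed by the md5 of the
  file content, with a sidecar checksum and a format version: corruption is
  a checksum error, staleness a regeneration signal, never a silent
  misread.
* **Determinism.** Result rows are sorted by `(file_id, scan, X)`;
  repeated executions serialize byte-identically, and batch output is
  invariant to worker count because files are processed independently and
  merged by sorted key. `file_id` is the input path as given, so same-named
  files in different directories cannot collide.
* **mzML writing** goes through `mzR` (proteowizard); MGF, whose line
  format is trivial and for which no reader is otherwise available here, is
  parsed and written directly. MGF carries MS2 only; exported blocks keep
  native scan numbers (`SCANS=`), which is what makes mzML- and MGF-derived
  query results comparable scan-for-scan.

## Validation strategy and problem sizes

Beyond unit tests, correctness rests on an independent brute-force
evaluator — scalar loops over scans × peaks × conditions × candidate
bindings — that re-implements the semantics naively. The suite checks
engine/oracle agreement on 140 random (query, dataset) pairs (40 in the
engine tests, 100 in the end-to-end suite), plus monotonicity laws
(widening a tolerance or relaxing an intensity gate never shrinks the
result set) and the exclusion partition law. The end-to-end recovery check
uses 3 files with 500 decoy MS1 scans / 20 planted iron envelopes and 200
decoy MS2 scans / 12 planted phosphate spectra — large enough that decoy
collisions would be seen, small enough to generate and query in seconds.

## Known limitations

* Neutral-loss arithmetic assumes singly charged precursors; multiply
  charged losses would require charge-aware mass arithmetic.
* Only one variable symbol (X) per query; nested or multi-variable
  envelopes are not expressible.
* No scoring: retrieval is Boolean, and ranking hits requires downstream
  tools.
* Scientific notation and negative literals are not part of the number
  grammar.
* The engine holds each file's peak table in memory; repository-scale runs
  are expected to shard by file through the batch runner.
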