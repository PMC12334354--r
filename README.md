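# massql

A query language and engine for finding patterns in mass spectrometry data,
implemented in R.

Untargeted metabolomics and proteomics experiments produce thousands of MS1
and MS/MS scans per file, and most of them are never interpreted. Chemical
classes nevertheless leave recognizable fingerprints in the raw data:
diagnostic product ions (organophosphate esters yield the phosphate cation
H₄O₄P⁺ at *m/z* 98.9842), characteristic neutral losses (sugar moieties),
isotope envelopes with known relative intensities (the ⁵⁴Fe/⁵⁶Fe pair of
iron-bound siderophores at ~6.3% abundance ratio, Δm ≈ 1.995 Da), and adduct
deltas (the apo/iron-bound spacing of 52.91 Da, i.e. Fe − 3H). This package
lets chemists and biologists express such patterns as short declarative
queries and retrieve the matching scans from mzML, mzXML or MGF files — one
file or a whole directory — without writing bespoke scripts.

## The query language

A query names an output function, a data level and a Boolean tree of
conditions with qualifiers:

```
QUERY scaninfo(MS2DATA) WHERE MS2PROD=98.9847:TOLERANCEPPM=50:INTENSITYPERCENT=50
```

*Conditions*: `MS1MZ`, `MS2PREC`, `MS2PROD`, `MS2NL`, `CHARGE`, `POLARITY`,
`RTMIN`/`RTMAX` (minutes), `SCANMIN`/`SCANMAX`, `MOBILITY=range(min=, max=)`.
*Qualifiers*: `TOLERANCEMZ` (Da) or `TOLERANCEPPM` (mutually exclusive; the
window is computed on the target *m/z*; default 0.1 Da),
`INTENSITYVALUE`, `INTENSITYPERCENT` (% of the scan base peak),
`INTENSITYTICPERCENT` (% of the scan TIC),
`INTENSITYMATCH`/`INTENSITYMATCHPERCENT` (expected intensity relative to the
anchor peak, with a relative tolerance in %), `MASSDEFECT=massdefect(min=,
max=)`, and `EXCLUDED` (the scan must *not* contain a matching peak).
Conditions combine with `AND`/`OR` (AND binds tighter) and parentheses.

Multi-peak envelopes are written with a variable: `MS1MZ=X` anchors X to any
peak in the scan, and the other conditions constrain peaks relative to it.
The iron-binding signature, for example, is

```
QUERY scaninfo(MS1DATA) WHERE MS1MZ=X:TOLERANCEPPM=10
  AND MS1MZ=X-1.993:TOLERANCEPPM=10:INTENSITYMATCH=0.063:INTENSITYMATCHPERCENT=25
  AND MS1MZ=X+1.0034:TOLERANCEPPM=10
  AND MS1MZ=X-52.91:TOLERANCEPPM=10
```

A scan is retrieved iff some binding of X satisfies every condition; the
result reports one row per (scan, binding) with the anchor *m/z* `X` and
anchor intensity `Y`.

## Worked example

Generate a small ground-truth dataset (2 planted iron patterns among 20
decoy MS1 scans; decoys are certified pattern-free at generation), then run
the iron query:

```r
library(massql)
gen <- generate_dataset("demo", n_files = 1, k_iron = 2, k_phosphate = 2,
                        n_decoy_ms1 = 20, n_decoy_ms2 = 20, seed = 1)
tab <- load_spectra(gen$files$mzml[1], file_id = "demo.mzML")
tab
#> <peak table: 22 MS1 scan(s) / 668 peaks; 22 MS2 scan(s) / 332 peaks; 1 file(s)>

res <- execute_query(reference_queries()[["iron"]], tab)
res[, c("scan", "rt", "X", "Y", "matched_intensity")]
#>   scan       rt        X        Y matched_intensity
#> 1   14 6.846896 769.3950 118496.4          118496.4
#> 2   17 7.686451 379.4459 231916.4          231916.4
```

Exactly the two planted scans come back: `X` is the apex *m/z* the pattern
was planted at, `Y` its intensity, and `matched_intensity` the most intense
peak matching a condition. Every query also renders to English:

```r
describe_massql(parse_massql(reference_queries()[["phosphate"]]))
#> [1] "Return information for all MS2 scans that contain a product ion at m/z
#>      98.9847 (tolerance 50 ppm) with intensity at least 50% of the base peak."
```

Batch runs over many files, from R (`run_batch()`) or the shell:

```sh
Rscript scripts/massql.R "QUERY scaninfo(MS2DATA) WHERE MS2PROD=98.9847:TOLERANCEPPM=50:INTENSITYPERCENT=50" \
  data/*.mzML --output hits.tsv --extract hits.mgf --workers 4
```

Merged output is sorted by `(file_id, scan, X)` and is byte-identical for
any worker count.

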