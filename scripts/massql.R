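#!/usr/bin/env Rscript
# Thin command-line wrapper:
#   Rscript scripts/massql.R "<QUERY>" <files...> --output results.tsv \
#     --format tsv|json --extract hits.mgf --extract-format mgf|mzml|json \
#     --cache-dir DIR --workers N [--keep-going]
status <- massql::massql_main(commandArgs(trailingOnly = TRUE))
quit(save = "no", status = status)
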