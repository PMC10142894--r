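# Regenerates the golden report consumed by the snapshot regression test.
# Run from the repository root after any intentional change to the pipeline:
#   Rscript tools/make_golden.R
library(nodeffect)
source("tests/testthat/helper-oracles.R")
report <- suppressWarnings(run_pipeline(golden_config()))
writeLines(format_report_json(report), "tests/testthat/golden/report.json")
cat("wrote tests/testthat/golden/report.json\n")
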