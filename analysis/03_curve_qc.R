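#!/usr/bin/env Rscript
# Standard-curve efficiency QC: fit each assay's dilution series and apply
# the retention gate (efficiency 90-110%, r-squared above 0.98). Assays
# failing the gate would be excluded from downstream quantification.

suppressMessages(library(erenorm))

series <- read_dilution_series("results/simdata/dilution_series.tsv")
qc <- curve_qc_table(series)
print(qc, digits = 4)
message(sprintf("%d of %d assays retained", sum(qc$pass), nrow(qc)))

utils::write.table(qc, "results/curve_qc.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
message("wrote results/curve_qc.tsv")
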