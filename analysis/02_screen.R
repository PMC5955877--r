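#!/usr/bin/env Rscript
# Candidate-assay screening: consensus conservation of the repeat family
# and mismatch-tolerant in-silico PCR target counts over the synthetic
# transcriptome, gated at 97% conservation and >= 30 expressed targets.

suppressMessages(library(erenorm))

sim <- "results/simdata"
dir.create("results", showWarnings = FALSE)

fam <- read_repeat_family(file.path(sim, "ere1_family.fasta"), "ere1")
pairs <- read_primer_table(file.path(sim, "primers.tsv"))
tx <- Biostrings::readDNAStringSet(file.path(sim, "transcriptome.fasta"))

res <- screen_assay(fam, pairs[["ere1"]], tx, conservation_min = 97,
                    min_hits = 30, caps = c(3, 2))
print(res)

truth <- utils::read.delim(file.path(sim, "insertion_truth.tsv"))
message(sprintf("constructed insertions: %d; predicted at cap 3: %d, cap 2: %d",
                sum(truth$inserted), res$n_targets[["cap3"]],
                res$n_targets[["cap2"]]))

write_screen_table(list(res), "results/screen.tsv")
write_amplicon_bed(tx, pairs[["ere1"]], "results/amplicons.tsv")
message("wrote results/screen.tsv and results/amplicons.tsv")
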