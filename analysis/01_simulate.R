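#!/usr/bin/env Rscript
# Generate the synthetic study inputs every later step consumes:
#   - six multi-condition Cq experiments sharing three truly stable and
#     three unstable ERE-like targets over a common per-sample mRNA shift
#   - a paired +RT/-RT Cq table with a known gDNA fraction
#   - standard-curve dilution series with known efficiencies
#   - a transcriptome with repeat cassettes embedded at known positions,
#     plus a gapped consensus alignment for conservation scoring
# Everything is a pure function of the seeds written below.

suppressMessages(library(erenorm))

seed <- 20181
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("simulating six stability experiments (20 samples, 6 targets each)")
for (e in 1:6) {
  g <- generate_cq(experiment_design(n_samples = 20, seed = seed + e))
  write_cq_table(g$cq, file.path(out, sprintf("experiment%d.csv", e)), "long")
}

message("simulating +RT/-RT pair at gDNA fraction 2^-11.64")
g <- generate_cq(experiment_design(n_samples = 12, seed = seed + 50))
rt <- generate_rt_pairs(g$cq, gdna_fraction = 2^(-11.64), noise_sd = 0.3,
                        seed = seed + 51)
write_cq_table(rt$plus_rt, file.path(out, "plus_rt.csv"), "long")
write_cq_table(rt$minus_rt, file.path(out, "minus_rt.csv"), "long")

message("simulating dilution series (6 points, 1/4 per step, 10 ug max)")
effs <- c(stable1 = 95, stable2 = 100, stable3 = 105, unstable1 = 88,
          unstable2 = 98, unstable3 = 113)
rows <- do.call(rbind, lapply(names(effs), function(t) {
  s <- generate_dilution_series(effs[[t]], noise_sd = 0.1,
                                seed = seed + match(t, names(effs)),
                                target_id = t)
  data.frame(target = t, log10_input = s$log10_input, cq = s$cq)
}))
utils::write.table(rows, file.path(out, "dilution_series.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)

message("simulating a transcriptome with embedded repeat cassettes")
pair <- primer_pair("ere1", "ACGTACGGTCCATGCATTGA", "TGCATGGACCTTAGCAGTCA")
gen <- generate_transcriptome(200, pair, insertion_prob = 0.4,
                              per_base_mutation_rate = 0.02,
                              antisense_prob = 0.3, seed = seed + 90)
writeLines(unlist(lapply(names(gen$transcripts), function(n)
  c(paste0(">", n), gen$transcripts[[n]]))),
  file.path(out, "transcriptome.fasta"))
utils::write.table(gen$truth, file.path(out, "insertion_truth.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(data.frame(assay = pair$assay_id, forward = pair$forward,
                              reverse = pair$reverse),
                   file.path(out, "primers.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)

# a small aligned repeat family: consensus plus copies mutated at ~2%
set.seed(seed + 99)
cons <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
copies <- vapply(1:8, function(i) {
  chars <- strsplit(cons, "")[[1]]
  mut <- which(runif(300) < 0.02)
  for (p in mut) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}, character(1))
writeLines(c(">ere1_consensus", cons,
             unlist(lapply(1:8, function(i) c(paste0(">copy", i), copies[i])))),
           file.path(out, "ere1_family.fasta"))

message("done: inputs under ", out)
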