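# a fixed assay used throughout (ACGT only, 20 nt each)
test_pair <- function() primer_pair("assay1",
                                    "ACGTACGGTCCATGCATTGA",
                                    "TGCATGGACCTTAGCAGTCA")

# transcript built around a known cassette: filler + fwd + spacer + rc(rev) + filler
build_transcript <- function(pair, spacer_n = 80, lead = 100, tail = 120,
                             seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  paste0(paste(sample(bases, lead, TRUE), collapse = ""),
         pair$forward,
         paste(sample(bases, spacer_n, TRUE), collapse = ""),
         revcomp <- chartr("ACGT", "TGCA",
                           paste(rev(strsplit(pair$reverse, "")[[1]]),
                                 collapse = "")),
         paste(sample(bases, tail, TRUE), collapse = ""))
}

test_that("conservation rate averages per-copy identity over consensus columns", {
  cons <- paste(rep("ACGT", 25), collapse = "")   # 100 nt
  fam <- repeat_family("f", cons, c(cons, cons))
  expect_equal(conservation_rate(fam), 100)

  copy <- cons
  substr(copy, 1, 3) <- "TTT"                      # 3 mismatches of 100
  expect_equal(conservation_rate(repeat_family("f", cons, copy)), 97)

  copy94 <- cons
  substr(copy94, 1, 6) <- "TGCATG"  # every base differs from ACGTAC
  fam2 <- repeat_family("f", cons, c(cons, copy94))
  expect_equal(conservation_rate(fam2), 97)        # mean of 100 and 94

  # gap columns in the consensus are excluded from the denominator
  gapped <- repeat_family("f", "AC-GT", c("ACAGT", "ACTGA"))
  expect_equal(conservation_rate(gapped), mean(c(1, 0.75)) * 100)
  expect_error(repeat_family("f", "AC-GT", "ACGT"), "width")
})

test_that("a constructed cassette yields exactly one sense amplicon", {
  pair <- test_pair()
  tx <- build_transcript(pair, spacer_n = 80)
  amps <- find_amplicons(tx, pair, max_mismatch = 0)
  expect_equal(nrow(amps), 1)
  expect_equal(amps$orientation, "+")
  expect_equal(amps$end - amps$start, 20 + 80 + 20)
  expect_equal(amps$start, 100)                    # 0-based after the lead
  expect_equal(substr(tx, amps$start + 1, amps$start + 20), pair$forward)
})

test_that("mismatch caps, 3' anchors and length windows are enforced", {
  pair <- test_pair()
  tx <- build_transcript(pair)
  # mutate 3 internal bases of the forward site (positions 3,5,7 of primer)
  mut <- tx
  for (p in c(103, 105, 107)) {
    old <- substr(mut, p, p)
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_equal(nrow(find_amplicons(mut, pair, max_mismatch = 3)), 1)
  expect_equal(nrow(find_amplicons(mut, pair, max_mismatch = 2)), 0)
  # pair-total semantics: 3 forward mismatches exceed a total cap of 3 is
  # false (3 <= 3), but a cap of 2 fails
  expect_equal(nrow(find_amplicons(mut, pair, 3, semantics = "pair_total")), 1)
  expect_equal(nrow(find_amplicons(mut, pair, 2, semantics = "pair_total")), 0)

  # 3'-terminal base of the forward primer must match exactly at any cap
  mut3p <- tx
  old <- substr(mut3p, 120, 120)                   # last base of fwd site
  substr(mut3p, 120, 120) <- setdiff(c("A", "C", "G", "T"), old)[1]
  expect_equal(nrow(find_amplicons(mut3p, pair, max_mismatch = 3)), 0)

  # amplicon length window
  expect_equal(nrow(find_amplicons(tx, pair, 0, amplicon_range = c(50, 100))), 0)
  # primer longer than transcript: empty, not an error
  expect_equal(nrow(find_amplicons("ACGT", pair, 0)), 0)
})

test_that("antisense cassettes are found with opposite orientation", {
  pair <- test_pair()
  tx <- build_transcript(pair)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(tx, "")[[1]]), collapse = ""))
  amps <- find_amplicons(rc, pair, max_mismatch = 0)
  expect_equal(nrow(amps), 1)
  expect_equal(amps$orientation, "-")
  expect_equal(amps$end - amps$start, 120)
  # coordinates map back onto the given strand
  expect_equal(amps$start, nchar(tx) - 220)        # lead 100 + cassette 120
})

test_that("target counting is exact against construction ground truth", {
  pair <- test_pair()
  gen <- generate_transcriptome(10, pair, insertion_prob = 1,
                                per_base_mutation_rate = 0, seed = 3)
  cnt <- count_expressed_targets(gen$transcripts, pair, caps = c(0, 2, 3))
  expect_equal(as.vector(cnt), c(10L, 10L, 10L))

  gen5 <- generate_transcriptome(10, pair, insertion_prob = 0.5, seed = 8)
  cnt5 <- count_expressed_targets(gen5$transcripts, pair, caps = c(3, 2))
  expect_equal(as.vector(cnt5["cap3"]), sum(gen5$truth$inserted))
  expect_setequal(attr(cnt5, "hits")$cap3,
                  gen5$truth$transcript[gen5$truth$inserted])

  absent <- primer_pair("none", "TTTTTTTTTTTTTTTTTTTT", "AAAAAAAAAAAAAAAAAAAC")
  expect_equal(as.vector(count_expressed_targets(gen5$transcripts, absent,
                                                 caps = c(3, 2))),
               c(0L, 0L))
})

test_that("counts are monotone in the cap and strand-symmetric", {
  pair <- test_pair()
  for (seed in 1:5) {
    gen <- generate_transcriptome(30, pair, insertion_prob = 0.6,
                                  per_base_mutation_rate = 0.03,
                                  antisense_prob = 0.4, seed = seed)
    cnt <- count_expressed_targets(gen$transcripts, pair, caps = c(3, 2, 1, 0))
    expect_true(all(diff(as.vector(cnt)) <= 0))    # caps listed descending
    rc <- vapply(gen$transcripts, function(s)
      chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = "")),
      character(1))
    cnt_rc <- count_expressed_targets(rc, pair, caps = c(3, 2, 1, 0))
    expect_equal(as.vector(cnt), as.vector(cnt_rc))
  }
})

test_that("screening combines conservation and adequacy gates", {
  pair <- test_pair()
  cons <- paste(rep("ACGT", 50), collapse = "")
  fam_pass <- repeat_family("f", cons, c(cons, cons))
  gen <- generate_transcriptome(40, pair, insertion_prob = 1, seed = 5)
  res <- screen_assay(fam_pass, pair, gen$transcripts, min_hits = 30)
  expect_true(res$conservation_pass)
  expect_true(res$adequacy_pass)
  expect_equal(unname(res$n_targets["cap3"]), 40L)

  # conservation 96.5% fails the 97% gate (7 true mismatches of 200 columns)
  copy <- cons
  substr(copy, 1, 7) <- "TGCATGC"
  fam_fail <- repeat_family("f", cons, copy)
  res2 <- screen_assay(fam_fail, pair, gen$transcripts)
  expect_equal(res2$conservation_rate, 96.5)
  expect_false(res2$conservation_pass)
  expect_true(res2$adequacy_pass)
})

test_that("screen and amplicon writers emit the declared columns", {
  pair <- test_pair()
  cons <- paste(rep("ACGT", 50), collapse = "")
  fam <- repeat_family("f", cons, cons)
  gen <- generate_transcriptome(8, pair, insertion_prob = 1, seed = 2)
  res <- screen_assay(fam, pair, gen$transcripts)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_screen_table(list(res), tsv)
  tab <- utils::read.delim(tsv)
  expect_named(tab, c("assay", "conservation_rate", "n_targets_cap3",
                      "n_targets_cap2", "conservation_pass", "adequacy_pass"))

  bed <- withr::local_tempfile(fileext = ".tsv")
  write_amplicon_bed(gen$transcripts, pair, bed)
  amp <- utils::read.delim(bed)
  expect_named(amp, c("transcript", "start", "end", "assay", "orientation"))
  expect_equal(nrow(amp), 8)
})

test_that("alignment FASTA and primer tables load through Biostrings readers", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">consensus", "ACGTACGT", ">copy1", "ACGTACGA", ">copy2",
               "ACGTACGT"), fa)
  fam <- read_repeat_family(fa)
  expect_equal(fam$family_id, "consensus")
  expect_equal(conservation_rate(fam), mean(c(7 / 8, 1)) * 100)

  pt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("assay\tforward\treverse",
               paste("a1", "ACGTACGGTCCATGCATTGA", "TGCATGGACCTTAGCAGTCA",
                     sep = "\t")), pt)
  pairs <- read_primer_table(pt)
  expect_equal(pairs[["a1"]]$forward, "ACGTACGGTCCATGCATTGA")
})
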