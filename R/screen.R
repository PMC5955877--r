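#' Primer pair for an ERE assay
#'
#' Both primers are given as synthesized, 5'->3': the forward primer reads
#' along the sense strand, the reverse primer is the reverse complement of
#' the sense strand downstream of it.
#'
#' @param assay_id assay identifier.
#' @param forward,reverse primer sequences, ACGT only, 15-35 nt.
#' @return A `primer_pair` object.
#' @export
primer_pair <- function(assay_id, forward, reverse) {
  for (p in c(forward, reverse)) {
    if (grepl("[^ACGTacgt]", p))
      stop("primer contains non-ACGT characters: ", p, call. = FALSE)
    if (nchar(p) < 15 || nchar(p) > 35)
      stop("primer length must be 15-35 nt: ", p, call. = FALSE)
  }
  structure(list(assay_id = assay_id,
                 forward = toupper(forward),
                 reverse = toupper(reverse)),
            class = "primer_pair")
}

#' Read primer pairs from a delimited table
#'
#' Expects columns `assay,forward,reverse`.
#'
#' @param path TSV/CSV path.
#' @return Named list of [primer_pair()] objects.
#' @export
read_primer_table <- function(path) {
  df <- read_delim_sniffed(path)
  need <- c("assay", "forward", "reverse")
  if (!all(need %in% names(df)))
    stop("primer table requires columns ", paste(need, collapse = ","), call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    primer_pair(df$assay[i], df$forward[i], df$reverse[i]))
  setNames(out, df$assay)
}

#' Repeat family: consensus plus aligned member copies
#'
#' The copies are supplied pre-aligned to the gapped consensus (all rows
#' share column coordinates); alignment construction is upstream of this
#' package.
#'
#' @param family_id family identifier.
#' @param consensus gapped consensus sequence (character, `-` for gaps).
#' @param copies character vector of aligned copies, all the same width as
#'   the consensus.
#' @return A `repeat_family` object.
#' @export
repeat_family <- function(family_id, consensus, copies) {
  if (length(copies) < 1) stop("a repeat family needs >= 1 copy", call. = FALSE)
  if (any(nchar(copies) != nchar(consensus)))
    stop("every copy must have the same aligned width as the consensus",
         call. = FALSE)
  structure(list(family_id = family_id,
                 consensus = toupper(consensus),
                 copies = toupper(copies)),
            class = "repeat_family")
}

#' Read a repeat family from a gapped alignment FASTA
#'
#' The first record is taken as the consensus; the remaining records are
#' the aligned copies.
#'
#' @param path FASTA path (plain text, `-` gaps allowed).
#' @param family_id optional id (default: name of the first record).
#' @return A [repeat_family()].
#' @export
read_repeat_family <- function(path, family_id = NULL) {
  aln <- Biostrings::readBStringSet(path)
  if (length(aln) < 2) stop("alignment FASTA needs a consensus plus >= 1 copy", call. = FALSE)
  seqs <- as.character(aln)
  repeat_family(family_id %||% names(aln)[1], seqs[1], unname(seqs[-1]))
}

#' Mean conservation rate of a repeat family
#'
#' Per copy, identity is the fraction of consensus non-gap columns at
#' which the copy matches the consensus; the family rate is the arithmetic
#' mean across copies, in percent. The screening threshold used in assay
#' selection is a minimum of 97%.
#'
#' @param family a [repeat_family()].
#' @return Percent identity in \[0, 100\].
#' @export
conservation_rate <- function(family) {
  stopifnot(inherits(family, "repeat_family"))
  cons <- strsplit(family$consensus, "", fixed = TRUE)[[1]]
  keep <- cons != "-"
  if (!any(keep)) stop("consensus is all gaps", call. = FALSE)
  idents <- vapply(family$copies, function(cp) {
    c_chars <- strsplit(cp, "", fixed = TRUE)[[1]]
    mean(c_chars[keep] == cons[keep])
  }, numeric(1))
  100 * mean(idents)
}

# integer-encode a sequence for fast Hamming scans
seq_int <- function(s) match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
                             c("A", "C", "G", "T"))

# coerce a transcript set (character vector or DNAStringSet) to a named
# character vector, preserving names
as_char_seqs <- function(x) {
  s <- as.character(x)
  if (is.null(names(s))) names(s) <- names(x)
  s
}

# Hamming-mismatch site search: positions (1-based) where `primer` aligns
# to `subject` with <= cap mismatches and an exact base at `exact_at`
# ("last" = primer 3' end lies at the site's last base, "first" = at its
# first base, as for the reverse-complemented reverse-primer site).
# Returns data.frame(start, mismatches).
match_sites <- function(primer_int, subject_int, cap, exact_at = c("last", "first")) {
  exact_at <- match.arg(exact_at)
  m <- length(primer_int)
  L <- length(subject_int)
  if (m > L) return(data.frame(start = integer(), mismatches = integer()))
  n_pos <- L - m + 1L
  mm <- integer(n_pos)
  for (o in seq_len(m)) {
    sub <- subject_int[o:(o + n_pos - 1L)]
    mm <- mm + (is.na(sub) | sub != primer_int[o])
  }
  anchor <- if (exact_at == "last") m else 1L
  sub_a <- subject_int[anchor:(anchor + n_pos - 1L)]
  ok <- mm <= cap & !is.na(sub_a) & sub_a == primer_int[anchor]
  data.frame(start = which(ok), mismatches = mm[ok])
}

#' Mismatch-tolerant in-silico PCR on one transcript
#'
#' Finds all predicted amplicons of a primer pair on a transcript. A site
#' match is Hamming distance only (no indels) with the primer's 3'-terminal
#' base required to match exactly — the base PCR extension starts from.
#' Both orientations of the template are searched; an amplicon is reported
#' when a forward site and a downstream reverse-complemented reverse-primer
#' site produce a product whose length lies in `amplicon_range`.
#'
#' @param transcript sequence (character string, ACGT; N is never matched).
#' @param pair a [primer_pair()].
#' @param max_mismatch mismatch cap (default 2).
#' @param amplicon_range allowed product length `(min, max)` in nt
#'   (default `c(50, 1000)`).
#' @param semantics `"per_primer"` (each primer independently <= cap,
#'   default) or `"pair_total"` (sum over both primers <= cap) — the two
#'   readings of a "mismatches per primer pair" cap.
#' @return data.frame `start,end,orientation,fwd_mismatches,rev_mismatches`
#'   with 0-based half-open coordinates on the input transcript;
#'   orientation `"+"` (cassette on the given strand) or `"-"`.
#' @export
find_amplicons <- function(transcript, pair, max_mismatch = 2,
                           amplicon_range = c(50, 1000),
                           semantics = c("per_primer", "pair_total")) {
  semantics <- match.arg(semantics)
  stopifnot(inherits(pair, "primer_pair"),
            length(amplicon_range) == 2, amplicon_range[1] <= amplicon_range[2],
            max_mismatch >= 0)
  transcript <- as.character(transcript)
  L <- nchar(transcript)
  fwd <- seq_int(pair$forward)
  rev_site <- seq_int(revcomp_chr(pair$reverse))
  sense <- seq_int(transcript)
  anti <- seq_int(revcomp_chr(transcript))

  scan_one <- function(subject_int, orientation) {
    f_hits <- match_sites(fwd, subject_int, max_mismatch, "last")
    r_hits <- match_sites(rev_site, subject_int, max_mismatch, "first")
    if (nrow(f_hits) == 0 || nrow(r_hits) == 0)
      return(NULL)
    grid <- expand.grid(f = seq_len(nrow(f_hits)), r = seq_len(nrow(r_hits)))
    a <- f_hits$start[grid$f]
    b <- r_hits$start[grid$r]
    len <- b + length(rev_site) - a
    ok <- b >= a + length(fwd) &
      len >= amplicon_range[1] & len <= amplicon_range[2]
    if (semantics == "pair_total")
      ok <- ok & (f_hits$mismatches[grid$f] + r_hits$mismatches[grid$r]) <= max_mismatch
    if (!any(ok)) return(NULL)
    start1 <- a[ok]                      # 1-based start on scanned strand
    end1 <- b[ok] + length(rev_site) - 1 # 1-based inclusive end
    if (orientation == "+") {
      s0 <- start1 - 1L; e0 <- end1
    } else {                             # map back from the reverse strand
      s0 <- L - end1; e0 <- L - start1 + 1L
    }
    data.frame(start = s0, end = e0, orientation = orientation,
               fwd_mismatches = f_hits$mismatches[grid$f][ok],
               rev_mismatches = r_hits$mismatches[grid$r][ok],
               stringsAsFactors = FALSE)
  }
  out <- rbind(scan_one(sense, "+"), scan_one(anti, "-"))
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      orientation = character(),
                      fwd_mismatches = integer(), rev_mismatches = integer(),
                      stringsAsFactors = FALSE)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Count transcripts with at least one predicted amplicon
#'
#' The BiSearch-style "predicted number of targets": per mismatch cap, the
#' number of distinct transcripts on which the pair yields any amplicon. A
#' transcript counts once regardless of amplicon multiplicity, so counts
#' are non-decreasing in the cap.
#'
#' @param transcripts named character vector, or a
#'   `Biostrings::DNAStringSet`.
#' @param pair a [primer_pair()].
#' @param caps integer vector of mismatch caps (default `c(3, 2)`).
#' @param amplicon_range,semantics see [find_amplicons()].
#' @return Named integer vector, one count per cap (names `cap3`, `cap2`,
#'   ...); attribute `hits` maps each cap to the hit transcript names.
#' @export
count_expressed_targets <- function(transcripts, pair, caps = c(3, 2),
                                    amplicon_range = c(50, 1000),
                                    semantics = c("per_primer", "pair_total")) {
  semantics <- match.arg(semantics)
  seqs <- as_char_seqs(transcripts)
  if (length(seqs) == 0) stop("transcript set is empty", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("tx", seq_along(seqs))
  max_cap <- max(caps)
  # one scan at the loosest cap; tighter caps are filtered from its hits
  amps <- lapply(seqs, find_amplicons, pair = pair, max_mismatch = max_cap,
                 amplicon_range = amplicon_range, semantics = semantics)
  counts <- integer(0)
  hits <- list()
  for (cap in caps) {
    hit <- vapply(amps, function(a) {
      if (nrow(a) == 0) return(FALSE)
      if (semantics == "per_primer")
        any(a$fwd_mismatches <= cap & a$rev_mismatches <= cap)
      else
        any(a$fwd_mismatches + a$rev_mismatches <= cap)
    }, logical(1))
    counts[paste0("cap", cap)] <- sum(hit)
    hits[[paste0("cap", cap)]] <- names(seqs)[hit]
  }
  structure(counts, hits = hits)
}

#' Screen one candidate ERE assay
#'
#' Combines the consensus conservation rate with the predicted target
#' counts and applies the selection gates: conservation at least
#' `conservation_min` percent, and at the loosest mismatch cap at least
#' `min_hits` expressed targets. There is no upper adequacy bound — more
#' predicted targets is considered better.
#'
#' @param family a [repeat_family()].
#' @param pair a [primer_pair()].
#' @param transcripts transcript set, see [count_expressed_targets()].
#' @param conservation_min conservation gate in percent (default 97).
#' @param min_hits adequacy gate on the predicted target count (default 30).
#' @param caps,amplicon_range,semantics see [count_expressed_targets()].
#' @return A `screen_result`: list with `assay_id`, `conservation_rate`,
#'   `n_targets` (named counts), `conservation_pass`, `adequacy_pass`.
#' @export
screen_assay <- function(family, pair, transcripts,
                         conservation_min = 97, min_hits = 30,
                         caps = c(3, 2), amplicon_range = c(50, 1000),
                         semantics = c("per_primer", "pair_total")) {
  semantics <- match.arg(semantics)
  cons <- conservation_rate(family)
  n <- count_expressed_targets(transcripts, pair, caps, amplicon_range, semantics)
  structure(list(assay_id = pair$assay_id,
                 family_id = family$family_id,
                 conservation_rate = cons,
                 n_targets = n,
                 conservation_pass = cons >= conservation_min,
                 adequacy_pass = unname(n[paste0("cap", max(caps))]) >= min_hits),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s: conservation %.2f%% (%s), targets %s (%s)\n",
              x$assay_id, x$conservation_rate,
              if (x$conservation_pass) "pass" else "FAIL",
              paste(names(x$n_targets), as.integer(x$n_targets),
                    sep = "=", collapse = " "),
              if (x$adequacy_pass) "adequate" else "INADEQUATE"))
  invisible(x)
}

#' Write screening results and per-amplicon coordinates
#'
#' @param results list of `screen_result` objects.
#' @param path output TSV `assay,conservation_rate,n_targets_cap3,
#'   n_targets_cap2,conservation_pass,adequacy_pass`.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(results, path) {
  rows <- lapply(results, function(r) {
    df <- data.frame(assay = r$assay_id,
                     conservation_rate = r$conservation_rate,
                     stringsAsFactors = FALSE)
    for (nm in names(r$n_targets))
      df[[paste0("n_targets_", nm)]] <- as.integer(r$n_targets[nm])
    df$conservation_pass <- r$conservation_pass
    df$adequacy_pass <- r$adequacy_pass
    df
  })
  write_delim_sniffed(do.call(rbind, rows), path)
}

#' Write amplicon coordinates as a BED-like table
#'
#' Columns `transcript,start,end,assay,orientation`, 0-based half-open.
#'
#' @param transcripts named character vector or `DNAStringSet`.
#' @param pair a [primer_pair()].
#' @param path output TSV path.
#' @param ... passed to [find_amplicons()].
#' @return `path`, invisibly.
#' @export
write_amplicon_bed <- function(transcripts, pair, path, ...) {
  seqs <- as_char_seqs(transcripts)
  if (is.null(names(seqs))) names(seqs) <- paste0("tx", seq_along(seqs))
  rows <- lapply(names(seqs), function(nm) {
    a <- find_amplicons(seqs[[nm]], pair, ...)
    if (nrow(a) == 0) return(NULL)
    data.frame(transcript = nm, start = a$start, end = a$end,
               assay = pair$assay_id, orientation = a$orientation,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript = character(), start = integer(), end = integer(),
               assay = character(), orientation = character())
  write_delim_sniffed(df, path)
}
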