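#' Design of a synthetic RT-qPCR experiment
#'
#' Describes the generative model behind [generate_cq()]:
#' `Cq_ij = baseline_j - s_i - delta_g(i),j - eta_ij - eps_ij`, where `s_i`
#' is a per-sample shift shared by every target (the varying mRNA fraction
#' that normalization exists to remove), `delta` a fixed condition effect,
#' `eta` target-specific instability noise with per-target standard
#' deviation `tau`, and `eps` technical noise. All terms act on the Cq
#' (log2-quantity) scale.
#'
#' @param n_samples number of samples.
#' @param targets data.frame with columns `target_id`, `baseline_cq` (in
#'   (5, 38)), `tau` (instability SD, cycles, >= 0); the default is three
#'   perfectly stable and three unstable (`tau = 0.5`) targets at
#'   baselines between 20 and 26.
#' @param groups character vector assigning each sample to a condition
#'   (default: one group).
#' @param group_effects optional matrix (conditions x targets) of fixed
#'   effects in cycles; default zero.
#' @param global_shift_sd SD of the shared per-sample shift `s_i`, cycles
#'   (default 1).
#' @param noise_sd technical noise SD, cycles (default 0.1, > 0).
#' @param max_cycles instrument ceiling (default 40).
#' @param seed integer seed; generation is a pure function of
#'   (design, seed).
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(n_samples = 20,
                              targets = default_sim_targets(),
                              groups = rep("g1", n_samples),
                              group_effects = NULL,
                              global_shift_sd = 1,
                              noise_sd = 0.1,
                              max_cycles = 40,
                              seed = 1L) {
  stopifnot(n_samples >= 2, length(groups) == n_samples,
            all(c("target_id", "baseline_cq", "tau") %in% names(targets)),
            all(targets$tau >= 0), global_shift_sd >= 0, noise_sd > 0)
  if (any(targets$baseline_cq <= 5 | targets$baseline_cq >= 38))
    stop("baseline Cq must lie in (5, 38)", call. = FALSE)
  conditions <- unique(groups)
  if (is.null(group_effects))
    group_effects <- matrix(0, length(conditions), nrow(targets),
                            dimnames = list(conditions, targets$target_id))
  stopifnot(all(conditions %in% rownames(group_effects)),
            all(targets$target_id %in% colnames(group_effects)))
  structure(list(n_samples = n_samples, targets = targets, groups = groups,
                 group_effects = group_effects,
                 global_shift_sd = global_shift_sd, noise_sd = noise_sd,
                 max_cycles = max_cycles, seed = as.integer(seed)),
            class = "experiment_design")
}

#' Default simulated target panel
#'
#' Three perfectly stable targets (`tau = 0`) and three unstable ones
#' (`tau = 0.5` cycles), the configuration used throughout the recovery
#' experiments.
#'
#' @param n_stable,n_unstable panel sizes.
#' @param tau_unstable instability SD of the unstable targets (cycles).
#' @return data.frame `target_id,baseline_cq,tau`.
#' @export
default_sim_targets <- function(n_stable = 3, n_unstable = 3, tau_unstable = 0.5) {
  n <- n_stable + n_unstable
  data.frame(
    target_id = c(sprintf("stable%d", seq_len(n_stable)),
                  sprintf("unstable%d", seq_len(n_unstable))),
    baseline_cq = seq(20, 26, length.out = n),
    tau = c(rep(0, n_stable), rep(tau_unstable, n_unstable)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic Cq matrix with known ground truth
#'
#' Draws from the model described in [experiment_design()]. Values are
#' clipped to `(1, max_cycles)`; any clipping is reported in the ground
#' truth, never silent. Identical (design, seed) pairs give identical
#' output.
#'
#' @param design an [experiment_design()].
#' @return List with `cq` (a [cq_matrix()]) and `truth`: `stable_targets`
#'   (tau = 0 and zero group effects), `sample_shifts` (realized `s_i`),
#'   `instability` (realized `eta` matrix), `noise` (realized `eps`),
#'   `clipped` (cell index matrix, possibly empty).
#' @export
generate_cq <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  with_seed(design$seed, {
    n <- design$n_samples
    tg <- design$targets
    Tn <- nrow(tg)
    sample_ids <- sprintf("s%02d", seq_len(n))
    s <- stats::rnorm(n, 0, design$global_shift_sd)
    eta <- sapply(seq_len(Tn), function(j) stats::rnorm(n, 0, tg$tau[j]))
    eps <- matrix(stats::rnorm(n * Tn, 0, design$noise_sd), n, Tn)
    delta <- design$group_effects[design$groups, tg$target_id, drop = FALSE]
    cqv <- matrix(rep(tg$baseline_cq, each = n), n, Tn) - s - delta - eta - eps
    dimnames(cqv) <- list(sample_ids, tg$target_id)
    clipped <- which(cqv <= 1 | cqv >= design$max_cycles, arr.ind = TRUE)
    cqv <- pmin(pmax(cqv, 1 + 1e-9), design$max_cycles)
    stable <- tg$target_id[tg$tau == 0 &
                             colSums(abs(design$group_effects[, tg$target_id,
                                                              drop = FALSE])) == 0]
    list(cq = cq_matrix(cqv, max_cycles = design$max_cycles),
         truth = list(stable_targets = stable,
                      sample_shifts = setNames(s, sample_ids),
                      instability = eta, noise = eps, clipped = clipped))
  })
}

#' Generate paired -RT controls for a +RT Cq matrix
#'
#' Emulates a no-reverse-transcriptase control: a gDNA fraction `f` of the
#' +RT signal remains, so the -RT reaction crosses threshold
#' `-log2(f)` cycles later (plus measurement noise). -RT values beyond the
#' cycle ceiling become non-detects, emulating instrument censoring.
#'
#' @param cq the +RT [cq_matrix()].
#' @param gdna_fraction scalar or named per-sample fraction in (0, 1).
#' @param noise_sd Cq noise SD of the -RT reaction (default 0.3).
#' @param seed integer seed.
#' @return An [rt_control_set()].
#' @export
generate_rt_pairs <- function(cq, gdna_fraction, noise_sd = 0.3, seed = 1L) {
  stopifnot(inherits(cq, "cq_matrix"))
  n <- length(cq$sample_ids)
  f <- if (length(gdna_fraction) == 1)
    setNames(rep(gdna_fraction, n), cq$sample_ids) else gdna_fraction[cq$sample_ids]
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("gdna_fraction must lie in (0, 1) for every sample", call. = FALSE)
  with_seed(seed, {
    shift <- matrix(-log2(f), n, length(cq$target_ids))
    noise <- matrix(stats::rnorm(length(shift), 0, noise_sd),
                    n, length(cq$target_ids))
    mv <- cq$values + shift + noise
    mv[mv > cq$max_cycles] <- NA_real_   # censored at the cycle ceiling
    dimnames(mv) <- dimnames(cq$values)
    rt_control_set(cq, cq_matrix(mv, max_cycles = cq$max_cycles))
  })
}

#' Generate a synthetic transcriptome with embedded primer cassettes
#'
#' Random ACGT backbones into which a PCR cassette — forward primer site,
#' spacer, reverse-complemented reverse primer site — is inserted with
#' probability `insertion_prob`, mimicking repeat copies interspersed
#' through transcripts. Each cassette base mutates independently at
#' `per_base_mutation_rate` (to one of the three other bases), and the
#' whole cassette is inserted in antisense orientation with probability
#' `antisense_prob`. The ground truth records every insertion with its
#' realized mismatch count per primer site and whether each primer's
#' 3'-terminal base survived intact.
#'
#' @param n_transcripts number of transcripts.
#' @param length_range backbone length range in nt (default
#'   `c(500, 2000)`).
#' @param pair the [primer_pair()] defining the cassette.
#' @param spacer_length nt between the primer sites (default 80).
#' @param insertion_prob per-transcript insertion probability.
#' @param per_base_mutation_rate cassette mutation rate in \[0, 1\].
#' @param antisense_prob probability a cassette is inserted antisense.
#' @param seed integer seed.
#' @return List with `transcripts` (named character vector) and `truth`:
#'   data.frame `transcript,inserted,position,orientation,fwd_mismatches,
#'   rev_mismatches,fwd_3p_intact,rev_3p_intact` (position 0-based,
#'   `NA` for non-inserted transcripts).
#' @export
generate_transcriptome <- function(n_transcripts, pair,
                                   length_range = c(500, 2000),
                                   spacer_length = 80,
                                   insertion_prob = 0.5,
                                   per_base_mutation_rate = 0,
                                   antisense_prob = 0,
                                   seed = 1L) {
  stopifnot(inherits(pair, "primer_pair"),
            insertion_prob >= 0, insertion_prob <= 1,
            per_base_mutation_rate >= 0, per_base_mutation_rate <= 1,
            antisense_prob >= 0, antisense_prob <= 1)
  bases <- c("A", "C", "G", "T")
  len_f <- nchar(pair$forward)
  len_r <- nchar(pair$reverse)
  cass_len <- len_f + spacer_length + len_r
  if (cass_len > length_range[1])
    stop("cassette (", cass_len, " nt) exceeds the minimum transcript length",
         call. = FALSE)
  with_seed(seed, {
    tx <- character(n_transcripts)
    truth <- vector("list", n_transcripts)
    for (i in seq_len(n_transcripts)) {
      L <- sample(length_range[1]:length_range[2], 1)
      backbone <- sample(bases, L, replace = TRUE)
      nm <- sprintf("tx%03d", i)
      if (stats::runif(1) < insertion_prob) {
        spacer <- sample(bases, spacer_length, replace = TRUE)
        cass <- c(strsplit(pair$forward, "")[[1]], spacer,
                  strsplit(revcomp_chr(pair$reverse), "")[[1]])
        mut <- stats::runif(cass_len) < per_base_mutation_rate
        for (p in which(mut))
          cass[p] <- sample(setdiff(bases, cass[p]), 1)
        fwd_mm <- sum(mut[seq_len(len_f)])
        rev_mm <- sum(mut[(cass_len - len_r + 1):cass_len])
        # 3' anchors: forward primer's last base; reverse primer's 3' end
        # maps to the FIRST base of its reverse-complemented site
        fwd_3p <- !mut[len_f]
        rev_3p <- !mut[cass_len - len_r + 1]
        antisense <- stats::runif(1) < antisense_prob
        if (antisense)
          cass <- strsplit(revcomp_chr(paste(cass, collapse = "")), "")[[1]]
        at <- sample.int(L - cass_len + 1L, 1)  # 1-based insertion offset
        tx[i] <- paste(c(backbone[seq_len(at - 1)], cass,
                         backbone[seq(at, length.out = L - cass_len - at + 1)]),
                       collapse = "")
        truth[[i]] <- data.frame(
          transcript = nm, inserted = TRUE, position = at - 1L,
          orientation = if (antisense) "-" else "+",
          fwd_mismatches = fwd_mm, rev_mismatches = rev_mm,
          fwd_3p_intact = fwd_3p, rev_3p_intact = rev_3p,
          stringsAsFactors = FALSE)
      } else {
        tx[i] <- paste(backbone, collapse = "")
        truth[[i]] <- data.frame(
          transcript = nm, inserted = FALSE, position = NA_integer_,
          orientation = NA_character_,
          fwd_mismatches = NA_integer_, rev_mismatches = NA_integer_,
          fwd_3p_intact = NA, rev_3p_intact = NA,
          stringsAsFactors = FALSE)
      }
      names(tx)[i] <- nm
    }
    list(transcripts = tx, truth = do.call(rbind, truth))
  })
}

#' Generate a standard-curve dilution series
#'
#' Simulates Cq responses along a serial dilution for a known true
#' amplification efficiency:
#' `Cq_p = intercept - log10(input_p) / log10(1 + e/100) + noise`, inputs
#' descending from `max_input` by `dilution_factor` per step. The default
#' design is the 6-point, 1/4-dilution, 10-microgram-maximum series.
#'
#' @param true_efficiency_percent true efficiency, in (50, 150); default
#'   95, a realistic passing assay.
#' @param n_points number of dilution points (default 6).
#' @param dilution_factor fold dilution per step (default 4).
#' @param max_input maximum template input in micrograms (default 10).
#' @param noise_sd Cq noise SD (default 0.1).
#' @param intercept Cq at 1 unit input (default 20).
#' @param seed integer seed.
#' @param target_id assay label.
#' @return A [dilution_series()].
#' @export
generate_dilution_series <- function(true_efficiency_percent = 95,
                                     n_points = 6, dilution_factor = 4,
                                     max_input = 10, noise_sd = 0.1,
                                     intercept = 20, seed = 1L,
                                     target_id = "sim") {
  stopifnot(true_efficiency_percent > 50, true_efficiency_percent < 150,
            n_points >= 3, dilution_factor > 1, noise_sd >= 0)
  a <- 1 + true_efficiency_percent / 100
  inputs <- max_input / dilution_factor^(seq_len(n_points) - 1)
  with_seed(seed, {
    cqs <- intercept - log10(inputs) / log10(a) +
      stats::rnorm(n_points, 0, noise_sd)
    dilution_series(target_id, log10(inputs), cqs,
                    n_points = n_points, dilution_factor = dilution_factor)
  })
}
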