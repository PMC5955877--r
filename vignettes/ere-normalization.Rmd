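---
title: "Selecting and validating expressed-repetitive-element reference targets for RT-qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating expressed-repetitive-element reference targets for RT-qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erenorm)
```

## The problem

RT-qPCR quantifies a transcript of interest relative to reference targets
assumed stable across samples. Classic single-gene references are often not
stable in the conditions under study. Expressed repetitive elements (EREs)
offer an alternative: a repeat family with many copies residing inside many
different transcripts measures the aggregate mRNA fraction, which is robust
to differential expression of any individual host gene. The price is that
ERE assays unavoidably co-amplify genomic DNA, so DNase treatment must be
verified explicitly.

`erenorm` implements the complete selection-and-validation workflow as
composable, tested functions: candidate screening by in-silico PCR,
standard-curve efficiency QC, geNorm stability analysis, genomic-DNA
carryover assessment, and cross-experiment consensus ranking. Seeded
generators supply synthetic data with known ground truth for every stage,
so the whole pipeline is verifiable without any external download.

## The geNorm model

Let $Q_{ij}$ be the relative quantity of target $j$ in sample $i$, obtained
from quantification cycles by
$Q_{ij} = a_j^{\min_i Cq_{ij} - Cq_{ij}}$ with amplification factor
$a_j = 1 + e_j/100$ (so the most abundant sample has $Q = 1$). For a pair
of targets $(j,k)$ the pairwise variation is

$$V_{jk} = \mathrm{sd}_i\left(\log_2 \frac{Q_{ij}}{Q_{ik}}\right),$$

using the sample ($n-1$) standard deviation throughout, matching the
original geNorm implementation. A target's stability measure is
$M_j = \frac{1}{T-1}\sum_{k \ne j} V_{jk}$; lower is more stable. The key
property exploited by the whole approach is *global-shift invariance*: any
per-sample shift common to all targets (the varying mRNA fraction itself)
cancels from every log ratio, so $M$ measures only target-specific
instability.

`rank_stepwise()` repeatedly removes the highest-$M$ target, recomputing
$M$ on the reduced panel each round, until two remain; those two are
inseparable (each one's $M$ equals the pair's mutual $V$) and are reported
tied. `v_curve()` computes $V_{n/n+1}$, the standard deviation of
$\log_2(NF_n/NF_{n+1})$ where $NF_n$ is the per-sample geometric mean of
the $n$ most stable targets, and `optimal_target_count()` returns the
smallest $n$ with $V_{n/n+1}$ below the cutoff.

Thresholds are configuration with conventional defaults: $M < 0.5$ "high"
and $M < 0.2$ "very high" stability (both read strictly), and $V < 0.15$
for the optimal panel size.

Design decisions that were genuinely open:

* **Which M the classes use.** Both a target's first-pass $M$ (computed on
  the full panel) and its $M$ at elimination are reported; stability
  classes are assigned from the elimination-step $M$, the value geNorm
  ranking charts plot. The per-target output table carries both columns so
  either convention can be read off.
* **Ties.** Equal $M$ values are broken by target id, the lexicographically
  later id eliminated first; the final pair is reported in lexicographic
  order. This makes the ranking a deterministic function of the input.
* **Missing data.** Non-detects are never imputed. The quantity transform
  rejects incomplete matrices and `subset_cq()` supports explicit
  pre-filtering, because no principled missing-data rule exists for Cq
  values censored at the instrument ceiling.

## Efficiency QC

`fit_standard_curve()` regresses Cq on $\log_{10}$ input over a dilution
series and derives the amplification efficiency
$e = (10^{-1/\text{slope}} - 1) \times 100$. The retention gate
(`gate_assay()`) keeps assays with $90 \le e \le 110$ percent (inclusive)
and $r^2 > 0.98$ (strict), reading the conventional bounds literally. The
default design mirrors standard practice: 6 points, 1/4 dilution per step,
10 µg maximum input. Only relative input spacing matters to the slope.

A note on precision: with a single 6-point series and Cq noise of
$\sigma = 0.1$ cycles, the standard error of the slope is
$\sigma/\sqrt{S_{xx}} \approx 0.04$, which propagates to roughly 1.5–2
percentage points of efficiency uncertainty depending on the true value.
Efficiency estimates from single series are therefore only accurate to a
few points; replicated series or more points tighten this proportionally.

## Genomic DNA carryover

With paired reactions, $\Delta Cq$ per sample is the average $-RT$ Cq
minus the average $+RT$ Cq over the chosen targets
(average-then-subtract; the subtract-then-average variant is exposed and
coincides when target sets match). The residual gDNA contribution to the
$+RT$ signal is $2^{-\Delta Cq}$, reported in percent at full precision
and rounded to two significant figures. `summarize_gdna()` reports the
mean with a two-sided 95% t-interval on $n-1$ degrees of freedom — a
deliberate choice recorded in the output metadata, since small per-group
sample sizes make the t-interval the defensible default. A $-RT$
non-detect contributes the instrument ceiling (default 40 cycles), which
biases $\Delta Cq$ conservatively upward; the sample is flagged censored
and excluded from the CI. A $+RT$ non-detect invalidates the comparison
and is rejected outright.

## In-silico PCR screening

Candidate assays are screened on two axes. First, family conservation:
mean per-copy identity to the gapped consensus over consensus non-gap
columns, gated at a minimum of 97%. Second, breadth of expression: the
number of transcripts on which the primer pair is predicted to amplify.
`find_amplicons()` uses Hamming matching (no indels) with a per-primer
mismatch cap and requires the 3'-terminal base of each primer to match
exactly — the base polymerase extension starts from. Both template
orientations are searched; coordinates are 0-based half-open with explicit
orientation. The amplicon length window defaults to 50–1000 nt.

Two ambiguities were resolved as switches rather than silently: the
mismatch cap is per primer by default (`semantics = "pair_total"` gives
the summed reading), and counting is transcript-level — a transcript
counts once however many amplicons it yields, which makes counts provably
non-decreasing in the cap. The adequacy gate requires at least 30
predicted targets at the loosest cap, with no upper bound.

## Cross-experiment consensus

Per-experiment rankings are combined by minimizing the summed Spearman
footrule displacement to all lists; the weighted variant multiplies each
target's displacement by its stability score min-max normalized to
$[0,1]$ within its list, so targets whose placement the experiment
determines sharply (high relative $M$) weigh more. Up to 9 targets
`aggregate_exhaustive()` enumerates all permutations and returns the
global minimum — it doubles as the oracle for the stochastic search.
`aggregate_ce()` is a cross-entropy Monte-Carlo optimizer: a
position-probability matrix, initialized uniform, drives sequential
sampling of permutations without replacement; each iteration the
lowest-objective `elite_fraction` of `sample_size` samples pulls the
matrix toward their position frequencies with learning rate `smoothing`.
Defaults (`sample_size = 10k²`, elite 0.1, smoothing 0.25, patience 15)
are magnitudes typical of cross-entropy combinatorial optimizers; they are
echoed in the output together with the seed, and identical seeds reproduce
identical results.

Tie-breaking among equal-objective minimizers is deterministic: candidates
are ordered by their sequence of mean-rank values, then by their target-id
sequence. Consequently exact relabeling invariance holds whenever the
minimizer is unique; with ties, the returned representative depends on
ids by construction.

When experiment rankings come from geNorm results (`as_ranked_list()`),
the scores attached to the ordering are the elimination-step M-values; in
the rare case that sequence is non-monotone along the ranking it is
monotonized by a running maximum so the ranked-list invariant (scores
non-decreasing along the ordering) holds, and the ordering itself is never
altered.

## What the synthetic data emulates — and what it does not

`generate_cq()` draws
$Cq_{ij} = \beta_j - s_i - \delta_{g(i),j} - \eta_{ij} - \varepsilon_{ij}$:
a shared per-sample shift $s_i \sim N(0, \sigma_s^2)$ (the mRNA-fraction
variation normalization exists to remove), fixed condition effects
$\delta$, target-specific instability $\eta_{ij} \sim N(0, \tau_j^2)$, and
technical noise $\varepsilon_{ij} \sim N(0, \sigma_\varepsilon^2)$, all on
the Cq (log2-quantity) scale. Modeling instability additively on this
scale makes ground truth analytically approachable — for two stable
targets, $E[V^2] = 2\sigma_\varepsilon^2$. The default panel is three
perfectly stable targets ($\tau = 0$) and three unstable ones
($\tau = 0.5$ cycles) over 20 samples with $\sigma_s = 1$ and
$\sigma_\varepsilon = 0.1$; the default dilution-series truth is 95%
efficiency with $\sigma = 0.1$ Cq noise, a realistic good assay; -RT
pairs default to noise 0.3 cycles with the gDNA fraction supplied
explicitly. Values are clipped to the instrument range with clipping
reported, never silent.

The generators emulate the *statistical structure* the analysis assumes,
not real tissue panels: no RNA degradation or integrity gradients, no
inter-plate effects, no correlated instability between targets, no
heavy-tailed outliers, Gaussian noise throughout, and transcriptome
backbones are uniform-random rather than drawn from a real genome (so
background priming is effectively absent). Recovery results on synthetic
data therefore demonstrate correctness of the machinery under the model,
not performance guarantees on real samples.

## Numerical choices and degenerate inputs

* Replicates are averaged on the Cq scale; a cell is non-detect only if
  every replicate failed. Within-cell ranges above `max_spread` (default
  0.5 cycles, a common plausibility bound; the choice is ours) are flagged
  but still averaged.
* Table round-trips are bit-exact for values with up to six fractional
  digits (numbers are written with 15 significant digits).
* Oracle-equivalence tests compare against independent straight-line
  reimplementations at tolerance 1e-12; sums and standard deviations in
  double precision agree far below that.
* Zero-variance dilution inputs, all-gap consensus sequences, single-target
  matrices, empty replicate tables, and non-permutation candidates are all
  rejected with specific errors rather than producing NaN.
* A non-negative standard-curve slope yields an efficiency flagged
  undefined rather than a negative efficiency; the gate then fails with
  that reason.

## Problem sizes

The bundled analysis scripts and the validation suite run six experiments
of 20 samples by 6 targets, 12-sample -RT panels, 200-transcript synthetic
transcriptomes, and consensus instances of 4–6 targets over 3–6 lists —
sizes at which the exhaustive aggregator is exact and the full suite
completes in well under typical qPCR analysis times. All stages scale
linearly in samples and quadratically in targets except exhaustive
aggregation (factorial, guarded at 9 targets; use the cross-entropy search
beyond).

## Known limitations

* geNorm cannot separate the final two targets; they are reported tied.
* The mismatch-cap reading ("per primer" vs "per pair, total") genuinely
  changes predicted counts at tight caps; both are implemented, the
  per-primer reading is the default, and published counts from other tools
  should be compared under the matching semantics.
* The cross-entropy search is a heuristic: its objective is bounded below
  by the exhaustive optimum and equality is empirical (checked on small
  instances), not guaranteed.
* Efficiency estimates from single 6-point series carry 1.5–2 points of
  standard error at $\sigma = 0.1$ Cq noise; gate decisions near the 90%
  or 110% boundaries are correspondingly noisy.
* No instrument-native file formats (RDML, vendor spreadsheets) and no
  inter-plate calibration; inputs are plain delimited tables and FASTA.
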