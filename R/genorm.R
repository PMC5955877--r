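#' geNorm pairwise variation between two targets
#'
#' `V_jk` is the sample standard deviation (n-1 denominator) across samples
#' of the log2 ratio of the two targets' relative quantities. Two targets
#' that track each other perfectly — i.e. differ only by the per-sample
#' mRNA fraction — have V = 0 regardless of expression level.
#'
#' @param q a `quantity_matrix` from [to_relative_quantities()].
#' @param j,k distinct target ids (or column indices).
#' @return V_jk, a non-negative scalar; symmetric in `j` and `k`.
#' @export
pairwise_variation <- function(q, j, k) {
  stopifnot(inherits(q, "quantity_matrix"))
  if (nrow(q$quantities) < 2)
    stop("pairwise variation needs >= 2 samples", call. = FALSE)
  lj <- log2(q$quantities[, j])
  lk <- log2(q$quantities[, k])
  if (identical(j, k)) stop("j and k must differ", call. = FALSE)
  stats::sd(lj - lk)
}

#' geNorm expression-stability measure M
#'
#' A target's M-value is the arithmetic mean of its pairwise variations
#' against every other target in the matrix. Lower M means more stable.
#' Conventional stability bands: M < 0.5 "high", M < 0.2 "very high".
#'
#' @param q a `quantity_matrix`.
#' @param j target id or column index; omit to get the full named vector.
#' @return M_j, or a named numeric vector of all M-values when `j` is `NULL`.
#' @export
m_value <- function(q, j = NULL) {
  stopifnot(inherits(q, "quantity_matrix"))
  m <- m_values_all(log2(q$quantities))
  if (is.null(j)) m else unname(m[if (is.character(j)) j else q$target_ids[j]])
}

# M for every target from the log2-quantity matrix; the workhorse used by
# the stepwise ranking so each round costs one pass over target pairs
m_values_all <- function(l2) {
  t_ids <- colnames(l2)
  Tn <- ncol(l2)
  if (Tn < 2) stop("M-value needs >= 2 targets", call. = FALSE)
  V <- matrix(0, Tn, Tn, dimnames = list(t_ids, t_ids))
  for (a in seq_len(Tn - 1)) for (b in (a + 1):Tn) {
    v <- stats::sd(l2[, a] - l2[, b])
    V[a, b] <- v
    V[b, a] <- v
  }
  setNames(rowSums(V) / (Tn - 1), t_ids)
}

#' Stepwise geNorm ranking by iterative exclusion
#'
#' Repeatedly removes the target with the highest current M-value,
#' recomputing all M-values on the reduced set after each exclusion, until
#' two targets remain. The final two cannot be separated (each one's M is
#' the pair's mutual V) and are reported tied, in lexicographic order. Ties
#' on M during elimination are broken deterministically: the
#' lexicographically later id is eliminated first.
#'
#' @param q a complete `quantity_matrix` with >= 3 targets and >= 2 samples.
#' @return A list: `elimination_order` (least stable first), `elimination_m`
#'   (M of the eliminated target at its elimination step; the final pair
#'   share the last value), `ranked_targets` (most stable first),
#'   `m_first_pass` (named M-values on the full matrix).
#' @export
rank_stepwise <- function(q) {
  stopifnot(inherits(q, "quantity_matrix"))
  l2 <- log2(q$quantities)
  if (ncol(l2) < 3) stop("stepwise ranking needs >= 3 targets", call. = FALSE)
  if (nrow(l2) < 2) stop("stepwise ranking needs >= 2 samples", call. = FALSE)
  if (any(!is.finite(l2)))
    stop("quantity matrix must be complete and strictly positive", call. = FALSE)
  m_first <- m_values_all(l2)
  elim <- character()
  elim_m <- numeric()
  cur <- l2
  while (ncol(cur) > 2) {
    m <- m_values_all(cur)
    # highest M goes; on ties the lexicographically later id goes first
    worst <- names(m)[m == max(m)]
    worst <- worst[order(worst, decreasing = TRUE)][1]
    elim <- c(elim, worst)
    elim_m <- c(elim_m, unname(m[worst]))
    cur <- cur[, setdiff(colnames(cur), worst), drop = FALSE]
  }
  last_m <- m_values_all(cur)  # both equal the pair's V
  final_pair <- sort(colnames(cur))
  elim <- c(elim, rev(final_pair))   # keeps ranked = rev(elim) lexicographic
  elim_m <- c(elim_m, rep(unname(last_m[1]), 2))
  list(elimination_order = elim,
       elimination_m = setNames(elim_m, elim),
       ranked_targets = rev(elim),
       m_first_pass = m_first)
}

#' Per-sample normalization factor
#'
#' The geometric mean of the selected reference targets' relative
#' quantities, per sample — the quantity a gene of interest is divided by
#' when normalizing.
#'
#' @param q a `quantity_matrix`.
#' @param targets non-empty character vector of target ids (order
#'   irrelevant).
#' @return Named numeric vector, one NF per sample.
#' @export
normalization_factor <- function(q, targets) {
  stopifnot(inherits(q, "quantity_matrix"))
  if (length(targets) == 0) stop("target subset must be non-empty", call. = FALSE)
  sub <- q$quantities[, targets, drop = FALSE]
  if (any(sub <= 0)) stop("all quantities must be > 0", call. = FALSE)
  setNames(apply(sub, 1, geometric_mean), q$sample_ids)
}

#' Pairwise-variation curve V_n/n+1
#'
#' For each n from 2 to T-1, the sample standard deviation across samples
#' of `log2(NF_n / NF_(n+1))`, where NF_n is the normalization factor built
#' from the n most stable targets. A small V_n/n+1 means the (n+1)-th
#' target adds nothing, so n references suffice.
#'
#' @param q a `quantity_matrix`.
#' @param ranked_targets most-stable-first ordering, e.g. from
#'   [rank_stepwise()].
#' @return Named numeric vector `V2`, `V3`, ... of length T-2.
#' @export
v_curve <- function(q, ranked_targets) {
  stopifnot(inherits(q, "quantity_matrix"))
  Tn <- length(ranked_targets)
  if (Tn < 3) stop("V curve needs >= 3 ranked targets", call. = FALSE)
  vs <- numeric(Tn - 2)
  for (n in 2:(Tn - 1)) {
    nf_n <- normalization_factor(q, ranked_targets[seq_len(n)])
    nf_n1 <- normalization_factor(q, ranked_targets[seq_len(n + 1)])
    vs[n - 1] <- stats::sd(log2(nf_n / nf_n1))
  }
  setNames(vs, paste0("V", 2:(Tn - 1)))
}

#' Optimal number of reference targets
#'
#' The smallest n whose V_n/n+1 falls below the cutoff (0.15 by
#' convention): at that point adding the next reference target no longer
#' changes the normalization factor appreciably. When no V is below the
#' cutoff, all T targets are returned with an advisory flag.
#'
#' @param v_series named vector from [v_curve()].
#' @param cutoff V threshold (default 0.15).
#' @return List with `optimal_n` and `flag` (`NA` or
#'   `"no V below cutoff"`).
#' @export
optimal_target_count <- function(v_series, cutoff = 0.15) {
  if (length(v_series) == 0) stop("empty V series", call. = FALSE)
  n_values <- 2:(length(v_series) + 1)
  below <- which(v_series < cutoff)
  if (length(below))
    list(optimal_n = n_values[below[1]], flag = NA_character_)
  else
    list(optimal_n = length(v_series) + 2, flag = "no V below cutoff")
}

#' Stability class from an M-value
#'
#' `very_high` for M < 0.2, `high` for 0.2 <= M < 0.5, otherwise
#' `unstable`; both boundaries are exclusive ("below" the threshold).
#'
#' @param M M-value(s), non-negative.
#' @param m_high,m_very_high class thresholds (defaults 0.5 and 0.2).
#' @return Character vector of classes.
#' @export
classify_stability <- function(M, m_high = 0.5, m_very_high = 0.2) {
  if (any(M < 0)) stop("M-values cannot be negative", call. = FALSE)
  if (!(m_very_high > 0 && m_very_high < m_high))
    stop("thresholds must satisfy 0 < m_very_high < m_high", call. = FALSE)
  ifelse(M < m_very_high, "very_high", ifelse(M < m_high, "high", "unstable"))
}

#' Full geNorm stability analysis of one experiment
#'
#' Runs the complete engine: first-pass M-values, stepwise exclusion
#' ranking, V curve, optimal reference-target count, and stability classes
#' (assigned from each target's M at its elimination step, the value the
#' geNorm ranking charts plot; first-pass M is reported alongside).
#'
#' @param q a complete `quantity_matrix` (>= 3 targets, >= 2 samples).
#' @param m_high,m_very_high,v_cutoff thresholds; defaults 0.5, 0.2, 0.15.
#' @return A `genorm_stability` object: list with `m_first_pass`,
#'   `elimination_order`, `elimination_m`, `ranked_targets`, `v_series`,
#'   `optimal_n`, `optimal_n_flag`, `classes`, and `table` (a per-target
#'   data.frame `target,M_first_pass,rank,M_at_elimination,class`).
#' @examples
#' set.seed(1)
#' cqm <- generate_cq(experiment_design(n_samples = 8, seed = 1))$cq
#' g <- genorm_stability(to_relative_quantities(cqm))
#' g$ranked_targets
#' @export
genorm_stability <- function(q, m_high = 0.5, m_very_high = 0.2, v_cutoff = 0.15) {
  rk <- rank_stepwise(q)
  vs <- v_curve(q, rk$ranked_targets)
  opt <- optimal_target_count(vs, cutoff = v_cutoff)
  classes <- classify_stability(rk$elimination_m, m_high, m_very_high)
  tab <- data.frame(
    target = rk$ranked_targets,
    M_first_pass = unname(rk$m_first_pass[rk$ranked_targets]),
    rank = seq_along(rk$ranked_targets),
    M_at_elimination = unname(rk$elimination_m[rk$ranked_targets]),
    class = unname(classes[rk$ranked_targets]),
    stringsAsFactors = FALSE)
  structure(list(m_first_pass = rk$m_first_pass,
                 elimination_order = rk$elimination_order,
                 elimination_m = rk$elimination_m,
                 ranked_targets = rk$ranked_targets,
                 v_series = vs,
                 optimal_n = opt$optimal_n,
                 optimal_n_flag = opt$flag,
                 classes = classes,
                 table = tab),
            class = "genorm_stability")
}

#' @export
print.genorm_stability <- function(x, ...) {
  cat("<genorm_stability> ", length(x$ranked_targets), " targets; optimal n = ",
      x$optimal_n,
      if (!is.na(x$optimal_n_flag)) paste0(" (", x$optimal_n_flag, ")") else "",
      "\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write geNorm outputs for one experiment
#'
#' Emits the per-target stability table and the `n,V` table as delimited
#' files, and a JSON summary with the ranking and optimal n.
#'
#' @param result a `genorm_stability` object.
#' @param stability_path,v_path,json_path output paths (any may be `NULL`
#'   to skip).
#' @return Invisibly, the list of written paths.
#' @export
write_genorm_result <- function(result, stability_path = NULL, v_path = NULL,
                                json_path = NULL) {
  stopifnot(inherits(result, "genorm_stability"))
  written <- list()
  if (!is.null(stability_path))
    written$stability <- write_delim_sniffed(result$table, stability_path)
  if (!is.null(v_path)) {
    vt <- data.frame(n = 2:(length(result$v_series) + 1),
                     V = unname(result$v_series))
    written$v <- write_delim_sniffed(vt, v_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(ranked_targets = result$ranked_targets,
           optimal_n = result$optimal_n,
           optimal_n_flag = result$optimal_n_flag,
           v_series = as.list(result$v_series)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    written$json <- json_path
  }
  invisible(written)
}
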