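#' Per-experiment stability ranking
#'
#' One experiment's most-stable-first target ordering together with the
#' stability scores (M-values) that produced it.
#'
#' @param experiment_id experiment label.
#' @param ordering character vector of targets, most stable first.
#' @param scores named numeric stability scores (lower = more stable),
#'   covering every target in `ordering`; the ordering must be consistent
#'   with non-decreasing scores.
#' @return A `ranked_list` object.
#' @export
ranked_list <- function(experiment_id, ordering, scores) {
  if (anyDuplicated(ordering)) stop("ordering contains duplicates", call. = FALSE)
  if (!all(ordering %in% names(scores)))
    stop("scores must cover every target in the ordering", call. = FALSE)
  s <- unname(scores[ordering])
  if (is.unsorted(s))
    stop("ordering is inconsistent with its scores (must be non-decreasing)",
         call. = FALSE)
  structure(list(experiment_id = experiment_id,
                 ordering = ordering,
                 scores = scores[ordering]),
            class = "ranked_list")
}

check_lists <- function(lists) {
  if (length(lists) == 0) stop("no ranked lists supplied", call. = FALSE)
  universe <- lists[[1]]$ordering
  for (l in lists) {
    stopifnot(inherits(l, "ranked_list"))
    if (!setequal(l$ordering, universe))
      stop("all ranked lists must share one target universe", call. = FALSE)
  }
  sort(universe)
}

#' Read per-experiment rankings from a delimited table
#'
#' Expects columns `experiment,target,rank,M`; one [ranked_list()] per
#' experiment, ordered by rank.
#'
#' @param path TSV/CSV path.
#' @return List of [ranked_list()] objects.
#' @export
read_ranked_lists <- function(path) {
  df <- read_delim_sniffed(path)
  need <- c("experiment", "target", "rank", "M")
  if (!all(need %in% names(df)))
    stop("ranking table requires columns ", paste(need, collapse = ","), call. = FALSE)
  df$rank <- as.numeric(df$rank)
  df$M <- as.numeric(df$M)
  lapply(split(df, df$experiment), function(d) {
    d <- d[order(d$rank), ]
    ranked_list(d$experiment[1], d$target, setNames(d$M, d$target))
  })
}

# per-list positions of a candidate's targets, 1-based
positions_of <- function(ordering) setNames(seq_along(ordering), ordering)

# per-list weights for the weighted footrule: scores min-max normalized
# within the list to [0, 1]
footrule_weights <- function(l) {
  s <- unname(l$scores)
  rng <- max(s) - min(s)
  w <- if (rng == 0) rep(1, length(s)) else (s - min(s)) / rng
  setNames(w, names(l$scores))
}

#' Aggregation objective of a candidate consensus ordering
#'
#' Spearman-footrule distance summed over the input lists: for each list,
#' the sum over targets of the absolute displacement between the target's
#' position in the candidate and its position in that list. The weighted
#' variant multiplies each term by the target's stability score min-max
#' normalized to \[0, 1\] within its list.
#'
#' @param candidate character vector: a permutation of the shared universe.
#' @param lists list of [ranked_list()] objects over one universe.
#' @param distance `"footrule"` or `"weighted_footrule"`.
#' @return Non-negative scalar; 0 iff the candidate equals every list.
#' @export
objective_of <- function(candidate, lists,
                         distance = c("footrule", "weighted_footrule")) {
  distance <- match.arg(distance)
  universe <- check_lists(lists)
  if (!setequal(candidate, universe) || anyDuplicated(candidate))
    stop("candidate must be a permutation of the shared target universe",
         call. = FALSE)
  pos_c <- positions_of(candidate)
  total <- 0
  for (l in lists) {
    pos_l <- positions_of(l$ordering)
    disp <- abs(pos_c[names(pos_l)] - pos_l)
    if (distance == "weighted_footrule")
      disp <- disp * footrule_weights(l)[names(pos_l)]
    total <- total + sum(disp)
  }
  unname(total)
}

#' Mean rank position per target
#'
#' @param lists list of [ranked_list()] objects over one universe.
#' @return Named numeric vector: arithmetic mean of 1-based positions.
#' @export
mean_rank_positions <- function(lists) {
  universe <- check_lists(lists)
  pos <- sapply(lists, function(l) positions_of(l$ordering)[universe])
  setNames(rowMeans(matrix(pos, nrow = length(universe))), universe)
}

# all permutations of 1..n as a matrix (n! rows); guarded by callers
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- (r + 1):(r + nrow(sub))
    out[rows, 1] <- i
    out[rows, -1] <- ifelse(sub >= i, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Exhaustive consensus ranking
#'
#' Enumerates every permutation of the target universe and returns the
#' global minimizer of the aggregation objective. Feasible only for small
#' universes (guarded at 9 targets, 362880 permutations); it doubles as
#' the verification oracle for the cross-entropy search. Among equal-
#' objective minimizers the tie is broken by the sequence of mean-rank
#' values along the ordering, then by the target-id sequence, both
#' lexicographically — a deterministic, input-order-independent rule.
#'
#' @param lists list of [ranked_list()] objects over one universe.
#' @param distance `"footrule"` or `"weighted_footrule"`.
#' @return A `consensus_ranking`: list with `ordering`, `objective`,
#'   `method = "exhaustive"`, `mean_rank`, `seed = NA`.
#' @export
aggregate_exhaustive <- function(lists, distance = c("footrule", "weighted_footrule")) {
  distance <- match.arg(distance)
  universe <- check_lists(lists)
  k <- length(universe)
  if (k > 9)
    stop("universe of ", k, " targets is too large for exhaustive search; ",
         "use aggregate_ce()", call. = FALSE)
  perms <- permutations_all(k)
  obj <- apply(perms, 1, function(p) objective_of(universe[p], lists, distance))
  best <- which(obj == min(obj))
  mr <- mean_rank_positions(lists)
  if (length(best) > 1) {
    keys <- lapply(best, function(i) {
      ord <- universe[perms[i, ]]
      list(mr = unname(mr[ord]), ids = ord)
    })
    ord_idx <- order_by_keys(keys)
    best <- best[ord_idx[1]]
  }
  ordering <- universe[perms[best[1], ]]
  structure(list(ordering = ordering,
                 objective = min(obj),
                 method = "exhaustive",
                 distance = distance,
                 mean_rank = mr,
                 seed = NA_integer_),
            class = "consensus_ranking")
}

# lexicographic order over composite keys: mean-rank sequence, then id
# sequence; returns an ordering of the key list
order_by_keys <- function(keys) {
  strings <- vapply(keys, function(k)
    paste(c(sprintf("%015.8f", k$mr), k$ids), collapse = "\r"), character(1))
  order(strings)
}

#' Cross-entropy configuration
#'
#' Tuning parameters of the cross-entropy Monte-Carlo search. Defaults are
#' magnitudes typical of cross-entropy combinatorial optimizers: the
#' per-iteration sample grows quadratically with the universe size, a
#' tenth of the sample forms the elite set, and the position-probability
#' matrix is updated with a 0.25 learning rate.
#'
#' @param k universe size (used only for the sample-size default).
#' @param sample_size permutations sampled per iteration (default `10 k^2`).
#' @param elite_fraction fraction of the sample retained as elite, in
#'   (0, 1) (default 0.1).
#' @param smoothing learning rate in (0, 1] for the probability-matrix
#'   update (default 0.25).
#' @param max_iterations hard iteration cap (default 100).
#' @param convergence_patience iterations without objective improvement
#'   before stopping (default 15).
#' @return A `ce_config` list.
#' @export
ce_config <- function(k = NULL, sample_size = if (!is.null(k)) 10 * k^2 else 250,
                      elite_fraction = 0.1, smoothing = 0.25,
                      max_iterations = 100, convergence_patience = 15) {
  stopifnot(sample_size >= 2,
            elite_fraction > 0, elite_fraction < 1,
            smoothing > 0, smoothing <= 1,
            max_iterations >= 1, convergence_patience >= 1)
  structure(list(sample_size = as.integer(sample_size),
                 elite_fraction = elite_fraction,
                 smoothing = smoothing,
                 max_iterations = as.integer(max_iterations),
                 convergence_patience = as.integer(convergence_patience)),
            class = "ce_config")
}

#' Cross-entropy Monte-Carlo consensus ranking
#'
#' Stochastic search over permutations. A k x k position-probability
#' matrix (rows = consensus positions, columns = targets), initialized
#' uniform, drives sequential sampling without replacement: each position
#' draws a not-yet-placed target with probability proportional to its
#' entry in that row. Each iteration samples `sample_size` permutations,
#' keeps the `elite_fraction` with the lowest objective, and moves the
#' matrix toward the elite position frequencies with learning rate
#' `smoothing`. The search stops after `convergence_patience` iterations
#' without improvement of the best objective, or at `max_iterations`, and
#' returns the best ordering ever seen. The same seed always reproduces
#' the same result.
#'
#' @param lists list of [ranked_list()] objects over one universe.
#' @param distance `"footrule"` or `"weighted_footrule"` (default
#'   weighted, with min-max-normalized M-values as weights).
#' @param config a [ce_config()]; defaults scale with the universe size.
#' @param seed integer seed for the sampler.
#' @return A `consensus_ranking` with `method = "cross_entropy"`, the
#'   `seed`, and a `config` echo.
#' @export
aggregate_ce <- function(lists, distance = c("weighted_footrule", "footrule"),
                         config = NULL, seed = 1L) {
  distance <- match.arg(distance)
  universe <- check_lists(lists)
  if (length(lists) < 2)
    stop("cross-entropy aggregation needs >= 2 ranked lists", call. = FALSE)
  k <- length(universe)
  if (is.null(config)) config <- ce_config(k)
  stopifnot(inherits(config, "ce_config"))
  n_elite <- max(1L, floor(config$sample_size * config$elite_fraction))

  # precompute per-list positions and weights so the objective is a few
  # vector ops per candidate
  pos_mat <- sapply(lists, function(l) positions_of(l$ordering)[universe])
  w_mat <- if (distance == "weighted_footrule")
    sapply(lists, function(l) footrule_weights(l)[universe])
  else matrix(1, k, length(lists))
  obj_fun <- function(perm) {       # perm: indices into universe by position
    pos_c <- integer(k)
    pos_c[perm] <- seq_len(k)
    sum(abs(pos_c - pos_mat) * w_mat)
  }

  with_seed(seed, {
    P <- matrix(1 / k, k, k)
    best_obj <- Inf
    best_perm <- seq_len(k)
    stall <- 0L
    for (iter in seq_len(config$max_iterations)) {
      samples <- replicate(config$sample_size, sample_permutation(P))
      objs <- apply(samples, 2, obj_fun)
      elite <- samples[, order(objs)[seq_len(n_elite)], drop = FALSE]
      it_best <- min(objs)
      if (it_best < best_obj - 1e-12) {
        best_obj <- it_best
        best_perm <- samples[, which.min(objs)]
        stall <- 0L
      } else stall <- stall + 1L
      Freq <- matrix(0, k, k)
      for (e in seq_len(ncol(elite)))
        Freq[cbind(seq_len(k), elite[, e])] <- Freq[cbind(seq_len(k), elite[, e])] + 1
      P <- (1 - config$smoothing) * P + config$smoothing * Freq / ncol(elite)
      if (stall >= config$convergence_patience) break
    }
    structure(list(ordering = universe[best_perm],
                   objective = best_obj,
                   method = "cross_entropy",
                   distance = distance,
                   mean_rank = mean_rank_positions(lists),
                   seed = as.integer(seed),
                   config = config),
              class = "consensus_ranking")
  })
}

# one permutation from the position-probability matrix: position by
# position, sample among the not-yet-placed targets
sample_permutation <- function(P) {
  k <- nrow(P)
  remaining <- seq_len(k)
  perm <- integer(k)
  for (pos in seq_len(k)) {
    p <- P[pos, remaining]
    if (sum(p) <= 0) p <- rep(1, length(remaining))
    pick <- if (length(remaining) == 1) remaining else
      remaining[sample.int(length(remaining), 1, prob = p)]
    perm[pos] <- pick
    remaining <- remaining[remaining != pick]
  }
  perm
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat("<consensus_ranking> method ", x$method, " (", x$distance,
      "), objective ", format(x$objective), "\n", sep = "")
  cat(paste(seq_along(x$ordering), x$ordering, collapse = " > "), "\n")
  invisible(x)
}

#' Box-plot summary of per-experiment M-values
#'
#' Quartiles (linear-interpolation definition), median, and outliers
#' beyond 1.5 x IQR of each target's M-values across experiments — the
#' tabular content of a stability box plot.
#'
#' @param lists list of [ranked_list()] objects carrying M-values as
#'   scores.
#' @return data.frame `target,q1,median,q3,outliers` (outliers as a
#'   comma-joined string), ordered by median.
#' @export
m_value_box_summary <- function(lists) {
  universe <- check_lists(lists)
  rows <- lapply(universe, function(t) {
    ms <- vapply(lists, function(l) unname(l$scores[t]), numeric(1))
    qs <- stats::quantile(ms, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- qs[3] - qs[1]
    out <- ms[ms < qs[1] - 1.5 * iqr | ms > qs[3] + 1.5 * iqr]
    data.frame(target = t, q1 = qs[1], median = qs[2], q3 = qs[3],
               outliers = paste(format(out, digits = 6, trim = TRUE), collapse = ","),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[order(df$median, df$target), , drop = FALSE]
}

#' Write a consensus ranking as JSON
#'
#' @param consensus a `consensus_ranking`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(consensus, path) {
  stopifnot(inherits(consensus, "consensus_ranking"))
  jsonlite::write_json(
    list(ordering = consensus$ordering,
         objective = consensus$objective,
         method = consensus$method,
         distance = consensus$distance,
         mean_rank = as.list(consensus$mean_rank),
         seed = consensus$seed,
         config = if (!is.null(consensus$config)) unclass(consensus$config) else NULL),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
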