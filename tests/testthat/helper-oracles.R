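# Independent straight-line reimplementations used as oracles. These are
# deliberately naive — explicit loops, explicit formulas — and share no
# code with the package internals they check.

# sample standard deviation written out longhand
oracle_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

# geNorm V_jk directly from the definition
oracle_v_jk <- function(qmat, j, k) {
  oracle_sd(log2(qmat[, j] / qmat[, k]))
}

# M_j as a plain loop over all other targets
oracle_m_j <- function(qmat, j) {
  others <- setdiff(colnames(qmat), j)
  total <- 0
  for (k in others) total <- total + oracle_v_jk(qmat, j, k)
  total / length(others)
}

oracle_m_all <- function(qmat) {
  sapply(colnames(qmat), function(j) oracle_m_j(qmat, j))
}

# stepwise exclusion, recomputing M from scratch each round; ties broken
# by eliminating the lexicographically later id first
oracle_rank <- function(qmat) {
  elim <- character()
  elim_m <- numeric()
  cur <- qmat
  while (ncol(cur) > 2) {
    m <- oracle_m_all(cur)
    mx <- max(m)
    tied <- sort(names(m)[abs(m - mx) == 0], decreasing = TRUE)
    worst <- tied[1]
    elim <- c(elim, worst)
    elim_m <- c(elim_m, m[[worst]])
    cur <- cur[, colnames(cur) != worst, drop = FALSE]
  }
  pair <- sort(colnames(cur))
  last <- oracle_v_jk(cur, pair[1], pair[2])
  list(elimination_order = c(elim, pair[2], pair[1]),
       elimination_m = c(elim_m, last, last),
       ranked = rev(c(elim, pair[2], pair[1])))
}

# normalization factor as an nth-root product, V curve from the definition
oracle_nf <- function(qmat, targets) {
  apply(qmat[, targets, drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
}

oracle_v_curve <- function(qmat, ranked) {
  Tn <- length(ranked)
  vs <- numeric(Tn - 2)
  for (n in 2:(Tn - 1)) {
    nf_n <- oracle_nf(qmat, ranked[1:n])
    nf_n1 <- oracle_nf(qmat, ranked[1:(n + 1)])
    vs[n - 1] <- oracle_sd(log2(nf_n / nf_n1))
  }
  vs
}

# footrule objective by double loop over lists and targets
oracle_footrule <- function(candidate, orderings, weights = NULL) {
  total <- 0
  for (li in seq_along(orderings)) {
    ord <- orderings[[li]]
    for (t in candidate) {
      d <- abs(which(candidate == t) - which(ord == t))
      if (!is.null(weights)) d <- d * weights[[li]][[t]]
      total <- total + d
    }
  }
  total
}

# a random complete quantity matrix (per-target max scaled to 1)
random_quantity_matrix <- function(n_samples, n_targets) {
  q <- matrix(2^stats::rnorm(n_samples * n_targets, 0, 1),
              n_samples, n_targets,
              dimnames = list(sprintf("s%02d", 1:n_samples),
                              sprintf("t%02d", 1:n_targets)))
  sweep(q, 2, apply(q, 2, max), "/")
}

as_qm <- function(qmat) {
  structure(list(quantities = qmat,
                 sample_ids = rownames(qmat),
                 target_ids = colnames(qmat),
                 amplification_factors = setNames(rep(2, ncol(qmat)),
                                                  colnames(qmat))),
            class = "quantity_matrix")
}

# a random ranked_list over `universe` with increasing scores
random_ranked_list <- function(id, universe) {
  ord <- sample(universe)
  ranked_list(id, ord, setNames(sort(runif(length(ord), 0.05, 1)), ord))
}
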