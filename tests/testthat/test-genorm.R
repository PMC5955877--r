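test_that("pairwise variation matches the log-ratio definition and is symmetric", {
  q <- as_qm(matrix(c(1, 0.5, 0.25,  0.8, 0.4, 0.2,  1, 1, 1), 3, 3,
                    dimnames = list(c("s1", "s2", "s3"), c("a", "b", "c"))))
  expect_equal(pairwise_variation(q, "a", "b"), 0)          # proportional pair
  expect_equal(pairwise_variation(q, "a", "c"), 1)          # sd of {0,-1,-2}
  set.seed(3)
  qm <- as_qm(random_quantity_matrix(8, 5))
  for (p in list(c("t01", "t03"), c("t02", "t05"))) {
    expect_equal(pairwise_variation(qm, p[1], p[2]),
                 pairwise_variation(qm, p[2], p[1]))
  }
  one_sample <- matrix(1, 1, 3, dimnames = list("s1", c("t01", "t02", "t03")))
  expect_error(pairwise_variation(as_qm(one_sample), "t01", "t02"),
               ">= 2 samples")
})

test_that("M is the mean pairwise variation against all other targets", {
  q <- as_qm(matrix(c(1, 0.5, 0.25,  1, 0.5, 0.25,  1, 1, 1), 3, 3,
                    dimnames = list(c("s1", "s2", "s3"), c("a", "b", "c"))))
  expect_equal(m_value(q, "a"), 0.5)       # mean of {0, 1}
  expect_equal(m_value(q, "b"), 0.5)
  q2 <- as_qm(matrix(c(1, 0.5, 0.8, 0.4, 0.6, 0.3), 2, 3,
                     dimnames = list(c("s1", "s2"), c("a", "b", "c"))))
  expect_equal(unname(m_value(q2)), c(0, 0, 0))   # all proportional

  set.seed(11)
  for (i in 1:50) {
    qm <- random_quantity_matrix(6, 10)
    expect_equal(m_value(as_qm(qm)), oracle_m_all(qm), tolerance = 1e-12)
  }
})

test_that("stepwise ranking eliminates a dominant-noise target first", {
  set.seed(5)
  base <- 2^rnorm(10)
  qmat <- cbind(a = base, b = base * 2^0.01, c = base * 2^-0.01,
                noisy = base * 2^rnorm(10, 0, 2))
  qmat <- sweep(qmat, 2, apply(qmat, 2, max), "/")
  rownames(qmat) <- sprintf("s%d", 1:10)
  rk <- rank_stepwise(as_qm(qmat))
  expect_equal(rk$elimination_order[1], "noisy")
  expect_equal(rk$ranked_targets, rev(rk$elimination_order))
})

test_that("stepwise ranking and V series equal the independent oracle", {
  set.seed(19)
  qmat <- random_quantity_matrix(8, 5)
  rk <- rank_stepwise(as_qm(qmat))
  orc <- oracle_rank(qmat)
  expect_identical(rk$elimination_order, orc$elimination_order)
  expect_equal(unname(rk$elimination_m), orc$elimination_m, tolerance = 1e-12)
  vs <- v_curve(as_qm(qmat), rk$ranked_targets)
  expect_equal(unname(vs), oracle_v_curve(qmat, rk$ranked_targets),
               tolerance = 1e-12)
})

test_that("equal-M ties eliminate the lexicographically later target first", {
  # b and d are exact copies: identical M at every step
  base <- c(1, 0.5, 0.25, 0.125)
  qmat <- cbind(b = base, d = base, a = base * 2^c(0, 0.3, -0.3, 0.1))
  qmat <- sweep(qmat, 2, apply(qmat, 2, max), "/")
  rownames(qmat) <- sprintf("s%d", 1:4)
  rk <- rank_stepwise(as_qm(qmat))
  expect_equal(rk$elimination_order[1], "a")      # only unstable one
  expect_equal(rk$ranked_targets[1:2], c("b", "d"))  # tied pair, lexicographic
  expect_equal(unname(rk$elimination_m["b"]), unname(rk$elimination_m["d"]))
})

test_that("normalization factors are geometric means, order-invariant", {
  q <- as_qm(matrix(c(1, 0.25, 1, 1), 2, 2,
                    dimnames = list(c("s1", "s2"), c("a", "b"))))
  expect_equal(unname(normalization_factor(q, c("a", "b"))), c(1, 0.5))
  expect_equal(unname(normalization_factor(q, "a")),
               unname(q$quantities[, "a"]))
  set.seed(2)
  qm <- as_qm(random_quantity_matrix(6, 4))
  expect_equal(normalization_factor(qm, c("t01", "t03", "t04")),
               normalization_factor(qm, c("t04", "t01", "t03")))
})

test_that("the V curve has T-2 entries and vanishes for a redundant target", {
  set.seed(4)
  qmat <- random_quantity_matrix(8, 3)
  nf2 <- sqrt(qmat[, 1] * qmat[, 2])
  qmat <- cbind(qmat, t99 = nf2 / max(nf2))   # proportional to NF_2
  vs <- v_curve(as_qm(qmat), c("t01", "t02", "t99", "t03"))
  expect_length(vs, 2)
  expect_equal(unname(vs["V2"]), 0, tolerance = 1e-12)
})

test_that("the optimal reference count is the first V below the cutoff", {
  expect_equal(optimal_target_count(c(V2 = 0.10, V3 = 0.2))$optimal_n, 2)
  expect_equal(optimal_target_count(c(V2 = 0.20, V3 = 0.12))$optimal_n, 3)
  res <- optimal_target_count(c(V2 = 0.2, V3 = 0.18, V4 = 0.16))
  expect_equal(res$optimal_n, 5)
  expect_equal(res$flag, "no V below cutoff")
})

test_that("stability classes use strict thresholds", {
  expect_equal(classify_stability(c(0.15, 0.45, 0.5, 0.2, 0.19999)),
               c("very_high", "high", "unstable", "high", "very_high"))
  expect_error(classify_stability(-0.1), "negative")
})

test_that("M, ranking and V are invariant to a global per-sample shift", {
  set.seed(23)
  d <- experiment_design(n_samples = 10, seed = 23)
  cqm <- generate_cq(d)$cq
  shift <- runif(10, -2, 2)
  shifted <- cq_matrix(cqm$values - shift, max_cycles = cqm$max_cycles)
  g1 <- genorm_stability(to_relative_quantities(cqm))
  g2 <- genorm_stability(to_relative_quantities(shifted))
  expect_equal(g1$m_first_pass, g2$m_first_pass, tolerance = 1e-9)
  expect_identical(g1$ranked_targets, g2$ranked_targets)
  expect_equal(g1$v_series, g2$v_series, tolerance = 1e-9)
})

test_that("more independent noise never lowers a target's expected M", {
  sds <- c(0.1, 0.3, 0.6)
  mean_m <- vapply(sds, function(tau) {
    ms <- vapply(1:50, function(seed) {
      tg <- default_sim_targets(3, 1, tau_unstable = tau)
      d <- experiment_design(n_samples = 10, targets = tg, seed = seed)
      q <- to_relative_quantities(generate_cq(d)$cq)
      m_value(q, "unstable1")
    }, numeric(1))
    mean(ms)
  }, numeric(1))
  expect_true(all(diff(mean_m) > 0))
})

test_that("the bundled analysis emits a coherent per-target table", {
  set.seed(31)
  g <- genorm_stability(to_relative_quantities(
    generate_cq(experiment_design(n_samples = 12, seed = 31))$cq))
  expect_setequal(g$table$target, g$ranked_targets)
  expect_equal(g$table$rank, seq_len(6))
  expect_equal(g$optimal_n, 2)
  expect_identical(
    unname(g$classes[g$table$target]),
    unname(classify_stability(g$table$M_at_elimination)))
  paths <- c(withr::local_tempfile(fileext = ".tsv"),
             withr::local_tempfile(fileext = ".tsv"),
             withr::local_tempfile(fileext = ".json"))
  write_genorm_result(g, paths[1], paths[2], paths[3])
  expect_equal(nrow(utils::read.delim(paths[1])), 6)
  js <- jsonlite::read_json(paths[3])
  expect_equal(unlist(js$ranked_targets), g$ranked_targets)
})
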