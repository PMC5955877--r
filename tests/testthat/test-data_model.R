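test_that("long Cq tables read one record per well and flag non-detects", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- expand.grid(sample = c("s1", "s2"), target = c("t1", "t2", "t3"),
                      replicate = 1:2, stringsAsFactors = FALSE)
  rows$cq <- 20 + seq_len(nrow(rows)) / 10
  writeLines(c("sample,target,replicate,cq",
               apply(rows, 1, paste, collapse = ",")), path)
  tab <- read_cq_table(path, "long")
  expect_s3_class(tab, "replicate_table")
  expect_equal(nrow(tab), 12)
  expect_false(anyNA(tab$cq))

  writeLines(c("sample,target,replicate,cq",
               "s1,t1,1,20.5", "s1,t1,2,Undetermined"), path)
  tab <- read_cq_table(path, "long")
  expect_true(is.na(tab$cq[2]))
})

test_that("malformed Cq tables are rejected with a pointer to the offender", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,target,replicate,cq",
               "s1,t1,1,20.5", "s1,t1,1,20.7"), path)
  expect_error(read_cq_table(path, "long"), "s1,t1,1")

  writeLines(c("sample,target,replicate,cq",
               "s1,t1,1,20.5", "s1,t2,1,twenty"), path)
  expect_error(read_cq_table(path, "long"), "row 2")
})

test_that("wide and long encodings of the same wells read identically", {
  v <- matrix(c(20.123456, 31.5, 18.25, 22.9, 40, 35.000001), 2, 3,
              dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
  cqm <- cq_matrix(v)
  wide <- withr::local_tempfile(fileext = ".tsv")
  long <- withr::local_tempfile(fileext = ".tsv")
  write_cq_table(cqm, wide, "wide")
  write_cq_table(cqm, long, "long")
  t_wide <- read_cq_table(wide, "wide")
  t_long <- read_cq_table(long, "long")
  key <- function(d) d[order(d$sample, d$target, d$replicate), ]
  expect_equal(key(as.data.frame(t_wide)), key(as.data.frame(t_long)),
               ignore_attr = TRUE)
})

test_that("write/read round-trips are bit-identical for 6-decimal inputs", {
  set.seed(42)
  for (layout in c("wide", "long")) {
    v <- matrix(round(runif(12, 5, 39.9), 6), 3, 4,
                dimnames = list(sprintf("s%d", 1:3), sprintf("t%d", 1:4)))
    cqm <- cq_matrix(v)
    path <- withr::local_tempfile(fileext = ".csv")
    write_cq_table(cqm, path, layout)
    back <- collapse_replicates(read_cq_table(path, layout))
    expect_identical(back$values[rownames(v), colnames(v)], v)
  }
})

test_that("replicate collapsing averages on the Cq scale and flags spread", {
  tab <- data.frame(sample = c("s1", "s1", "s2", "s2", "s3", "s4", "s4"),
                    target = "t1",
                    replicate = c(1, 2, 1, 2, 1, 1, 2),
                    cq = c(20.0, 20.4, 20.0, 21.0, 33.3, NA, NA))
  out <- collapse_replicates(tab, max_spread = 0.5)
  expect_equal(unname(out$values["s1", "t1"]), 20.2)
  expect_equal(unname(out$values["s2", "t1"]), 20.5)
  expect_equal(unname(out$values["s3", "t1"]), 33.3)
  expect_true(is.na(out$values["s4", "t1"]))      # all replicates failed
  qc <- attr(out, "qc")
  expect_false(qc$flag[qc$sample == "s1"])
  expect_true(qc$flag[qc$sample == "s2"])
  expect_error(collapse_replicates(tab[0, ]), "empty")
})

test_that("partial non-detects average over the detected replicates only", {
  tab <- data.frame(sample = "s1", target = "t1", replicate = 1:3,
                    cq = c(30, NA, 31))
  out <- collapse_replicates(tab)
  expect_equal(unname(out$values["s1", "t1"]), 30.5)
})

test_that("relative quantities follow the geNorm transform", {
  v <- matrix(c(20, 21, 22, 25, 25, 25), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("t1", "t2")))
  q <- to_relative_quantities(cq_matrix(v))
  expect_equal(unname(q$quantities[, "t1"]), c(1, 0.5, 0.25))
  expect_equal(unname(q$quantities[, "t2"]), c(1, 1, 1))

  # efficiency-corrected: a = 1.9, two samples two cycles apart
  v2 <- matrix(c(20, 22), 2, 1, dimnames = list(c("s1", "s2"), "t1"))
  q2 <- to_relative_quantities(cq_matrix(v2), list(t1 = assay_efficiency("t1", 90)))
  expect_equal(unname(q2$quantities[, 1]), c(1, 1 / 1.9^2), tolerance = 1e-12)
})

test_that("quantity transform is invariant to per-target Cq offsets and scales to max 1", {
  set.seed(7)
  for (i in 1:20) {
    v <- matrix(runif(24, 15, 35), 6, 4,
                dimnames = list(sprintf("s%d", 1:6), sprintf("t%d", 1:4)))
    q1 <- to_relative_quantities(cq_matrix(v))
    shift <- matrix(rep(runif(4, -3, 3), each = 6), 6, 4)
    q2 <- to_relative_quantities(cq_matrix(v + shift))
    expect_equal(q1$quantities, q2$quantities, tolerance = 1e-9)
    expect_equal(unname(apply(q1$quantities, 2, max)), rep(1, 4))
  }
})

test_that("non-detects block the quantity transform with advice", {
  v <- matrix(c(20, NA, 22, 25), 2, 2,
              dimnames = list(c("s1", "s2"), c("t1", "t2")))
  expect_error(to_relative_quantities(cq_matrix(v)), "drop the")
})

test_that("cq_matrix enforces its invariants", {
  v <- matrix(c(20, 45), 1, 2, dimnames = list("s1", c("t1", "t2")))
  expect_error(cq_matrix(v), "max_cycles")
  v2 <- matrix(20, 2, 1, dimnames = list(c("s1", "s1"), "t1"))
  expect_error(cq_matrix(v2), "duplicate sample")
})
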