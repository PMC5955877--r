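#' Quantification-cycle (Cq) matrix
#'
#' A `cq_matrix` holds one Cq value per sample x target cell, with an
#' explicit non-detect mask and the instrument cycle ceiling. Cq is the PCR
#' cycle at which a reaction crosses the fluorescence threshold; lower Cq
#' means more template, and one cycle corresponds to roughly one doubling at
#' 100% amplification efficiency.
#'
#' @param values numeric matrix, samples in rows, targets in columns;
#'   dimnames give sample and target ids. `NA` cells are non-detects.
#' @param max_cycles instrument cycle ceiling (default 40); every present Cq
#'   must lie in `(0, max_cycles]`.
#' @return An object of class `cq_matrix`: a list with `values`, `missing`
#'   (logical matrix), `sample_ids`, `target_ids`, `max_cycles`.
#' @examples
#' m <- matrix(c(20, 21, 22, 23), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' cq_matrix(m)
#' @export
cq_matrix <- function(values, max_cycles = 40) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample (row) and target (column) names", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate target ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  present <- values[!is.na(values)]
  if (length(present) && (any(present <= 0) || any(present > max_cycles)))
    stop("all present Cq values must lie in (0, max_cycles]", call. = FALSE)
  structure(list(values = values,
                 missing = is.na(values),
                 sample_ids = rownames(values),
                 target_ids = colnames(values),
                 max_cycles = max_cycles),
            class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat("<cq_matrix> ", length(x$sample_ids), " samples x ",
      length(x$target_ids), " targets; ",
      sum(x$missing), " non-detect(s); max_cycles = ", x$max_cycles, "\n",
      sep = "")
  print(utils::head(x$values, 6))
  invisible(x)
}

#' @export
dim.cq_matrix <- function(x) dim(x$values)

# tokens that denote a non-detect well in input tables
NON_DETECT_TOKENS <- c("", "NA", "N/A", "Undetermined", "undetermined", "ND", "nd")

#' Read a Cq table into a replicate table
#'
#' Reads a long (`sample,target,replicate,cq`) or wide (first column
#' `sample`, remaining headers target ids) delimited text file. The
#' separator is sniffed from the extension: `.csv` is comma, anything else
#' tab. Cells equal to one of `""`, `NA`, `N/A`, `Undetermined`, `ND` (any
#' case of the latter two) become explicit non-detects (`NA` Cq); any other
#' non-numeric Cq is rejected with its row number.
#'
#' @param path path to the table.
#' @param layout `"long"` or `"wide"`. Wide tables carry no replicate
#'   dimension; every well gets replicate index 1.
#' @return A `replicate_table`: a data.frame with columns
#'   `sample`, `target`, `replicate` (integer), `cq` (numeric, `NA` =
#'   non-detect), one row per well.
#' @seealso [collapse_replicates()], [write_cq_table()]
#' @examples
#' path <- system.file("extdata", "example_cq_long.csv", package = "erenorm")
#' tab <- read_cq_table(path, "long")
#' collapse_replicates(tab)
#' @export
read_cq_table <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  df <- read_delim_sniffed(path)
  if (layout == "long") {
    need <- c("sample", "target", "replicate", "cq")
    if (!all(need %in% names(df)))
      stop("long layout requires columns ", paste(need, collapse = ","),
           "; found: ", paste(names(df), collapse = ","), call. = FALSE)
    rep_idx <- suppressWarnings(as.integer(df$replicate))
    if (anyNA(rep_idx))
      stop("non-integer replicate index at row ",
           which(is.na(rep_idx))[1], call. = FALSE)
    out <- data.frame(sample = df$sample, target = df$target,
                      replicate = rep_idx,
                      cq = parse_cq(df$cq),
                      stringsAsFactors = FALSE)
  } else {
    if (names(df)[1] != "sample")
      stop("wide layout requires first column `sample`", call. = FALSE)
    targets <- names(df)[-1]
    if (length(targets) == 0) stop("wide table has no target columns", call. = FALSE)
    out <- data.frame(
      sample = rep(df$sample, times = length(targets)),
      target = rep(targets, each = nrow(df)),
      replicate = 1L,
      cq = parse_cq(unlist(df[targets], use.names = FALSE)),
      stringsAsFactors = FALSE)
  }
  key <- paste(out$sample, out$target, out$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- out[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate (sample,target,replicate) triple: (%s,%s,%d)",
                 d$sample, d$target, d$replicate), call. = FALSE)
  }
  class(out) <- c("replicate_table", "data.frame")
  out
}

parse_cq <- function(x) {
  x <- trimws(x)
  nd <- x %in% NON_DETECT_TOKENS
  val <- suppressWarnings(as.numeric(x))
  bad <- !nd & is.na(val)
  if (any(bad))
    stop("unparseable Cq value ", dQuote(x[which(bad)[1]]), " at row ",
         which(bad)[1], call. = FALSE)
  val[nd] <- NA_real_
  val
}

#' Write a Cq matrix to a delimited file
#'
#' Inverse of [read_cq_table()] at matrix resolution. Numbers are written
#' with enough digits that reading the file back reproduces the doubles
#' bit-identically for inputs with up to six fractional digits; non-detects
#' are written as empty cells.
#'
#' @param cq a [cq_matrix()].
#' @param path output path (`.csv` comma-separated, otherwise tab).
#' @param layout `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(cq, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  stopifnot(inherits(cq, "cq_matrix"))
  v <- cq$values
  if (layout == "wide") {
    df <- data.frame(sample = rownames(v), stringsAsFactors = FALSE,
                     check.names = FALSE)
    for (t in colnames(v)) df[[t]] <- num_chr(v[, t])
  } else {
    df <- data.frame(
      sample = rep(rownames(v), times = ncol(v)),
      target = rep(colnames(v), each = nrow(v)),
      replicate = 1L,
      cq = num_chr(as.vector(v)),
      stringsAsFactors = FALSE)
  }
  write_delim_sniffed(df, path)
}

#' Average technical replicates into a Cq matrix
#'
#' Wells sharing (sample, target) are averaged on the Cq scale, the
#' universal qPCR convention. A cell is a non-detect only if every replicate
#' failed to amplify; otherwise the mean of the detected replicates is used.
#' Cells whose replicate range exceeds `max_spread` are still averaged but
#' flagged in the attached QC listing.
#'
#' @param table a `replicate_table` from [read_cq_table()].
#' @param max_spread maximum acceptable within-cell replicate range, in
#'   cycles (default 0.5).
#' @param max_cycles instrument ceiling passed to [cq_matrix()].
#' @return A [cq_matrix()] with attribute `qc`: a data.frame
#'   `sample,target,range,flag` (one row per cell with >= 2 detected
#'   replicates).
#' @export
collapse_replicates <- function(table, max_spread = 0.5, max_cycles = 40) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("empty replicate table", call. = FALSE)
  stopifnot(max_spread > 0)
  samples <- unique(table$sample)
  targets <- unique(table$target)
  v <- matrix(NA_real_, length(samples), length(targets),
              dimnames = list(samples, targets))
  qc <- list()
  for (s in samples) for (t in targets) {
    cqs <- table$cq[table$sample == s & table$target == t]
    if (length(cqs) == 0) next
    det <- cqs[!is.na(cqs)]
    if (length(det) == 0) next            # all-replicate non-detect: NA cell
    v[s, t] <- mean(det)
    if (length(det) >= 2) {
      rng <- max(det) - min(det)
      qc[[length(qc) + 1L]] <- data.frame(
        sample = s, target = t, range = rng,
        flag = rng > max_spread, stringsAsFactors = FALSE)
    }
  }
  qc <- if (length(qc)) do.call(rbind, qc) else
    data.frame(sample = character(), target = character(),
               range = numeric(), flag = logical())
  out <- cq_matrix(v, max_cycles = max_cycles)
  attr(out, "qc") <- qc
  out
}

#' Write the replicate-spread QC listing
#'
#' @param cq a [cq_matrix()] produced by [collapse_replicates()].
#' @param path output TSV/CSV path.
#' @return `path`, invisibly.
#' @export
write_replicate_qc <- function(cq, path) {
  qc <- attr(cq, "qc")
  if (is.null(qc)) stop("no QC listing attached; run collapse_replicates()", call. = FALSE)
  write_delim_sniffed(qc, path)
}

#' Assay amplification efficiency
#'
#' Bundles a target's amplification efficiency (percent; 100 = perfect
#' per-cycle doubling) with the amplification factor `a = 1 + e/100` used in
#' the relative-quantity transform.
#'
#' @param target_id assay/target identifier.
#' @param efficiency_percent efficiency in percent; the implied
#'   amplification factor must lie in (1, 3).
#' @return An `assay_efficiency` object.
#' @export
assay_efficiency <- function(target_id, efficiency_percent) {
  a <- 1 + efficiency_percent / 100
  if (!is.finite(a) || a <= 1 || a >= 3)
    stop("amplification factor must lie in (1, 3); got ", a, call. = FALSE)
  structure(list(target_id = target_id,
                 efficiency_percent = efficiency_percent,
                 amplification_factor = a),
            class = "assay_efficiency")
}

#' Convert Cq values to efficiency-corrected relative quantities
#'
#' The geNorm input transform: per target j with amplification factor
#' `a_j`, `Q_ij = a_j^(minCq_j - Cq_ij)` where `minCq_j` is that target's
#' minimum Cq across samples, so the most abundant sample has Q = 1 and
#' every Q lies in (0, 1]. With no efficiency supplied a target defaults to
#' `a = 2` (100% efficiency), the geNorm convention; the efficiency gate
#' keeps retained assays close to doubling anyway.
#'
#' @param cq a complete [cq_matrix()] (no non-detects among the targets
#'   used); drop samples or targets first if needed.
#' @param efficiencies optional named list of [assay_efficiency()] objects
#'   (or named numeric amplification factors), keyed by target id.
#' @return A `quantity_matrix`: list with `quantities` (samples x targets),
#'   `sample_ids`, `target_ids`, `amplification_factors`.
#' @examples
#' m <- matrix(c(20, 21, 22, 25, 25, 25), 3, 2,
#'             dimnames = list(c("s1","s2","s3"), c("t1","t2")))
#' q <- to_relative_quantities(cq_matrix(m))
#' q$quantities   # t1: 1, 0.5, 0.25; t2: 1, 1, 1
#' @export
to_relative_quantities <- function(cq, efficiencies = NULL) {
  stopifnot(inherits(cq, "cq_matrix"))
  if (any(cq$missing))
    stop("Cq matrix contains non-detects; drop the affected sample or ",
         "target before computing relative quantities", call. = FALSE)
  v <- cq$values
  a <- setNames(rep(2, ncol(v)), colnames(v))
  for (t in names(efficiencies)) {
    if (!t %in% colnames(v)) next
    e <- efficiencies[[t]]
    a[t] <- if (inherits(e, "assay_efficiency")) e$amplification_factor else as.numeric(e)
  }
  if (any(a <= 1 | a >= 3))
    stop("amplification factors must lie in (1, 3)", call. = FALSE)
  q <- v
  for (j in seq_len(ncol(v)))
    q[, j] <- a[j]^(min(v[, j]) - v[, j])
  structure(list(quantities = q,
                 sample_ids = rownames(v),
                 target_ids = colnames(v),
                 amplification_factors = a),
            class = "quantity_matrix")
}

#' @export
print.quantity_matrix <- function(x, ...) {
  cat("<quantity_matrix> ", length(x$sample_ids), " samples x ",
      length(x$target_ids), " targets\n", sep = "")
  print(utils::head(x$quantities, 6))
  invisible(x)
}

#' Subset a Cq matrix
#'
#' Helper for the explicit pre-filtering workflow: keep or drop samples and
#' targets before the complete-matrix stages.
#'
#' @param cq a [cq_matrix()].
#' @param samples,targets character vectors of ids to keep (default all).
#' @return A [cq_matrix()].
#' @export
subset_cq <- function(cq, samples = NULL, targets = NULL) {
  stopifnot(inherits(cq, "cq_matrix"))
  s <- samples %||% cq$sample_ids
  t <- targets %||% cq$target_ids
  missing_s <- setdiff(s, cq$sample_ids)
  missing_t <- setdiff(t, cq$target_ids)
  if (length(missing_s) || length(missing_t))
    stop("unknown ids: ", paste(c(missing_s, missing_t), collapse = ", "), call. = FALSE)
  cq_matrix(cq$values[s, t, drop = FALSE], max_cycles = cq$max_cycles)
}
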