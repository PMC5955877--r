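#' Paired +RT / -RT control set
#'
#' Couples a Cq matrix from reverse-transcribed reactions (+RT) with the
#' matching matrix from reactions on RNA never reverse-transcribed (-RT).
#' Any -RT amplification reflects contaminating genomic DNA, because the
#' repeat assays cannot avoid gDNA co-amplification by design.
#'
#' @param plus_rt,minus_rt [cq_matrix()] objects over identical sample and
#'   target sets (the -RT matrix is reordered to match).
#' @return An `rt_control_set` object.
#' @export
rt_control_set <- function(plus_rt, minus_rt) {
  stopifnot(inherits(plus_rt, "cq_matrix"), inherits(minus_rt, "cq_matrix"))
  if (!setequal(plus_rt$sample_ids, minus_rt$sample_ids) ||
      !setequal(plus_rt$target_ids, minus_rt$target_ids))
    stop("+RT and -RT matrices must share identical sample and target sets",
         call. = FALSE)
  minus <- cq_matrix(minus_rt$values[plus_rt$sample_ids, plus_rt$target_ids,
                                     drop = FALSE],
                     max_cycles = minus_rt$max_cycles)
  structure(list(plus_rt = plus_rt, minus_rt = minus,
                 max_cycles = minus_rt$max_cycles),
            class = "rt_control_set")
}

#' Per-sample +RT/-RT Cq difference
#'
#' For each sample, the difference between the average -RT Cq and the
#' average +RT Cq over the chosen targets (average-then-subtract, matching
#' how such comparisons are reported; a per-target subtract-then-average
#' variant is available and coincides when the target sets match). A -RT
#' non-detect contributes the instrument ceiling `max_cycles` and marks the
#' sample censored — a conservative lower bound on the true separation. A
#' +RT non-detect invalidates the comparison and is rejected.
#'
#' @param controls an [rt_control_set()].
#' @param targets target ids to average over (default: all shared targets).
#' @param method `"average_then_subtract"` (default) or
#'   `"subtract_then_average"`.
#' @return List with `delta` (named per-sample ΔCq, cycles) and `censored`
#'   (named logical).
#' @export
delta_cq <- function(controls, targets = NULL,
                     method = c("average_then_subtract", "subtract_then_average")) {
  stopifnot(inherits(controls, "rt_control_set"))
  method <- match.arg(method)
  targets <- targets %||% controls$plus_rt$target_ids
  if (length(targets) == 0) stop("target subset must be non-empty", call. = FALSE)
  bad <- setdiff(targets, controls$plus_rt$target_ids)
  if (length(bad)) stop("unknown targets: ", paste(bad, collapse = ", "), call. = FALSE)
  p <- controls$plus_rt$values[, targets, drop = FALSE]
  m <- controls$minus_rt$values[, targets, drop = FALSE]
  if (anyNA(p)) {
    idx <- which(is.na(p), arr.ind = TRUE)[1, ]
    stop(sprintf("+RT non-detect for sample %s, target %s invalidates the comparison",
                 rownames(p)[idx[1]], colnames(p)[idx[2]]), call. = FALSE)
  }
  censored <- apply(m, 1, anyNA)
  m[is.na(m)] <- controls$max_cycles
  delta <- switch(method,
    average_then_subtract = rowMeans(m) - rowMeans(p),
    subtract_then_average = rowMeans(m - p))
  list(delta = delta, censored = censored)
}

#' Residual genomic-DNA signal fraction
#'
#' Converts a +RT/-RT Cq difference into the fraction of the +RT signal
#' attributable to gDNA, `100 * 2^(-delta)` percent: each cycle of
#' separation halves the contaminating contribution. A separation of 11.64
#' cycles corresponds to 0.031%.
#'
#' @param delta ΔCq value(s) in cycles; negative values are allowed (they
#'   yield > 100%).
#' @return Numeric vector of percentages (full precision); attribute
#'   `rounded` carries the 2-significant-figure presentation values.
#' @examples
#' residual_fraction(11.64)   # 0.031%
#' residual_fraction(3)       # 12.5%
#' @export
residual_fraction <- function(delta) {
  pct <- 100 * 2^(-delta)
  structure(pct, rounded = signif(pct, 2))
}

#' Summarize gDNA carryover across samples
#'
#' Mean ΔCq with a two-sided 95% t-interval (n-1 degrees of freedom) over
#' the uncensored samples, the min/max range over all samples, and residual
#' signal fractions per sample and at the mean. When every sample is
#' censored the mean is only a lower bound (all -RT reactions hit the
#' cycle ceiling) and no CI is formed.
#'
#' @param delta named per-sample ΔCq vector (from [delta_cq()]).
#' @param censored named logical vector marking samples whose -RT never
#'   amplified (default none).
#' @param conf_level confidence level for the t-interval (default 0.95).
#' @return A `gdna_report`: list with `per_sample_delta`, `mean_delta`,
#'   `ci95` (low, high), `range`, `per_sample_residual_percent`,
#'   `mean_residual_percent`, `censored_samples`, `mean_is_lower_bound`,
#'   `ci_method`.
#' @export
summarize_gdna <- function(delta, censored = NULL, conf_level = 0.95) {
  if (is.null(censored)) censored <- setNames(rep(FALSE, length(delta)), names(delta))
  stopifnot(length(delta) == length(censored))
  unc <- delta[!censored]
  if (length(unc) >= 2) {
    n <- length(unc)
    mu <- mean(unc)
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * stats::sd(unc) / sqrt(n)
    ci <- c(low = mu - half, high = mu + half)
    lower_bound_only <- FALSE
  } else if (length(unc) == 1) {
    mu <- unc
    ci <- c(low = NA_real_, high = NA_real_)
    lower_bound_only <- FALSE
  } else {
    mu <- min(delta)  # every sample censored: mean exceeds this bound
    ci <- c(low = NA_real_, high = NA_real_)
    lower_bound_only <- TRUE
  }
  res <- residual_fraction(delta)
  structure(list(per_sample_delta = delta,
                 mean_delta = unname(mu),
                 ci95 = ci,
                 range = c(min = min(delta), max = max(delta)),
                 per_sample_residual_percent = setNames(as.numeric(res), names(delta)),
                 mean_residual_percent = as.numeric(residual_fraction(unname(mu))),
                 censored_samples = names(delta)[censored],
                 mean_is_lower_bound = lower_bound_only,
                 ci_method = "two-sided t interval, n-1 df (CI method not standardized; recorded here)"),
            class = "gdna_report")
}

#' @export
print.gdna_report <- function(x, ...) {
  cat(sprintf("<gdna_report> mean dCq %s%.2f cycles",
              if (x$mean_is_lower_bound) "> " else "", x$mean_delta))
  if (!anyNA(x$ci95))
    cat(sprintf(" (95%% CI %.2f-%.2f)", x$ci95["low"], x$ci95["high"]))
  cat(sprintf(", range %.2f to %.2f; mean residual %s%%\n",
              x$range["min"], x$range["max"], signif(x$mean_residual_percent, 2)))
  if (length(x$censored_samples))
    cat("censored samples:", paste(x$censored_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full gDNA assessment and write its outputs
#'
#' @param controls an [rt_control_set()].
#' @param targets target subset (default all).
#' @param tsv_path per-sample table `sample,delta_cq,residual_percent,
#'   censored` (`NULL` to skip).
#' @param json_path JSON summary (mean, ci95, range, censored) (`NULL` to
#'   skip).
#' @return The [summarize_gdna()] report, invisibly when writing.
#' @export
gdna_assessment <- function(controls, targets = NULL, tsv_path = NULL,
                            json_path = NULL) {
  d <- delta_cq(controls, targets)
  rep <- summarize_gdna(d$delta, d$censored)
  if (!is.null(tsv_path)) {
    df <- data.frame(sample = names(d$delta),
                     delta_cq = unname(d$delta),
                     residual_percent = unname(rep$per_sample_residual_percent),
                     censored = unname(d$censored),
                     stringsAsFactors = FALSE)
    write_delim_sniffed(df, tsv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(mean_delta = rep$mean_delta,
           mean_is_lower_bound = rep$mean_is_lower_bound,
           ci95 = as.list(rep$ci95),
           range = as.list(rep$range),
           mean_residual_percent = rep$mean_residual_percent,
           censored_samples = rep$censored_samples,
           ci_method = rep$ci_method),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  if (is.null(tsv_path) && is.null(json_path)) rep else invisible(rep)
}
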