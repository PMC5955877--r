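#' Dilution series for standard-curve efficiency estimation
#'
#' A serial dilution of a template measured by qPCR: each point pairs the
#' log10 of the template input with the observed Cq. The classic design
#' used here as default elsewhere is 6 points, 1/4 dilution per step,
#' maximum input 10 micrograms.
#'
#' @param target_id assay identifier.
#' @param log10_input numeric vector, log10 of template amount per point
#'   (only relative spacing matters to the slope).
#' @param cq observed Cq per point, same length.
#' @param n_points,dilution_factor design metadata (recorded, not enforced
#'   beyond basic validity).
#' @return A `dilution_series` object.
#' @export
dilution_series <- function(target_id, log10_input, cq,
                            n_points = length(log10_input),
                            dilution_factor = NULL) {
  if (length(log10_input) != length(cq))
    stop("log10_input and cq must have equal length", call. = FALSE)
  if (length(unique(log10_input)) < 3)
    stop("a dilution series needs >= 3 distinct input levels", call. = FALSE)
  if (!is.null(dilution_factor) && dilution_factor <= 1)
    stop("dilution_factor must exceed 1", call. = FALSE)
  if (anyNA(cq)) stop("Cq must be present at every point", call. = FALSE)
  structure(list(target_id = target_id,
                 log10_input = as.numeric(log10_input),
                 cq = as.numeric(cq),
                 n_points = n_points,
                 dilution_factor = dilution_factor),
            class = "dilution_series")
}

#' Fit a qPCR standard curve
#'
#' Ordinary least-squares regression of Cq on log10 input. The
#' amplification efficiency follows from the slope as
#' `e = (10^(-1/slope) - 1) * 100`: a perfect doubling assay loses
#' `1/log10(2) = 3.32` cycles per 10-fold input increase. `r_squared` is
#' the squared Pearson correlation of the regression. A non-negative slope
#' (no dilution response) yields `efficiency_percent = NA` with
#' `efficiency_defined = FALSE`.
#'
#' @param series a [dilution_series()].
#' @return A `standard_curve`: list with `target_id`, `slope` (cycles per
#'   log10 input), `intercept`, `r_squared`, `efficiency_percent`,
#'   `efficiency_defined`.
#' @examples
#' s <- dilution_series("t", log10_input = c(1, 0, -1, -2),
#'                      cq = c(20, 23.32193, 26.64386, 29.96578))
#' fit_standard_curve(s)   # efficiency ~100%
#' @export
fit_standard_curve <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  x <- series$log10_input
  y <- series$cq
  if (stats::var(x) == 0)
    stop("zero variance in log10_input; cannot fit a curve", call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- if (stats::var(y) == 0) 1 else unname(stats::cor(x, y)^2)
  defined <- slope < 0
  eff <- if (defined) (10^(-1 / slope) - 1) * 100 else NA_real_
  structure(list(target_id = series$target_id,
                 slope = slope,
                 intercept = intercept,
                 r_squared = r2,
                 efficiency_percent = eff,
                 efficiency_defined = defined),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %s: slope %.4f, efficiency %s%%, r2 %.4f\n",
              x$target_id,
              x$slope,
              if (x$efficiency_defined) sprintf("%.2f", x$efficiency_percent) else "undefined",
              x$r_squared))
  invisible(x)
}

#' Assay retention gate on standard-curve quality
#'
#' An assay is retained only if its amplification efficiency lies within
#' `[e_low, e_high]` percent (bounds inclusive) and the standard curve's
#' coefficient of determination strictly exceeds `r2_min`. Defaults are the
#' screening thresholds 90-110% and r2 > 0.98.
#'
#' @param curve a `standard_curve` from [fit_standard_curve()].
#' @param e_low,e_high efficiency bounds in percent (inclusive).
#' @param r2_min minimum r2 (exclusive bound).
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   every violated criterion; empty when passing).
#' @export
gate_assay <- function(curve, e_low = 90, e_high = 110, r2_min = 0.98) {
  stopifnot(inherits(curve, "standard_curve"))
  reasons <- character()
  if (!curve$efficiency_defined) {
    reasons <- c(reasons, "efficiency undefined (non-negative slope)")
  } else {
    if (curve$efficiency_percent < e_low)
      reasons <- c(reasons, sprintf("efficiency below %g%%", e_low))
    if (curve$efficiency_percent > e_high)
      reasons <- c(reasons, sprintf("efficiency above %g%%", e_high))
  }
  if (!(curve$r_squared > r2_min))
    reasons <- c(reasons, sprintf("r-squared not above %g", r2_min))
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Read dilution series from a delimited table
#'
#' Expects columns `target,log10_input,cq`; one [dilution_series()] per
#' distinct target.
#'
#' @param path TSV/CSV path.
#' @return Named list of [dilution_series()] objects.
#' @export
read_dilution_series <- function(path) {
  df <- read_delim_sniffed(path)
  need <- c("target", "log10_input", "cq")
  if (!all(need %in% names(df)))
    stop("dilution table requires columns ", paste(need, collapse = ","), call. = FALSE)
  out <- lapply(split(df, df$target), function(d)
    dilution_series(d$target[1], as.numeric(d$log10_input), as.numeric(d$cq)))
  out[unique(df$target)]
}

#' Fit and gate a set of dilution series, with a tabular verdict
#'
#' @param series_list named list of [dilution_series()].
#' @param e_low,e_high,r2_min gate thresholds, see [gate_assay()].
#' @return A data.frame `target,slope,efficiency_percent,r_squared,pass,
#'   reasons` (reasons `;`-joined), one row per assay, plus the fitted
#'   curves in attribute `curves`.
#' @export
curve_qc_table <- function(series_list, e_low = 90, e_high = 110, r2_min = 0.98) {
  curves <- lapply(series_list, fit_standard_curve)
  rows <- lapply(curves, function(cv) {
    g <- gate_assay(cv, e_low, e_high, r2_min)
    data.frame(target = cv$target_id, slope = cv$slope,
               efficiency_percent = cv$efficiency_percent,
               r_squared = cv$r_squared, pass = g$pass,
               reasons = paste(g$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "curves") <- curves
  out
}
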