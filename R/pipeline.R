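# report structural contract: versioned required-field list used by
# validate_report(); bump the version when the layout changes
REPORT_SCHEMA_VERSION <- "1.0"
REPORT_REQUIRED_FIELDS <- list(
  schema_version = "character",
  thresholds = "list",
  experiments = "list",
  aggregation = "list",
  provenance = "list")

default_thresholds <- function() list(
  m_high = 0.5, m_very_high = 0.2, v_cutoff = 0.15,
  efficiency_low = 90, efficiency_high = 110, r2_min = 0.98,
  conservation_min = 97, min_hits = 30)

default_aggregation <- function() list(
  distance = "weighted_footrule", method = "auto",
  sample_size = NULL, elite_fraction = 0.1, smoothing = 0.25,
  max_iterations = 100, convergence_patience = 15, seed = 1L)

KNOWN_TOP_KEYS <- c("experiments", "thresholds", "aggregation", "gdna",
                    "efficiency", "output_dir")
KNOWN_EXPERIMENT_KEYS <- c("id", "cq_table", "layout", "drop_samples",
                           "drop_targets", "max_spread")
KNOWN_GDNA_KEYS <- c("plus_rt", "minus_rt", "layout", "targets")

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), injects the
#' default thresholds and aggregation settings, and checks everything at
#' once: unknown keys (typo guard), threshold ranges, and that every
#' referenced path resolves. All violations are reported together, not
#' first-failure.
#'
#' @param config path to a YAML file, or a list with the same structure:
#'   `experiments` (list of `id`, `cq_table`, optional `layout`,
#'   `drop_samples`, `drop_targets`, `max_spread`), optional `thresholds`,
#'   `aggregation`, `gdna` (`plus_rt`, `minus_rt`, optional `targets`),
#'   `efficiency` (path to a dilution-series table), `output_dir`.
#' @return A normalized `pipeline_config` list; errors with the full
#'   violation listing otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  unknown <- setdiff(names(config), KNOWN_TOP_KEYS)
  if (length(unknown)) note(paste0("unknown key(s): ", paste(unknown, collapse = ", ")))

  th <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  unknown_th <- setdiff(names(config$thresholds %||% list()), names(default_thresholds()))
  if (length(unknown_th))
    note(paste0("unknown thresholds key(s): ", paste(unknown_th, collapse = ", ")))
  if (!(th$m_very_high > 0 && th$m_very_high < th$m_high))
    note("thresholds must satisfy 0 < m_very_high < m_high")
  if (th$v_cutoff <= 0) note("v_cutoff must be positive")
  if (!(th$efficiency_low < th$efficiency_high))
    note("efficiency_low must be below efficiency_high")
  if (th$r2_min <= 0 || th$r2_min >= 1) note("r2_min must lie in (0, 1)")
  if (th$conservation_min <= 0 || th$conservation_min > 100)
    note("conservation_min must lie in (0, 100]")
  if (th$min_hits < 0) note("min_hits must be non-negative")

  agg <- utils::modifyList(default_aggregation(), config$aggregation %||% list())
  unknown_agg <- setdiff(names(config$aggregation %||% list()), names(default_aggregation()))
  if (length(unknown_agg))
    note(paste0("unknown aggregation key(s): ", paste(unknown_agg, collapse = ", ")))
  if (!agg$distance %in% c("footrule", "weighted_footrule"))
    note("aggregation distance must be footrule or weighted_footrule")
  if (!agg$method %in% c("auto", "exhaustive", "cross_entropy"))
    note("aggregation method must be auto, exhaustive or cross_entropy")

  exps <- config$experiments %||% list()
  if (length(exps) == 0) note("at least one experiment is required")
  for (i in seq_along(exps)) {
    e <- exps[[i]]
    unknown_e <- setdiff(names(e), KNOWN_EXPERIMENT_KEYS)
    if (length(unknown_e))
      note(paste0("experiment ", i, ": unknown key(s): ",
                  paste(unknown_e, collapse = ", ")))
    if (is.null(e$id)) note(paste0("experiment ", i, ": missing id"))
    if (is.null(e$cq_table)) note(paste0("experiment ", i, ": missing cq_table"))
    else if (!file.exists(e$cq_table))
      note(paste0("experiment ", i, ": cq_table not found: ", e$cq_table))
    exps[[i]]$layout <- e$layout %||% "long"
    exps[[i]]$max_spread <- e$max_spread %||% 0.5
  }

  gd <- config$gdna
  if (!is.null(gd)) {
    unknown_g <- setdiff(names(gd), KNOWN_GDNA_KEYS)
    if (length(unknown_g))
      note(paste0("gdna: unknown key(s): ", paste(unknown_g, collapse = ", ")))
    for (k in c("plus_rt", "minus_rt")) {
      if (is.null(gd[[k]])) note(paste0("gdna: missing ", k))
      else if (!file.exists(gd[[k]])) note(paste0("gdna: ", k, " not found: ", gd[[k]]))
    }
    gd$layout <- gd$layout %||% "long"
  }
  if (!is.null(config$efficiency) && !file.exists(config$efficiency))
    note(paste0("efficiency table not found: ", config$efficiency))

  if (length(problems))
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(list(experiments = exps, thresholds = th, aggregation = agg,
                 gdna = gd, efficiency = config$efficiency,
                 output_dir = config$output_dir %||% "."),
            class = "pipeline_config")
}

#' Ranked list from a geNorm stability result
#'
#' Ordering from the stepwise ranking; scores are each target's M at its
#' elimination step. In the rare case the elimination-M sequence is not
#' monotone along the ranking it is monotonized by a running maximum so
#' the list satisfies the scores-sorted invariant (the ordering itself is
#' never changed).
#'
#' @param result a `genorm_stability` object.
#' @param experiment_id experiment label.
#' @return A [ranked_list()].
#' @export
as_ranked_list <- function(result, experiment_id) {
  stopifnot(inherits(result, "genorm_stability"))
  s <- unname(result$elimination_m[result$ranked_targets])
  s <- cummax(s)
  ranked_list(experiment_id, result$ranked_targets,
              setNames(s, result$ranked_targets))
}

#' Run the full stability workflow over configured experiments
#'
#' For each experiment: read the Cq table, average replicates, apply the
#' declared sample/target drops, transform to relative quantities
#' (efficiency-corrected when a dilution-series table is configured), and
#' run the complete geNorm analysis. With two or more experiments the
#' per-experiment rankings are then aggregated into a consensus ordering
#' (exhaustively up to 9 targets under `method = "auto"`, by cross-entropy
#' beyond); a single experiment skips aggregation with an explicit notice.
#' An optional +RT/-RT pair adds the gDNA carryover report. The JSON
#' report is written atomically (temp file then rename); on failure
#' partial outputs are removed.
#'
#' @param config a `pipeline_config` from [validate_config()], or a path /
#'   list accepted by it.
#' @param write logical: write the report and per-experiment tables under
#'   `output_dir` (default `TRUE`).
#' @return A `run_report`: list with `experiments` (per-experiment
#'   `genorm_stability` objects), `consensus` (or `NULL`),
#'   `aggregation_notice`, `gdna` (or `NULL`), `curve_qc` (or `NULL`),
#'   `thresholds`, `provenance`.
#' @export
run_stability_suite <- function(config, write = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  th <- config$thresholds
  stage <- "setup"
  written <- character()
  on_fail_cleanup <- function() for (f in written) if (file.exists(f)) unlink(f)

  tryCatch({
    efficiencies <- NULL
    curve_qc <- NULL
    if (!is.null(config$efficiency)) {
      stage <- "efficiency_qc"
      series <- read_dilution_series(config$efficiency)
      curve_qc <- curve_qc_table(series, th$efficiency_low, th$efficiency_high,
                                 th$r2_min)
      curves <- attr(curve_qc, "curves")
      efficiencies <- lapply(curves[curve_qc$pass],
                             function(cv) 1 + cv$efficiency_percent / 100)
      names(efficiencies) <- curve_qc$target[curve_qc$pass]
    }

    results <- list()
    for (e in config$experiments) {
      stage <- paste0("stability:", e$id)
      tab <- read_cq_table(e$cq_table, layout = e$layout)
      cqm <- collapse_replicates(tab, max_spread = e$max_spread)
      keep_s <- setdiff(cqm$sample_ids, e$drop_samples %||% character())
      keep_t <- setdiff(cqm$target_ids, e$drop_targets %||% character())
      cqm <- subset_cq(cqm, keep_s, keep_t)
      q <- to_relative_quantities(cqm, efficiencies)
      results[[e$id]] <- genorm_stability(q, th$m_high, th$m_very_high,
                                          th$v_cutoff)
    }

    notice <- NA_character_
    consensus <- NULL
    if (length(results) >= 2) {
      stage <- "aggregation"
      lists <- mapply(as_ranked_list, results, names(results),
                      SIMPLIFY = FALSE)
      agg <- config$aggregation
      k <- length(lists[[1]]$ordering)
      method <- agg$method
      if (method == "auto") method <- if (k <= 9) "exhaustive" else "cross_entropy"
      consensus <- if (method == "exhaustive")
        aggregate_exhaustive(lists, agg$distance)
      else
        aggregate_ce(lists, agg$distance,
                     ce_config(k,
                               sample_size = agg$sample_size %||% (10 * k^2),
                               elite_fraction = agg$elite_fraction,
                               smoothing = agg$smoothing,
                               max_iterations = agg$max_iterations,
                               convergence_patience = agg$convergence_patience),
                     seed = agg$seed)
    } else {
      notice <- "single experiment: rank aggregation skipped"
    }

    gdna <- NULL
    if (!is.null(config$gdna)) {
      stage <- "gdna_qc"
      plus <- collapse_replicates(read_cq_table(config$gdna$plus_rt,
                                                config$gdna$layout))
      minus <- collapse_replicates(read_cq_table(config$gdna$minus_rt,
                                                 config$gdna$layout))
      ctr <- rt_control_set(plus, minus)
      d <- delta_cq(ctr, config$gdna$targets)
      gdna <- summarize_gdna(d$delta, d$censored)
    }

    report <- structure(
      list(experiments = results, consensus = consensus,
           aggregation_notice = notice, gdna = gdna, curve_qc = curve_qc,
           thresholds = th,
           provenance = list(schema_version = REPORT_SCHEMA_VERSION,
                             package_version = as.character(utils::packageVersion("erenorm")),
                             aggregation = config$aggregation)),
      class = "run_report")

    if (write) {
      stage <- "write_report"
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
      for (id in names(results)) {
        sp <- file.path(config$output_dir, paste0("stability_", id, ".tsv"))
        vp <- file.path(config$output_dir, paste0("v_series_", id, ".tsv"))
        write_genorm_result(results[[id]], sp, vp)
        written <- c(written, sp, vp)
      }
      jp <- file.path(config$output_dir, "report.json")
      tmp <- paste0(jp, ".tmp")
      jsonlite::write_json(report_to_list(report), tmp, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null")
      file.rename(tmp, jp)
    }
    report
  }, error = function(err) {
    on_fail_cleanup()
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(err),
         call. = FALSE)
  })
}

# flatten a run_report into plain lists for JSON serialization
report_to_list <- function(report) {
  list(
    schema_version = REPORT_SCHEMA_VERSION,
    thresholds = report$thresholds,
    experiments = lapply(report$experiments, function(r) list(
      ranked_targets = r$ranked_targets,
      m_first_pass = as.list(r$m_first_pass),
      m_at_elimination = as.list(r$elimination_m),
      classes = as.list(r$classes),
      v_series = as.list(r$v_series),
      optimal_n = r$optimal_n,
      optimal_n_flag = r$optimal_n_flag)),
    aggregation = if (!is.null(report$consensus)) list(
      ordering = report$consensus$ordering,
      objective = report$consensus$objective,
      method = report$consensus$method,
      distance = report$consensus$distance,
      mean_rank = as.list(report$consensus$mean_rank),
      seed = report$consensus$seed)
    else list(notice = report$aggregation_notice),
    gdna = if (!is.null(report$gdna)) list(
      mean_delta = report$gdna$mean_delta,
      ci95 = as.list(report$gdna$ci95),
      range = as.list(report$gdna$range),
      mean_residual_percent = report$gdna$mean_residual_percent,
      censored_samples = report$gdna$censored_samples) else NULL,
    provenance = report$provenance)
}

#' Structural validation of a written pipeline report
#'
#' Checks a report JSON against the versioned required-field contract the
#' package ships (field presence and type); a lightweight structural
#' validator rather than a full JSON-Schema engine.
#'
#' @param path path to a `report.json` written by [run_stability_suite()].
#' @return `TRUE` invisibly; errors listing every missing or mistyped
#'   field otherwise.
#' @export
validate_report <- function(path) {
  rep <- jsonlite::read_json(path)
  problems <- character()
  for (field in names(REPORT_REQUIRED_FIELDS)) {
    if (is.null(rep[[field]])) {
      problems <- c(problems, paste0("missing field: ", field))
    } else {
      want <- REPORT_REQUIRED_FIELDS[[field]]
      ok <- if (want == "character") is.character(rep[[field]]) else is.list(rep[[field]])
      if (!ok) problems <- c(problems, paste0("field ", field, " has wrong type"))
    }
  }
  if (!identical(rep$schema_version, REPORT_SCHEMA_VERSION))
    problems <- c(problems, paste0("schema_version mismatch: ",
                                   rep$schema_version %||% "absent"))
  if (length(problems))
    stop("report fails structural validation:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", length(x$experiments), " experiment(s)\n", sep = "")
  for (id in names(x$experiments)) {
    r <- x$experiments[[id]]
    cat(sprintf("  %s: top targets %s; optimal n = %d\n", id,
                paste(utils::head(r$ranked_targets, 3), collapse = ", "),
                r$optimal_n))
  }
  if (!is.null(x$consensus))
    cat("  consensus:", paste(utils::head(x$consensus$ordering, 3), collapse = ", "),
        "... (", x$consensus$method, ")\n")
  else if (!is.na(x$aggregation_notice)) cat(" ", x$aggregation_notice, "\n")
  if (!is.null(x$gdna))
    cat(sprintf("  gDNA: mean dCq %.2f, mean residual %s%%\n",
                x$gdna$mean_delta, signif(x$gdna$mean_residual_percent, 2)))
  invisible(x)
}
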