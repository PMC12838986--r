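# End-to-end orchestration: simulate -> qc -> preprocess -> evaluate ->
# report, driven by a single validated configuration with one global seed.

#' Pipeline configuration
#'
#' Validates and normalizes a full pipeline configuration (typically read
#' from YAML). The global `seed` deterministically derives every stage
#' seed, so a configuration reproduces all numeric outputs exactly.
#'
#' @param x A named list (or path to a YAML file) with elements:
#'   `cohort` (arguments to [cohort_config()], or `list(reference = TRUE,
#'   effect_size =, ...)` to use [reference_cohort()]), `qc` (threshold
#'   overrides, see [qc_record()]), `model` (arguments to
#'   [model_config()]), `evaluation` (`k_out`, `k_in`, `n_runs`),
#'   `output_dir`, `write_records`, `seed`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) config_stop("config file not found: %s", x)
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) config_stop("pipeline config must be a list or YAML path")
  known <- c("cohort", "qc", "model", "evaluation", "output_dir",
             "write_records", "seed")
  bad <- setdiff(names(x), known)
  if (length(bad)) config_stop("unknown config field(s): %s",
                               paste(bad, collapse = ", "))
  seed <- x$seed %||% 1L
  if (!is_count(seed)) config_stop("seed must be a positive integer")
  seeds <- derive_seeds(seed, 3L)

  cohort <- x$cohort %||% list()
  reference <- isTRUE(cohort$reference)
  cohort$reference <- NULL
  if (!reference) {
    if (!is.null(cohort$category_mix)) {
      cohort$category_mix <- unlist(cohort$category_mix)
    }
    if (!is.null(cohort$malignancy_prob_per_category)) {
      cohort$malignancy_prob_per_category <-
        unlist(cohort$malignancy_prob_per_category)
    }
    if (!is.null(cohort$failure_rates)) {
      cohort$failure_rates <- unlist(cohort$failure_rates)
    }
    cohort$n_participants <- cohort$n_participants %||% 125L
    cohort$seed <- seeds[1]
    # validate eagerly, before any compute
    do.call(cohort_config, cohort)
  } else {
    cohort$seed <- seeds[1]
  }
  ev <- x$evaluation %||% list()
  ev$k_out <- ev$k_out %||% 5L
  ev$k_in <- ev$k_in %||% 3L
  ev$n_runs <- ev$n_runs %||% 100L
  if (!is_count(ev$n_runs) || !is_count(ev$k_out) || !is_count(ev$k_in)) {
    config_stop("evaluation k_out, k_in and n_runs must be positive integers")
  }
  model <- do.call(model_config, x$model %||% list())
  structure(
    list(cohort = cohort, reference = reference, qc = x$qc %||% list(),
         model = model, evaluation = ev,
         output_dir = x$output_dir %||% "breathstrat_out",
         write_records = isTRUE(x$write_records %||% FALSE),
         seed = as.integer(seed), stage_seeds = seeds),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Simulates (or builds the reference) cohort, applies QC and exclusion
#' accounting, evaluates the fusion model by repeated nested CV, and
#' writes all artifacts (cohort manifest, QC report JSON and per-record
#' criterion CSV, fold plan JSON, per-run and aggregated metrics CSVs,
#' summary JSON, run manifest) under `config$output_dir`. Re-running with
#' the same configuration reproduces all numeric outputs.
#'
#' @param config A [pipeline_config()] (or list/path coercible to one).
#' @return Invisibly, a list with `cohort`, `analysis_set`, `qc_report`,
#'   `evaluation`, and `paths`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)

  bs_log("stage simulate: %s cohort",
         if (config$reference) "reference-margin" else "sampled")
  cohort <- run_stage("simulate", {
    if (config$reference) {
      do.call(reference_cohort, config$cohort)
    } else {
      simulate_cohort(do.call(cohort_config, config$cohort))
    }
  })
  write_cohort(cohort, out("cohort"), write_records = config$write_records)

  bs_log("stage qc: %d participants", length(cohort))
  excl <- run_stage("qc", {
    qc <- qc_cohort(cohort, thresholds = config$qc)
    apply_exclusions(cohort, qc)
  })
  utils::write.csv(excl$report$per_record, out("qc_records.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(excl$report$counts,
      list(breathprints_by_category_and_outcome =
             as.data.frame(excl$report$breathprints_by_category_and_outcome))),
    out("qc_report.json"), auto_unbox = TRUE, digits = NA)
  cnt <- excl$report$counts
  bs_log("stage qc: %d analyzed participants, %d successful breathprints",
         cnt$analyzed_participants, cnt$successful_breathprints)

  bs_log("stage evaluate: %d runs of %d x %d nested CV",
         config$evaluation$n_runs, config$evaluation$k_out,
         config$evaluation$k_in)
  ev <- run_stage("evaluate", evaluate_cohort(
    excl$analysis_set, config$model,
    k_out = config$evaluation$k_out, k_in = config$evaluation$k_in,
    n_runs = config$evaluation$n_runs, seed = config$stage_seeds[2]
  ))
  write_fold_plan(ev$fold_plan, out("fold_plan.json"))
  long <- do.call(rbind, lapply(seq_along(ev$per_run_metrics), function(r) {
    cbind(run = r, ev$per_run_metrics[[r]])
  }))
  utils::write.csv(long, out("metrics_per_run.csv"), row.names = FALSE)
  utils::write.csv(format_summary(ev$summary), out("metrics_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = ev$summary, auc = ev$auc,
         auc_within_category = ev$auc_within_category),
    out("summary.json"), auto_unbox = TRUE, digits = NA, na = "null")

  manifest <- list(
    package_version = as.character(utils::packageVersion("breathstrat")),
    seed = config$seed, stage_seeds = config$stage_seeds,
    reference_cohort = config$reference,
    n_participants = length(cohort),
    evaluation = config$evaluation
  )
  jsonlite::write_json(manifest, out("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(cohort = cohort, analysis_set = excl$analysis_set,
                 qc_report = excl$report, evaluation = ev,
                 paths = out(c("cohort", "qc_report.json", "fold_plan.json",
                               "metrics_per_run.csv", "metrics_summary.csv",
                               "summary.json", "run_manifest.json"))))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "breathstrat_config_error")) stop(e)
    bs_stop("stage '%s' failed: %s", stage, conditionMessage(e),
            class = "breathstrat_stage_error")
  })
}

# "mean +/- SD" presentation of an aggregated metrics table.
format_summary <- function(summary) {
  if (!any(grepl("_mean$", names(summary)))) return(summary)
  metrics <- sub("_mean$", "", grep("_mean$", names(summary), value = TRUE))
  out <- summary[, c("subgroup", "n_runs")]
  for (m in metrics) {
    out[[m]] <- sprintf("%.3f ± %.3f", summary[[paste0(m, "_mean")]],
                        summary[[paste0(m, "_sd")]])
  }
  out
}
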