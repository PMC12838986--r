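# Nested cross-validation with a conservative majority-vote ensemble, and
# the subgroup metric tables reported over repeated runs.

#' Majority vote with conservative tie-breaking
#'
#' @param votes Binary vector of per-model votes (1 = malignant).
#' @return `list(final, tie_broken)`: the majority label; exact ties
#'   resolve to malignant (1) with `tie_broken = TRUE`.
#' @export
majority_vote <- function(votes) {
  n_mal <- sum(votes == 1)
  n_ben <- sum(votes == 0)
  if (n_mal == n_ben) {
    list(final = 1L, tie_broken = TRUE)
  } else {
    list(final = as.integer(n_mal > n_ben), tie_broken = FALSE)
  }
}

#' Run one nested cross-validation repetition
#'
#' For each outer fold, the `k_in` inner-fold models (each trained on the
#' other inner folds of the outer training set, with epoch selection on
#' its own inner validation fold) form the ensemble that votes on every
#' outer-test breathprint; ties resolve to malignant. Training uses all
#' eligible breathprints (BI-RADS 3 through 5); each analysis-set
#' breathprint receives exactly one ensemble prediction.
#'
#' @param model_data A [build_model_data()] result over the full analysis
#'   set.
#' @param plan_run One element of `fold_plan$runs` (see
#'   [build_fold_plan()]).
#' @param config A [model_config()]; each inner model gets a distinct
#'   init seed derived from `config$init_seed` and `seed_offset`.
#' @param seed_offset Integer distinguishing repetitions (default 0).
#' @return A data.frame with one row per breathprint: `record_id`,
#'   `participant_id`, `birads`, `label`, `n_votes`, `votes_malignant`,
#'   `final`, `tie_broken`, `mean_prob`.
#' @export
run_nested_cv <- function(model_data, plan_run, config, seed_offset = 0) {
  rows <- lapply(seq_along(plan_run), function(f) {
    fold <- plan_run[[f]]
    test_idx <- which(model_data$participant_id %in% fold$test)
    if (!length(test_idx)) bs_stop("outer fold %d has an empty test set", f)
    test <- subset_model_data(model_data, test_idx)
    k_in <- length(fold$inner)
    probs <- vapply(seq_len(k_in), function(j) {
      inner <- fold$inner[[j]]
      tr <- subset_model_data(model_data,
                              which(model_data$participant_id %in% inner$train))
      va <- subset_model_data(model_data,
                              which(model_data$participant_id %in% inner$val))
      cfg <- config
      cfg$init_seed <- (config$init_seed + 7919L * seed_offset +
                          101L * f + j) %% 2147483647L
      model <- train_fusion_model(tr, va, cfg)
      predict_fusion_model(model, test)
    }, numeric(length(test_idx)))
    probs <- matrix(probs, nrow = length(test_idx))
    votes <- probs >= config$threshold
    verdict <- apply(votes, 1, function(v) majority_vote(as.integer(v)))
    data.frame(
      outer_fold = f,
      record_id = test$record_id,
      participant_id = test$participant_id,
      birads = test$birads,
      label = test$y,
      n_votes = k_in,
      votes_malignant = rowSums(votes),
      final = vapply(verdict, `[[`, 0L, "final"),
      tie_broken = vapply(verdict, `[[`, FALSE, "tie_broken"),
      mean_prob = rowMeans(probs),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out$record_id),
            nrow(out) == length(model_data$record_id))
  out
}

#' Confusion-matrix metrics for one subgroup
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), NPV = TN/(TN+FN),
#' PPV = TP/(TP+FP). A ratio with zero denominator is reported as `NA`
#' (undefined), never 0.
#'
#' @param predictions Binary predicted labels.
#' @param labels True labels.
#' @param subgroup_mask Optional logical mask selecting the subgroup.
#' @return One-row data.frame: `n`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `npv`, `ppv`.
#' @export
compute_metrics <- function(predictions, labels, subgroup_mask = NULL) {
  if (!is.null(subgroup_mask)) {
    predictions <- predictions[subgroup_mask]
    labels <- labels[subgroup_mask]
  }
  if (!length(labels)) bs_stop("empty subgroup")
  tp <- sum(predictions == 1 & labels == 1)
  fp <- sum(predictions == 1 & labels == 0)
  tn <- sum(predictions == 0 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  data.frame(n = length(labels), tp = tp, fp = fp, tn = tn, fn = fn,
             sensitivity = ratio(tp, tp + fn),
             specificity = ratio(tn, tn + fp),
             npv = ratio(tn, tn + fn),
             ppv = ratio(tp, tp + fp))
}

subgroup_masks <- function(birads) {
  list("4A" = birads == "4A", "4B" = birads == "4B", "4C" = birads == "4C",
       "4A+4B+4C" = birads %in% c("4A", "4B", "4C"),
       "all" = rep(TRUE, length(birads)))
}

#' Breathprint-level malignancy rate of a subgroup
#'
#' The ratio of breathprints from biopsy-confirmed malignant participants
#' to all breathprints in the subgroup.
#'
#' @param labels Per-breathprint outcome labels (0/1).
#' @param subgroup_mask Optional logical mask.
#' @return Fraction in `[0, 1]`.
#' @export
malignancy_rate <- function(labels, subgroup_mask = NULL) {
  if (!is.null(subgroup_mask)) labels <- labels[subgroup_mask]
  if (!length(labels)) bs_stop("empty subgroup")
  mean(labels == 1)
}

#' Per-subgroup metrics for one run's predictions
#'
#' Rows for 4A, 4B, 4C, the combined BI-RADS 4 group, and all analyzed
#' breathprints. BI-RADS 3/5 breathprints participate in training but
#' never enter a BI-RADS 4 row's denominator.
#'
#' @param predictions Output of [run_nested_cv()].
#' @return A data.frame keyed by `subgroup`.
#' @export
metrics_table <- function(predictions) {
  masks <- subgroup_masks(predictions$birads)
  rows <- lapply(names(masks), function(g) {
    m <- masks[[g]]
    if (!any(m)) return(NULL)
    row <- compute_metrics(predictions$final, predictions$label, m)
    cbind(data.frame(subgroup = g, stringsAsFactors = FALSE), row,
          data.frame(malignancy_rate = malignancy_rate(predictions$label, m)))
  })
  do.call(rbind, rows)
}

#' Aggregate per-run metric tables into mean and SD
#'
#' @param tables List (length >= 2) of [metrics_table()] results from
#'   independent runs.
#' @return A data.frame with one row per subgroup and `<metric>_mean` /
#'   `<metric>_sd` columns for sensitivity, specificity, NPV, PPV and
#'   malignancy rate; `n_runs` recorded per row. SDs are sample SDs over
#'   runs; `NA` cells (undefined ratios) are dropped pairwise.
#' @export
aggregate_runs <- function(tables) {
  if (length(tables) < 2L) {
    bs_stop("aggregation needs at least 2 runs (SD undefined for %d)",
            length(tables))
  }
  metrics <- c("sensitivity", "specificity", "npv", "ppv", "malignancy_rate")
  groups <- unique(unlist(lapply(tables, `[[`, "subgroup")))
  rows <- lapply(groups, function(g) {
    cells <- lapply(metrics, function(m) {
      vals <- vapply(tables, function(tb) {
        v <- tb[[m]][tb$subgroup == g]
        if (length(v)) v else NA_real_
      }, 0)
      c(mean = mean(vals, na.rm = TRUE), sd = stats::sd(vals[!is.na(vals)]))
    })
    out <- data.frame(subgroup = g, n_runs = length(tables),
                      stringsAsFactors = FALSE)
    for (i in seq_along(metrics)) {
      out[[paste0(metrics[i], "_mean")]] <- cells[[i]][["mean"]]
      out[[paste0(metrics[i], "_sd")]] <- cells[[i]][["sd"]]
    }
    out
  })
  do.call(rbind, rows)
}

# Mann-Whitney AUC of scores against binary labels.
auc_mann_whitney <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Model-level AUC within BI-RADS categories
#'
#' Because the BI-RADS category is itself a model input and carries
#' category-specific malignancy prevalence, the unconditional AUC is
#' above 0.5 even for a breathprint-blind model. Pooling scores across
#' folds additionally biases a cross-validated AUC below 0.5 under the
#' null (fold-specific calibration offsets). Chance behavior of the
#' breathprint channel is therefore assessed within (BI-RADS category,
#' outer fold) cells: the AUC of the ensemble mean probability is
#' computed inside every cell containing both classes and averaged
#' weighted by the cell's number of discordant (malignant, benign)
#' pairs -- the within-stratum Mann-Whitney statistic.
#'
#' @param predictions Output of [run_nested_cv()].
#' @return Scalar AUC (0.5 = chance).
#' @export
auc_within_category <- function(predictions) {
  cell <- if ("outer_fold" %in% names(predictions)) {
    interaction(predictions$birads, predictions$outer_fold, drop = TRUE)
  } else {
    predictions$birads
  }
  cats <- split(predictions, cell)
  aucs <- vapply(cats, function(d) auc_mann_whitney(d$mean_prob, d$label), 0)
  wts <- vapply(cats, function(d) sum(d$label == 1) * sum(d$label == 0), 0)
  keep <- !is.na(aucs)
  if (!any(keep)) return(NA_real_)
  sum(aucs[keep] * wts[keep]) / sum(wts[keep])
}

#' Evaluate a cohort end-to-end over repeated nested-CV runs
#'
#' Normalizes and shapes the analysis set, builds `n_runs` independent
#' nested fold plans, runs the ensemble nested CV for each, and
#' aggregates per-subgroup metrics as mean and SD over runs.
#'
#' @param analysis_set Retained cohort from [apply_exclusions()].
#' @param config A [model_config()].
#' @param k_out,k_in Fold counts (defaults 5, 3).
#' @param n_runs Number of repetitions (default 100).
#' @param seed Master seed (fold plans and model init seeds derive from
#'   it).
#' @param progress Log per-run progress (default FALSE).
#' @return A list: `per_run_predictions`, `per_run_metrics`, `summary`
#'   (aggregated table when `n_runs >= 2`), `auc` (unconditional,
#'   mean over runs), `auc_within_category` (mean over runs), `fold_plan`.
#' @export
evaluate_cohort <- function(analysis_set, config = model_config(),
                            k_out = 5, k_in = 3, n_runs = 100, seed = 1,
                            progress = FALSE) {
  prepared <- prepare_analysis_data(analysis_set,
                                    target_length = config$target_length)
  md <- build_model_data(prepared, config)
  plan <- build_fold_plan(analysis_set, k_out = k_out, k_in = k_in,
                          n_runs = n_runs, seed = seed)
  init_seeds <- derive_seeds(seed + 1L, n_runs)
  per_run <- lapply(seq_len(n_runs), function(r) {
    cfg <- config
    cfg$init_seed <- init_seeds[r]
    if (progress) bs_log("nested-CV run %d/%d", r, n_runs)
    run_nested_cv(md, plan$runs[[r]], cfg, seed_offset = r)
  })
  tables <- lapply(per_run, metrics_table)
  list(
    per_run_predictions = per_run,
    per_run_metrics = tables,
    summary = if (n_runs >= 2) aggregate_runs(tables) else tables[[1]],
    auc = mean(vapply(per_run, function(p) auc_mann_whitney(p$mean_prob, p$label), 0)),
    auc_within_category = mean(vapply(per_run, auc_within_category, 0)),
    fold_plan = plan
  )
}
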