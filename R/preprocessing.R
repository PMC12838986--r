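# Ambient-referenced normalization, fixed-size model tensors, and
# participant-grouped stratified nested-CV fold plans.

#' Normalize a breathprint against its ambient baseline
#'
#' Per channel i, `v_i(t) = (R_i(t) - R0_i) / R0_i` where `R0_i` is the
#' mean resistance over the settled tail (last `baseline_s` seconds) of
#' the ambient window. The result is the unitless relative-response
#' matrix consumed by the model; it is invariant to rescaling the whole
#' record by a positive constant.
#'
#' @param record A [breathprint_record()] (QC-passing).
#' @param baseline_s Length of the ambient tail used as reference
#'   (default 10 s).
#' @param birads_code,label Optional diagnostic category (`"3"`,...,`"5"`)
#'   and outcome label (0 benign / 1 malignant) carried through to the
#'   model.
#' @return A `normalized_breathprint`: `record_id`, `participant_id`,
#'   `values` (32 x T), `birads_code`, `label`.
#' @export
normalize_breathprint <- function(record, baseline_s = 10,
                                  birads_code = NULL, label = NULL) {
  amb <- phase_idx(record, "ambient")
  n_tail <- min(length(amb), round(baseline_s * record$sample_rate_hz))
  tail_idx <- amb[seq.int(length(amb) - n_tail + 1L, length(amb))]
  base <- rowMeans(record$resistances[, tail_idx, drop = FALSE])
  if (any(base <= 0)) {
    bs_stop("non-positive ambient baseline in record '%s'", record$record_id)
  }
  values <- sweep(sweep(record$resistances, 1, base, "-"), 1, base, "/")
  structure(
    list(record_id = record$record_id, participant_id = record$participant_id,
         values = values, birads_code = birads_code, label = label),
    class = "normalized_breathprint"
  )
}

#' Shape a normalized breathprint to the model's fixed length
#'
#' Crops or edge-pads the time axis to `target_length` samples. The
#' ambient phase sits at the start of every record and capture onset is at
#' a fixed offset, so cropping/padding at the tail preserves phase
#' alignment. Padding repeats the last observed column.
#'
#' @param normalized A [normalize_breathprint()] result.
#' @param target_length Target number of samples (default 295 = 30 + 15 +
#'   250 at 1 Hz).
#' @param max_jitter Largest tolerated length mismatch (default 11
#'   samples, the capture-duration jitter).
#' @return A 32 x `target_length` matrix.
#' @export
to_model_tensor <- function(normalized, target_length = 295, max_jitter = 11) {
  v <- normalized$values
  d <- ncol(v) - target_length
  if (abs(d) > max_jitter) {
    bs_stop("record '%s' is %d samples long, outside +/-%d of target %d",
            normalized$record_id, ncol(v), max_jitter, target_length)
  }
  if (d > 0) {
    v <- v[, seq_len(target_length), drop = FALSE]
  } else if (d < 0) {
    v <- cbind(v, v[, rep(ncol(v), -d), drop = FALSE])
  }
  v
}

#' Flatten an analysis set into model-ready per-record data
#'
#' Normalizes every retained breathprint, shapes it to the fixed model
#' length and attaches the participant's BI-RADS category and outcome
#' label.
#'
#' @param analysis_set Cohort of retained participants (QC-passing
#'   replicates only), e.g. from [apply_exclusions()].
#' @param target_length,baseline_s See [to_model_tensor()] and
#'   [normalize_breathprint()].
#' @return A list with `tensors` (list of 32 x T matrices), and vectors
#'   `record_id`, `participant_id`, `birads`, `label` (0/1).
#' @export
prepare_analysis_data <- function(analysis_set, target_length = 295,
                                  baseline_s = 10) {
  tensors <- list(); rid <- pid <- birads <- character(); label <- integer()
  for (p in analysis_set) {
    for (rec in p$replicates) {
      norm <- normalize_breathprint(rec, baseline_s = baseline_s)
      tensors[[length(tensors) + 1L]] <- to_model_tensor(norm, target_length)
      rid <- c(rid, rec$record_id)
      pid <- c(pid, p$participant_id)
      birads <- c(birads, p$birads_status)
      label <- c(label, if (p$biopsy_outcome == "malignant") 1L else 0L)
    }
  }
  list(tensors = tensors, record_id = rid, participant_id = pid,
       birads = birads, label = label)
}

#' One-hot encode BI-RADS categories
#'
#' @param birads Character vector over `"3"`, `"4A"`, `"4B"`, `"4C"`, `"5"`.
#' @return An `n x 5` indicator matrix with columns in that order.
#' @export
one_hot_birads <- function(birads) {
  f <- factor(birads, levels = ELIGIBLE_BIRADS)
  if (anyNA(f)) config_stop("BI-RADS codes must be among %s",
                            paste(ELIGIBLE_BIRADS, collapse = ", "))
  m <- matrix(0, length(birads), length(ELIGIBLE_BIRADS),
              dimnames = list(NULL, ELIGIBLE_BIRADS))
  m[cbind(seq_along(birads), as.integer(f))] <- 1
  m
}

# Deal the members of each stratum into k folds, shuffling members and
# always dealing to the currently least-loaded folds (random tie-break):
# every fold's count of any single stratum differs by at most 1, and the
# total fold sizes also stay within 1 of each other.
stratified_fold_assignment <- function(ids, strata, k) {
  fold <- integer(length(ids))
  load <- integer(k)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < k) {
      bs_log("stratum '%s' has %d members for %d folds; distributing as evenly as possible",
             s, length(idx), k)
    }
    idx <- idx[sample.int(length(idx))]
    while (length(idx)) {
      ord <- order(load, sample.int(k))
      take <- min(length(idx), k)
      chosen <- ord[seq_len(take)]
      fold[idx[seq_len(take)]] <- chosen
      load[chosen] <- load[chosen] + 1L
      idx <- idx[-seq_len(take)]
    }
  }
  fold
}

#' Build a nested, stratified, participant-grouped fold plan
#'
#' Partitions participants (never individual breathprints: all replicates
#' of a participant share a fold, preventing identity leakage) into
#' `k_out` outer folds, stratified by the joint (BI-RADS category, outcome
#' label) stratum. Within each outer training set, participants are
#' re-stratified into `k_in` inner folds; inner model `j` trains on the
#' other `k_in - 1` folds and validates on fold `j`. Each of `n_runs`
#' repetitions uses an independent sub-seed, so folds re-randomize per run.
#'
#' @param analysis_set Cohort of retained participants.
#' @param k_out,k_in Outer/inner fold counts (defaults 5 and 3).
#' @param n_runs Number of independent repetitions (default 1).
#' @param seed Master seed for the plan.
#' @return A `fold_plan`: list with `k_out`, `k_in`, `n_runs`, `seed` and
#'   `runs`, where `runs[[r]][[f]]` is
#'   `list(test = ids, inner = list(list(train = ids, val = ids), ...))`.
#' @export
build_fold_plan <- function(analysis_set, k_out = 5, k_in = 3, n_runs = 1,
                            seed = 1) {
  pid <- vapply(analysis_set, `[[`, "", "participant_id")
  strata <- paste(vapply(analysis_set, `[[`, "", "birads_status"),
                  vapply(analysis_set, `[[`, "", "biopsy_outcome"), sep = "|")
  run_seeds <- derive_seeds(seed, n_runs)
  runs <- lapply(seq_len(n_runs), function(r) {
    withr::with_seed(run_seeds[r], {
      outer_fold <- stratified_fold_assignment(pid, strata, k_out)
      lapply(seq_len(k_out), function(f) {
        test_ids <- pid[outer_fold == f]
        pool <- which(outer_fold != f)
        inner_fold <- stratified_fold_assignment(pid[pool], strata[pool], k_in)
        inner <- lapply(seq_len(k_in), function(j) {
          list(train = pid[pool[inner_fold != j]],
               val = pid[pool[inner_fold == j]])
        })
        list(test = test_ids, inner = inner)
      })
    })
  })
  structure(list(k_out = k_out, k_in = k_in, n_runs = n_runs, seed = seed,
                 runs = runs),
            class = "fold_plan")
}

#' Serialize a fold plan to JSON
#'
#' @param plan A [build_fold_plan()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
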