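# Breathprint inclusion criteria, cohort exclusion accounting and the
# chronological drift check.
#
# The four record-level criteria are evaluated in a fixed order
# (ambient stability -> breath capture -> data integrity -> recovery) and
# short-circuit: a record that never captured a breath is not judged on
# recovery, which avoids the vacuous near-zero-peak degenerate case.

# Ambient-referenced relative response using the full ambient-window mean
# as reference (QC view; the model-facing normalization in normalize()
# uses the settled tail of the window instead).
qc_relative_response <- function(record) {
  amb <- phase_idx(record, "ambient")
  base <- rowMeans(record$resistances[, amb, drop = FALSE])
  sweep(sweep(record$resistances, 1, base, "-"), 1, base, "/")
}

#' QC criterion: ambient stability
#'
#' A record passes if, for every channel, the relative span
#' `(max - min) / mean` of the raw resistance over the ambient window is
#' strictly below the threshold (default `1e-4`, i.e. 0.01%).
#'
#' @param record A [breathprint_record()].
#' @param threshold Maximum allowed relative span (strict), default `1e-4`.
#' @return Logical.
#' @export
qc_ambient_stability <- function(record, threshold = 1e-4) {
  amb <- phase_idx(record, "ambient")
  x <- record$resistances[, amb, drop = FALSE]
  span <- (apply(x, 1, max) - apply(x, 1, min)) / rowMeans(x)
  all(span < threshold)
}

#' QC criterion: successful breath capture
#'
#' Tests that a breath actually reached the array: the maximum absolute
#' ambient-referenced response over the capture window plus the first 30 s
#' of recovery must exceed `theta` times the ambient-window noise SD (on
#' the relative-response scale) on at least `m` channels. On noiseless
#' records the noise floor is taken as machine epsilon, so a zero response
#' still fails and an arbitrarily strict `theta` fails every record.
#'
#' @param record A [breathprint_record()].
#' @param theta Noise-SD multiple a channel must exceed (default 5).
#' @param m Minimum number of exceeding channels (default 3).
#' @return Logical.
#' @export
qc_breath_capture <- function(record, theta = 5, m = 3) {
  v <- qc_relative_response(record)
  amb <- phase_idx(record, "ambient")
  sigma <- apply(v[, amb, drop = FALSE], 1, stats::sd)
  sigma <- pmax(sigma, .Machine$double.eps)
  recov <- phase_idx(record, "recovery")
  early <- recov[seq_len(min(30L * record$sample_rate_hz, length(recov)))]
  win <- c(phase_idx(record, "capture"), early)
  peak <- apply(abs(v[, win, drop = FALSE]), 1, max)
  sum(peak > theta * sigma) >= m
}

#' QC criterion: data integrity
#'
#' Passes if the time axis has no gaps at the declared sample rate and the
#' record contains no missing values. (Construction of
#' `breathprint_record` already rejects non-finite values; gaps are the
#' criterion exercised by dropped-sample failures.)
#'
#' @param record A [breathprint_record()].
#' @param tol Tolerance on the sample spacing, default `1e-9` s.
#' @return Logical.
#' @export
qc_data_integrity <- function(record, tol = 1e-9) {
  dt <- diff(record$times)
  all(abs(dt - 1 / record$sample_rate_hz) < tol) &&
    !anyNA(record$resistances)
}

#' QC criterion: sensor recovery
#'
#' Identifies the `q` most-responsive channels by peak absolute
#' ambient-referenced response and requires each of them to end the
#' recovery phase strictly below `frac` (default 20%) of its own peak.
#'
#' @param record A [breathprint_record()].
#' @param q Number of most-responsive channels examined (default 5).
#' @param frac Maximum allowed end-of-recovery residual as a fraction of
#'   peak (strict), default 0.2.
#' @return Logical.
#' @export
qc_recovery <- function(record, q = 5, frac = 0.2) {
  v <- qc_relative_response(record)
  active <- c(phase_idx(record, "capture"), phase_idx(record, "recovery"))
  peak <- apply(abs(v[, active, drop = FALSE]), 1, max)
  top <- order(peak, decreasing = TRUE)[seq_len(min(q, length(peak)))]
  final <- abs(v[top, ncol(v)])
  all(final < frac * peak[top])
}

#' Run all four QC criteria on one record
#'
#' Criteria run in order and short-circuit: once one fails, later criteria
#' are reported as `NA` (not judged).
#'
#' @param record A [breathprint_record()].
#' @param thresholds Optional named list overriding criterion parameters:
#'   `ambient_threshold`, `theta`, `m`, `q`, `recovery_frac`.
#' @return A one-row data.frame: `record_id`, `participant_id`,
#'   `ambient_stable`, `breath_captured`, `data_intact`, `recovered`,
#'   `pass`.
#' @export
qc_record <- function(record, thresholds = list()) {
  th <- utils::modifyList(list(ambient_threshold = 1e-4, theta = 5, m = 3,
                               q = 5, recovery_frac = 0.2), thresholds)
  r <- c(ambient_stable = NA, breath_captured = NA, data_intact = NA,
         recovered = NA)
  r["ambient_stable"] <- qc_ambient_stability(record, th$ambient_threshold)
  if (isTRUE(r[["ambient_stable"]])) {
    r["breath_captured"] <- qc_breath_capture(record, th$theta, th$m)
  }
  if (isTRUE(r[["breath_captured"]])) {
    r["data_intact"] <- qc_data_integrity(record)
  }
  if (isTRUE(r[["data_intact"]])) {
    r["recovered"] <- qc_recovery(record, th$q, th$recovery_frac)
  }
  data.frame(record_id = record$record_id,
             participant_id = record$participant_id,
             ambient_stable = r[["ambient_stable"]],
             breath_captured = r[["breath_captured"]],
             data_intact = r[["data_intact"]],
             recovered = r[["recovered"]],
             pass = isTRUE(r[["recovered"]]),
             stringsAsFactors = FALSE)
}

#' Run QC over a whole cohort
#'
#' @param cohort A list of [participant_record()]s.
#' @param thresholds See [qc_record()].
#' @return A data.frame with one row per replicate record.
#' @export
qc_cohort <- function(cohort, thresholds = list()) {
  rows <- lapply(cohort, function(p) {
    if (!length(p$replicates)) return(NULL)
    do.call(rbind, lapply(p$replicates, qc_record, thresholds = thresholds))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(record_id = character(), participant_id = character(),
                      ambient_stable = logical(), breath_captured = logical(),
                      data_intact = logical(), recovered = logical(),
                      pass = logical(), stringsAsFactors = FALSE)
  }
  out
}

#' Apply cohort exclusion rules
#'
#' Participants are retained iff their BI-RADS status is one of 3, 4A, 4B,
#' 4C, 5 AND at least one replicate passes QC. Status eligibility is
#' assessed before QC failure, so each excluded participant occupies
#' exactly one exclusion bucket. The analysis set keeps only QC-passing
#' breathprints.
#'
#' @param cohort A list of [participant_record()]s.
#' @param qc_results Output of [qc_cohort()] for the same cohort.
#' @return A list with `analysis_set` (cohort of retained participants,
#'   replicates filtered to passing records) and `report` (a `qc_report`:
#'   `counts` with the exclusion accounting, `breathprints_by_category_and_outcome`,
#'   `participants_by_category_and_outcome`, and the per-record table).
#' @export
apply_exclusions <- function(cohort, qc_results) {
  pass_by_record <- stats::setNames(qc_results$pass, qc_results$record_id)
  status <- vapply(cohort, `[[`, "", "birads_status")
  eligible <- status %in% ELIGIBLE_BIRADS

  n_pass <- vapply(cohort, function(p) {
    if (!length(p$replicates)) return(0L)
    ids <- vapply(p$replicates, `[[`, "", "record_id")
    sum(pass_by_record[ids], na.rm = TRUE)
  }, 0L)

  retained <- eligible & n_pass >= 1L
  analysis_set <- lapply(cohort[retained], function(p) {
    keep <- vapply(p$replicates, function(r) isTRUE(pass_by_record[[r$record_id]]),
                   FALSE)
    p$replicates <- p$replicates[keep]
    p
  })
  class(analysis_set) <- c("breathstrat_cohort", "list")

  cat_f <- factor(vapply(analysis_set, `[[`, "", "birads_status"),
                  levels = ELIGIBLE_BIRADS)
  out_f <- factor(vapply(analysis_set, `[[`, "", "biopsy_outcome"),
                  levels = c("benign", "malignant"))
  n_rep <- vapply(analysis_set, function(p) length(p$replicates), 0L)
  bp_table <- stats::xtabs(n_rep ~ cat_f + out_f)
  part_table <- table(cat_f, out_f)
  dimnames(bp_table) <- dimnames(part_table) <-
    list(category = ELIGIBLE_BIRADS, outcome = c("benign", "malignant"))

  counts <- list(
    enrolled = length(cohort),
    excluded_inconclusive = sum(status == "inconclusive"),
    excluded_unreported = sum(status == "unreported"),
    excluded_ineligible_category = sum(status == "other_category"),
    excluded_all_attempts_failed = sum(eligible & n_pass == 0L),
    analyzed_participants = sum(retained),
    successful_breathprints = sum(n_rep)
  )
  stopifnot(counts$analyzed_participants ==
              counts$enrolled - counts$excluded_inconclusive -
              counts$excluded_unreported - counts$excluded_ineligible_category -
              counts$excluded_all_attempts_failed)

  report <- structure(
    list(counts = counts,
         breathprints_by_category_and_outcome = bp_table,
         participants_by_category_and_outcome = part_table,
         per_record = qc_results),
    class = "qc_report"
  )
  list(analysis_set = analysis_set, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  c <- x$counts
  cat(sprintf(
    "<qc_report> %d enrolled; excluded: %d inconclusive, %d unreported, %d ineligible category, %d all-attempts-failed; %d analyzed (%d breathprints)\n",
    c$enrolled, c$excluded_inconclusive, c$excluded_unreported,
    c$excluded_ineligible_category, c$excluded_all_attempts_failed,
    c$analyzed_participants, c$successful_breathprints))
  print(x$breathprints_by_category_and_outcome)
  invisible(x)
}

#' Chronological drift check
#'
#' Reproducibility check across the study period: for each QC-passing
#' breathprint the signed extremum (maximum-magnitude value) of the
#' normalized response over all channels and time points is computed;
#' records are split into four chronological subsets by enrollment order
#' and each consecutive subset pair is compared with a two-sided Welch
#' t-test. Replicates from one participant share physiology and are not
#' independent, so within each subset the extrema are first averaged per
#' participant and the t-test runs on those participant means (a
#' breathprint-level test would be anti-conservative). The device is
#' considered stable if all three p-values exceed `alpha`. Degenerate
#' zero-variance comparisons with equal means return p = 1.
#'
#' @param records A list of [breathprint_record()]s (QC-passing).
#' @param n_subsets Number of chronological subsets (default 4).
#' @param alpha Significance level (default 0.05).
#' @return A `drift_report`: `extrema`, `subset` assignment, `p_values`
#'   (length `n_subsets - 1`), `pass`.
#' @export
drift_check <- function(records, n_subsets = 4, alpha = 0.05) {
  if (length(records) < 2L * n_subsets) {
    bs_stop("drift check needs at least %d records, got %d",
            2L * n_subsets, length(records))
  }
  ord <- order(vapply(records, `[[`, 0L, "enrollment_index"),
               vapply(records, `[[`, 0L, "replicate_index"))
  records <- records[ord]
  extrema <- vapply(records, function(rec) {
    v <- normalize_breathprint(rec)$values
    v[which.max(abs(v))]
  }, 0)
  subset <- cut(seq_along(extrema), breaks = n_subsets, labels = FALSE)
  pid <- vapply(records, `[[`, "", "participant_id")
  p_values <- vapply(seq_len(n_subsets - 1L), function(i) {
    a <- tapply(extrema[subset == i], pid[subset == i], mean)
    b <- tapply(extrema[subset == i + 1L], pid[subset == i + 1L], mean)
    if (length(a) < 2L || length(b) < 2L) {
      bs_stop("drift subset %d or %d has fewer than 2 participants", i, i + 1L)
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(a, b)$p.value
  }, 0)
  structure(
    list(extrema = extrema, subset = subset, p_values = p_values,
         alpha = alpha, pass = all(p_values > alpha)),
    class = "drift_report"
  )
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("<drift_report> %d records in %d subsets; p-values: %s; %s\n",
              length(x$extrema), max(x$subset),
              paste(signif(x$p_values, 3), collapse = ", "),
              if (x$pass) "no significant shift" else "shift detected"))
  invisible(x)
}
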