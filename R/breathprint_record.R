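#' Breathprint record
#'
#' One replicate's digitized breath specimen: a 32-channel resistance time
#' series sampled at 1 Hz spanning three device phases (ambient sampling,
#' breath capture, sensor recovery). Phase boundaries are stored as 0-based
#' half-open sample-index intervals, so the three intervals partition
#' `[0, T)`.
#'
#' @param record_id Unique record identifier.
#' @param participant_id Owning participant identifier.
#' @param replicate_index Integer replicate number within the participant.
#' @param times Numeric vector of sample times in seconds from record start;
#'   strictly increasing.
#' @param resistances Numeric matrix, 32 rows (channels) by `length(times)`
#'   columns, in ohm.
#' @param phase_bounds Named list with elements `ambient`, `capture`,
#'   `recovery`, each a length-2 numeric `c(start, end)` 0-based half-open
#'   sample-index interval.
#' @param sample_rate_hz Sampling frequency (Hz), default 1.
#' @param enrollment_index Chronological enrollment order of the owning
#'   participant (used by the drift check).
#'
#' @return An object of class `breathprint_record`.
#' @export
breathprint_record <- function(record_id, participant_id, replicate_index,
                               times, resistances, phase_bounds,
                               sample_rate_hz = 1, enrollment_index = NA_integer_) {
  rec <- structure(
    list(
      record_id = as.character(record_id),
      participant_id = as.character(participant_id),
      replicate_index = as.integer(replicate_index),
      times = as.numeric(times),
      resistances = resistances,
      phase_bounds = phase_bounds,
      sample_rate_hz = sample_rate_hz,
      enrollment_index = as.integer(enrollment_index)
    ),
    class = "breathprint_record"
  )
  validate_breathprint(rec)
  rec
}

#' Validate a breathprint record
#'
#' Checks the type invariants in a fixed order and raises a validation error
#' naming the first violated one: channel count (32), non-empty series,
#' strictly increasing times, matching time/resistance dimensions, finite
#' resistances, and phase intervals partitioning `[0, T)`.
#'
#' @param record A `breathprint_record`.
#' @return The record, invisibly.
#' @export
validate_breathprint <- function(record) {
  res <- record$resistances
  if (!is.matrix(res) || nrow(res) != 32L) {
    bs_stop("invalid breathprint '%s': expected 32 channels, found %s",
            record$record_id %||% "?",
            if (is.matrix(res)) nrow(res) else "non-matrix",
            class = "breathstrat_validation_error")
  }
  n <- length(record$times)
  if (n == 0L || ncol(res) == 0L) {
    bs_stop("invalid breathprint '%s': empty time series (T = 0)",
            record$record_id, class = "breathstrat_validation_error")
  }
  if (ncol(res) != n) {
    bs_stop("invalid breathprint '%s': %d time points but %d resistance columns",
            record$record_id, n, ncol(res),
            class = "breathstrat_validation_error")
  }
  if (any(diff(record$times) <= 0)) {
    bs_stop("invalid breathprint '%s': times not strictly increasing",
            record$record_id, class = "breathstrat_validation_error")
  }
  if (any(!is.finite(res))) {
    bs_stop("invalid breathprint '%s': non-finite resistance values",
            record$record_id, class = "breathstrat_validation_error")
  }
  pb <- record$phase_bounds
  if (!all(c("ambient", "capture", "recovery") %in% names(pb))) {
    bs_stop("invalid breathprint '%s': phase_bounds must name ambient/capture/recovery",
            record$record_id, class = "breathstrat_validation_error")
  }
  iv <- rbind(pb$ambient, pb$capture, pb$recovery)
  if (iv[1, 1] != 0 || iv[3, 2] != n ||
      iv[1, 2] != iv[2, 1] || iv[2, 2] != iv[3, 1] ||
      any(iv[, 2] <= iv[, 1])) {
    bs_stop("invalid breathprint '%s': phase intervals do not partition [0, %d)",
            record$record_id, n, class = "breathstrat_validation_error")
  }
  invisible(record)
}

# 1-based column indices of a phase window.
phase_idx <- function(record, phase) {
  b <- record$phase_bounds[[phase]]
  if (is.null(b)) bs_stop("unknown phase '%s'", phase)
  if (b[2] <= b[1]) bs_stop("empty %s window in record '%s'", phase, record$record_id)
  seq.int(b[1] + 1L, b[2])
}

#' @export
print.breathprint_record <- function(x, ...) {
  cat(sprintf(
    "<breathprint_record %s> participant %s, replicate %d, %d channels x %d s (ambient %d, capture %d, recovery %d)\n",
    x$record_id, x$participant_id, x$replicate_index,
    nrow(x$resistances), ncol(x$resistances),
    diff(x$phase_bounds$ambient), diff(x$phase_bounds$capture),
    diff(x$phase_bounds$recovery)))
  invisible(x)
}

#' Participant record
#'
#' A study participant: BI-RADS status (or an exclusion-triggering status),
#' biopsy outcome, chronological enrollment index and the list of replicate
#' breathprint records.
#'
#' @param participant_id Identifier.
#' @param birads_status One of `"3"`, `"4A"`, `"4B"`, `"4C"`, `"5"`,
#'   `"inconclusive"`, `"unreported"`, `"other_category"`.
#' @param biopsy_outcome `"benign"`, `"malignant"` or `"not_applicable"`.
#' @param enrollment_index Integer, unique within a cohort.
#' @param replicates List of [breathprint_record()] objects (0 to 5).
#' @return An object of class `participant_record`.
#' @export
participant_record <- function(participant_id, birads_status, biopsy_outcome,
                               enrollment_index, replicates = list()) {
  birads_status <- as.character(birads_status)
  if (!birads_status %in% c(ELIGIBLE_BIRADS, EXCLUSION_STATUSES)) {
    config_stop("unknown birads_status '%s'", birads_status)
  }
  if (!biopsy_outcome %in% c("benign", "malignant", "not_applicable")) {
    config_stop("unknown biopsy_outcome '%s'", biopsy_outcome)
  }
  if (length(replicates) > 5L) {
    bs_stop("participant '%s' has %d replicates (max 5)",
            participant_id, length(replicates))
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      birads_status = birads_status,
      biopsy_outcome = biopsy_outcome,
      enrollment_index = as.integer(enrollment_index),
      replicates = replicates
    ),
    class = "participant_record"
  )
}

#' Cohort manifest as a data frame
#'
#' @param cohort List of [participant_record()] objects.
#' @return A data.frame with one row per participant: `participant_id`,
#'   `birads_status`, `biopsy_outcome`, `enrollment_index`, `n_replicates`.
#' @export
cohort_manifest <- function(cohort) {
  data.frame(
    participant_id = vapply(cohort, `[[`, "", "participant_id"),
    birads_status = vapply(cohort, `[[`, "", "birads_status"),
    biopsy_outcome = vapply(cohort, `[[`, "", "biopsy_outcome"),
    enrollment_index = vapply(cohort, `[[`, 0L, "enrollment_index"),
    n_replicates = vapply(cohort, function(p) length(p$replicates), 0L),
    stringsAsFactors = FALSE
  )
}
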