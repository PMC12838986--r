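# Breathprint and cohort serialization.
#
# Dialect: one CSV per record with columns time_s, s01..s32 (resistance,
# ohm; 9 significant digits), plus a JSON sidecar carrying identifiers,
# 0-based half-open phase-bound intervals and the sample rate. Cohort
# manifests are plain CSV.

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a breathprint record
#'
#' Writes the resistance CSV and its JSON sidecar next to it. Output is
#' deterministic (fixed field order, 9 significant digits on resistance),
#' so writing the same record twice is byte-identical. Records with
#' non-finite resistances or an empty time series are refused.
#'
#' @param record A [breathprint_record()].
#' @param path Path of the CSV to write; the sidecar replaces `.csv` with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_breathprint <- function(record, path) {
  validate_breathprint(record)
  df <- data.frame(time_s = format(record$times, trim = TRUE),
                   stringsAsFactors = FALSE)
  for (i in 1:32) {
    df[[sprintf("s%02d", i)]] <-
      format(signif(record$resistances[i, ], 9), trim = TRUE, digits = 9)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(
    record_id = record$record_id,
    participant_id = record$participant_id,
    replicate_index = record$replicate_index,
    phase_bounds = lapply(record$phase_bounds, as.integer),
    sample_rate_hz = record$sample_rate_hz,
    enrollment_index = record$enrollment_index
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a breathprint record
#'
#' Reads the CSV + JSON sidecar pair written by [write_breathprint()] and
#' validates every type invariant, raising a validation error naming the
#' first violated one (missing sidecar, channel count, monotone time,
#' phase partition, finite values).
#'
#' @param path Path of the record CSV.
#' @return A [breathprint_record()].
#' @export
read_breathprint <- function(path) {
  if (!file.exists(path)) {
    bs_stop("breathprint file not found: %s", path,
            class = "breathstrat_validation_error")
  }
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    bs_stop("missing sidecar for %s", path,
            class = "breathstrat_validation_error")
  }
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  chan_cols <- grep("^s[0-9]{2}$", names(df), value = TRUE)
  if (length(chan_cols) != 32L) {
    bs_stop("invalid breathprint '%s': expected 32 channels, found %d",
            side$record_id %||% path, length(chan_cols),
            class = "breathstrat_validation_error")
  }
  breathprint_record(
    record_id = side$record_id,
    participant_id = side$participant_id,
    replicate_index = side$replicate_index,
    times = df$time_s,
    resistances = t(as.matrix(df[, chan_cols])),
    phase_bounds = lapply(side$phase_bounds, as.numeric),
    sample_rate_hz = side$sample_rate_hz,
    enrollment_index = side$enrollment_index %||% NA_integer_
  )
}

record_filename <- function(participant_id, replicate_index) {
  sprintf("%s_r%02d.csv", participant_id, replicate_index)
}

#' Write a cohort to disk
#'
#' Writes the cohort manifest CSV (`participant_id, birads_status,
#' biopsy_outcome, enrollment_index, n_replicates`) and, optionally, every
#' replicate record via [write_breathprint()].
#'
#' @param cohort A list of [participant_record()]s.
#' @param dir Output directory (created if needed).
#' @param write_records Whether to write per-record CSVs (default TRUE).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_records = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort_manifest(cohort)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  if (write_records) {
    for (p in cohort) {
      for (rec in p$replicates) {
        write_breathprint(rec, file.path(dir, record_filename(p$participant_id,
                                                              rec$replicate_index)))
      }
    }
  }
  invisible(manifest_path)
}

#' Read a cohort from a manifest and records directory
#'
#' Joins manifest rows to record files by participant id. A missing record
#' file models a failed digitization attempt: the participant is retained
#' with fewer replicates and the gap is logged. Duplicated participant ids
#' in the manifest are fatal.
#'
#' @param manifest_path Cohort manifest CSV.
#' @param records_dir Directory holding the per-record CSV/JSON pairs.
#' @return A `breathstrat_cohort` list of [participant_record()]s.
#' @export
read_cohort <- function(manifest_path, records_dir = dirname(manifest_path)) {
  manifest <- utils::read.csv(manifest_path, colClasses = "character")
  if (anyDuplicated(manifest$participant_id)) {
    dup <- manifest$participant_id[duplicated(manifest$participant_id)][1]
    bs_stop("duplicate participant_id '%s' in manifest", dup,
            class = "breathstrat_validation_error")
  }
  cohort <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    n_rep <- as.integer(row$n_replicates)
    reps <- list()
    for (r in seq_len(n_rep)) {
      f <- file.path(records_dir, record_filename(row$participant_id, r))
      if (!file.exists(f)) {
        bs_log("record file missing for participant %s replicate %d (%s); treated as failed attempt",
               row$participant_id, r, basename(f))
        next
      }
      reps[[length(reps) + 1L]] <- read_breathprint(f)
    }
    participant_record(row$participant_id, row$birads_status,
                       row$biopsy_outcome,
                       as.integer(row$enrollment_index), reps)
  })
  class(cohort) <- c("breathstrat_cohort", "list")
  cohort
}
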