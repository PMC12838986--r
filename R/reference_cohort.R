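#' Enrollment margins of the reference study population
#'
#' Per-category counts of analyzed participants and successful breathprints
#' by biopsy outcome, together with the exclusion counts (15 inconclusive,
#' 13 unreported BI-RADS, 6 ineligible category, 17 participants whose
#' breath digitization failed on every attempt), totalling 176 enrolled and
#' 125 analyzed participants with 437 successful breathprints.
#'
#' @return A list with `analyzed` (data.frame: category, outcome,
#'   participants, breathprints) and `excluded` (named counts).
#' @export
reference_margins <- function() {
  analyzed <- data.frame(
    category = rep(c("3", "5", "4A", "4B", "4C"), each = 2),
    outcome = rep(c("benign", "malignant"), times = 5),
    participants = c(2L, 0L, 2L, 36L, 26L, 2L, 34L, 6L, 8L, 9L),
    breathprints = c(7L, 0L, 7L, 114L, 103L, 7L, 124L, 18L, 29L, 28L),
    stringsAsFactors = FALSE
  )
  excluded <- c(inconclusive = 15L, unreported = 13L,
                ineligible_category = 6L, all_attempts_failed = 17L)
  list(analyzed = analyzed, excluded = excluded)
}

#' Simulate the reference cohort with exact enrollment margins
#'
#' Builds a synthetic cohort of 176 participants whose category, outcome,
#' replicate and exclusion structure reproduces the reference study margins
#' exactly (see [reference_margins()]): every analyzed participant receives
#' exactly the prescribed number of QC-passing breathprints (3 to 5 each),
#' excluded participants carry an exclusion-triggering BI-RADS status, and
#' 17 eligible participants have breath capture fail on all five attempts.
#' Enrollment order is randomly permuted. Breathprints carry the planted
#' malignancy signal configured by `effect_size`/`signal_channels`.
#'
#' @param seed Master seed.
#' @param effect_size Standardized malignant mean shift (default 2).
#' @param signal_channels Signal-bearing compound classes (default `1:4`).
#' @param spec Optional [sensor_array_spec()] override.
#' @param ... Further arguments passed to [cohort_config()] (noise,
#'   variance split, ...). `n_participants`, `category_mix` and
#'   `failure_rates` are fixed by the margins and cannot be overridden.
#' @return A `breathstrat_cohort` of 176 participants.
#' @export
reference_cohort <- function(seed = 1, effect_size = 2, signal_channels = 1:4,
                             spec = NULL, ...) {
  m <- reference_margins()
  config <- cohort_config(n_participants = 176L, effect_size = effect_size,
                          signal_channels = signal_channels,
                          failure_rates = c(no_breath_captured = 0),
                          seed = seed, ...)
  seeds <- derive_seeds(config$seed, 2L)
  if (is.null(spec)) spec <- sensor_array_spec(config$n_compounds, seed = seeds[1])

  # one row per participant: status, outcome, number of successful records
  rows <- do.call(rbind, lapply(seq_len(nrow(m$analyzed)), function(i) {
    g <- m$analyzed[i, ]
    if (g$participants == 0L) return(NULL)
    data.frame(status = g$category, outcome = g$outcome,
               n_success = distribute_counts(g$breathprints, g$participants),
               n_failed = 0L, stringsAsFactors = FALSE)
  }))
  excl <- m$excluded
  rows <- rbind(
    rows,
    data.frame(status = rep(c("inconclusive", "unreported", "other_category"),
                            times = excl[c("inconclusive", "unreported",
                                           "ineligible_category")]),
               outcome = "not_applicable", n_success = 3L, n_failed = 0L,
               stringsAsFactors = FALSE),
    # eligible participants whose digitization failed on every attempt
    data.frame(status = rep(c("4A", "4B", "4C", "5"), length.out = excl[["all_attempts_failed"]]),
               outcome = "benign", n_success = 0L, n_failed = 5L,
               stringsAsFactors = FALSE)
  )

  cohort <- withr::with_seed(seeds[2], {
    order_idx <- sample.int(nrow(rows))
    rows <- rows[order_idx, ]
    sd_p <- config$concentration_sd * sqrt(1 - config$replicate_var_frac)
    sd_r <- config$concentration_sd * sqrt(config$replicate_var_frac)
    lapply(seq_len(nrow(rows)), function(i) {
      info <- rows[i, ]
      pid <- sprintf("P%04d", i)
      draw_outcome <- if (info$outcome == "malignant") "malignant" else "benign"
      mu <- voc_profile_mean(draw_outcome, config)
      latent <- mu + sd_p * stats::rnorm(config$n_compounds)
      n_rep <- info$n_success + info$n_failed
      reps <- lapply(seq_len(n_rep), function(r) {
        conc <- pmax(latent + sd_r * stats::rnorm(config$n_compounds), 0)
        prof <- structure(list(concentrations = conc, outcome_label = draw_outcome),
                          class = "voc_profile")
        sched <- phase_schedule(capture_s = sample(5:15, 1L))
        rec <- simulate_breathprint(prof, spec, sched,
                                    record_id = sprintf("%s_r%d", pid, r),
                                    participant_id = pid, replicate_index = r,
                                    enrollment_index = i)
        if (r > info$n_success) rec <- fail_breath_capture(rec)
        rec
      })
      participant_record(pid, info$status, info$outcome,
                         enrollment_index = i, replicates = reps)
    })
  })
  class(cohort) <- c("breathstrat_cohort", "list")
  attr(cohort, "sensor_spec") <- spec
  cohort
}
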