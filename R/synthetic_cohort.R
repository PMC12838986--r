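#' Sensor array specification
#'
#' Describes a cross-reactive chemiresistive array of 32 thin films. Each
#' film responds to every volatile compound class with its own gain
#' (relative resistance change per unit concentration), adsorption and
#' desorption time constants, baseline resistance and multiplicative noise
#' scale. Gains are drawn log-normally with a random per-film sign
#' structure so that rows are cross-reactive but distinct.
#'
#' @param n_compounds Number of latent VOC compound classes K (default 8).
#' @param seed Seed used to draw the film properties.
#' @param noise_sd Multiplicative noise scale relative to baseline
#'   (default `1e-5`, i.e. 0.001% of baseline; kept well below the 0.01%
#'   ambient-stability acceptance threshold so a healthy device passes QC).
#' @param residual_frac Fraction of the peak response that persists at the
#'   end of an infinitely long recovery (slow-desorbing residue), default
#'   0.05.
#' @param drift_per_s Optional linear baseline drift, relative units per
#'   second (default 0).
#' @return An object of class `sensor_array_spec` with fields
#'   `sensitivity` (32 x K), `tau_adsorb`, `tau_desorb` (seconds),
#'   `baseline_resistance` (ohm), `noise_sd`, `residual_frac`,
#'   `drift_per_s`.
#' @export
sensor_array_spec <- function(n_compounds = 8, seed = 1, noise_sd = 1e-5,
                              residual_frac = 0.05, drift_per_s = 0) {
  if (!is_count(n_compounds)) config_stop("n_compounds must be a positive integer")
  if (residual_frac < 0 || residual_frac >= 1) config_stop("residual_frac must be in [0, 1)")
  withr::with_seed(as.integer(seed), {
    n_films <- 32L
    magnitude <- matrix(
      stats::rlnorm(n_films * n_compounds, meanlog = log(0.002), sdlog = 0.5),
      nrow = n_films
    )
    signs <- matrix(sample(c(-1, 1), n_films * n_compounds, replace = TRUE),
                    nrow = n_films)
    spec <- structure(
      list(
        sensitivity = magnitude * signs,
        tau_adsorb = stats::runif(n_films, 3, 10),
        tau_desorb = stats::runif(n_films, 20, 60),
        baseline_resistance = stats::runif(n_films, 1e4, 1e5),
        noise_sd = noise_sd,
        residual_frac = residual_frac,
        drift_per_s = drift_per_s
      ),
      class = "sensor_array_spec"
    )
  })
  stopifnot(all(spec$tau_adsorb > 0), all(spec$tau_desorb > 0),
            all(spec$baseline_resistance > 0))
  spec
}

#' Phase schedule
#'
#' Durations of the three measurement phases of one breath specimen:
#' ambient sampling (30 s), breath capture (5 to 15 s) and sensor recovery
#' (250 s), sampled at 1 Hz.
#'
#' @param ambient_s Ambient-sampling duration in seconds (default 30).
#' @param capture_s Breath-capture duration in seconds; must lie in
#'   `[5, 15]` (default 10).
#' @param recovery_s Recovery duration in seconds (default 250).
#' @param sample_rate_hz Sampling frequency (default 1).
#' @return An object of class `phase_schedule`.
#' @export
phase_schedule <- function(ambient_s = 30, capture_s = 10, recovery_s = 250,
                           sample_rate_hz = 1) {
  if (capture_s < 5 || capture_s > 15) {
    config_stop("capture_s must lie in [5, 15] s, got %s", capture_s)
  }
  if (ambient_s <= 0 || recovery_s <= 0 || sample_rate_hz <= 0) {
    config_stop("phase durations and sample rate must be positive")
  }
  structure(
    list(ambient_s = ambient_s, capture_s = capture_s,
         recovery_s = recovery_s, sample_rate_hz = sample_rate_hz),
    class = "phase_schedule"
  )
}

#' Cohort configuration
#'
#' Parameters of the synthetic study population. Defaults encode the study
#' conditions: the BI-RADS category mix and per-category malignancy
#' probabilities follow the analyzed-cohort margins (breathprint-level
#' malignancy rates 4A 7/110, 4B 18/142, 4C 28/57), participants provide 4
#' or 5 replicate attempts of which each fails breath capture with
#' probability 0.36 (so roughly 3 of 4.7 attempts succeed on average), and
#' malignant VOC profiles are shifted by `effect_size` within-class
#' standard deviations on the designated signal channels.
#'
#' @param n_participants Number of participants to simulate.
#' @param category_mix Named probability vector over BI-RADS statuses
#'   (may include exclusion statuses); must sum to 1.
#' @param malignancy_prob_per_category Named vector, probability that a
#'   participant in each category is biopsy-confirmed malignant.
#' @param effect_size Standardized mean shift applied to malignant VOC
#'   profiles on `signal_channels` (within-class SD units), default 2.
#' @param signal_channels Indices of the VOC compound classes carrying the
#'   malignancy signal (default `1:4`).
#' @param n_compounds Number of VOC compound classes K (default 8).
#' @param concentration_mean,concentration_sd Baseline VOC concentration
#'   mean and within-class SD per compound class (arbitrary units).
#' @param replicate_var_frac Fraction of the within-class concentration
#'   variance attributed to replicate-to-replicate (breath-to-breath)
#'   variability; the rest is between-participant (default 0.3).
#' @param failure_rates Named vector of per-unit failure-mode
#'   probabilities, see [inject_failures()]. The default fails breath
#'   capture on 36% of attempts.
#' @param prob_five_attempts Probability a participant makes 5 rather than
#'   4 attempts (default 0.7, giving a mean of 4.7 attempts).
#' @param sensitivity_step Optional mid-study device drift: a list
#'   `list(at_fraction =, factor =)` scaling the response amplitude of all
#'   records from participants enrolled after the given fraction of the
#'   cohort. Default `NULL` (stationary device).
#' @param seed Master seed; every draw in the cohort flows from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants,
                          category_mix = c("3" = 0.016, "4A" = 0.224,
                                           "4B" = 0.320, "4C" = 0.136,
                                           "5" = 0.304),
                          malignancy_prob_per_category =
                            c("3" = 0, "4A" = 7 / 110, "4B" = 18 / 142,
                              "4C" = 28 / 57, "5" = 114 / 121),
                          effect_size = 2,
                          signal_channels = 1:4,
                          n_compounds = 8,
                          concentration_mean = 10,
                          concentration_sd = 1,
                          replicate_var_frac = 0.3,
                          failure_rates = c(no_breath_captured = 0.36),
                          prob_five_attempts = 0.7,
                          sensitivity_step = NULL,
                          seed = 1) {
  if (!is_count(n_participants)) config_stop("n_participants must be a positive integer")
  if (abs(sum(category_mix) - 1) > 1e-8) config_stop("category_mix must sum to 1")
  if (any(category_mix < 0)) config_stop("category_mix entries must be non-negative")
  if (any(malignancy_prob_per_category < 0 | malignancy_prob_per_category > 1)) {
    config_stop("malignancy probabilities must lie in [0, 1]")
  }
  if (!is_count(n_compounds)) config_stop("n_compounds must be a positive integer")
  if (length(signal_channels) &&
      (max(signal_channels) > n_compounds || min(signal_channels) < 1)) {
    config_stop("signal_channels out of range for %d compound classes", n_compounds)
  }
  if (replicate_var_frac < 0 || replicate_var_frac > 1) {
    config_stop("replicate_var_frac must lie in [0, 1]")
  }
  check_failure_modes(names(failure_rates))
  if (any(failure_rates < 0 | failure_rates > 1)) {
    config_stop("failure rates must lie in [0, 1]")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         category_mix = category_mix,
         malignancy_prob_per_category = malignancy_prob_per_category,
         effect_size = effect_size,
         signal_channels = signal_channels,
         n_compounds = as.integer(n_compounds),
         concentration_mean = concentration_mean,
         concentration_sd = concentration_sd,
         replicate_var_frac = replicate_var_frac,
         failure_rates = failure_rates,
         prob_five_attempts = prob_five_attempts,
         sensitivity_step = sensitivity_step,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

FAILURE_MODES <- c("unstable_ambient", "no_breath_captured", "dropped_samples",
                   "incomplete_recovery", "all_attempts_failed",
                   "inconclusive_birads", "unreported_birads",
                   "ineligible_category")

check_failure_modes <- function(modes) {
  bad <- setdiff(modes, FAILURE_MODES)
  if (length(bad)) {
    config_stop("unknown failure mode(s): %s", paste(bad, collapse = ", "))
  }
  invisible(modes)
}

#' Simulate a latent VOC profile
#'
#' Draws the K non-negative compound-class abundances transduced by the
#' sensor array. Benign and malignant profiles share the same covariance
#' (independent Gaussian per class, truncated at zero); malignant profiles
#' have their mean shifted by `effect_size` within-class SDs on the
#' designated signal channels, so with `effect_size = 0` both outcomes
#' follow the identical generator law.
#'
#' @param outcome `"benign"` or `"malignant"`.
#' @param config A [cohort_config()].
#' @return An object of class `voc_profile` with fields `concentrations`
#'   (length K) and `outcome_label`.
#' @export
simulate_voc_profile <- function(outcome, config) {
  if (!outcome %in% c("benign", "malignant")) {
    config_stop("outcome must be 'benign' or 'malignant'")
  }
  mu <- voc_profile_mean(outcome, config)
  z <- stats::rnorm(config$n_compounds)
  conc <- pmax(mu + config$concentration_sd * z, 0)
  structure(list(concentrations = conc, outcome_label = outcome),
            class = "voc_profile")
}

voc_profile_mean <- function(outcome, config) {
  mu <- rep(config$concentration_mean, config$n_compounds)
  if (outcome == "malignant" && length(config$signal_channels)) {
    mu[config$signal_channels] <- mu[config$signal_channels] +
      config$effect_size * config$concentration_sd
  }
  mu
}

#' Simulate one breathprint from a VOC profile
#'
#' First-order sorption kinetics per film: baseline resistance during
#' ambient sampling; a saturating exponential rise
#' `R_i(t) = R0_i * (1 + A_i * (1 - exp(-(t - t_on)/tau_adsorb_i)))` from
#' capture onset, with amplitude `A_i = sum_j sensitivity_ij * c_j`;
#' exponential relaxation toward baseline during recovery with
#' `tau_desorb_i`, leaving the configured slow residual fraction.
#' Multiplicative Gaussian noise (and optional linear baseline drift) is
#' applied throughout. Consumes random numbers only when `noise_sd > 0`.
#'
#' @param profile A [simulate_voc_profile()] result.
#' @param spec A [sensor_array_spec()].
#' @param schedule A [phase_schedule()].
#' @param record_id,participant_id,replicate_index,enrollment_index
#'   Metadata carried on the record.
#' @param amplitude_scale Multiplier on all response amplitudes (used to
#'   model mid-study device drift), default 1.
#' @return A [breathprint_record()].
#' @export
simulate_breathprint <- function(profile, spec, schedule,
                                 record_id = "r1", participant_id = "p1",
                                 replicate_index = 1L,
                                 enrollment_index = NA_integer_,
                                 amplitude_scale = 1) {
  K <- ncol(spec$sensitivity)
  if (length(profile$concentrations) != K) {
    bs_stop("profile has %d compound classes but sensor spec expects %d",
            length(profile$concentrations), K,
            class = "breathstrat_dimension_error")
  }
  rate <- schedule$sample_rate_hz
  n_amb <- round(schedule$ambient_s * rate)
  n_cap <- round(schedule$capture_s * rate)
  n_rec <- round(schedule$recovery_s * rate)
  n_tot <- n_amb + n_cap + n_rec
  t <- seq.int(0L, n_tot - 1L) / rate

  A <- as.numeric(spec$sensitivity %*% profile$concentrations) * amplitude_scale
  R0 <- spec$baseline_resistance
  t_on <- n_amb / rate
  t_rec <- (n_amb + n_cap) / rate

  # relative response x_i(t), one row per film
  x <- matrix(0, nrow = 32L, ncol = n_tot)
  cap_cols <- seq.int(n_amb + 1L, n_amb + n_cap)
  rec_cols <- seq.int(n_amb + n_cap + 1L, n_tot)
  x[, cap_cols] <- A * (1 - exp(-outer(1 / spec$tau_adsorb, t[cap_cols] - t_on)))
  peak <- A * (1 - exp(-schedule$capture_s / spec$tau_adsorb))
  rho <- spec$residual_frac
  x[, rec_cols] <- peak * ((1 - rho) * exp(-outer(1 / spec$tau_desorb, t[rec_cols] - t_rec)) + rho)

  res <- R0 * (1 + x)
  if (spec$drift_per_s != 0) {
    res <- res * (1 + spec$drift_per_s * matrix(t, 32L, n_tot, byrow = TRUE))
  }
  if (spec$noise_sd > 0) {
    res <- res * (1 + matrix(stats::rnorm(32L * n_tot, sd = spec$noise_sd),
                             32L, n_tot))
  }

  breathprint_record(
    record_id = record_id, participant_id = participant_id,
    replicate_index = replicate_index, times = t, resistances = res,
    phase_bounds = list(ambient = c(0, n_amb),
                        capture = c(n_amb, n_amb + n_cap),
                        recovery = c(n_amb + n_cap, n_tot)),
    sample_rate_hz = rate, enrollment_index = enrollment_index
  )
}

#' Simulate a cohort of participants with replicate breathprints
#'
#' Each participant draws a BI-RADS status from `category_mix` and a biopsy
#' outcome from the category's malignancy probability; a participant-level
#' VOC profile is drawn and each replicate adds breath-to-breath jitter
#' (variance fraction `replicate_var_frac`). Capture duration is drawn
#' uniformly over 5 to 15 s per replicate. Per-record and per-participant
#' failures configured in `config$failure_rates` are then injected via
#' [inject_failures()]; the injection ledger is attached as attribute
#' `"failure_ledger"`. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param spec Optional [sensor_array_spec()]; drawn from the master seed
#'   when omitted.
#' @return A list of [participant_record()] objects (class
#'   `breathstrat_cohort`).
#' @export
simulate_cohort <- function(config, spec = NULL) {
  seeds <- derive_seeds(config$seed, 3L)
  if (is.null(spec)) spec <- sensor_array_spec(config$n_compounds, seed = seeds[1])

  cohort <- withr::with_seed(seeds[2], {
    cats <- names(config$category_mix)
    sd_p <- config$concentration_sd * sqrt(1 - config$replicate_var_frac)
    sd_r <- config$concentration_sd * sqrt(config$replicate_var_frac)
    step <- config$sensitivity_step
    lapply(seq_len(config$n_participants), function(i) {
      pid <- sprintf("P%04d", i)
      status <- sample(cats, 1L, prob = config$category_mix)
      eligible <- status %in% ELIGIBLE_BIRADS
      outcome <- if (!eligible) {
        "not_applicable"
      } else if (stats::runif(1) < config$malignancy_prob_per_category[[status]]) {
        "malignant"
      } else {
        "benign"
      }
      draw_outcome <- if (outcome == "not_applicable") "benign" else outcome
      mu <- voc_profile_mean(draw_outcome, config)
      latent <- mu + sd_p * stats::rnorm(config$n_compounds)
      n_attempts <- if (stats::runif(1) < config$prob_five_attempts) 5L else 4L
      amp <- 1
      if (!is.null(step) && i > step$at_fraction * config$n_participants) {
        amp <- step$factor
      }
      reps <- lapply(seq_len(n_attempts), function(r) {
        conc <- pmax(latent + sd_r * stats::rnorm(config$n_compounds), 0)
        prof <- structure(list(concentrations = conc, outcome_label = draw_outcome),
                          class = "voc_profile")
        sched <- phase_schedule(capture_s = sample(5:15, 1L))
        simulate_breathprint(prof, spec, sched,
                             record_id = sprintf("%s_r%d", pid, r),
                             participant_id = pid, replicate_index = r,
                             enrollment_index = i, amplitude_scale = amp)
      })
      participant_record(pid, status, outcome, enrollment_index = i,
                         replicates = reps)
    })
  })
  class(cohort) <- c("breathstrat_cohort", "list")
  injected <- inject_failures(cohort, config$failure_rates, seed = seeds[3])
  attr(injected$cohort, "sensor_spec") <- spec
  attr(injected$cohort, "failure_ledger") <- injected$ledger
  injected$cohort
}

#' Inject device and enrollment failure modes into a cohort
#'
#' Modifies records or participants so that the corresponding QC criterion
#' or exclusion rule fires, and returns a ground-truth ledger of what was
#' injected where. Record-level modes (applied independently per record
#' with the given probability): `unstable_ambient` (0.05% ramp on one
#' channel during ambient sampling), `no_breath_captured` (response
#' flattened to the ambient level), `dropped_samples` (one sample removed
#' from the recovery window), `incomplete_recovery` (recovery tail reshaped
#' to end at 40% of peak). Participant-level modes: `all_attempts_failed`
#' (every replicate loses its breath capture), `inconclusive_birads`,
#' `unreported_birads`, `ineligible_category` (status overwritten).
#'
#' @param cohort List of [participant_record()]s.
#' @param failure_rates Named vector of probabilities over the modes above.
#' @param seed Seed for the injection draws.
#' @return A list with `cohort` (modified) and `ledger` (data.frame with
#'   columns `unit_id`, `mode`).
#' @export
inject_failures <- function(cohort, failure_rates, seed = 1) {
  check_failure_modes(names(failure_rates))
  failure_rates <- failure_rates[failure_rates > 0]
  ledger <- data.frame(unit_id = character(), mode = character(),
                       stringsAsFactors = FALSE)
  if (!length(failure_rates)) {
    return(list(cohort = cohort, ledger = ledger))
  }
  part_modes <- intersect(names(failure_rates),
                          c("all_attempts_failed", "inconclusive_birads",
                            "unreported_birads", "ineligible_category"))
  rec_modes <- setdiff(names(failure_rates), part_modes)

  withr::with_seed(as.integer(seed), {
    cohort <- lapply(cohort, function(p) {
      for (mode in part_modes) {
        if (stats::runif(1) >= failure_rates[[mode]]) next
        ledger[nrow(ledger) + 1L, ] <<- c(p$participant_id, mode)
        p <- switch(mode,
          inconclusive_birads = { p$birads_status <- "inconclusive"; p },
          unreported_birads = { p$birads_status <- "unreported"; p },
          ineligible_category = { p$birads_status <- "other_category"; p },
          all_attempts_failed = {
            p$replicates <- lapply(p$replicates, fail_breath_capture)
            p
          })
      }
      p$replicates <- lapply(p$replicates, function(rec) {
        for (mode in rec_modes) {
          if (stats::runif(1) >= failure_rates[[mode]]) next
          ledger[nrow(ledger) + 1L, ] <<- c(rec$record_id, mode)
          rec <- apply_record_failure(rec, mode)
        }
        rec
      })
      p
    })
  })
  class(cohort) <- c("breathstrat_cohort", "list")
  list(cohort = cohort, ledger = ledger)
}

apply_record_failure <- function(rec, mode) {
  switch(mode,
    no_breath_captured = fail_breath_capture(rec),
    unstable_ambient = {
      amb <- phase_idx(rec, "ambient")
      ch <- sample(32L, 1L)
      ramp <- seq(0, 5e-4, length.out = length(amb))
      rec$resistances[ch, amb] <- rec$resistances[ch, amb] * (1 + ramp)
      rec
    },
    dropped_samples = {
      recov <- phase_idx(rec, "recovery")
      drop <- recov[ceiling(length(recov) / 2)]
      rec$times <- rec$times[-drop]
      rec$resistances <- rec$resistances[, -drop, drop = FALSE]
      rec$phase_bounds$recovery[2] <- rec$phase_bounds$recovery[2] - 1L
      rec
    },
    incomplete_recovery = {
      amb <- phase_idx(rec, "ambient")
      recov <- phase_idx(rec, "recovery")
      base <- rowMeans(rec$resistances[, amb, drop = FALSE])
      active <- c(phase_idx(rec, "capture"), recov)
      resp <- rec$resistances[, active, drop = FALSE] - base
      pk_idx <- apply(abs(resp), 1L, which.max)
      pk <- resp[cbind(seq_len(32L), pk_idx)]
      tt <- seq_along(recov) - 1L
      shape <- 0.4 + 0.6 * exp(-tt / 30)
      rec$resistances[, recov] <- base + pk %o% shape
      rec
    },
    bs_stop("unknown record failure mode '%s'", mode))
}

# Flatten capture + recovery to the per-channel ambient mean: no breath
# reached the chip, so only baseline (and its noise) remains.
fail_breath_capture <- function(rec) {
  amb <- phase_idx(rec, "ambient")
  base <- rowMeans(rec$resistances[, amb, drop = FALSE])
  post <- seq.int(max(amb) + 1L, ncol(rec$resistances))
  rec$resistances[, post] <- base
  rec
}
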