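# Shared fixtures, built in code. All seeds fixed for reproducibility.

quiet <- function(expr) suppressMessages(expr)

# Small noiseless array spec for kinetics and QC tests.
noiseless_spec <- function(n_compounds = 8, seed = 42, residual_frac = 0.05) {
  sensor_array_spec(n_compounds = n_compounds, seed = seed, noise_sd = 0,
                    residual_frac = residual_frac)
}

tiny_config <- function(n = 12, seed = 3, ...) {
  cohort_config(n_participants = n, seed = seed,
                failure_rates = c(no_breath_captured = 0), ...)
}

# A single clean simulated record (with noise unless sd = 0).
make_record <- function(seed = 7, capture_s = 10, noise_sd = 1e-5,
                        outcome = "benign", residual_frac = 0.05,
                        conc = NULL) {
  cfg <- tiny_config()
  spec <- sensor_array_spec(seed = seed, noise_sd = noise_sd,
                            residual_frac = residual_frac)
  prof <- if (is.null(conc)) {
    withr::with_seed(seed, simulate_voc_profile(outcome, cfg))
  } else {
    structure(list(concentrations = conc, outcome_label = outcome),
              class = "voc_profile")
  }
  withr::with_seed(seed + 1, simulate_breathprint(
    prof, spec, phase_schedule(capture_s = capture_s),
    record_id = sprintf("rec_s%d", seed), participant_id = "pX",
    enrollment_index = 1L))
}

# Hand-built record with exact control over baseline / peak / tail values,
# used for boundary tests of the QC criteria. Shapes all 32 channels
# identically: flat baseline, linear rise to `peak_rel` (relative), decay
# to `tail_rel` fraction of peak at the last sample.
synthetic_record <- function(baseline = 1000, peak_rel = 0.05,
                             tail_frac = 0.05, capture_s = 10,
                             ambient_noise = 0) {
  n_amb <- 30L; n_cap <- as.integer(capture_s); n_rec <- 250L
  n <- n_amb + n_cap + n_rec
  amb <- rep(baseline, n_amb)
  if (ambient_noise > 0) {
    amb <- amb * (1 + withr::with_seed(1, stats::rnorm(n_amb, sd = ambient_noise)))
  }
  rise <- baseline * (1 + peak_rel * seq_len(n_cap) / n_cap)
  peak_abs <- baseline * peak_rel
  decay <- baseline + peak_abs * seq(1, tail_frac, length.out = n_rec)
  series <- c(amb, rise, decay)
  breathprint_record(
    record_id = "synth", participant_id = "pS", replicate_index = 1L,
    times = 0:(n - 1), resistances = matrix(rep(series, each = 32), nrow = 32),
    phase_bounds = list(ambient = c(0, n_amb), capture = c(n_amb, n_amb + n_cap),
                        recovery = c(n_amb + n_cap, n)),
    enrollment_index = 1L)
}

# Analysis-ready small cohort for model/evaluation tests.
small_analysis_set <- function(n = 24, seed = 9, effect_size = 3) {
  cfg <- cohort_config(
    n_participants = n, seed = seed, effect_size = effect_size,
    category_mix = c("4A" = 0.3, "4B" = 0.3, "4C" = 0.2, "5" = 0.2),
    malignancy_prob_per_category = c("3" = 0, "4A" = 0.3, "4B" = 0.4,
                                     "4C" = 0.5, "5" = 0.9),
    failure_rates = c(no_breath_captured = 0))
  co <- simulate_cohort(cfg)
  quiet(apply_exclusions(co, qc_cohort(co)))$analysis_set
}
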