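# Generator law, sorption kinetics, cohort structure and failure injection.

test_that("malignant profiles shift only the signal channels by the configured effect", {
  cfg <- tiny_config(effect_size = 2, n = 10)
  draws <- withr::with_seed(11, {
    list(ben = t(replicate(1000, simulate_voc_profile("benign", cfg)$concentrations)),
         mal = t(replicate(1000, simulate_voc_profile("malignant", cfg)$concentrations)))
  })
  pooled_sd <- sqrt((apply(draws$ben, 2, var) + apply(draws$mal, 2, var)) / 2)
  smd <- (colMeans(draws$mal) - colMeans(draws$ben)) / pooled_sd
  expect_true(all(abs(smd[1:4] - 2) < 0.2))
  expect_true(all(abs(smd[5:8]) < 0.2))
})

test_that("with zero effect size the two outcome classes follow the same law", {
  cfg <- tiny_config(effect_size = 0)
  a <- withr::with_seed(5, simulate_voc_profile("benign", cfg))
  b <- withr::with_seed(5, simulate_voc_profile("malignant", cfg))
  expect_identical(a$concentrations, b$concentrations)
})

test_that("profile draws are deterministic under a fixed seed", {
  cfg <- tiny_config()
  a <- withr::with_seed(8, simulate_voc_profile("malignant", cfg))
  b <- withr::with_seed(8, simulate_voc_profile("malignant", cfg))
  expect_identical(a, b)
})

test_that("zero concentration and zero noise give a flat series at baseline", {
  spec <- noiseless_spec()
  prof <- structure(list(concentrations = rep(0, 8), outcome_label = "benign"),
                    class = "voc_profile")
  rec <- simulate_breathprint(prof, spec, phase_schedule())
  expect_equal(rec$resistances,
               matrix(spec$baseline_resistance, 32, 290),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("noiseless kinetics match the closed-form sorption expressions pointwise", {
  spec <- noiseless_spec(seed = 13)
  conc <- c(5, 0, 0, 2, 0, 0, 0, 1)
  prof <- structure(list(concentrations = conc, outcome_label = "benign"),
                    class = "voc_profile")
  cap <- 12
  rec <- simulate_breathprint(prof, spec, phase_schedule(capture_s = cap))
  # independent oracle: evaluate the stated law directly per film/time
  A <- as.numeric(spec$sensitivity %*% conc)
  rho <- spec$residual_frac
  n_tot <- 30 + cap + 250
  oracle <- sapply(0:(n_tot - 1), function(t) {
    vapply(1:32, function(i) {
      R0 <- spec$baseline_resistance[i]
      if (t < 30) R0
      else if (t < 30 + cap) R0 * (1 + A[i] * (1 - exp(-(t - 30) / spec$tau_adsorb[i])))
      else {
        pk <- A[i] * (1 - exp(-cap / spec$tau_adsorb[i]))
        R0 * (1 + pk * ((1 - rho) * exp(-(t - 30 - cap) / spec$tau_desorb[i]) + rho))
      }
    }, 0)
  })
  expect_equal(rec$resistances, oracle, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("per-film response peaks at end of capture and decays below 20% with no residual", {
  spec <- noiseless_spec(seed = 21, residual_frac = 0)
  prof <- withr::with_seed(3, simulate_voc_profile("malignant", tiny_config()))
  rec <- simulate_breathprint(prof, spec, phase_schedule(capture_s = 10))
  v <- abs(sweep(sweep(rec$resistances, 1, spec$baseline_resistance, "-"),
                 1, spec$baseline_resistance, "/"))
  # phase intervals are half-open, so the end-of-capture instant is the
  # first recovery sample: that is where the saturating rise peaks
  cap_end <- 41L
  peak_idx <- apply(v, 1, which.max)
  expect_true(all(peak_idx == cap_end))
  # monotone rise throughout the exposure
  expect_true(all(apply(v[, 31:41, drop = FALSE], 1, function(x) all(diff(x) >= 0))))
  # recovery_s >> tau_desorb: end-of-recovery residual under 20% of peak
  expect_true(all(v[, 290] < 0.2 * v[cbind(1:32, peak_idx)]))
})

test_that("simulated records conserve phase durations at the sample rate", {
  co <- simulate_cohort(tiny_config(n = 6, seed = 2))
  for (p in co) {
    for (rec in p$replicates) {
      pb <- rec$phase_bounds
      expect_equal(ncol(rec$resistances), pb$recovery[2])
      expect_equal(pb$ambient, c(0, 30))
      cap_len <- diff(pb$capture)
      expect_true(cap_len >= 5 && cap_len <= 15)
      expect_equal(diff(pb$recovery), 250)
    }
  }
})

test_that("cohorts are reproducible and respect a degenerate category mix", {
  cfg <- tiny_config(n = 8, seed = 14)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_equal(a, b, ignore_attr = TRUE)
  cfg4a <- cohort_config(n_participants = 8, seed = 14,
                         category_mix = c("4A" = 1),
                         malignancy_prob_per_category = c("4A" = 0.2),
                         failure_rates = c(no_breath_captured = 0))
  co <- simulate_cohort(cfg4a)
  expect_true(all(vapply(co, `[[`, "", "birads_status") == "4A"))
})

test_that("empirical 4C malignancy fraction matches the configured prevalence", {
  cfg <- cohort_config(n_participants = 400, seed = 31,
                       failure_rates = c(no_breath_captured = 0))
  co <- simulate_cohort(cfg)
  status <- vapply(co, `[[`, "", "birads_status")
  outcome <- vapply(co, `[[`, "", "biopsy_outcome")
  n_rep <- vapply(co, function(p) length(p$replicates), 0L)
  in4c <- status == "4C"
  frac <- sum(n_rep[in4c & outcome == "malignant"]) / sum(n_rep[in4c])
  # binomial band around 49% at the participant level (replicates cluster)
  n_part <- sum(in4c)
  expect_lt(abs(frac - 28 / 57), 2 * sqrt(0.25 / n_part))
})

test_that("failure injection is the identity at rate zero and trips the intended defects", {
  co <- simulate_cohort(tiny_config(n = 5, seed = 6))
  none <- inject_failures(co, c(unstable_ambient = 0), seed = 1)
  expect_equal(none$cohort, co, ignore_attr = TRUE)
  expect_equal(nrow(none$ledger), 0L)

  all_amb <- inject_failures(co, c(unstable_ambient = 1), seed = 2)
  rec <- all_amb$cohort[[1]]$replicates[[1]]
  amb <- rec$resistances[, 1:30]
  span <- max((apply(amb, 1, max) - apply(amb, 1, min)) / rowMeans(amb))
  expect_gt(span, 1e-4)

  dropped <- inject_failures(co, c(dropped_samples = 1), seed = 3)
  rec <- dropped$cohort[[1]]$replicates[[1]]
  expect_true(any(diff(rec$times) > 1.5))
  expect_error(inject_failures(co, c(bogus_mode = 1)), "unknown failure mode")
})
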