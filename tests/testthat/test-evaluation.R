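# Ensemble voting, metric arithmetic, aggregation, nested-CV wiring.

# independent brute-force oracle for the 2x2 table metrics
oracle_metrics <- function(pred, truth) {
  tab <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (i in seq_along(pred)) {
    key <- if (pred[i] == 1 && truth[i] == 1) "tp"
    else if (pred[i] == 1 && truth[i] == 0) "fp"
    else if (pred[i] == 0 && truth[i] == 0) "tn"
    else "fn"
    tab[key] <- tab[key] + 1
  }
  safe <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  list(sens = safe(tab[["tp"]], tab[["fn"]]),
       spec = safe(tab[["tn"]], tab[["fp"]]),
       npv = safe(tab[["tn"]], tab[["fn"]]),
       ppv = safe(tab[["tp"]], tab[["fp"]]))
}

test_that("majority voting is conservative on ties only", {
  expect_equal(majority_vote(c(1, 0, 1)), list(final = 1L, tie_broken = FALSE))
  expect_equal(majority_vote(c(0, 1)), list(final = 1L, tie_broken = TRUE))
  expect_equal(majority_vote(c(0, 0, 0)), list(final = 0L, tie_broken = FALSE))
})

test_that("metric formulas agree with hand arithmetic including undefined ratios", {
  pred <- c(1, 1, 0, 0, 0, 0, 1)
  truth <- c(1, 0, 1, 0, 0, 0, 1)
  row <- compute_metrics(pred, truth)
  expect_equal(row$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(row$specificity, 3 / 4, tolerance = 1e-12)
  expect_equal(row$ppv, 2 / 3, tolerance = 1e-12)
  expect_equal(row$npv, 3 / 4, tolerance = 1e-12)

  perfect <- compute_metrics(truth, truth)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "npv", "ppv")]),
               rep(1, 4), ignore_attr = TRUE)

  none <- compute_metrics(c(0, 0, 1), c(0, 0, 0))
  expect_true(is.na(none$sensitivity))
  expect_false(is.na(none$specificity))

  for (i in 1:100) {
    n <- withr::with_seed(i, sample(1:12, 1))
    pred <- withr::with_seed(i * 2, sample(0:1, n, replace = TRUE))
    truth <- withr::with_seed(i * 3, sample(0:1, n, replace = TRUE))
    row <- compute_metrics(pred, truth)
    o <- oracle_metrics(pred, truth)
    expect_equal(row$sensitivity, o$sens)
    expect_equal(row$specificity, o$spec)
    expect_equal(row$npv, o$npv)
    expect_equal(row$ppv, o$ppv)
    expect_equal(row$tp + row$fp + row$tn + row$fn, n)
  }
})

test_that("malignancy rates reproduce the per-category arithmetic", {
  co <- reference_cohort(seed = 4)
  ex <- quiet(apply_exclusions(co, qc_cohort(co)))
  tab <- ex$report$breathprints_by_category_and_outcome
  rate <- function(cats) sum(tab[cats, "malignant"]) / sum(tab[cats, ])
  expect_equal(round(100 * rate("4A")), 6)
  expect_equal(round(100 * rate("4B")), 13)
  expect_equal(round(100 * rate("4C")), 49)
  expect_equal(round(100 * rate(c("4A", "4B", "4C"))), 17)
  expect_equal(malignancy_rate(c(0, 0, 0)), 0)
  expect_error(malignancy_rate(numeric(0)), "empty")
})

test_that("run aggregation gives exact means and sample SDs", {
  t1 <- data.frame(subgroup = "4A+4B+4C", sensitivity = 0.8, specificity = 0.7,
                   npv = 0.9, ppv = 0.5, malignancy_rate = 0.17)
  t2 <- t1; t2$sensitivity <- 0.9
  agg <- aggregate_runs(list(t1, t2))
  expect_equal(agg$sensitivity_mean, 0.85)
  expect_equal(agg$sensitivity_sd, sd(c(0.8, 0.9)), tolerance = 1e-12)
  expect_equal(agg$sensitivity_sd, 0.0707, tolerance = 1e-3)
  expect_equal(agg$specificity_sd, 0)
  same <- aggregate_runs(list(t1, t1, t1))
  expect_true(all(unlist(same[grepl("_sd$", names(same))]) == 0))
  expect_error(aggregate_runs(list(t1)), "at least 2")
})

test_that("conservative ties dominate benign ties in sensitivity and cede specificity", {
  benign_tie <- function(votes) {
    n1 <- sum(votes == 1); n0 <- sum(votes == 0)
    as.integer(n1 > n0)
  }
  for (len in 1:5) {
    grids <- expand.grid(rep(list(0:1), len))
    for (r in seq_len(nrow(grids))) {
      votes <- as.integer(grids[r, ])
      cons <- majority_vote(votes)
      ben <- benign_tie(votes)
      expect_equal(cons$final == 1 && !cons$tie_broken,
                   sum(votes == 1) > sum(votes == 0))
      # conservative rule can only move verdicts toward malignant
      expect_gte(cons$final, ben)
    }
  }
})

test_that("nested CV covers every breathprint once and excludes 3/5 from subgroup rows", {
  aset <- small_analysis_set(n = 24, seed = 9)
  cfg <- model_config(epochs = 8)
  prepared <- prepare_analysis_data(aset)
  md <- build_model_data(prepared, cfg)
  plan <- quiet(build_fold_plan(aset, k_out = 3, k_in = 3, n_runs = 1, seed = 7))
  pred <- run_nested_cv(md, plan$runs[[1]], cfg)
  expect_setequal(pred$record_id, md$record_id)
  expect_equal(nrow(pred), length(md$record_id))
  expect_true(all(pred$final %in% 0:1))
  expect_true(all(pred$votes_malignant <= pred$n_votes))
  # tie flag consistent with the vote count
  expect_equal(pred$tie_broken, pred$votes_malignant * 2 == pred$n_votes)

  tab <- metrics_table(pred)
  row4 <- tab[tab$subgroup == "4A+4B+4C", ]
  expect_equal(row4$n, sum(pred$birads %in% c("4A", "4B", "4C")))
  expect_equal(tab[tab$subgroup == "all", "n"], nrow(pred))
  expect_equal(row4$tp + row4$fp + row4$tn + row4$fn, row4$n)
})

test_that("rank AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  scores <- withr::with_seed(15, rnorm(40))
  labels <- withr::with_seed(16, sample(0:1, 40, replace = TRUE))
  ours <- breathstrat:::auc_mann_whitney(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})
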