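# Forward pass, composite loss, gradients, training behavior, utility.

small_model_cfg <- function(epochs = 0, ...) {
  model_config(latent_dim = 6, n_bins = 4, hidden_d = 8, hidden_c = 3,
               task_hidden = 4, epochs = epochs, init_seed = 2, ...)
}

# model_data built directly from random tensors, bypassing the simulator
toy_model_data <- function(n = 8, seed = 1, cfg = small_model_cfg(),
                           labels = rep_len(0:1, n)) {
  withr::with_seed(seed, {
    tensors <- lapply(seq_len(n), function(i) {
      matrix(rnorm(cfg$n_channels * cfg$target_length, sd = 0.01),
             cfg$n_channels, cfg$target_length)
    })
  })
  prepared <- list(tensors = tensors,
                   record_id = sprintf("r%02d", seq_len(n)),
                   participant_id = sprintf("p%02d", seq_len(n)),
                   birads = rep_len(c("4A", "4B", "4C", "5"), n),
                   label = labels)
  build_model_data(prepared, cfg)
}

test_that("forward pass is deterministic and sensitive to both inputs", {
  cfg <- small_model_cfg()
  params <- breathstrat:::init_params(cfg)
  d <- matrix(0.01, cfg$n_channels, cfg$target_length)
  c1 <- c(0, 1, 0, 0, 0)
  out1 <- forward(d, c1, params, cfg)
  out2 <- forward(d, c1, params, cfg)
  expect_identical(out1, out2)
  expect_true(out1$outputs$y_hat > 0 && out1$outputs$y_hat < 1)
  expect_equal(sum(out1$outputs$c_hat), 1, tolerance = 1e-12)

  # perturbing the BI-RADS input with d fixed moves the latent vector
  out3 <- forward(d, c(0, 0, 0, 1, 0), params, cfg)
  expect_gt(max(abs(out1$latent - out3$latent)), 0)
})

test_that("a zero network with zero-bias head predicts probability one half", {
  cfg <- small_model_cfg()
  params <- breathstrat:::init_params(cfg)
  params <- lapply(params, function(p) p * 0)
  d <- matrix(0.5, cfg$n_channels, cfg$target_length)
  out <- forward(d, c(1, 0, 0, 0, 0), params, cfg)
  expect_equal(out$outputs$y_hat, 0.5)
  expect_equal(out$outputs$c_hat, rep(0.2, 5))
})

test_that("composite loss decomposes and matches the training-internal loss", {
  cfg <- small_model_cfg(class_weights = c(benign = 1, malignant = 1))
  md <- toy_model_data(n = 6, cfg = cfg)
  params <- breathstrat:::init_params(cfg)
  fw <- breathstrat:::forward_batch(md$D, md$C, params)
  w <- breathstrat:::task_weights(md$y, cfg)
  terms <- breathstrat:::batch_loss_terms(fw, md, w)
  internal_total <- cfg$lambda_task * terms$task +
    cfg$lambda_bp * terms$breathprint + cfg$lambda_birads * terms$birads

  # same quantities through the public single-example API; rebuilding x
  # from the pooled vector makes the within-bin variance zero, so the
  # internal term differs from the public one by exactly mean(ssw)/M
  outs <- lapply(seq_len(6), function(i) {
    forward(breathstrat:::unpool_vector(md$D[i, ], cfg),
            md$C[i, ], params, cfg)$outputs
  })
  tgts <- lapply(seq_len(6), function(i) {
    list(d = breathstrat:::unpool_vector(md$D[i, ], cfg), c = md$C[i, ],
         y = md$y[i])
  })
  loss <- composite_loss(outs, tgts, cfg)
  expect_equal(loss$total,
               cfg$lambda_task * loss$task + cfg$lambda_bp * loss$breathprint +
                 cfg$lambda_birads * loss$birads, tolerance = 1e-9)
  expect_equal(loss$task, terms$task, tolerance = 1e-9)
  expect_equal(loss$birads, terms$birads, tolerance = 1e-9)
  # internal breathprint term carries the within-bin variance of the raw
  # tensors on top of the pooled-scale error
  ssw_mean <- mean(md$ssw / md$n_elements)
  expect_equal(loss$breathprint + ssw_mean, terms$breathprint,
               tolerance = 1e-9)
  expect_equal(internal_total,
               loss$total + cfg$lambda_bp * ssw_mean, tolerance = 1e-9)
})

test_that("perfect reconstruction drives the breathprint term to zero", {
  cfg <- small_model_cfg()
  d <- matrix(0.3, 4, 6)
  out <- list(x_hat = d, c_hat = c(0, 0, 1, 0, 0) * 0.96 + 0.008,
              y_hat = 0.999)
  tgt <- list(d = d, c = c(0, 0, 1, 0, 0), y = 1)
  loss <- composite_loss(out, tgt, cfg)
  expect_equal(loss$breathprint, 0)
  expect_lt(loss$birads, 0.05)
})

test_that("zero reconstruction weights reduce the loss to the weighted task term", {
  cfg <- model_config(lambda_bp = 0, lambda_birads = 0,
                      class_weights = c(benign = 2, malignant = 1),
                      fn_penalty_multiplier = 3)
  out <- list(x_hat = matrix(5, 2, 2), c_hat = rep(0.2, 5), y_hat = 0.8)
  tgt <- list(d = matrix(0, 2, 2), c = c(1, 0, 0, 0, 0), y = 1)
  loss <- composite_loss(out, tgt, cfg)
  expect_equal(loss$total, 1 * 3 * -log(0.8), tolerance = 1e-12)
})

test_that("doubling the FN penalty doubles the malignant term on a hand-built batch", {
  # two examples: one malignant predicted 0.6, one benign predicted 0.3
  outs <- list(list(x_hat = matrix(0, 1, 1), c_hat = rep(0.2, 5), y_hat = 0.6),
               list(x_hat = matrix(0, 1, 1), c_hat = rep(0.2, 5), y_hat = 0.3))
  tgts <- list(list(d = matrix(0, 1, 1), c = c(1, 0, 0, 0, 0), y = 1),
               list(d = matrix(0, 1, 1), c = c(1, 0, 0, 0, 0), y = 0))
  cfg1 <- model_config(fn_penalty_multiplier = 1,
                       class_weights = c(benign = 1, malignant = 1))
  cfg2 <- model_config(fn_penalty_multiplier = 2,
                       class_weights = c(benign = 1, malignant = 1))
  l1 <- composite_loss(outs, tgts, cfg1)
  l2 <- composite_loss(outs, tgts, cfg2)
  mal1 <- -log(0.6) / 2; ben <- -log(0.7) / 2   # hand arithmetic
  expect_equal(l1$task, mal1 + ben, tolerance = 1e-12)
  expect_equal(l2$task, 2 * mal1 + ben, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  cfg <- small_model_cfg(class_weights = c(benign = 1, malignant = 2),
                         fn_penalty_multiplier = 2)
  md <- toy_model_data(n = 5, cfg = cfg, labels = c(0, 1, 0, 1, 1))
  params <- breathstrat:::init_params(cfg)
  w <- breathstrat:::task_weights(md$y, cfg)
  loss_at <- function(p) {
    fw <- breathstrat:::forward_batch(md$D, md$C, p)
    t <- breathstrat:::batch_loss_terms(fw, md, w)
    cfg$lambda_task * t$task + cfg$lambda_bp * t$breathprint +
      cfg$lambda_birads * t$birads
  }
  fw <- breathstrat:::forward_batch(md$D, md$C, params)
  grads <- breathstrat:::backward_batch(fw, md, w, params, cfg)
  h <- 1e-6
  for (nm in c("W1", "Wc", "Wf", "Wd", "Wc2", "Wt1", "wt2", "bt2", "bf")) {
    p <- params[[nm]]
    idx <- withr::with_seed(3, sample.int(length(p), min(4, length(p))))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- p[i] + h
      pm <- params; pm[[nm]][i] <- p[i] - h
      num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic, inert at zero epochs, and fits separable data", {
  cfg <- small_model_cfg()
  md <- toy_model_data(n = 10, cfg = cfg, labels = rep_len(0:1, 10))
  m0 <- train_fusion_model(md, NULL, cfg)
  expect_identical(m0$params, breathstrat:::init_params(cfg))
  expect_equal(nrow(m0$history), 0L)

  # plant a large clean separation on the pooled scale
  cfg2 <- small_model_cfg(epochs = 120, learning_rate = 0.02)
  md2 <- md
  md2$D[md$y == 1, 1:8] <- md2$D[md$y == 1, 1:8] + 0.5
  m1 <- train_fusion_model(md2, NULL, cfg2)
  m2 <- train_fusion_model(md2, NULL, cfg2)
  expect_identical(m1$params, m2$params)
  pred <- as.integer(predict_fusion_model(m1, md2) >= 0.5)
  expect_equal(sum(pred == 1 & md2$y == 1) / sum(md2$y == 1), 1)
  expect_equal(sum(pred == 0 & md2$y == 0) / sum(md2$y == 0), 1)
  # loss history is decomposable
  with(m1$history, expect_equal(
    total, cfg2$lambda_task * task + cfg2$lambda_bp * breathprint +
      cfg2$lambda_birads * birads, tolerance = 1e-9))

  single <- md
  single$y <- rep(1, length(single$y))
  expect_error(train_fusion_model(single, NULL, cfg), "both classes")
})

test_that("higher FN penalty does not lower held-out sensitivity on average", {
  aset <- small_analysis_set(n = 26, seed = 41, effect_size = 1.5)
  prepared <- prepare_analysis_data(aset)
  cfg_base <- model_config(epochs = 30)
  md <- build_model_data(prepared, cfg_base)
  n <- length(md$y)
  split_at <- md$participant_id %in% unique(md$participant_id)[1:18]
  sens <- function(fnmult, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- model_config(epochs = 30, fn_penalty_multiplier = fnmult,
                          init_seed = s)
      m <- train_fusion_model(breathstrat:::subset_model_data(md, which(split_at)),
                              NULL, cfg)
      p <- predict_fusion_model(m, breathstrat:::subset_model_data(md, which(!split_at)))
      y <- md$y[!split_at]
      sum(p >= 0.5 & y == 1) / sum(y == 1)
    }, 0))
  }
  seeds <- 1:10
  expect_gte(sens(3, seeds), sens(1, seeds))
})

test_that("clinical utility matches its closed forms", {
  labels <- c(1, 1, 0, 0, 0)
  expect_equal(clinical_utility(labels, labels), 1)
  expect_equal(clinical_utility(rep(1, 5), labels, 0.7), 0.7)
  preds <- c(1, 0, 0, 1, 0)
  sens <- 1 / 2; spec <- 2 / 3
  expect_equal(clinical_utility(preds, labels, 0.5), (sens + spec) / 2)
  expect_error(clinical_utility(preds, rep(1, 5)), "both classes")
})
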