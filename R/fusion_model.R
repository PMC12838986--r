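# Dual-input autoencoder-classifier.
#
# Two encoders map the breathprint time series (d) and its BI-RADS
# category (c) into a shared latent vector z; from z, two decoders
# reconstruct the breathprint and the category, and a small MLP head
# predicts malignancy. The whole network is optimized jointly under the
# composite loss
#
#   L = lambda_task * L_Task + lambda_bp * L_Breathprint + lambda_birads * L_BIRADS
#
# where L_Breathprint is the mean squared reconstruction error on d,
# L_BIRADS the categorical cross-entropy on c, and L_Task a class-weighted
# binary cross-entropy whose malignant-example weight is multiplied by an
# extra false-negative penalty.
#
# The breathprint branch first applies a FIXED average pooling of each
# channel into n_bins temporal bins; trainable layers act on the pooled
# representation and the decoder reconstructs it, expanded back to the
# full series as a piecewise-constant curve. Because the pooling is a
# partition of the time axis, the full-series reconstruction MSE
# decomposes exactly into a bin-weighted MSE on the pooled representation
# plus the (parameter-free) within-bin variance, which is what training
# uses; composite_loss() on forward() outputs and the training-internal
# loss agree to machine precision. Gradients are exact (hand-derived) and
# optimization is Adam, full-batch by default.

#' Model configuration
#'
#' @param latent_dim Size of the shared latent vector z (default 16).
#' @param n_bins Temporal bins per channel in the fixed pooling stage
#'   (default 16).
#' @param hidden_d,hidden_c Widths of the breathprint / BI-RADS encoder
#'   layers (defaults 32 and 4).
#' @param task_hidden Width of the malignancy-head hidden layer (default 8).
#' @param lambda_task,lambda_bp,lambda_birads Loss weights (defaults 1, 1,
#'   1); non-negative, not all zero.
#' @param class_weights Optional `c(benign =, malignant =)` weights for
#'   L_Task; when `NULL`, inverse-prevalence weights are computed from the
#'   training set.
#' @param fn_penalty_multiplier Extra multiplier on the malignant-example
#'   weight (>= 1, default 3): false negatives cost more than false
#'   positives.
#' @param learning_rate Adam step size (default 0.01).
#' @param epochs Training epochs (default 60).
#' @param batch_size Minibatch size; `NULL` (default) trains full-batch.
#' @param init_seed Seed for parameter initialization (and minibatch
#'   shuffling).
#' @param threshold Decision threshold on the malignancy probability
#'   (default 0.5).
#' @param weight_sensitivity Sensitivity weight in the clinical utility
#'   used for epoch selection (default 0.7).
#' @param n_channels,target_length Input geometry (defaults 32 and 295).
#' @return A `model_config` list.
#' @export
model_config <- function(latent_dim = 16, n_bins = 16, hidden_d = 32,
                         hidden_c = 4, task_hidden = 8,
                         lambda_task = 1, lambda_bp = 1, lambda_birads = 1,
                         class_weights = NULL, fn_penalty_multiplier = 3,
                         learning_rate = 0.01, epochs = 60, batch_size = NULL,
                         init_seed = 1, threshold = 0.5,
                         weight_sensitivity = 0.7,
                         n_channels = 32, target_length = 295) {
  lambdas <- c(lambda_task, lambda_bp, lambda_birads)
  if (any(lambdas < 0) || all(lambdas == 0)) {
    config_stop("loss weights must be non-negative and not all zero")
  }
  if (fn_penalty_multiplier < 1) config_stop("fn_penalty_multiplier must be >= 1")
  if (threshold <= 0 || threshold >= 1) config_stop("threshold must lie in (0, 1)")
  structure(
    list(latent_dim = latent_dim, n_bins = n_bins, hidden_d = hidden_d,
         hidden_c = hidden_c, task_hidden = task_hidden,
         lambda_task = lambda_task, lambda_bp = lambda_bp,
         lambda_birads = lambda_birads, class_weights = class_weights,
         fn_penalty_multiplier = fn_penalty_multiplier,
         learning_rate = learning_rate, epochs = epochs,
         batch_size = batch_size, init_seed = init_seed,
         threshold = threshold, weight_sensitivity = weight_sensitivity,
         n_channels = n_channels, target_length = target_length),
    class = "model_config"
  )
}

# Near-equal partition of the time axis into n_bins bins.
bin_sizes <- function(target_length, n_bins) {
  base <- target_length %/% n_bins
  rem <- target_length - base * n_bins
  sizes <- rep(base, n_bins)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  as.integer(sizes)
}

bin_index <- function(target_length, n_bins) {
  rep(seq_len(n_bins), times = bin_sizes(target_length, n_bins))
}

# Pool a 32 x T tensor to the flattened (channel-major) binned-mean vector
# and the within-bin sum of squares (the parameter-free part of the MSE).
pool_tensor <- function(x, config) {
  bidx <- bin_index(ncol(x), config$n_bins)
  sizes <- bin_sizes(ncol(x), config$n_bins)
  pooling <- matrix(0, ncol(x), config$n_bins)
  pooling[cbind(seq_len(ncol(x)), bidx)] <- 1 / sizes[bidx]
  binned <- x %*% pooling                       # 32 x n_bins
  ssw <- sum((x - binned[, bidx, drop = FALSE])^2)
  list(pooled = as.numeric(binned), ssw = ssw)
}

# Expand a pooled vector back to a piecewise-constant 32 x T matrix.
unpool_vector <- function(r, config) {
  bidx <- bin_index(config$target_length, config$n_bins)
  matrix(r, config$n_channels, config$n_bins)[, bidx, drop = FALSE]
}

#' Assemble model-ready data from prepared breathprints
#'
#' @param prepared Output of [prepare_analysis_data()].
#' @param config A [model_config()].
#' @return A `model_data` list: `D` (N x 32*n_bins pooled matrix, which is
#'   both the model input and the reconstruction target), `ssw`, `C`
#'   (N x 5 one-hot BI-RADS), `y` (0/1), `nb` (per-column bin sizes),
#'   `n_elements` (32 * target_length), plus record/participant metadata.
#' @export
build_model_data <- function(prepared, config) {
  pooled <- lapply(prepared$tensors, pool_tensor, config = config)
  D <- do.call(rbind, lapply(pooled, `[[`, "pooled"))
  structure(
    list(D = D,
         ssw = vapply(pooled, `[[`, 0, "ssw"),
         C = one_hot_birads(prepared$birads),
         y = as.numeric(prepared$label),
         nb = rep(bin_sizes(config$target_length, config$n_bins),
                  each = config$n_channels),
         n_elements = config$n_channels * config$target_length,
         record_id = prepared$record_id,
         participant_id = prepared$participant_id,
         birads = prepared$birads),
    class = "model_data"
  )
}

subset_model_data <- function(md, idx) {
  out <- md
  out$D <- md$D[idx, , drop = FALSE]
  out$ssw <- md$ssw[idx]
  out$C <- md$C[idx, , drop = FALSE]
  out$y <- md$y[idx]
  out$record_id <- md$record_id[idx]
  out$participant_id <- md$participant_id[idx]
  out$birads <- md$birads[idx]
  out
}

xavier <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

init_params <- function(config) {
  P <- config$n_channels * config$n_bins
  withr::with_seed(as.integer(config$init_seed), list(
    W1 = xavier(P, config$hidden_d), b1 = rep(0, config$hidden_d),
    Wc = xavier(5L, config$hidden_c), bc = rep(0, config$hidden_c),
    Wf = xavier(config$hidden_d + config$hidden_c, config$latent_dim),
    bf = rep(0, config$latent_dim),
    Wd = xavier(config$latent_dim, P), bd = rep(0, P),
    Wc2 = xavier(config$latent_dim, 5L), bc2 = rep(0, 5L),
    Wt1 = xavier(config$latent_dim, config$task_hidden),
    bt1 = rep(0, config$task_hidden),
    wt2 = as.numeric(xavier(config$task_hidden, 1L)), bt2 = 0
  ))
}

sigmoid <- function(u) 1 / (1 + exp(-u))

row_softmax <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

add_bias <- function(M, b) sweep(M, 2, b, "+")

forward_batch <- function(D, C, params) {
  H <- tanh(add_bias(D %*% params$W1, params$b1))
  Hc <- tanh(add_bias(C %*% params$Wc, params$bc))
  F_ <- cbind(H, Hc)
  Z <- add_bias(F_ %*% params$Wf, params$bf)
  Rr <- add_bias(Z %*% params$Wd, params$bd)
  Lc <- add_bias(Z %*% params$Wc2, params$bc2)
  A1 <- tanh(add_bias(Z %*% params$Wt1, params$bt1))
  u <- as.numeric(A1 %*% params$wt2 + params$bt2)
  list(H = H, Hc = Hc, F_ = F_, Z = Z, Rr = Rr, S = row_softmax(Lc),
       A1 = A1, p = sigmoid(u))
}

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Per-term losses on a batch; `w` is the per-example task weight.
batch_loss_terms <- function(fw, md, w) {
  N <- nrow(md$D)
  dev2 <- (fw$Rr - md$D)^2
  l_bp <- mean((as.numeric(dev2 %*% md$nb) + md$ssw) / md$n_elements)
  ci <- max.col(md$C, ties.method = "first")
  l_birads <- -mean(log(clamp_prob(fw$S[cbind(seq_len(N), ci)])))
  p <- clamp_prob(fw$p)
  l_task <- mean(w * -(md$y * log(p) + (1 - md$y) * log(1 - p)))
  list(task = l_task, breathprint = l_bp, birads = l_birads)
}

backward_batch <- function(fw, md, w, params, config) {
  N <- nrow(md$D)
  dRr <- sweep(fw$Rr - md$D, 2, md$nb, "*") *
    (2 * config$lambda_bp / (N * md$n_elements))
  dLc <- config$lambda_birads / N * (fw$S - md$C)
  du <- config$lambda_task / N * w * (fw$p - md$y)
  dA1 <- (du %o% params$wt2) * (1 - fw$A1^2)
  dZ <- dRr %*% t(params$Wd) + dLc %*% t(params$Wc2) + dA1 %*% t(params$Wt1)
  dF <- dZ %*% t(params$Wf)
  hd <- config$hidden_d
  dH <- dF[, seq_len(hd), drop = FALSE] * (1 - fw$H^2)
  dHc <- dF[, hd + seq_len(config$hidden_c), drop = FALSE] * (1 - fw$Hc^2)
  list(
    W1 = crossprod(md$D, dH), b1 = colSums(dH),
    Wc = crossprod(md$C, dHc), bc = colSums(dHc),
    Wf = crossprod(fw$F_, dZ), bf = colSums(dZ),
    Wd = crossprod(fw$Z, dRr), bd = colSums(dRr),
    Wc2 = crossprod(fw$Z, dLc), bc2 = colSums(dLc),
    Wt1 = crossprod(fw$Z, dA1), bt1 = colSums(dA1),
    wt2 = as.numeric(crossprod(fw$A1, du)), bt2 = sum(du)
  )
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

task_weights <- function(y, config) {
  cw <- config$class_weights
  if (is.null(cw)) {
    n <- length(y)
    cw <- c(benign = n / (2 * sum(y == 0)), malignant = n / (2 * sum(y == 1)))
  }
  ifelse(y == 1, cw[["malignant"]] * config$fn_penalty_multiplier,
         cw[["benign"]])
}

#' Train the fusion model
#'
#' Joint gradient-based minimization of the composite loss with Adam.
#' When a validation set is supplied, the clinical utility
#' (`weight_sensitivity * sensitivity + (1 - weight_sensitivity) *
#' specificity` at the configured threshold) is evaluated after every
#' epoch and the parameters achieving the best validation utility are
#' returned (earliest epoch on ties) -- an early-stopping surrogate for
#' utility-driven model selection. Deterministic given
#' `config$init_seed`.
#'
#' @param train_data,val_data `model_data` objects (see
#'   [build_model_data()]); `val_data` may be `NULL`.
#' @param config A [model_config()].
#' @return A `fusion_model`: `params` (selected), `final_params`,
#'   `history` (per-epoch loss terms and validation utility), `config`,
#'   `task_class_weights`.
#' @export
train_fusion_model <- function(train_data, val_data = NULL, config = model_config()) {
  if (length(unique(train_data$y)) < 2L) {
    bs_stop("training set must contain both classes")
  }
  w <- task_weights(train_data$y, config)
  params <- init_params(config)
  state <- adam_init(params)
  n <- nrow(train_data$D)
  hist <- vector("list", config$epochs)
  best_u <- -Inf
  best_params <- params
  batch_seeds <- if (!is.null(config$batch_size) && config$epochs > 0) {
    derive_seeds(config$init_seed + 1L, config$epochs)
  }

  for (epoch in seq_len(config$epochs)) {
    batches <- if (is.null(config$batch_size)) {
      list(seq_len(n))
    } else {
      idx <- withr::with_seed(batch_seeds[epoch], sample.int(n))
      split(idx, ceiling(seq_along(idx) / config$batch_size))
    }
    for (b in batches) {
      mb <- if (length(b) == n) train_data else subset_model_data(train_data, b)
      fw <- forward_batch(mb$D, mb$C, params)
      grads <- backward_batch(fw, mb, w[b], params, config)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    fw <- forward_batch(train_data$D, train_data$C, params)
    terms <- batch_loss_terms(fw, train_data, w)
    total <- config$lambda_task * terms$task +
      config$lambda_bp * terms$breathprint +
      config$lambda_birads * terms$birads
    val_u <- NA_real_
    if (!is.null(val_data)) {
      pv <- forward_batch(val_data$D, val_data$C, params)$p
      if (length(unique(val_data$y)) == 2L) {
        val_u <- clinical_utility(as.integer(pv >= config$threshold),
                                  val_data$y, config$weight_sensitivity)
        if (val_u > best_u) {
          best_u <- val_u
          best_params <- params
        }
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, total = total,
                                task = terms$task,
                                breathprint = terms$breathprint,
                                birads = terms$birads, val_utility = val_u)
  }
  if (is.infinite(best_u)) best_params <- params
  structure(
    list(params = best_params, final_params = params,
         history = if (config$epochs > 0) do.call(rbind, hist) else
           data.frame(epoch = integer(), total = numeric(), task = numeric(),
                      breathprint = numeric(), birads = numeric(),
                      val_utility = numeric()),
         config = config,
         task_class_weights = w),
    class = "fusion_model"
  )
}

#' Predict malignancy probabilities
#'
#' @param model A [train_fusion_model()] result.
#' @param data A `model_data` object.
#' @param use_final Use the final-epoch parameters instead of the
#'   utility-selected ones (default FALSE).
#' @return Numeric vector of malignancy probabilities.
#' @export
predict_fusion_model <- function(model, data, use_final = FALSE) {
  params <- if (use_final) model$final_params else model$params
  forward_batch(data$D, data$C, params)$p
}

#' Forward pass for a single breathprint
#'
#' Maps one breathprint tensor and its BI-RADS one-hot through the
#' encoders to the shared latent vector, then decodes the breathprint
#' (piecewise-constant over the pooling bins), the category distribution
#' and the malignancy probability. Deterministic given `params`.
#'
#' @param d A 32 x `target_length` normalized breathprint matrix.
#' @param c_onehot Length-5 one-hot BI-RADS vector.
#' @param params Parameter list (e.g. `model$params` or [init_params]).
#' @param config A [model_config()].
#' @return `list(latent = z, outputs = list(x_hat, c_hat, y_hat))`.
#' @export
forward <- function(d, c_onehot, params, config = model_config()) {
  if (!is.matrix(d) || nrow(d) != config$n_channels ||
      ncol(d) != config$target_length) {
    bs_stop("d must be a %d x %d matrix", config$n_channels,
            config$target_length, class = "breathstrat_dimension_error")
  }
  if (length(c_onehot) != 5L) {
    bs_stop("c must be a length-5 one-hot vector",
            class = "breathstrat_dimension_error")
  }
  D <- matrix(pool_tensor(d, config)$pooled, nrow = 1)
  fw <- forward_batch(D, matrix(as.numeric(c_onehot), nrow = 1), params)
  list(latent = as.numeric(fw$Z),
       outputs = list(x_hat = unpool_vector(as.numeric(fw$Rr), config),
                      c_hat = as.numeric(fw$S),
                      y_hat = as.numeric(fw$p)))
}

#' Composite loss for one example (or a batch of examples)
#'
#' `L = lambda_task * L_Task + lambda_bp * L_Breathprint + lambda_birads *
#' L_BIRADS`, with L_Breathprint the mean squared error between `x_hat`
#' and `d`, L_BIRADS the cross-entropy between `c_hat` and the true
#' one-hot category, and L_Task the class-weighted binary cross-entropy in
#' which the malignant-example weight is `class_weights["malignant"] *
#' fn_penalty_multiplier`. For a batch (lists of outputs/targets), terms
#' are averaged over examples.
#'
#' @param outputs `list(x_hat, c_hat, y_hat)` from [forward()], or a list
#'   of such lists.
#' @param targets `list(d, c, y)` (matrix, one-hot vector, 0/1 label), or
#'   a list of such lists.
#' @param config A [model_config()]; `class_weights` defaults to
#'   `c(benign = 1, malignant = 1)` here when unset.
#' @return `list(total, task, breathprint, birads)`.
#' @export
composite_loss <- function(outputs, targets, config = model_config()) {
  if (!is.null(outputs$y_hat)) {
    outputs <- list(outputs)
    targets <- list(targets)
  }
  cw <- config$class_weights %||% c(benign = 1, malignant = 1)
  one <- function(o, tg) {
    w <- if (tg$y == 1) cw[["malignant"]] * config$fn_penalty_multiplier else
      cw[["benign"]]
    p <- clamp_prob(o$y_hat)
    c(breathprint = mean((o$x_hat - tg$d)^2),
      birads = -sum(tg$c * log(clamp_prob(o$c_hat))),
      task = w * -(tg$y * log(p) + (1 - tg$y) * log(1 - p)))
  }
  per_example <- mapply(one, outputs, targets, SIMPLIFY = FALSE)
  terms <- Reduce(`+`, per_example) / length(per_example)
  total <- config$lambda_task * terms[["task"]] +
    config$lambda_bp * terms[["breathprint"]] +
    config$lambda_birads * terms[["birads"]]
  list(total = total, task = terms[["task"]],
       breathprint = terms[["breathprint"]], birads = terms[["birads"]])
}

#' Clinical utility of a set of predictions
#'
#' `U = w_s * sensitivity + (1 - w_s) * specificity`. With `w_s = 0.5`
#' this is balanced accuracy; the default `w_s = 0.7` encodes the
#' rule-out priority of catching malignant cases over avoiding false
#' alarms.
#'
#' @param predictions Binary predicted labels (0/1).
#' @param labels True labels (0/1); both classes must be present.
#' @param weight_sensitivity Sensitivity weight `w_s` in `[0, 1]`.
#' @return Scalar utility in `[0, 1]`.
#' @export
clinical_utility <- function(predictions, labels, weight_sensitivity = 0.7) {
  if (length(unique(labels)) < 2L) {
    bs_stop("clinical utility needs both classes in `labels`")
  }
  sens <- sum(predictions == 1 & labels == 1) / sum(labels == 1)
  spec <- sum(predictions == 0 & labels == 0) / sum(labels == 0)
  weight_sensitivity * sens + (1 - weight_sensitivity) * spec
}
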