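#' Training configuration for the LSTM gait regressor
#'
#' @param folds number of cross-validation folds (subjects are assigned to
#'   folds whole, never split).
#' @param split_ratio fraction of subjects used for cross-validation
#'   training (the remainder is the held-out test set).
#' @param max_iterations maximum training epochs.
#' @param patience early-stopping patience: training stops when the
#'   validation RMSE fails to decrease for this many consecutive epochs.
#' @param forgetting_rate dropout probability on the recurrent hidden state
#'   (one mask per sequence, shared across timesteps).
#' @param l2 L2 penalty on the weight matrices.
#' @param sequence_length number of consecutive feature windows fed to the
#'   LSTM per prediction (history ending at the target time).
#' @param hidden_units LSTM hidden-state size.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param adapt_iterations,adapt_lr epochs and learning rate for incremental
#'   per-subject adaptation.
#' @param adapt_frac fraction of a new subject's rows (time-ordered, from
#'   the start) used for adaptation; the remainder is the gating evaluation
#'   slice.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return a `training_config` list.
#' @export
training_config <- function(folds = 4, split_ratio = 0.8, max_iterations = 200,
                            patience = 8, forgetting_rate = 0.2, l2 = 1e-4,
                            sequence_length = 10, hidden_units = 64,
                            learning_rate = 1e-3, batch_size = 128,
                            adapt_iterations = 20, adapt_lr = 2e-4,
                            adapt_frac = 0.7, seed = 1L) {
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (patience >= max_iterations) stop("patience must be < max_iterations", call. = FALSE)
  if (forgetting_rate < 0 || forgetting_rate >= 1)
    stop("forgetting_rate must be in [0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "training_config")
}

#' Z-score normalization fitted on training rows
#'
#' @param train numeric matrix of training rows.
#' @return list with per-column `mean` and `sd` (zero sds stored as-is;
#'   [zscore_apply()] maps such columns to 0).
#' @export
zscore_fit <- function(train) {
  stopifnot(nrow(train) >= 2)
  list(mean = colMeans(train), sd = apply(train, 2, sd))
}

#' Apply stored z-score statistics to rows
#'
#' @param stats a [zscore_fit()] result.
#' @param x matrix (or vector treated as one column) to normalize.
#' @return normalized matrix; constant training columns map to 0.
#' @export
zscore_apply <- function(stats, x) {
  x <- as.matrix(x)
  s <- stats$sd
  out <- sweep(x, 2, stats$mean)
  nz <- s > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, s[nz], "/")
  out[, !nz] <- 0
  out
}

# Build B x L x D sequence array: for each row, the last `seq_len` rows of
# its own trial (rows are time-ordered within trials), padded at the trial
# start by repeating the first row. `groups` identifies the trial of each
# row so no sequence straddles trials or subjects.
build_sequences <- function(X, groups, seq_len) {
  n <- nrow(X)
  out <- array(0, c(n, seq_len, ncol(X)))
  for (g in unique(groups)) {
    rows <- which(groups == g)
    for (j in seq_along(rows)) {
      hist <- rows[pmax(1, (j - seq_len + 1):j)]
      out[rows[j], , ] <- X[hist, , drop = FALSE]
    }
  }
  out
}

# Partition subject ids into folds, seeded and balanced.
assign_folds <- function(subjects, folds, seed) {
  u <- sort(unique(subjects))
  if (length(u) < folds)
    stop("need at least ", folds, " subjects for ", folds, "-fold CV", call. = FALSE)
  perm <- with_seed(derive_seed(seed, "folds"), sample(u))
  stats::setNames(rep(seq_len(folds), length.out = length(u))[order(order(perm))],
                  u)[as.character(subjects)]
}

#' Train the LSTM regressor with subject-wise cross-validation
#'
#' Subjects are partitioned into `folds` validation folds. Per fold,
#' features and target are z-scored with training-fold statistics, sequences
#' of the last `sequence_length` windows are built per trial, and the LSTM
#' is trained with recurrent dropout, L2 penalty and patience-based early
#' stopping on the validation RMSE (best checkpoint restored). A final model
#' is then refit on all cross-validation subjects for the median of the
#' per-fold best epoch counts.
#'
#' @param features rows x features matrix (reduced feature codes).
#' @param target aligned numeric target (physical units); NA rows dropped.
#' @param meta data.frame with `subject` and `trial` per row, rows in time
#'   order within each trial.
#' @param config a [training_config()].
#' @return a `gait_model`: final parameters, normalization statistics,
#'   per-fold metrics, and training histories.
#' @export
train_cv <- function(features, target, meta, config = training_config()) {
  keep <- is.finite(target)
  features <- features[keep, , drop = FALSE]
  target <- target[keep]
  meta <- meta[keep, , drop = FALSE]
  fold_of <- assign_folds(meta$subject, config$folds, config$seed)
  fold_metrics <- data.frame()
  histories <- list()
  for (f in seq_len(config$folds)) {
    tr <- fold_of != f
    nx <- zscore_fit(features[tr, , drop = FALSE])
    ny <- zscore_fit(matrix(target[tr]))
    Xn <- zscore_apply(nx, features)
    yn <- as.numeric(zscore_apply(ny, matrix(target)))
    seqs <- build_sequences(Xn, meta$trial, config$sequence_length)
    hp <- config; hp$seed <- derive_seed(config$seed, "fold", f)
    fit <- lstm_train(seqs[tr, , , drop = FALSE], yn[tr],
                      seqs[!tr, , , drop = FALSE], yn[!tr], hp)
    pred_n <- lstm_forward(fit$params, seqs[!tr, , , drop = FALSE])$yhat
    pred <- pred_n * ny$sd + ny$mean
    fold_metrics <- rbind(fold_metrics, data.frame(
      fold = f, n_val = sum(!tr),
      rmse_relative = rmse_relative(pred, target[!tr]),
      r_squared = r_squared(pred, target[!tr]),
      best_epoch = fit$best_epoch, stop_reason = fit$stop_reason))
    histories[[f]] <- fit$history
  }
  # final refit on every cross-validation subject at the calibrated epoch count
  nx <- zscore_fit(features)
  ny <- zscore_fit(matrix(target))
  Xn <- zscore_apply(nx, features)
  yn <- as.numeric(zscore_apply(ny, matrix(target)))
  seqs <- build_sequences(Xn, meta$trial, config$sequence_length)
  hp <- config
  hp$seed <- derive_seed(config$seed, "final")
  hp$max_iterations <- max(5L, as.integer(round(median(fold_metrics$best_epoch))))
  fit <- lstm_train(seqs, yn, NULL, NULL, hp)
  structure(list(params = fit$params, norm_x = nx, norm_y = ny,
                 config = config, fold_metrics = fold_metrics,
                 histories = histories, final_epochs = hp$max_iterations),
            class = "gait_model")
}

#' Predict staircase gait parameters for feature rows
#'
#' Normalizes with the model's stored statistics, rebuilds per-trial
#' sequences, runs the LSTM without dropout and maps predictions back to
#' physical units.
#'
#' @param object a `gait_model`.
#' @param features rows x features matrix matching the training dimension.
#' @param meta data.frame with `trial` per row (time-ordered within trials).
#' @param ... unused.
#' @return numeric vector of predicted staircase values (physical units).
#' @export
predict.gait_model <- function(object, features, meta, ...) {
  if (ncol(features) != length(object$norm_x$mean))
    stop("expected ", length(object$norm_x$mean), " feature columns, received ",
         ncol(features), call. = FALSE)
  Xn <- zscore_apply(object$norm_x, features)
  seqs <- build_sequences(Xn, meta$trial, object$config$sequence_length)
  pred_n <- lstm_forward(object$params, seqs)$yhat
  pred_n * object$norm_y$sd + object$norm_y$mean
}

#' R-squared-gated incremental adaptation to a new subject
#'
#' Splits the new subject's rows time-ordered into an adaptation slice
#' (first `adapt_frac`) and a held-out gating slice. Continues training
#' briefly on the adaptation rows at a small learning rate, then keeps the
#' updated parameters only if R-squared on the gating rows strictly
#' improved; otherwise the original model is returned unchanged. Using a
#' gating slice disjoint from the adaptation rows prevents self-confirming
#' updates.
#'
#' @param model a `gait_model`.
#' @param features,target,meta the new subject's rows (see [train_cv()]).
#' @param iterations,lr adaptation epochs and learning rate (defaults from
#'   the model's config).
#' @return list: `model` (updated or original), `accepted`, `r2_before`,
#'   `r2_after` (both computed on the gating rows), `rmse_before`,
#'   `rmse_after`, and the row counts used.
#' @export
adaptive_update <- function(model, features, target, meta,
                            iterations = NULL, lr = NULL) {
  cfg <- model$config
  if (is.null(iterations)) iterations <- cfg$adapt_iterations
  if (is.null(lr)) lr <- cfg$adapt_lr
  keep <- is.finite(target)
  features <- features[keep, , drop = FALSE]
  target <- target[keep]
  meta <- meta[keep, , drop = FALSE]
  n <- nrow(features)
  n_adapt <- floor(cfg$adapt_frac * n)
  if (n_adapt < 2 || n - n_adapt < 2)
    stop("too few rows (", n, ") to split into adaptation and gating slices",
         call. = FALSE)
  eval_rows <- (n_adapt + 1):n
  Xn <- zscore_apply(model$norm_x, features)
  yn <- as.numeric(zscore_apply(model$norm_y, matrix(target)))
  seqs <- build_sequences(Xn, meta$trial, cfg$sequence_length)
  denorm <- function(p) p * model$norm_y$sd + model$norm_y$mean
  pred_before <- denorm(lstm_forward(model$params, seqs[eval_rows, , , drop = FALSE])$yhat)
  r2_before <- r_squared(pred_before, target[eval_rows])
  rmse_before <- rmse_relative(pred_before, target[eval_rows])
  if (iterations > 0) {
    hp <- cfg
    hp$learning_rate <- lr
    hp$max_iterations <- iterations
    hp$seed <- derive_seed(cfg$seed, "adapt", meta$subject[1])
    fit <- lstm_train(seqs[seq_len(n_adapt), , , drop = FALSE], yn[seq_len(n_adapt)],
                      NULL, NULL, hp, params = model$params)
    new_params <- fit$params
  } else new_params <- model$params
  pred_after <- denorm(lstm_forward(new_params, seqs[eval_rows, , , drop = FALSE])$yhat)
  r2_after_cand <- r_squared(pred_after, target[eval_rows])
  accepted <- r2_after_cand > r2_before
  out_model <- model
  if (accepted) out_model$params <- new_params
  list(model = out_model, accepted = accepted,
       r2_before = r2_before,
       r2_after = if (accepted) r2_after_cand else r2_before,
       r2_candidate = r2_after_cand,
       rmse_before = rmse_before,
       rmse_after = if (accepted) rmse_relative(pred_after, target[eval_rows])
                    else rmse_before,
       n_adapt = n_adapt, n_eval = length(eval_rows))
}
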