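# quick LSTM hyperparameters for unit tests
quick_config <- function(...) {
  args <- utils::modifyList(
    list(hidden_units = 16, max_iterations = 80, batch_size = 64,
         learning_rate = 5e-3, sequence_length = 5, seed = 7),
    list(...))
  do.call(training_config, args)
}

# smooth multi-subject dataset with a noiseless linear feature-target map
linear_fixture <- function(n_subj = 8, rows = 60, d = 4, seed = 31) {
  set.seed(seed)
  w <- runif(d, -1, 1)
  X <- NULL; meta <- NULL
  for (s in seq_len(n_subj)) {
    base <- matrix(rnorm(rows * d), rows, d)
    sm <- apply(base, 2, function(x) oracle_moving_average(x, 9))
    X <- rbind(X, sm)
    meta <- rbind(meta, data.frame(subject = s, trial = paste0("t", s),
                                   time = seq_len(rows)))
  }
  list(X = X, y = 100 + 20 * as.numeric(X %*% w), meta = meta)
}

test_that("z-score uses training statistics only, with hand-computed values", {
  train <- matrix(c(1, 2, 3, 10, 20, 30), 3)
  st <- zscore_fit(train)
  zt <- zscore_apply(st, train)
  expect_equal(colMeans(zt), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(zt, 2, sd), c(1, 1))
  held <- matrix(c(4, 40), 1)
  expect_equal(as.numeric(zscore_apply(st, held)),
               c((4 - 2) / 1, (40 - 20) / 10))
  cst <- zscore_fit(cbind(c(5, 5, 5), c(1, 2, 3)))
  expect_equal(zscore_apply(cst, cbind(c(7, 8), c(1, 2)))[, 1], c(0, 0))
})

test_that("sequences never straddle trials and pad at trial starts", {
  X <- matrix(1:12, 6, 2)
  groups <- c("a", "a", "a", "b", "b", "b")
  s <- nirgait:::build_sequences(X, groups, 2)
  expect_equal(dim(s), c(6, 2, 2))
  expect_equal(s[1, , 1], c(1, 1))        # padded with the first row
  expect_equal(s[2, , 1], c(1, 2))
  expect_equal(s[4, , 1], c(4, 4))        # trial b restarts padding
  expect_equal(s[5, , 1], c(4, 5))
})

test_that("fold assignment partitions subjects", {
  subj <- rep(1:9, each = 4)
  f <- nirgait:::assign_folds(subj, 4, seed = 3)
  expect_length(f, length(subj))
  per_subject <- tapply(f, subj, unique)
  expect_true(all(lengths(per_subject) == 1))
  expect_setequal(as.integer(unlist(per_subject)), 1:4)
  expect_error(nirgait:::assign_folds(1:3, 4, 1), "at least 4")
})

test_that("a noiseless linear mapping is recovered with high validation R2", {
  fx <- linear_fixture()
  model <- train_cv(fx$X, fx$y, fx$meta, quick_config())
  expect_gt(mean(model$fold_metrics$r_squared), 0.9)
  expect_true(all(model$fold_metrics$best_epoch <=
                  quick_config()$max_iterations))
  pred <- predict(model, fx$X, fx$meta)
  expect_true(all(is.finite(pred)))
  expect_gt(r_squared(pred, fx$y), 0.9)
})

test_that("training is deterministic given config and seed", {
  fx <- linear_fixture(n_subj = 4, rows = 30)
  cfg <- quick_config(max_iterations = 15, patience = 5)
  m1 <- train_cv(fx$X, fx$y, fx$meta, cfg)
  m2 <- train_cv(fx$X, fx$y, fx$meta, cfg)
  expect_identical(m1$fold_metrics, m2$fold_metrics)
  expect_identical(m1$params, m2$params)
})

test_that("early stopping fires on plateauing validation error", {
  fx <- linear_fixture(n_subj = 4, rows = 30, seed = 32)
  set.seed(33)
  noise_y <- rnorm(length(fx$y))           # unlearnable target
  cfg <- quick_config(max_iterations = 150, patience = 8)
  model <- train_cv(fx$X, noise_y + 10, fx$meta, cfg)
  expect_true(any(model$fold_metrics$stop_reason == "patience"))
  stopped <- model$fold_metrics[model$fold_metrics$stop_reason == "patience", ]
  expect_true(all(stopped$best_epoch < cfg$max_iterations))
  # the restored checkpoint is the minimum-RMSE epoch
  h <- model$histories[[which(model$fold_metrics$stop_reason == "patience")[1]]]
  expect_equal(stopped$best_epoch[1], which.min(h$val_rmse))
})

test_that("prediction is deterministic and checks feature dimensions", {
  fx <- linear_fixture(n_subj = 4, rows = 30)
  model <- train_cv(fx$X, fx$y, fx$meta, quick_config(max_iterations = 15,
                                                      patience = 5))
  p1 <- predict(model, fx$X, fx$meta)
  p2 <- predict(model, fx$X, fx$meta)
  expect_identical(p1, p2)
  expect_error(predict(model, fx$X[, 1:2], fx$meta), "expected 4")
})

test_that("the R2 gate never degrades the gating metric and rejects bad updates", {
  fx <- linear_fixture(n_subj = 5, rows = 60, seed = 35)
  cfg <- quick_config(max_iterations = 40)
  train_rows <- fx$meta$subject <= 4
  model <- train_cv(fx$X[train_rows, ], fx$y[train_rows],
                    fx$meta[train_rows, ], cfg)
  new_rows <- fx$meta$subject == 5
  Xn <- fx$X[new_rows, ]; yn <- fx$y[new_rows]; mn <- fx$meta[new_rows, ]
  # zero iterations: identity update, R2 unchanged, state returned intact
  upd0 <- adaptive_update(model, Xn, yn, mn, iterations = 0)
  expect_false(upd0$accepted)
  expect_identical(upd0$model$params, model$params)
  expect_equal(upd0$r2_after, upd0$r2_before)
  # gated update: reported post-adaptation R2 is never below pre-adaptation
  for (s in 1:5) {
    rows <- fx$meta$subject == s
    up <- adaptive_update(model, fx$X[rows, ] * 1.2, fx$y[rows] * 1.1,
                          fx$meta[rows, ], iterations = 10, lr = 1e-3)
    expect_gte(up$r2_after, up$r2_before)
    if (!up$accepted) expect_identical(up$model$params, model$params)
  }
  expect_error(adaptive_update(model, Xn[1:3, ], yn[1:3], mn[1:3, ]),
               "too few rows")
})
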