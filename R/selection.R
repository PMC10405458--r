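#' Correlation (filter) screening of features against the staircase target
#'
#' Computes p = |Pearson correlation| between each feature column and the
#' target and retains features with p strictly greater than the threshold
#' (default 0.3). Negative correlations are as informative as positive ones,
#' hence the absolute value. Zero-variance features get p = 0 and are
#' dropped with a warning.
#'
#' @param features numeric matrix (rows x features).
#' @param target numeric target vector, row-aligned with `features`.
#' @param threshold retention threshold on p (strict inequality).
#' @return data.frame with `feature_id`, `p`, `retained`.
#' @export
pearson_screen <- function(features, target, threshold = 0.3) {
  stopifnot(nrow(features) == length(target))
  sds <- apply(features, 2, sd)
  p <- rep(0, ncol(features))
  ok <- sds > 0
  if (any(!ok)) warning(sum(!ok), " zero-variance feature(s): p set to 0, dropped")
  p[ok] <- abs(as.numeric(cor(features[, ok, drop = FALSE], target)))
  data.frame(feature_id = seq_len(ncol(features)), p = p,
             retained = p > threshold)
}

#' Embedded coefficients from a gradient-boosted tree ensemble
#'
#' Fits gradient-boosted regression trees (100 rounds, depth 3, learning
#' rate 0.1, single thread, fixed seed) of the target on the screened
#' features and returns each feature's importance (total gain) as its
#' embedded coefficient c. Features the ensemble never splits on get c = 0.
#'
#' @param features numeric matrix of retained features.
#' @param target numeric target vector.
#' @param seed integer seed for the booster.
#' @param nrounds,max_depth,learning_rate booster hyperparameters.
#' @return numeric vector c, one per column of `features`.
#' @export
embedded_coefficients <- function(features, target, seed = 1L,
                                  nrounds = 100, max_depth = 3, learning_rate = 0.1) {
  if (nrow(features) < 10) stop("need at least 10 rows to fit the booster", call. = FALSE)
  cn <- colnames(features)
  if (is.null(cn)) cn <- paste0("f", seq_len(ncol(features)))
  colnames(features) <- cn
  dm <- xgboost::xgb.DMatrix(features, label = target)
  bst <- xgboost::xgb.train(
    params = xgboost::xgb.params(max_depth = max_depth, learning_rate = learning_rate,
                                 nthread = 1, seed = seed,
                                 objective = "reg:squarederror"),
    data = dm, nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = bst)
  cc <- stats::setNames(rep(0, length(cn)), cn)
  cc[imp$Feature] <- imp$Gain
  unname(cc)
}

#' Harmonic-mean combined feature score
#'
#' `f_score = 2 p |c| / (p + |c|)`: the harmonic mean of the filter score p
#' (absolute target correlation) and the magnitude of the embedded
#' coefficient c. Zero whenever either ingredient is zero; guarded at
#' p + |c| = 0.
#'
#' @param p nonnegative correlation score(s).
#' @param c embedded coefficient(s), any sign.
#' @return f_score value(s), same length as the inputs.
#' @export
f_score <- function(p, c) {
  if (any(p < 0)) stop("p must be nonnegative (absolute correlation)", call. = FALSE)
  ac <- abs(c)
  den <- p + ac
  ifelse(den > 0, 2 * p * ac / den, 0)
}

#' Select the top-k features by combined score
#'
#' Ties are broken by smaller feature id for determinism. Requesting more
#' features than available keeps all and emits a message.
#'
#' @param scores data.frame with `feature_id` and `f_score` columns.
#' @param k number of features to keep.
#' @return integer vector of selected feature ids, in score order.
#' @export
select_top <- function(scores, k) {
  stopifnot(k >= 1)
  if (k > nrow(scores)) {
    message("k = ", k, " exceeds ", nrow(scores), " available features; keeping all")
    k <- nrow(scores)
  }
  ord <- order(-scores$f_score, scores$feature_id)
  scores$feature_id[ord][seq_len(k)]
}

#' Full hybrid selection: screen, embed, score, rank
#'
#' Runs [pearson_screen()], fits [embedded_coefficients()] on the retained
#' columns, combines them with [f_score()], and ranks. Features failing the
#' screen keep c = 0 and f_score = 0.
#'
#' @param features rows x features matrix.
#' @param target aligned target vector.
#' @param threshold correlation threshold (default 0.3).
#' @param k number of features to select.
#' @param seed booster seed.
#' @return list with `scores` (per-feature data.frame: feature_id, p, c,
#'   f_score, retained, selected) and `selected` (ids of the top-k).
#' @export
score_features <- function(features, target, threshold = 0.3, k = 100, seed = 1L) {
  scr <- pearson_screen(features, target, threshold)
  scr$c <- 0
  if (any(scr$retained)) {
    keep <- which(scr$retained)
    scr$c[keep] <- embedded_coefficients(features[, keep, drop = FALSE], target,
                                         seed = seed)
  }
  scr$f_score <- f_score(scr$p * as.numeric(scr$retained), scr$c)
  sel <- select_top(scr[scr$retained, , drop = FALSE], min(k, max(1L, sum(scr$retained))))
  scr$selected <- scr$feature_id %in% sel
  list(scores = scr, selected = sel)
}

#' Fit a single-hidden-layer autoencoder for feature reduction
#'
#' Symmetric encoder/decoder: `x -> tanh(x W1 + b1) -> h W2 + b2`, trained
#' to minimize mean-squared reconstruction error with Adam on standardized
#' inputs. Training is full-batch, seeded and early-stops when the loss
#' fails to improve for `patience` consecutive epochs.
#'
#' @param features rows x features matrix.
#' @param latent_dim size of the code layer (< input dimension).
#' @param seed integer seed for weight initialization.
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (epochs).
#' @return an `autoencoder` model: weights, input standardization
#'   statistics, loss curve and metadata.
#' @export
fit_autoencoder <- function(features, latent_dim = 20, seed = 1L,
                            epochs = 200, lr = 0.01, patience = 8) {
  d <- ncol(features)
  if (latent_dim >= d) stop("latent_dim must be smaller than the input dimension",
                            call. = FALSE)
  if (nrow(features) < latent_dim) stop("need at least latent_dim rows", call. = FALSE)
  mu <- colMeans(features)
  sdv <- apply(features, 2, sd)
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  n <- nrow(X)
  params <- with_seed(seed, list(
    W1 = matrix(rnorm(d * latent_dim, 0, sqrt(2 / (d + latent_dim))), d, latent_dim),
    b1 = rep(0, latent_dim),
    W2 = matrix(rnorm(latent_dim * d, 0, sqrt(2 / (d + latent_dim))), latent_dim, d),
    b2 = rep(0, d)))
  adam <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  losses <- numeric(0)
  for (ep in seq_len(epochs)) {
    H <- tanh(sweep(X %*% params$W1, 2, params$b1, "+"))
    R <- sweep(H %*% params$W2, 2, params$b2, "+")
    E <- R - X
    loss <- mean(E^2)
    losses[ep] <- loss
    if (loss < best$loss - 1e-12) {
      best <- list(loss = loss, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
    G <- 2 * E / (n * d)
    gW2 <- crossprod(H, G); gb2 <- colSums(G)
    dH <- (G %*% t(params$W2)) * (1 - H^2)
    gW1 <- crossprod(X, dH); gb1 <- colSums(dH)
    upd <- adam_step(params, list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2), adam, lr)
    params <- upd$params; adam <- upd$state
  }
  structure(list(params = best$params, center = mu, scale = sdv,
                 input_dim = d, latent_dim = latent_dim,
                 loss_curve = losses, best_epoch = best$epoch,
                 best_loss = best$loss, seed = seed),
            class = "autoencoder")
}

#' Encode feature rows into the autoencoder's latent space
#'
#' @param model an [fit_autoencoder()] result.
#' @param features rows x features matrix with the model's input dimension.
#' @return rows x latent_dim matrix of codes.
#' @export
encode <- function(model, features) {
  if (ncol(features) != model$input_dim)
    stop("expected ", model$input_dim, " columns, received ", ncol(features),
         call. = FALSE)
  X <- sweep(sweep(features, 2, model$center), 2, model$scale, "/")
  tanh(sweep(X %*% model$params$W1, 2, model$params$b1, "+"))
}

#' Reconstruct feature rows through the autoencoder
#'
#' @param model an [fit_autoencoder()] result.
#' @param features rows x features matrix.
#' @return reconstruction on the original feature scale.
#' @export
reconstruct <- function(model, features) {
  H <- encode(model, features)
  R <- sweep(H %*% model$params$W2, 2, model$params$b2, "+")
  sweep(sweep(R, 2, model$scale, "*"), 2, model$center, "+")
}

# --- minimal Adam optimizer over a named list of arrays ------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
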