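# Minimal LSTM sequence regressor: one LSTM layer, linear read-out from the
# final hidden state, trained by backpropagation through time with Adam.
# Recurrent ("variational") dropout uses one mask per sequence, shared across
# timesteps, applied to the hidden state entering the gates; inverted
# scaling keeps the expected activation unchanged at inference.
#
# Gate layout in the fused weight matrices: columns [i | f | o | g].

lstm_init <- function(d_in, hidden, seed) {
  with_seed(seed, {
    g <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
    b <- rep(0, 4 * hidden)
    b[hidden + seq_len(hidden)] <- 1       # forget-gate bias
    list(Wx = g(d_in, 4 * hidden), Wh = g(hidden, 4 * hidden), b = b,
         Wy = matrix(rnorm(hidden, 0, 1 / sqrt(hidden)), hidden, 1), by = 0,
         hidden = hidden, d_in = d_in)
  })
}

sigm <- function(x) 1 / (1 + exp(-x))

# X: B x T x D array. Returns predictions and (optionally) the cache needed
# for BPTT. `mask`: B x H recurrent dropout mask (already inverted-scaled).
lstm_forward <- function(params, X, mask = NULL, keep_cache = FALSE) {
  B <- dim(X)[1]; Tt <- dim(X)[2]; H <- params$hidden
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", Tt)
  bmat <- matrix(params$b, B, 4 * H, byrow = TRUE)
  for (t in seq_len(Tt)) {
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(B, dim(X)[3])
    hd <- if (is.null(mask)) h else h * mask
    z <- xt %*% params$Wx + hd %*% params$Wh + bmat
    i <- sigm(z[, 1:H, drop = FALSE])
    f <- sigm(z[, H + 1:H, drop = FALSE])
    o <- sigm(z[, 2 * H + 1:H, drop = FALSE])
    g <- tanh(z[, 3 * H + 1:H, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    if (keep_cache)
      cache[[t]] <- list(xt = xt, hd = hd, i = i, f = f, o = o, g = g,
                         c_prev = c_prev, tc = tc)
    h <- o * tc
  }
  yhat <- as.numeric(h %*% params$Wy + params$by)
  list(yhat = yhat, h_last = h, cache = cache)
}

# Backward pass for mean-squared-error loss plus L2 penalty on the weight
# matrices (biases unpenalized).
lstm_backward <- function(params, X, y, fw, mask, l2) {
  B <- dim(X)[1]; Tt <- dim(X)[2]; H <- params$hidden
  err <- (fw$yhat - y) / B                       # d(MSE/2)/d yhat
  gWy <- crossprod(fw$h_last, err) + l2 * params$Wy
  gby <- sum(err)
  dh <- err %*% t(params$Wy)
  dc <- matrix(0, B, H)
  gWx <- params$Wx * 0; gWh <- params$Wh * 0; gb <- params$b * 0
  for (t in rev(seq_len(Tt))) {
    cs <- fw$cache[[t]]
    do <- dh * cs$tc
    dc <- dc + dh * cs$o * (1 - cs$tc^2)
    di <- dc * cs$g
    dg <- dc * cs$i
    df <- dc * cs$c_prev
    dZ <- cbind(di * cs$i * (1 - cs$i),
                df * cs$f * (1 - cs$f),
                do * cs$o * (1 - cs$o),
                dg * (1 - cs$g^2))
    gWx <- gWx + crossprod(cs$xt, dZ)
    gWh <- gWh + crossprod(cs$hd, dZ)
    gb <- gb + colSums(dZ)
    dhd <- dZ %*% t(params$Wh)
    dh <- if (is.null(mask)) dhd else dhd * mask
    dc <- dc * cs$f
  }
  list(Wx = gWx + l2 * params$Wx, Wh = gWh + l2 * params$Wh, b = gb,
       Wy = gWy, by = gby)
}

lstm_rmse <- function(params, X, y) {
  sqrt(mean((lstm_forward(params, X)$yhat - y)^2))
}

# Train with minibatch Adam and patience-based early stopping on the
# validation RMSE. With Xval = NULL, runs exactly `max_iterations` epochs
# (used for the final refit at a fold-calibrated epoch count).
lstm_train <- function(X, y, Xval = NULL, yval = NULL, hp, params = NULL) {
  B <- dim(X)[1]
  if (is.null(params)) params <- lstm_init(dim(X)[3], hp$hidden_units, hp$seed)
  trainable <- c("Wx", "Wh", "b", "Wy", "by")
  adam <- adam_init(params[trainable])
  p_drop <- hp$forgetting_rate
  best <- list(rmse = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_rmse = numeric(0))
  stop_reason <- "max_iterations"
  with_seed(derive_seed(hp$seed, "train"), {
    for (ep in seq_len(hp$max_iterations)) {
      idx <- sample.int(B)
      nb <- ceiling(B / hp$batch_size)
      tl <- 0
      for (bi in seq_len(nb)) {
        rows <- idx[((bi - 1) * hp$batch_size + 1):min(bi * hp$batch_size, B)]
        Xb <- X[rows, , , drop = FALSE]
        yb <- y[rows]
        mask <- if (p_drop > 0)
          matrix(rbinom(length(rows) * hp$hidden_units, 1, 1 - p_drop),
                 length(rows)) / (1 - p_drop)
        fw <- lstm_forward(params, Xb, mask, keep_cache = TRUE)
        tl <- tl + sum((fw$yhat - yb)^2)
        gr <- lstm_backward(params, Xb, yb, fw, mask, hp$l2)
        upd <- adam_step(params[trainable], gr, adam, hp$learning_rate)
        params[trainable] <- upd$params
        adam <- upd$state
      }
      vr <- if (!is.null(Xval)) lstm_rmse(params, Xval, yval) else NA_real_
      history[ep, ] <- list(ep, tl / (2 * B), vr)
      if (!is.null(Xval)) {
        if (vr < best$rmse - 1e-12) {
          best <- list(rmse = vr, params = params, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= hp$patience) { stop_reason <- "patience"; break }
        }
      } else best <- list(rmse = NA_real_, params = params, epoch = ep)
    }
  })
  list(params = best$params, best_epoch = best$epoch, best_rmse = best$rmse,
       history = history, stop_reason = stop_reason)
}
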