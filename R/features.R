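#' Sliding-window plan for feature extraction
#'
#' Windows are end-aligned: a window's feature row is time-stamped at its
#' last sample, where the staircase target is read.
#'
#' @param window_s window length in seconds.
#' @param stride_s hop between consecutive windows in seconds.
#' @return a `windowing_plan` list.
#' @export
windowing_plan <- function(window_s = 5, stride_s = 0.5) {
  if (stride_s <= 0 || stride_s > window_s)
    stop("require 0 < stride_s <= window_s", call. = FALSE)
  structure(list(window_s = window_s, stride_s = stride_s), class = "windowing_plan")
}

time_feature_names <- c("energy", "mean", "std", "peak", "range",
                        "kurtosis", "skewness", "zero_crossings", "entropy")

# Sign convention for zero-crossing counting: zeros inherit the previous
# sign; leading zeros count as positive.
signed <- function(x) {
  s <- sign(x)
  if (s[1] == 0) s[1] <- 1
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  s
}

# Shannon entropy (bits) of a 16-equal-width-bin histogram over the window's
# own min-max range; a zero-width range yields 0 by convention.
window_entropy <- function(x, bins = 16) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(0)
  edges <- seq(r[1], r[2], length.out = bins + 1)
  cnt <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins = bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

#' Nine time-domain features of one signal window
#'
#' Energy (sum of squares), mean, population standard deviation, peak
#' (maximum absolute value), range, kurtosis (fourth standardized moment),
#' skewness (third standardized moment), number of zero crossings (strict
#' adjacent sign changes, zeros inheriting the previous sign), and Shannon
#' entropy of a 16-bin histogram. For a constant window the standard
#' deviation is 0 and skewness, kurtosis and entropy are defined as 0.
#'
#' @param x numeric window, length >= 4.
#' @return named numeric vector of length 9.
#' @export
time_domain_features <- function(x) {
  if (length(x) < 4) stop("window must have at least 4 samples", call. = FALSE)
  m <- mean(x)
  v <- mean((x - m)^2)
  s <- sqrt(v)
  if (s > 0) {
    skew <- mean((x - m)^3) / s^3
    kurt <- mean((x - m)^4) / v^2
  } else skew <- kurt <- 0
  sg <- signed(x)
  c(energy = sum(x^2), mean = m, std = s, peak = max(abs(x)),
    range = max(x) - min(x), kurtosis = kurt, skewness = skew,
    zero_crossings = sum(sg[-1] != sg[-length(sg)]),
    entropy = window_entropy(x))
}

#' Pairwise Pearson spatial features of a multichannel window
#'
#' One Pearson correlation coefficient per unordered channel pair, in fixed
#' lexicographic order (1-2, 1-3, ..., (C-1)-C). A zero-variance channel
#' yields 0 for all its pairs, with a warning.
#'
#' @param mat samples x channels matrix (>= 3 samples, >= 2 channels).
#' @return named numeric vector of length C*(C-1)/2.
#' @export
spatial_features <- function(mat) {
  if (ncol(mat) < 2 || nrow(mat) < 3)
    stop("need >= 2 channels and >= 3 samples", call. = FALSE)
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    warning("zero-variance channel in window; its correlations set to 0")
    cm <- matrix(0, ncol(mat), ncol(mat))
    ok <- sds > 0
    if (sum(ok) >= 2) cm[ok, ok] <- cor(mat[, ok, drop = FALSE])
  } else cm <- cor(mat)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- cm[idx]
  names(out) <- paste0("ch", idx[, 1], "_ch", idx[, 2])
  out
}

#' Expected feature-count for the structured battery
#'
#' `n_bands * n_species * (9 C + C(C-1)/2)` columns for C channels: nine
#' time-domain statistics per channel plus one Pearson coefficient per
#' channel pair, repeated for every band/species combination.
#'
#' @param n_channels number of channels.
#' @param n_bands,n_species battery dimensions.
#' @return integer column count (1035 for the default 6-channel montage).
#' @export
feature_count <- function(n_channels, n_bands = 5, n_species = 3) {
  as.integer(n_bands * n_species * (9 * n_channels + n_channels * (n_channels - 1) / 2))
}

# Vectorized time-domain battery over a windows matrix (samples x windows).
windows_time_features <- function(M) {
  w <- nrow(M)
  m1 <- colMeans(M)
  Mc <- M - rep(m1, each = w)
  v <- colMeans(Mc^2)
  s <- sqrt(v)
  skew <- ifelse(s > 0, colMeans(Mc^3) / s^3, 0)
  kurt <- ifelse(v > 0, colMeans(Mc^4) / v^2, 0)
  zc <- apply(M, 2, function(x) { sg <- signed(x); sum(sg[-1] != sg[-w]) })
  ent <- apply(M, 2, window_entropy)
  cbind(energy = colSums(M^2), mean = m1, std = s,
        peak = apply(abs(M), 2, max),
        range = apply(M, 2, max) - apply(M, 2, min),
        kurtosis = kurt, skewness = skew, zero_crossings = zc, entropy = ent)
}

#' Build the full windowed feature matrix from a band decomposition
#'
#' For every window position, concatenates the nine time-domain features per
#' channel and the pairwise Pearson features, across all band x species
#' combinations, in a fixed order (band, then species, then per-channel
#' features, then pairs). For 5 bands, 3 species and 6 channels this yields
#' exactly 1,035 columns. Rows are time-stamped at the window end.
#'
#' @param decomp nested list `decomp[[band]][[species]]` from
#'   [decompose_trial()].
#' @param plan a [windowing_plan()].
#' @return a `feature_matrix`: list with `values` (windows x features),
#'   `index` (data.frame: band, species, channel, feature), `target_times`.
#' @export
build_feature_matrix <- function(decomp, plan = windowing_plan()) {
  first <- decomp[[1]][[1]]
  fs <- first$sampling_rate
  n <- ncol(first$data)
  w <- round(plan$window_s * fs)
  st <- max(1L, round(plan$stride_s * fs))
  if (n < w) stop("trial shorter than one window", call. = FALSE)
  ends <- seq(w, n, by = st)
  nw <- length(ends)
  row_idx <- outer(seq_len(w) - w, ends, "+")   # w x nw sample indices
  blocks <- list()
  index <- list()
  for (band in names(decomp)) {
    for (species in names(decomp[[band]])) {
      rec <- decomp[[band]][[species]]
      C <- nrow(rec$data)
      for (ch in seq_len(C)) {
        M <- matrix(rec$data[ch, row_idx], nrow = w)
        tf <- windows_time_features(M)
        blocks[[length(blocks) + 1]] <- tf
        index[[length(index) + 1]] <- data.frame(
          band = band, species = species, channel = rec$channel_ids[ch],
          feature = time_feature_names, stringsAsFactors = FALSE)
      }
      # spatial block: correlations per window across channels
      pair_idx <- which(upper.tri(diag(C)), arr.ind = TRUE)
      pair_idx <- pair_idx[order(pair_idx[, 1], pair_idx[, 2]), , drop = FALSE]
      sp <- matrix(0, nw, nrow(pair_idx))
      for (k in seq_len(nw)) {
        Wm <- t(rec$data[, row_idx[, k], drop = FALSE])
        sds <- apply(Wm, 2, sd)
        if (any(sds == 0)) {
          cm <- matrix(0, C, C); ok <- sds > 0
          if (sum(ok) >= 2) cm[ok, ok] <- cor(Wm[, ok, drop = FALSE])
        } else cm <- cor(Wm)
        sp[k, ] <- cm[pair_idx]
      }
      blocks[[length(blocks) + 1]] <- sp
      index[[length(index) + 1]] <- data.frame(
        band = band, species = species,
        channel = paste0(rec$channel_ids[pair_idx[, 1]], "-",
                         rec$channel_ids[pair_idx[, 2]]),
        feature = "pearson", stringsAsFactors = FALSE)
    }
  }
  values <- do.call(cbind, blocks)
  index <- do.call(rbind, index)
  colnames(values) <- paste(abbreviate_band(index$band), index$species,
                            index$channel, index$feature, sep = ".")
  structure(list(values = values, index = index,
                 target_times = (ends - 1) / fs),
            class = "feature_matrix")
}

abbreviate_band <- function(b) {
  map <- c(heart = "b1", respiration = "b2", myogenic = "b3",
           neurological = "b4", endothelial = "b5")
  ifelse(b %in% names(map), map[b], b)
}

#' Read the staircase target at each feature-window end time
#'
#' Looks up the per-cycle staircase value of the processed gait trace at the
#' inertial sample nearest each window-end time. Windows whose target time
#' falls inside a flagged partial edge cycle return NA (excluded from
#' training by default).
#'
#' @param gait a trace from [preprocess_gait()].
#' @param target_times window-end times in seconds.
#' @param target `"speed"` (angular-velocity staircase) or `"step"` (angle).
#' @return numeric vector, NA for partial-cycle windows.
#' @export
window_targets <- function(gait, target_times, target = c("speed", "step")) {
  target <- match.arg(target)
  series <- if (target == "speed") gait$staircase_speed else gait$staircase_step
  i <- pmax(1L, pmin(length(series), round(target_times * gait$sampling_rate) + 1L))
  out <- series[i]
  out[gait$partial_mask[i]] <- NA
  out
}
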