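#' Pairwise lagged voltage cross-correlations
#'
#' Pearson correlation between every pair of subthreshold voltage traces
#' at each lag in `[-max_lag, max_lag]`.  In a sampler network the
#' voltage noise is the readout noise lifted through `D^T`, so neurons
#' with aligned decoding columns show positive lag-0 correlations and
#' anti-aligned (opposite-tuned) pairs negative ones.
#'
#' @param V voltage matrix, time x N (at least 100 samples).
#' @param max_lag maximum lag, s.
#' @param dt sample spacing, s.
#' @return long data frame `(i, j, lag, cor)`; pairs with a constant
#'   trace get `NA` correlations (flagged, not dropped).
#' @export
voltage_xcorr <- function(V, max_lag = 0, dt = 1) {
  V <- as.matrix(V)
  n <- nrow(V)
  N <- ncol(V)
  if (N < 2) stop("need at least 2 neurons")
  if (n < 100) stop("need at least 100 samples")
  L <- as.integer(round(max_lag / dt))
  sds <- apply(V, 2, stats::sd)
  out <- vector("list", N * (N - 1) / 2 + N)
  k <- 0
  for (i in seq_len(N)) for (j in i:N) {
    cors <- vapply(-L:L, function(l) {
      if (sds[i] == 0 || sds[j] == 0) return(NA_real_)
      if (l >= 0) stats::cor(V[1:(n - l), i], V[(1 + l):n, j])
      else stats::cor(V[(1 - l):n, i], V[1:(n + l), j])
    }, numeric(1))
    k <- k + 1
    out[[k]] <- data.frame(i = i, j = j, lag = (-L:L) * dt, cor = cors)
  }
  do.call(rbind, out[seq_len(k)])
}

# dense time x N spike matrix from an scn_sim or matrix input
spike_matrix <- function(spikes, N = NULL) {
  if (inherits(spikes, "scn_sim")) {
    idx <- spikes$spikes
    N <- spikes$network$N
    m <- matrix(0, length(idx), N)
    nz <- which(idx > 0)
    m[cbind(nz, idx[nz])] <- 1
    return(m)
  }
  as.matrix(spikes)
}

#' Spike-train correlations at two timescales
#'
#' Convolves each spike train with a Gaussian kernel of each width and
#' computes pairwise Pearson correlations.  At a millisecond kernel the
#' correlations reflect the fast (balancing) connectivity; at a
#' 100-millisecond kernel they reflect the slow (computational)
#' connectivity.
#'
#' @param spikes `scn_sim` or dense time-by-N 0/1 matrix.
#' @param dt time step of the trains, s.
#' @param widths Gaussian kernel standard deviations, s.
#' @return named list of `N x N` correlation matrices, one per width;
#'   empty trains yield `NA` rows/columns (flagged via attribute
#'   `empty_trains`).
#' @export
spike_corr_two_scales <- function(spikes, dt, widths = c(0.001, 0.1)) {
  S <- spike_matrix(spikes)
  N <- ncol(S)
  empty <- colSums(S) == 0
  out <- lapply(widths, function(w) {
    sd_steps <- max(w / dt, 0.5)
    half <- max(1L, as.integer(ceiling(4 * sd_steps)))
    half <- min(half, (nrow(S) - 1L) %/% 2L) # kernel must fit the series
    kern <- stats::dnorm(-half:half, sd = sd_steps)
    kern <- kern / sum(kern)
    Sm <- apply(S, 2, function(x)
      stats::filter(x, kern, method = "convolution", sides = 2))
    Sm <- Sm[stats::complete.cases(Sm), , drop = FALSE]
    C <- suppressWarnings(stats::cor(Sm))
    C[empty, ] <- NA_real_
    C[, empty] <- NA_real_
    dimnames(C) <- NULL
    C
  })
  names(out) <- paste0("w", widths)
  attr(out, "empty_trains") <- unname(which(empty))
  out
}

#' Tuning curves over heading
#'
#' Mean filtered spike train of each neuron in each heading bin.
#'
#' @param R filtered-train matrix, time x N.
#' @param theta decoded (or true) heading series, rad, same length.
#' @param n_bins number of angle bins over `[-pi, pi)`.
#' @return `n_bins x N` matrix of mean rates; attributes `angles` (bin
#'   centers) and `empty_bins` (bins never visited; their rows are `NA`,
#'   not interpolated).
#' @export
tuning_curves <- function(R, theta, n_bins = 36) {
  R <- as.matrix(R)
  if (nrow(R) != length(theta)) stop("R and theta must have matching length")
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- findInterval(wrap_angle(theta), breaks, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  curves <- matrix(NA_real_, n_bins, ncol(R))
  counts <- tabulate(bin, n_bins)
  for (b in which(counts > 0))
    curves[b, ] <- colMeans(R[bin == b, , drop = FALSE])
  attr(curves, "angles") <- (breaks[-1] + breaks[-length(breaks)]) / 2
  attr(curves, "empty_bins") <- which(counts == 0)
  attr(curves, "occupancy") <- counts
  curves
}

#' Population-bump localization index
#'
#' Mean resultant length of the population-activity profile: 1 when all
#' activity sits in one neuron, near 0 for a flat profile.
#'
#' @param R filtered-train matrix, time x N.
#' @param angles preferred angle of each neuron (defaults to an even
#'   ring).
#' @return scalar in `[0, 1]`.
#' @export
bump_localization <- function(R, angles = NULL) {
  R <- as.matrix(R)
  N <- ncol(R)
  angles <- angles %||% (2 * pi * (seq_len(N) - 1) / N)
  tot <- rowSums(R)
  keep <- tot > 0
  if (!any(keep)) return(NA_real_)
  res <- sqrt((R[keep, , drop = FALSE] %*% cos(angles))^2 +
              (R[keep, , drop = FALSE] %*% sin(angles))^2)
  mean(res / tot[keep])
}

#' Across-neuron tuning-curve heterogeneity
#'
#' Shape dispersion of the tuning curves: for every pair of neurons the
#' maximum circular cross-correlation over all bin shifts is computed,
#' and the dispersion is the mean of `1 - max_corr` over pairs.  Zero
#' for identical curves up to rotation (the homogeneous ring-attractor
#' ideal), approaching 1 when curve shapes are unrelated.
#'
#' @param curves matrix from [tuning_curves()].
#' @return scalar dispersion in `[0, 2]`.
#' @export
tuning_dispersion <- function(curves) {
  cc <- curves[stats::complete.cases(curves), , drop = FALSE]
  nb <- nrow(cc)
  N <- ncol(cc)
  max_circ_cor <- function(a, b) {
    max(vapply(seq_len(nb) - 1L, function(s) {
      bs <- b[((seq_len(nb) - 1L + s) %% nb) + 1L]
      if (stats::sd(a) == 0 || stats::sd(bs) == 0) return(1)
      stats::cor(a, bs)
    }, numeric(1)))
  }
  d <- 0
  np <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    d <- d + (1 - max_circ_cor(cc[, i], cc[, j]))
    np <- np + 1
  }
  d / np
}

#' Bump-velocity statistics
#'
#' Wrapped finite-difference velocities of a decoded-angle series,
#' grouped by angular-velocity condition; reports mean, variance and
#' skewness per condition plus the (true omega, bump velocity) scatter
#' table.
#'
#' @param theta_hat decoded heading series, rad.
#' @param omega true angular-velocity series (same length).
#' @param dt step, s.
#' @param window difference lag in steps (velocities are computed over
#'   `window * dt`).
#' @return list with `stats` (data frame: condition, n, mean, var,
#'   skewness) and `scatter` (data frame: omega, velocity).
#' @export
bump_velocity_stats <- function(theta_hat, omega, dt, window = 1L) {
  v <- wrap_diff(theta_hat, window) / (window * dt)
  om <- omega[(window + 1L):length(omega)]
  cond <- factor(om)
  stats_df <- do.call(rbind, lapply(levels(cond), function(lv) {
    x <- v[cond == lv]
    data.frame(condition = as.numeric(lv), n = length(x), mean = mean(x),
               var = stats::var(x), skewness = sample_skewness(x))
  }))
  list(stats = stats_df, scatter = data.frame(omega = om, velocity = v))
}

#' Drift curve over repetitions
#'
#' Mean and standard-deviation band of the absolute wrapped angle error
#' over time, across repeated runs.
#'
#' @param err matrix of shortest-arc errors, repetitions x time (all
#'   runs must share the time base; ragged input is rejected by the
#'   matrix shape).
#' @param dt step, s.
#' @return data frame `(t, mean, sd)`.
#' @export
drift_curve <- function(err, dt = 1) {
  if (is.list(err)) {
    if (length(unique(lengths(err))) != 1)
      stop("ragged runs: all repetitions must share the time base")
    err <- do.call(rbind, err)
  }
  err <- as.matrix(err)
  if (nrow(err) < 2) stop("need at least 2 repetitions")
  data.frame(t = seq_len(ncol(err)) * dt,
             mean = colMeans(err),
             sd = apply(err, 2, stats::sd))
}
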