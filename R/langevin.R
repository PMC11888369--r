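#' Direct Langevin reference sampler
#'
#' Euler-Maruyama integration of the overdamped Langevin equation
#' `dz = -(1/tau_s) grad U(z) dt + sqrt(2/tau_s) dW`, whose stationary
#' distribution is `P(z) = exp(-U(z)) / Z`.  This non-spiking integrator
#' is the reference against which the spiking sampler networks are
#' validated.
#'
#' @param U an [energy_poly()]; must pass [check_normalizable()].
#' @param tau_s sampling timescale, s.
#' @param dt integration step, s (`dt << tau_s`).
#' @param duration simulated time, s.
#' @param seed integer seed (`NULL` leaves RNG state untouched).
#' @param z0 starting point (length M, default 0).
#' @param noise_amp noise multiplier (0 turns the sampler into plain
#'   gradient descent on `U`).
#' @param bound divergence guard on `|z|`; default 10x the outermost
#'   stationary point of `U`.  Exceeding it aborts with an error.
#' @return matrix of samples (`n_steps x M`) with attributes `dt`,
#'   `tau_s`, `seed`.
#' @export
sample_langevin <- function(U, tau_s = 0.01, dt = 1e-4, duration = 10,
                            seed = NULL, z0 = NULL, noise_amp = 1,
                            bound = NULL) {
  if (noise_amp > 0 && !check_normalizable(U))
    stop("exp(-U) is not normalizable; refusing to sample")
  drift <- grad_energy(U)
  z0 <- z0 %||% numeric(U$M)
  bound <- bound %||% divergence_bound(U)
  n_steps <- as.integer(round(duration / dt))
  if (!is.null(seed)) set.seed(seed)
  path <- tryCatch(
    .langevin_path_cpp(drift$coeffs, z0, n_steps, dt, tau_s, noise_amp, bound),
    error = function(e) stop("Langevin sampler (seed ", seed %||% "unset",
                             "): ", conditionMessage(e), call. = FALSE))
  attr(path, "dt") <- dt
  attr(path, "tau_s") <- tau_s
  attr(path, "seed") <- seed
  path
}

# default divergence guard: 10x the outermost stationary point of U
divergence_bound <- function(U) {
  if (U$M == 1) {
    g <- grad_energy(U)
    co <- numeric(g$degree + 1L)
    for (d in seq_along(g$coeffs) - 1L) co[d + 1L] <- g$coeffs[[d + 1L]][1, 1]
    while (length(co) > 1 && co[length(co)] == 0) co <- co[-length(co)]
    if (length(co) <= 1) return(50)
    rts <- polyroot(co)
    real <- Mod(Im(rts)) < 1e-8
    r <- if (any(real)) max(abs(Re(rts[real]))) else 0
    return(10 * max(1, r))
  }
  # radial probe on a coarse direction/radius grid
  ang <- 2 * pi * (0:15) / 16
  dirs <- if (U$M == 2) cbind(cos(ang), sin(ang))
          else diag(U$M)
  radii <- seq(0.05, 10, by = 0.05)
  r_out <- max(vapply(seq_len(nrow(dirs)), function(i) {
    u <- eval_energy(U, outer(radii, dirs[i, ]))
    radii[which.min(u)]
  }, numeric(1)))
  10 * max(1, r_out)
}

#' Spiking Langevin sampler network
#'
#' Configures a spike-coding network whose readout performs Langevin
#' sampling from `P(z) = exp(-U(z))`: the slow drift is
#' `D^T(-(1/tau_s) grad U(zhat) + lambda zhat)` and the voltage noise is
#' the readout noise `sqrt(2/tau_s) xi` lifted through `D^T` (so it is
#' rank-M and correlated across neurons).
#'
#' @param U an [energy_poly()]; must be normalizable.
#' @param D decoding matrix, readout dimension equal to the dimension
#'   of `U`.
#' @param params [scn_params()].
#' @param noise logical; `FALSE` disables the stochastic term (useful for
#'   fixed-point checks).
#' @return an `scn_network` for [simulate_network()].
#' @export
build_sampler_network <- function(U, D, params, noise = TRUE) {
  D <- validate_readout(D)
  if (!check_normalizable(U))
    stop("exp(-U) is not normalizable; refusing to build a sampler")
  if (nrow(D) != U$M)
    stop("readout dimension of D must equal the dimension of U")
  g <- grad_energy(U)
  coeffs <- lapply(g$coeffs, function(A) -A / params$tau_s)
  if (length(coeffs) < 2)
    coeffs <- c(coeffs, list(matrix(0, U$M, U$M)))
  coeffs[[2]] <- coeffs[[2]] + params$lambda * diag(U$M)
  new_network(D, params, "poly", list(coeffs = coeffs),
              noise_amp = if (noise) sqrt(2 / params$tau_s) else 0,
              divergence_bound = divergence_bound(U))
}

#' Normalized target density by quadrature
#'
#' Evaluates `exp(-U)/Z` on a regular grid with `Z` from trapezoidal
#' quadrature; supports one- and two-dimensional energies.
#'
#' @param U an [energy_poly()] with `M <= 2`.
#' @param lower,upper grid bounds (length M).
#' @param n grid points per dimension.
#' @return data frame with grid coordinates and a `density` column;
#'   attribute `Z` holds the normalizer.
#' @export
density_quadrature <- function(U, lower = -4, upper = 4, n = 1001) {
  if (U$M > 2)
    stop("grid quadrature supports M <= 2 (use importance sampling beyond)")
  if (!check_normalizable(U)) stop("exp(-U) is not normalizable")
  if (length(lower) == 1) lower <- rep(lower, U$M)
  if (length(upper) == 1) upper <- rep(upper, U$M)
  grids <- lapply(seq_len(U$M), function(m) seq(lower[m], upper[m],
                                                length.out = n))
  pts <- as.matrix(expand.grid(grids))
  un <- exp(-eval_energy(U, pts))
  w <- Reduce(kronecker,
              rev(lapply(seq_len(U$M), function(m)
                trapz_weights(n, grids[[m]][2] - grids[[m]][1]))))
  Z <- sum(w * un)
  out <- as.data.frame(pts)
  names(out) <- if (U$M == 1) "z" else c("x", "y")
  out$density <- un / Z
  attr(out, "Z") <- Z
  attr(out, "weights") <- w
  out
}

#' Sampling diagnostics against a tabulated density
#'
#' Kolmogorov-Smirnov distance (1-D), the first four moments of samples
#' and density, and a mode count from the tabulated density.
#'
#' @param samples numeric vector (1-D) or matrix of samples.
#' @param dens density table from [density_quadrature()].
#' @return list with `ks` (1-D only), `moments` (matrix: sample vs target
#'   mean, variance, skewness, kurtosis), `n_modes`, `n`.
#' @export
compare_samples <- function(samples, dens) {
  if (is.matrix(samples) && ncol(samples) > 1)
    stop("diagnostics support 1-D samples")
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty sample set")
  zg <- dens$z
  h <- zg[2] - zg[1]
  cdf <- cumsum(dens$density) * h
  cdf <- cdf / cdf[length(cdf)]
  ecdf_at <- stats::approx(zg, cdf, xout = sort(samples), rule = 2)$y
  n <- length(samples)
  ks <- max(abs(ecdf_at - (seq_len(n) - 0.5) / n)) + 0.5 / n

  mom <- function(x, w = NULL) {
    if (is.null(w)) w <- rep(1 / length(x), length(x))
    m <- sum(w * x)
    v <- sum(w * (x - m)^2)
    c(mean = m, var = v,
      skewness = sum(w * (x - m)^3) / v^1.5,
      kurtosis = sum(w * (x - m)^4) / v^2)
  }
  wq <- dens$density * h
  wq <- wq / sum(wq)
  moments <- rbind(sample = mom(samples), target = mom(zg, wq))

  d <- dens$density
  local_max <- which(diff(sign(diff(d))) == -2) + 1L
  n_modes <- sum(d[local_max] > 0.05 * max(d))

  list(ks = ks, moments = moments, n_modes = n_modes, n = n)
}

#' Thin an autocorrelated sample path
#'
#' Keeps every `interval/dt`-th sample; by convention the sampling
#' timescale `tau_s` is used as the thinning interval for distributional
#' tests on Langevin paths.
#'
#' @param path matrix or vector of samples with time step `dt`.
#' @param dt time step of the path, s.
#' @param interval thinning interval, s.
#' @param burn_in initial time to discard, s.
#' @return thinned samples (same column structure as the input).
#' @export
thin_samples <- function(path, dt, interval, burn_in = 0) {
  x <- if (is.matrix(path)) path else matrix(path, ncol = 1)
  k <- max(1L, as.integer(round(interval / dt)))
  i0 <- as.integer(round(burn_in / dt)) + 1L
  idx <- seq(i0, nrow(x), by = k)
  out <- x[idx, , drop = FALSE]
  if (!is.matrix(path)) out <- drop(out)
  out
}
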