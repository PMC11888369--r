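#' Simulation parameters for a spike-coding network
#'
#' Bundles the time constants and spike costs of a spike-coding network
#' (SCN).  The leak `lambda` sets both the voltage and the filtered
#' spike-train decay; `tau_s` is the timescale of the Langevin sampling
#' dynamics implemented by the slow connectivity; `nu` and `mu` are the
#' linear and quadratic spike costs entering the thresholds.
#'
#' @param lambda voltage/readout leak, 1/s.  Must be positive.
#' @param dt integration step, s.
#' @param tau_s sampling timescale, s.
#' @param nu linear spike cost.
#' @param mu quadratic spike cost.
#' @param filter_variant `"main"` for `r' = -lambda r + o` with readout
#'   `zhat = D r`, or `"methods"` for `r' = -lambda r + lambda o` with
#'   readout `zhat = D r / lambda`.  The two differ only by a fixed
#'   rescaling of `r`.
#' @return an object of class `scn_params`.
#' @export
scn_params <- function(lambda = 10, dt = 1e-4, tau_s = 0.01, nu = 0, mu = 0,
                       filter_variant = c("main", "methods")) {
  filter_variant <- match.arg(filter_variant)
  if (lambda <= 0) stop("lambda must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (tau_s <= 0) stop("tau_s must be positive")
  if (abs(lambda * dt) >= 1) stop("dt too coarse: require |lambda * dt| < 1")
  structure(list(lambda = lambda, dt = dt, tau_s = tau_s, nu = nu, mu = mu,
                 filter_variant = filter_variant),
            class = "scn_params")
}

validate_readout <- function(D) {
  D <- as.matrix(D)
  if (!is.numeric(D) || nrow(D) < 1 || ncol(D) < 1)
    stop("decoding matrix must be a non-empty numeric matrix (M x N)")
  norms <- sqrt(colSums(D^2))
  if (any(norms == 0))
    stop("decoding matrix has an all-zero column: every neuron must decode to something")
  D
}

#' Ring decoding matrix
#'
#' Columns at evenly spaced angles `2 pi i / N` with a common norm, the
#' standard construction for a ring-attractor readout in two dimensions.
#' The default norm `rho / N` makes the per-spike readout jump (and hence
#' the decoded-angle quantization) shrink as `1/N`; at `N = 8` a
#' self-sustained bump then tracks constant angular velocity to within a
#' few percent when the network step is ten times finer than the
#' encoder step.
#'
#' @param N number of neurons.
#' @param rho ring-radius scale of the represented variable.
#' @param norm common column norm; defaults to `rho / N`.
#' @return a `2 x N` decoding matrix.
#' @export
ring_decoder <- function(N, rho = 1, norm = NULL) {
  if (N < 2) stop("a ring decoder needs at least 2 neurons")
  norm <- norm %||% (rho / N)
  ang <- 2 * pi * (seq_len(N) - 1) / N
  rbind(norm * cos(ang), norm * sin(ang))
}

#' One-dimensional decoding matrix with both signs
#'
#' Half the columns decode `+norm`, half `-norm`, so the readout can move
#' in both directions along a 1-D variable.
#'
#' @param N number of neurons (even).
#' @param norm column magnitude.
#' @return a `1 x N` decoding matrix.
#' @export
line_decoder <- function(N, norm = 0.1) {
  if (N < 2 || N %% 2 != 0) stop("line_decoder needs an even N >= 2")
  matrix(rep(c(norm, -norm), N / 2), nrow = 1)
}

#' Fast recurrent connectivity
#'
#' The fast (spike-timescale) weights of an SCN are `-D^T D`: symmetric,
#' with self-inhibition `-|D_i|^2` on the diagonal carrying the effective
#' post-spike reset.
#'
#' @param D decoding matrix (M x N).
#' @return the `N x N` fast weight matrix.
#' @export
build_fast_weights <- function(D) {
  D <- validate_readout(D)
  -crossprod(D)
}

#' Spiking thresholds
#'
#' `T_i = (nu * lambda + mu * lambda^2 + |D_i|^2) / 2`; with zero spike
#' costs this is half the squared column norm of the decoder.
#'
#' @param D decoding matrix.
#' @param lambda leak (needed when `nu` or `mu` are non-zero).
#' @param nu,mu linear and quadratic spike costs.
#' @return vector of `N` strictly positive thresholds.
#' @export
thresholds <- function(D, lambda = 1, nu = 0, mu = 0) {
  D <- validate_readout(D)
  0.5 * (nu * lambda + mu * lambda^2 + colSums(D^2))
}

#' Greedy threshold spike rule
#'
#' Returns the index of the neuron with the largest positive threshold
#' violation `v_i - T_i` (ties broken by lowest index), or `integer(0)`
#' when no voltage exceeds its threshold.  At most one neuron spikes per
#' time step; the greedy choice is the spike whose emission most decreases
#' the instantaneous readout reconstruction error.
#'
#' @param v voltage vector.
#' @param thr threshold vector.
#' @return integer index of the spiking neuron, or `integer(0)`.
#' @export
spike_rule <- function(v, thr) {
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v))[1]
    stop(sprintf("simulation instability: non-finite voltage for neuron %d", bad))
  }
  viol <- v - thr
  if (all(viol <= 0)) return(integer(0))
  which.max(viol)
}

#' Network state constructor
#'
#' @param N number of neurons.
#' @param v,r optional initial voltages and filtered spike trains.
#' @param t starting time, s.
#' @return list with fields `v`, `r`, `o` (spike indicators), `t`.
#' @export
scn_state <- function(N, v = numeric(N), r = numeric(N), t = 0) {
  list(v = v, r = r, o = integer(N), t = t)
}

#' Single Euler-Maruyama step of an SCN (reference implementation)
#'
#' Pure-R stepper with the same semantics as the compiled engine: the
#' greedy spike is drawn from the *current* voltages, the fast weights
#' deliver the spike, and the filtered trains integrate it.  Used for
#' short runs and as the semantic reference in tests; long simulations go
#' through [simulate_network()].
#'
#' @param state state list from [scn_state()].
#' @param drift_v drift in neuron space (length N), i.e. `D^T F(zhat)`.
#' @param omega_f fast weights from [build_fast_weights()].
#' @param thr thresholds.
#' @param params [scn_params()].
#' @param noise_v optional pre-scaled voltage noise increment (length N),
#'   already multiplied by `sqrt(dt)`.
#' @return updated state.
#' @export
scn_step <- function(state, drift_v, omega_f, thr, params, noise_v = NULL) {
  N <- length(state$v)
  if (length(drift_v) != N) stop("drift_v length must equal the number of neurons")
  dt <- params$dt
  lam <- params$lambda
  inc <- if (params$filter_variant == "methods") lam else 1
  rs <- if (params$filter_variant == "methods") 1 / lam else 1

  sp <- spike_rule(state$v, thr)
  o <- integer(N)
  v <- state$v + dt * (-lam * state$v + drift_v + params$mu * lam^2 * state$r)
  if (length(sp)) {
    o[sp] <- 1L
    v <- v + omega_f[, sp] * inc * rs
    v[sp] <- v[sp] - params$mu * lam * inc
  }
  if (!is.null(noise_v)) v <- v + noise_v
  r <- state$r - dt * lam * state$r
  if (length(sp)) r[sp] <- r[sp] + inc
  list(v = v, r = r, o = o, t = state$t + dt)
}

#' Linear readout of the filtered spike trains
#'
#' @param r filtered spike-train vector (or a time-by-N matrix).
#' @param D decoding matrix.
#' @param params optional [scn_params()]; under the `"methods"` filter
#'   variant the readout is `D r / lambda`.
#' @return readout vector (length M) or matrix (time x M).
#' @export
readout <- function(r, D, params = NULL) {
  D <- validate_readout(D)
  scale <- if (!is.null(params) && params$filter_variant == "methods")
    1 / params$lambda else 1
  if (is.matrix(r)) scale * r %*% t(D) else scale * drop(D %*% r)
}

# internal network-specification constructor
new_network <- function(D, params, drift_type, drift_pars, noise_amp,
                        n_steps = NULL, divergence_bound = 0) {
  D <- validate_readout(D)
  structure(list(
    D = D, M = nrow(D), N = ncol(D), params = params,
    thresholds = thresholds(D, params$lambda, params$nu, params$mu),
    drift_type = drift_type, drift_pars = drift_pars,
    noise_amp = noise_amp, n_steps = n_steps,
    divergence_bound = divergence_bound
  ), class = "scn_network")
}

#' @export
print.scn_network <- function(x, ...) {
  cat(sprintf("<scn_network> %d neurons, readout dim %d, drift '%s'\n",
              x$N, x$M, x$drift_type))
  cat(sprintf("  lambda = %g /s, dt = %g s, tau_s = %g s, noise amp = %g\n",
              x$params$lambda, x$params$dt, x$params$tau_s, x$noise_amp))
  invisible(x)
}

#' Network for tracking a polynomial dynamical system
#'
#' Configures an SCN whose readout follows `z' = F(z)` for a polynomial
#' drift `F`, the deterministic (noise-free) embedding of a dynamical
#' system in a spiking network.
#'
#' @param drift a `poly_drift` object (see [grad_energy()] /
#'   [poly_drift()]) giving `F` as per-degree coefficient matrices.
#' @param D decoding matrix with readout dimension matching the drift.
#' @param params [scn_params()].
#' @return an `scn_network` specification for [simulate_network()].
#' @export
build_dynamics_network <- function(drift, D, params) {
  D <- validate_readout(D)
  if (drift$M != nrow(D))
    stop("drift dimension must equal the readout dimension of D")
  coeffs <- drift$coeffs
  # fold the leak compensation +lambda*z into the linear term
  if (length(coeffs) < 2)
    coeffs <- c(coeffs, list(matrix(0, drift$M, drift$M)))
  coeffs[[2]] <- coeffs[[2]] + params$lambda * diag(drift$M)
  new_network(D, params, "poly", list(coeffs = coeffs), noise_amp = 0)
}

#' Run a configured spike-coding network
#'
#' Integrates an `scn_network` specification with the compiled
#' Euler-Maruyama engine (or the pure-R reference stepper for short
#' runs).  All randomness (voltage noise, any landmark resampling) is
#' governed by `seed`.
#'
#' @param net an `scn_network` from [build_sampler_network()],
#'   [build_inference_network()], [build_hd_network()] or
#'   [build_dynamics_network()].
#' @param duration simulated time, s.  For networks driven by a spike
#'   record the duration is implied by the record and may be omitted.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param v0,r0 optional initial conditions (default zero).
#' @param record_v,record_r record voltages / filtered trains (strided by
#'   `record_every`).
#' @param record_every recording stride in steps.
#' @param engine `"cpp"` (default) or `"r"` (reference stepper; slow).
#' @param noise_path optional pre-drawn standard-normal increments
#'   (`n_steps x M`) for noise-matched comparisons.
#' @return an `scn_sim` object: list with `t`, `readout` (time x M),
#'   `spikes` (0 = none, else neuron index), optional `v`, `r`, and the
#'   originating network.
#' @export
simulate_network <- function(net, duration = NULL, seed = NULL,
                             v0 = NULL, r0 = NULL,
                             record_v = FALSE, record_r = FALSE,
                             record_every = 1L, engine = c("cpp", "r"),
                             noise_path = NULL) {
  stopifnot(inherits(net, "scn_network"))
  engine <- match.arg(engine)
  p <- net$params
  n_steps <- if (!is.null(net$n_steps)) net$n_steps
             else {
               if (is.null(duration)) stop("duration required for this network")
               as.integer(round(duration / p$dt))
             }
  if (!is.null(duration) && !is.null(net$n_steps)) {
    want <- as.integer(round(duration / p$dt))
    if (want > net$n_steps)
      stop("requested duration exceeds the attached observation stream")
    n_steps <- want
  }
  v0 <- v0 %||% numeric(net$N)
  r0 <- r0 %||% numeric(net$N)
  if (!is.null(seed)) set.seed(seed)
  inc <- if (p$filter_variant == "methods") p$lambda else 1
  rs <- if (p$filter_variant == "methods") 1 / p$lambda else 1

  if (engine == "cpp") {
    res <- .scn_simulate_cpp(net$D, n_steps, p$dt, p$lambda, net$thresholds,
                             p$mu, net$drift_type, net$drift_pars,
                             net$noise_amp, noise_path, v0, r0, inc, rs,
                             as.integer(record_every), record_v, record_r,
                             net$divergence_bound)
  } else {
    res <- simulate_network_r(net, n_steps, v0, r0, record_v, record_r,
                              record_every, noise_path)
  }
  out <- list(
    t = seq_len(n_steps) * p$dt,
    readout = res$readout,
    spikes = as.integer(res$spikes),
    n_spikes = res$n_spikes,
    v = res$v %||% NULL, r = res$r %||% NULL,
    record_every = as.integer(record_every),
    v_final = res$v_final, r_final = res$r_final,
    reset_counts = res$reset_counts %||% NULL,
    network = net, seed = seed
  )
  class(out) <- "scn_sim"
  out
}

#' @export
print.scn_sim <- function(x, ...) {
  cat(sprintf("<scn_sim> %d steps, %d neurons, %d spikes\n",
              length(x$t), x$network$N, sum(x$spikes > 0)))
  invisible(x)
}

# pure-R engine mirroring the compiled loop; short runs only
simulate_network_r <- function(net, n_steps, v0, r0, record_v, record_r,
                               record_every, noise_path) {
  p <- net$params
  D <- net$D
  M <- net$M
  N <- net$N
  omega_f <- build_fast_weights(D)
  thr <- net$thresholds
  rs <- if (p$filter_variant == "methods") 1 / p$lambda else 1
  dp <- net$drift_pars
  stride <- dp$stride %||% 1L

  drift_z_fun <- switch(net$drift_type,
    poly = function(z, sigma, sigma_reset) {
      g <- numeric(M)
      for (d in seq_along(dp$coeffs)) {
        zd <- if (d == 1) 1 else Reduce(kronecker, rep(list(z), d - 1))
        g <- g + drop(dp$coeffs[[d]] %*% zd)
      }
      g
    },
    exp_inference = function(z, sigma, sigma_reset) {
      bz <- drop(dp$beta %*% z)
      drop(-crossprod(dp$beta, dp$rate_scale * exp(bz) - sigma)) / dp$tau_s +
        p$lambda * z
    },
    hd = function(z, sigma, sigma_reset) {
      binp <- sum(dp$beta * (sigma - 1)) / dp$alpha
      s2 <- sum(z^2)
      att <- -dp$gamma * (s2 - dp$ring_k * dp$rho^2)
      g <- c(-binp * z[2], binp * z[1]) + att * z + p$lambda * z
      if (isTRUE(dp$reset_on)) {
        dx <- z[1] - dp$r_lm
        gg <- exp(-dx^2 - z[2]^2) - 2 * sigma_reset
        g <- g + 2 * c(dx, z[2]) * gg
      }
      g
    },
    stop("unknown drift type")
  )

  state <- scn_state(N, v0, r0)
  readout_m <- matrix(0, n_steps, M)
  spikes <- integer(n_steps)
  n_rec <- if (record_every > 0) ceiling(n_steps / record_every) else 0
  v_rec <- if (record_v) matrix(0, n_rec, N) else NULL
  r_rec <- if (record_r) matrix(0, n_rec, N) else NULL
  sigma <- NULL
  sigma_reset <- 0L

  for (t in seq_len(n_steps) - 1L) {
    z <- rs * drop(D %*% state$r)
    if (net$drift_type != "poly" && t %% stride == 0) {
      row <- t %/% stride + 1L
      sigma <- dp$counts[row, ]
      if (isTRUE(dp$reset_on)) {
        d2 <- (z[1] - dp$r_lm)^2 + z[2]^2
        sigma_reset <- stats::rpois(1, dp$c_reset * exp(-d2))
      }
    }
    drift_v <- drop(crossprod(D, drift_z_fun(z, sigma, sigma_reset)))
    noise_v <- NULL
    if (net$noise_amp > 0) {
      xi <- if (!is.null(noise_path)) noise_path[t + 1L, ]
            else stats::rnorm(M)
      noise_v <- net$noise_amp * sqrt(p$dt) * drop(crossprod(D, xi))
    }
    state <- scn_step(state, drift_v, omega_f, thr, p, noise_v)
    if (any(state$o == 1L)) spikes[t + 1L] <- which(state$o == 1L)
    readout_m[t + 1L, ] <- rs * drop(D %*% state$r)
    if (record_every > 0 && t %% record_every == 0) {
      row <- t %/% record_every + 1L
      if (record_v) v_rec[row, ] <- state$v
      if (record_r) r_rec[row, ] <- state$r
    }
  }
  list(readout = readout_m, spikes = spikes, n_spikes = sum(spikes > 0),
       v = v_rec, r = r_rec, v_final = state$v, r_final = state$r)
}
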