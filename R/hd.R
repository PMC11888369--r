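#' Head-direction model configuration
#'
#' Parameters of the Bayesian-filter head-direction (HD) sampler: the
#' angular-velocity encoder gains, the soft ring prior, and the derived
#' normalizer `alpha = 1 + dt * beta' beta` that weights each step's
#' velocity observation against the previous estimate.
#'
#' The default encoder is a population of `n_inputs` Poisson neurons with
#' alternating gains `+/- b` whose per-step count mean is
#' `exp(beta_i * omega * dt)` (mean 1 at zero velocity, so standing still
#' is a fixed point of the update).  The antisymmetric arrangement
#' cancels the even-order bias of the exponential kernel, and
#' `b = 100` at `dt = 1e-3` puts the observation gain
#' `dt * beta' beta / alpha` at 100/101, so constant angular velocities
#' are integrated to within a few percent.
#'
#' @param rho ring-radius parameter of the soft prior (readout units).
#' @param gain attractor strength `gamma` (default 4, the literal
#'   coefficient of the published dynamics).
#' @param beta encoder gain vector (length = number of input neurons);
#'   default `n_inputs` alternating `+/- b`.
#' @param n_inputs,b used to build the default `beta`.
#' @param dt time step of the map / encoder, s.
#' @param mode `"literal"`: attractor factor `(x^2 + y^2 - 2 rho^2)`,
#'   stable radius `sqrt(2) rho`; `"exact"`: the exact gradient of the
#'   ring prior `exp[-(x^2+y^2)(x^2+y^2-2 rho^2)]`, factor
#'   `(x^2 + y^2 - rho^2)`, stable radius `rho`.
#' @param landmark optional list `(c, r)` for a landmark-reset input
#'   population at angle 0: Poisson gain `c` and landmark distance `r`
#'   from the origin (default `sqrt(2) * rho`, on the literal-mode
#'   attractor circle).
#' @param alpha override the derived normalizer (testing only).
#' @return object of class `hd_config`.
#' @export
hd_config <- function(rho = 1, gain = 4, beta = NULL, n_inputs = 10, b = 100,
                      dt = 1e-3, mode = c("literal", "exact"),
                      landmark = NULL, alpha = NULL) {
  mode <- match.arg(mode)
  beta <- beta %||% rep(c(b, -b), length.out = n_inputs)
  alpha <- alpha %||% (1 + dt * sum(beta^2))
  if (alpha < 1) stop("alpha must be >= 1")
  if (gain <= 0) stop("attractor gain must be positive")
  if (!is.null(landmark)) {
    landmark$c <- landmark$c %||% 20
    landmark$r <- landmark$r %||% (sqrt(2) * rho)
  }
  structure(list(rho = rho, gain = gain, beta = beta, dt = dt,
                 alpha = alpha, mode = mode,
                 ring_k = if (mode == "literal") 2 else 1,
                 landmark = landmark),
            class = "hd_config")
}

#' @export
print.hd_config <- function(x, ...) {
  cat(sprintf(
    "<hd_config> rho = %g, gamma = %g, %d inputs, dt = %g s, alpha = %.3g, %s mode%s\n",
    x$rho, x$gain, length(x$beta), x$dt, x$alpha, x$mode,
    if (is.null(x$landmark)) "" else ", landmark active"))
  invisible(x)
}

#' Encode angular velocity as Poisson counts
#'
#' Each encoder neuron emits a per-step count with mean
#' `exp(beta_i * omega_t * dt)` — the exponential kernel applied to the
#' per-step angular increment, with baseline count 1 at zero velocity.
#'
#' @param omega angular-velocity series (rad/s) or a trajectory from
#'   [make_trajectory()].
#' @param config an [hd_config()].
#' @param seed integer seed.
#' @return a `spike_record` (`counts`: steps x inputs; `dt` from the
#'   config).
#' @export
encode_velocity <- function(omega, config, seed = NULL) {
  if (is.data.frame(omega)) omega <- omega$omega
  lam <- exp(outer(omega * config$dt, config$beta))
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(stats::rpois(length(lam), lam), nrow = length(omega))
  structure(list(counts = counts, dt = config$dt, pop = NULL, seed = seed),
            class = "spike_record")
}

#' One step of the 1-D head-direction sampler
#'
#' `theta <- wrap(theta + (dt/alpha) * beta'(sigma - 1)
#'                + xi * sqrt(2 dt) / alpha)`.
#'
#' @param theta previous angle, rad.
#' @param sigma encoder counts for this step (length = inputs).
#' @param config an [hd_config()].
#' @param xi standard-normal noise draw (0 disables noise).
#' @return updated angle in `[-pi, pi)`.
#' @export
hd_step_1d <- function(theta, sigma, config, xi = 0) {
  if (length(sigma) != length(config$beta))
    stop("sigma must have one count per encoder neuron")
  wrap_angle(theta +
               (config$dt / config$alpha) * sum(config$beta * (sigma - 1)) +
               xi * sqrt(2 * config$dt) / config$alpha)
}

#' One step of the 2-D (Cartesian) head-direction sampler
#'
#' The rotational velocity-observation term, the soft ring attractor,
#' and the stochastic term:
#' `z <- z + (dt/alpha) beta'(sigma - 1) (-y, x)
#'        - (gamma dt / alpha) z (x^2 + y^2 - k rho^2)
#'        + xi sqrt(2 dt / alpha)`
#' with `k = 2` (literal mode) or `k = 1` (exact-gradient mode).  The
#' rotational term is oriented so that a positive encoded velocity
#' advances the decoded angle counter-clockwise, consistent with the
#' one-dimensional update.
#'
#' @param xy previous Cartesian estimate, length 2.
#' @param sigma encoder counts for this step.
#' @param config an [hd_config()].
#' @param xi standard-normal pair (0 disables noise).
#' @param bound divergence guard on `|xy|`.
#' @return updated `(x, y)`.
#' @export
hd_step_2d <- function(xy, sigma, config, xi = c(0, 0), bound = 100) {
  binp <- sum(config$beta * (sigma - 1)) / config$alpha
  s2 <- sum(xy^2)
  att <- -(config$gain * config$dt / config$alpha) *
    (s2 - config$ring_k * config$rho^2)
  out <- xy + config$dt * binp * c(-xy[2], xy[1]) + att * xy +
    xi * sqrt(2 * config$dt / config$alpha)
  if (sum(out^2) > bound^2)
    stop("head-direction state exceeded the divergence bound")
  out
}

#' Landmark reset term (2-D)
#'
#' Additive update from a landmark-encoding Poisson population at angle
#' 0 and distance `r` from the origin:
#' `2 dt (x - r, y) (exp(-(x - r)^2 - y^2) - 2 sigma_reset)`.
#' A strong reset count drags the estimate toward the landmark; with no
#' counts and the bump far away the term vanishes.
#'
#' @param xy current Cartesian estimate.
#' @param sigma_reset landmark population count for this step.
#' @param config an [hd_config()] with a landmark.
#' @return additive update, length 2.
#' @export
reset_update <- function(xy, sigma_reset, config) {
  if (is.null(config$landmark)) stop("no landmark configured")
  r <- config$landmark$r
  d2 <- (xy[1] - r)^2 + xy[2]^2
  2 * config$dt * c(xy[1] - r, xy[2]) * (exp(-d2) - 2 * sigma_reset)
}

#' Combine update terms from multiple input populations
#'
#' Independent input populations multiply in the likelihood, so their
#' log-posterior gradient contributions add: the combined update is the
#' sum of the per-population terms evaluated at the same state.
#'
#' @param ... additive update terms (equal-length numeric vectors).
#' @return their sum.
#' @export
multimodal_compose <- function(...) {
  Reduce(`+`, list(...))
}

#' Run the low-dimensional head-direction map
#'
#' Iterates [hd_step_2d()] (plus the landmark term when configured and
#' `reset = TRUE`) over a count stream, using the compiled loop.
#'
#' @param record encoder `spike_record` from [encode_velocity()].
#' @param config an [hd_config()].
#' @param xy0 initial state; default on the attractor circle at angle 0.
#' @param seed integer seed.
#' @param noise logical; disable the stochastic term if `FALSE`.
#' @param noise_path optional pre-drawn standard normal increments
#'   (`steps x 2`) for noise-matched comparisons.
#' @param reset activate the landmark population.
#' @param reset_stream optional pre-drawn landmark counts (overrides the
#'   internal Poisson draw).
#' @return data frame `(t, x, y, theta_hat, radius)`; attribute
#'   `reset_counts` when the landmark is active.
#' @export
simulate_hd_map <- function(record, config, xy0 = NULL, seed = NULL,
                            noise = TRUE, noise_path = NULL, reset = FALSE,
                            reset_stream = NULL) {
  counts <- record$counts
  storage.mode(counts) <- "integer"
  r_fix <- sqrt(config$ring_k) * config$rho
  xy0 <- xy0 %||% c(r_fix, 0)
  if (!is.null(seed)) set.seed(seed)
  reset_on <- reset && !is.null(config$landmark)
  res <- .hd_map_cpp(xy0, counts, config$beta, config$dt, config$alpha,
                     config$gain, config$rho, config$ring_k,
                     if (noise) 1 else 0, noise_path, reset_on,
                     if (reset_on) config$landmark$c else 0,
                     if (reset_on) config$landmark$r else 0,
                     reset_stream)
  path <- res$path
  out <- data.frame(t = seq_len(nrow(path)) * config$dt,
                    x = path[, 1], y = path[, 2],
                    theta_hat = atan2(path[, 2], path[, 1]),
                    radius = sqrt(path[, 1]^2 + path[, 2]^2))
  if (reset_on) attr(out, "reset_counts") <- res$reset_counts
  out
}

#' Spiking head-direction network
#'
#' Configures the explicit spiking implementation of the 2-D
#' head-direction sampler: drift
#' `D^T[ (beta'(sigma_t - 1)/alpha)(-y, x)
#'       - gamma z (|z|^2 - k rho^2) + lambda z ]`,
#' fast weights `-D^T D`, voltage noise `sqrt(2/alpha) D^T xi`, fed by an
#' encoder count stream.  The attractor term enters the voltage equation
#' at full strength (unlike the low-D map, which scales it by `1/alpha`):
#' the spiking readout needs the full restoring force to stay on the ring
#' against spike quantization, and the noise-free fixed point (radius
#' `sqrt(k) rho`) coincides with that of [hd_step_2d()] either way.
#'
#' @param config an [hd_config()].
#' @param D decoding matrix with readout dimension 2 (e.g.
#'   [ring_decoder()]).
#' @param params [scn_params()]; `params$dt` must divide the record's
#'   `dt`.
#' @param record encoder `spike_record` from [encode_velocity()].
#' @param noise logical; disable the stochastic term if `FALSE`.
#' @param reset activate the landmark population.
#' @return an `scn_network` for [simulate_network()].
#' @export
build_hd_network <- function(config, D, params, record, noise = TRUE,
                             reset = FALSE) {
  D <- validate_readout(D)
  if (nrow(D) != 2) stop("head-direction networks need readout dimension 2")
  counts <- record$counts
  storage.mode(counts) <- "integer"
  stride <- record$dt / params$dt
  if (abs(stride - round(stride)) > 1e-8)
    stop("record dt must be an integer multiple of params$dt")
  stride <- as.integer(round(stride))
  reset_on <- reset && !is.null(config$landmark)
  new_network(D, params, "hd",
              list(beta = config$beta, counts = counts, stride = stride,
                   alpha = config$alpha, gamma = config$gain,
                   rho = config$rho, ring_k = config$ring_k,
                   reset_on = reset_on,
                   c_reset = if (reset_on) config$landmark$c else 0,
                   r_lm = if (reset_on) config$landmark$r else 0),
              noise_amp = if (noise) sqrt(2 / config$alpha) else 0,
              n_steps = nrow(counts) * stride,
              divergence_bound = 100 * config$rho)
}

#' Filtered-train initial condition for a target readout
#'
#' Non-negative least-norm filtered spike trains `r0` such that
#' `D r0` approximates `z` (ridge pseudo-inverse, clipped at zero —
#' filtered trains count non-negative spike events).  Useful for
#' starting a network with its bump at a chosen heading.
#'
#' @param D decoding matrix.
#' @param z target readout (length = readout dimension).
#' @return non-negative vector of length N.
#' @export
init_trains_at <- function(D, z) {
  D <- validate_readout(D)
  r <- drop(crossprod(D, solve(tcrossprod(D) + 1e-9 * diag(nrow(D)), z)))
  r <- pmax(r, 0)
  zr <- drop(D %*% r)
  if (sum(zr^2) > 0) r <- r * sqrt(sum(z^2) / sum(zr^2)) # undo clipping loss
  r
}

#' Decode angle and radius from a 2-D readout
#'
#' @param z readout: length-2 vector, `n x 2` matrix, or an `scn_sim`.
#' @param D optional decoding matrix when `z` is a filtered-spike-train
#'   vector/matrix instead of a readout.
#' @return data frame `(theta_hat, radius)`; `theta_hat` is `NA` where
#'   the readout is exactly zero (undefined angle).
#' @export
decode_angle <- function(z, D = NULL) {
  if (inherits(z, "scn_sim")) z <- z$readout
  if (!is.null(D)) z <- if (is.matrix(z)) z %*% t(D) else drop(D %*% z)
  zm <- if (is.null(dim(z))) matrix(z, ncol = 2) else z
  radius <- sqrt(zm[, 1]^2 + zm[, 2]^2)
  theta <- ifelse(radius == 0, NA_real_, atan2(zm[, 2], zm[, 1]))
  data.frame(theta_hat = theta, radius = radius)
}
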