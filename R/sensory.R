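#' Noisy sensory population
#'
#' Describes a population of input neurons encoding an M-dimensional
#' stimulus through a firing-rate kernel and a count-noise family.  The
#' population is both a generative model (spike-count emission) and the
#' source of the log-posterior gradients that drive sampling-based
#' inference networks.
#'
#' Kernels: `"exponential"` `phi_i(z) = exp(beta_i . z)`; `"linear"`
#' `phi_i(z) = max(beta_i . z + r0, floor)`; `"logistic"`
#' `phi_i(z) = 1 / (1 + exp(-beta_i . z))`.  The Bernoulli, binomial and
#' geometric noise families use the logistic kernel value as their
#' success probability and therefore require `kernel = "logistic"`.
#'
#' @param beta per-neuron rate parameters: an `Np x M` matrix (a vector is
#'   taken as `M = 1`).
#' @param kernel firing-rate kernel.
#' @param r0 base rate for the linear kernel, events/s.
#' @param noise count-noise family.
#' @param size number of trials for the binomial family.
#' @param taylor_order expansion order `K` for the truncated posterior
#'   gradients of the linear (default 2) and logistic (default 3)
#'   kernels: the highest power of `beta . z` retained in the `1/phi`
#'   expansion.
#' @param rate_floor lower bound applied to linear-kernel rates.
#' @return object of class `sensory_pop`.
#' @export
sensory_population <- function(beta,
                               kernel = c("exponential", "linear", "logistic"),
                               r0 = 1,
                               noise = c("poisson", "bernoulli", "binomial",
                                         "geometric"),
                               size = NULL, taylor_order = NULL,
                               rate_floor = 1e-6) {
  kernel <- match.arg(kernel)
  noise <- match.arg(noise)
  if (is.null(dim(beta))) beta <- matrix(beta, ncol = 1)
  beta <- as.matrix(beta)
  if (noise == "binomial" && is.null(size))
    stop("binomial noise requires a trial count 'size'")
  if (noise != "poisson" && kernel != "logistic")
    stop(noise, " noise uses the logistic kernel as success probability; ",
         "set kernel = 'logistic'")
  if (is.null(taylor_order))
    taylor_order <- switch(kernel, linear = 2L, logistic = 3L, NULL)
  if (kernel == "linear" && taylor_order < 1)
    stop("linear kernel requires taylor_order >= 1")
  structure(list(Np = nrow(beta), M = ncol(beta), beta = beta,
                 kernel = kernel, r0 = r0, noise = noise, size = size,
                 taylor_order = taylor_order, rate_floor = rate_floor),
            class = "sensory_pop")
}

#' @export
print.sensory_pop <- function(x, ...) {
  cat(sprintf("<sensory_pop> %d neurons, %d-D stimulus, %s kernel, %s noise\n",
              x$Np, x$M, x$kernel, x$noise))
  invisible(x)
}

#' Firing-rate kernel of a sensory population
#'
#' @param pop a [sensory_population()].
#' @param z stimulus: length-M vector or `n x M` matrix.
#' @return rates: length-Np vector, or `n x Np` matrix for a matrix input.
#' @export
firing_rate <- function(pop, z) {
  zm <- if (is.null(dim(z))) matrix(z, ncol = pop$M) else as.matrix(z)
  if (ncol(zm) != pop$M) stop("stimulus dimension mismatch")
  if (any(!is.finite(zm))) stop("stimulus must be finite")
  lin <- zm %*% t(pop$beta) # n x Np
  out <- switch(pop$kernel,
    exponential = exp(lin),
    linear = pmax(lin + pop$r0, pop$rate_floor),
    logistic = 1 / (1 + exp(-lin))
  )
  if (is.null(dim(z))) drop(out) else out
}

#' Emit spike counts from a sensory population
#'
#' Draws one count per neuron per time step.  Poisson counts have mean
#' `rate * dt`; the Bernoulli/binomial/geometric families use the
#' (logistic) kernel value as their per-step success probability, with no
#' `dt` scaling.
#'
#' @param pop a [sensory_population()].
#' @param z stimulus series: length-n vector (M = 1) or `n x M` matrix;
#'   a single stimulus value gives a single row of counts.
#' @param dt observation window per step, s (Poisson mean `rate * dt`).
#'   With `dt = 1` the kernel value itself is the Poisson mean.
#' @param seed integer seed.
#' @return object of class `spike_record`: list with integer `counts`
#'   (`n x Np`), `dt`, and the generating population.
#' @export
emit_spikes <- function(pop, z, dt = 1, seed = NULL) {
  zm <- if (is.null(dim(z))) matrix(z, ncol = pop$M) else as.matrix(z)
  rates <- firing_rate(pop, zm) # n x Np
  n <- nrow(rates)
  if (!is.null(seed)) set.seed(seed)
  counts <- switch(pop$noise,
    poisson = matrix(stats::rpois(n * pop$Np, lambda = rates * dt), n, pop$Np),
    bernoulli = matrix(stats::rbinom(n * pop$Np, 1L, prob = rates), n, pop$Np),
    binomial = matrix(stats::rbinom(n * pop$Np, pop$size, prob = rates),
                      n, pop$Np),
    geometric = matrix(stats::rgeom(n * pop$Np, prob = rates), n, pop$Np)
  )
  structure(list(counts = counts, dt = dt, pop = pop, seed = seed),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d steps x %d neurons, dt = %g s, %d spikes\n",
              nrow(x$counts), ncol(x$counts), x$dt, sum(x$counts)))
  invisible(x)
}

# truncated polynomial gradient of the negative log posterior for the
# linear and logistic kernels at a fixed count vector (Poisson noise)
posterior_drift_poly <- function(pop, counts, dt = 1) {
  M <- pop$M
  K <- pop$taylor_order
  if (pop$kernel == "linear") {
    # grad U = sum_i A_i [dt - (sigma_i / r0) sum_{n=0}^{K} (-A_i.z / r0)^n]
    g <- K
    coeffs <- lapply(0:g, function(d) matrix(0, M, M^d))
    for (i in seq_len(pop$Np)) {
      A <- pop$beta[i, ]
      coeffs[[1]] <- coeffs[[1]] +
        matrix(A * (dt - counts[i] / pop$r0), ncol = 1)
      for (n in seq_len(K)) {
        cn <- -counts[i] / pop$r0 * (-1 / pop$r0)^n
        coeffs[[n + 1L]] <- coeffs[[n + 1L]] +
          cn * (matrix(A, ncol = 1) %*% kron_power(matrix(A, nrow = 1), n))
      }
    }
    return(poly_drift(coeffs, M))
  }
  if (pop$kernel == "logistic") {
    if (M != 1) stop("the truncated logistic gradient is one-dimensional")
    # dphi/dz ~ A (1/4 - (A z)^2 / 16)  (parabola approximation)
    # 1/phi   = 1 + exp(-A z) ~ 2 + sum_{n=1}^{K} (-A z)^n / n!
    # grad U  ~ sum_i dphi_i (dt - sigma_i / phi_i)
    deg <- K + 2L
    co <- numeric(deg + 1L) # coefficient of z^0 .. z^deg
    for (i in seq_len(pop$Np)) {
      A <- pop$beta[i, 1]
      dphi <- c(A / 4, 0, -A^3 / 16) # z^0, z^1, z^2
      invphi <- c(2, (-A)^seq_len(K) / factorial(seq_len(K)))
      fac <- -counts[i] * invphi
      fac[1] <- fac[1] + dt
      prod_co <- numeric(deg + 1L)
      for (a in seq_along(dphi))
        for (b in seq_along(fac))
          prod_co[a + b - 1L] <- prod_co[a + b - 1L] + dphi[a] * fac[b]
      co <- co + prod_co
    }
    return(poly_drift(lapply(co, function(x) matrix(x, 1, 1)), 1L))
  }
  stop("no truncated form for kernel ", pop$kernel)
}

#' Gradient of the negative log posterior
#'
#' For a flat prior the posterior over the stimulus given one count
#' vector is `P(z | sigma) prop P(sigma | z)`; this returns
#' `grad_z U(z)` with `U = -log P(sigma | z)`.  For the linear and
#' logistic kernels the default is the truncated polynomial expansion of
#' order `taylor_order` (the network-implementable form); `exact = TRUE`
#' evaluates the exact gradient instead.
#'
#' @param pop a [sensory_population()].
#' @param z stimulus point, length M.
#' @param counts one count per neuron (length Np).
#' @param dt observation window used when the counts were emitted
#'   (Poisson mean `rate * dt`); use 1 when the kernel value is the mean.
#' @param exact logical; evaluate the exact gradient.
#' @return gradient vector of length M.
#' @export
posterior_grad <- function(pop, z, counts, dt = 1, exact = FALSE) {
  if (length(z) != pop$M) stop("z must have length ", pop$M)
  if (length(counts) != pop$Np) stop("one count per sensory neuron required")
  B <- pop$beta
  if (pop$noise == "poisson") {
    phi <- firing_rate(pop, z)
    if (pop$kernel == "exponential") {
      return(drop(crossprod(B, dt * phi - counts)))
    }
    if (!exact) return(eval_drift(posterior_drift_poly(pop, counts, dt), z))
    if (pop$kernel == "linear") {
      at_floor <- phi <= pop$rate_floor & counts > 0
      if (any(at_floor))
        warning("rate at floor with non-zero count for neuron(s) ",
                paste(which(at_floor), collapse = ", "))
      return(drop(crossprod(B, dt - counts / phi)))
    }
    # logistic: dphi = beta * exp(-bz) * phi^2
    bz <- drop(B %*% z)
    dphi <- exp(-bz) * phi^2
    return(drop(crossprod(B, dphi * (dt - counts / phi))))
  }
  f <- firing_rate(pop, z)
  grad_logp <- switch(pop$noise,
    bernoulli = drop(crossprod(B, counts - f)),
    binomial = drop(crossprod(B, counts - pop$size * f)),
    geometric = drop(crossprod(B, 1 - f * (1 + counts)))
  )
  -grad_logp
}

#' Posterior density over a 1-D stimulus by quadrature
#'
#' Normalized `exp(-U(z))` on a grid, with `U` the negative log
#' likelihood of the observed counts under the population's noise family
#' (flat prior).  The independent reference for the sampling-based
#' inference networks.
#'
#' @param pop a [sensory_population()] with `M = 1`.
#' @param counts one count per neuron.
#' @param dt observation window (see [posterior_grad()]).
#' @param lower,upper,n grid specification.
#' @return data frame `(z, density)`; attribute `Z` is the normalizer.
#' @export
posterior_quadrature <- function(pop, counts, dt = 1, lower = -5, upper = 5,
                                 n = 2001) {
  if (pop$M != 1) stop("grid posterior supports M = 1")
  zg <- seq(lower, upper, length.out = n)
  rates <- firing_rate(pop, matrix(zg, ncol = 1)) # n x Np
  U <- switch(pop$noise,
    poisson = {
      lam <- rates * dt
      rowSums(lam - rep(counts, each = n) * log(lam))
    },
    bernoulli = -rowSums(rep(counts, each = n) * log(rates) +
                         rep(1 - counts, each = n) * log1p(-rates)),
    binomial = -rowSums(rep(counts, each = n) * log(rates) +
                        rep(pop$size - counts, each = n) * log1p(-rates)),
    geometric = -rowSums(log(rates) + rep(counts, each = n) * log1p(-rates))
  )
  U <- U - min(U)
  un <- exp(-U)
  w <- trapz_weights(n, zg[2] - zg[1])
  Z <- sum(w * un)
  out <- data.frame(z = zg, density = un / Z)
  attr(out, "Z") <- Z
  out
}

#' Moments of a tabulated density
#'
#' @param dens data frame `(z, density)` on a uniform grid.
#' @return list with `mean`, `var`, `sd`, `skewness`.
#' @export
posterior_moments <- function(dens) {
  h <- dens$z[2] - dens$z[1]
  w <- dens$density * h
  w <- w / sum(w)
  m <- sum(w * dens$z)
  v <- sum(w * (dens$z - m)^2)
  list(mean = m, var = v, sd = sqrt(v),
       skewness = sum(w * (dens$z - m)^3) / v^1.5)
}

#' Sampling-based inference network
#'
#' Configures an SCN whose readout samples from the posterior over the
#' stimulus encoded by a sensory population: the slow drift is
#' `D^T(-(1/tau_s) grad U(zhat, sigma_t) + lambda zhat)` with the count
#' stream `sigma_t` taken from a spike record.  The exponential kernel is
#' integrated exactly; linear and logistic kernels use their truncated
#' polynomial gradients and require a static (single-row) record.
#'
#' @param pop a [sensory_population()] with Poisson noise.
#' @param record a `spike_record` from [emit_spikes()]; one row is held
#'   for `record$dt / params$dt` network steps (a single row is held
#'   forever, for static-stimulus inference).
#' @param D decoding matrix (readout dimension `pop$M`).
#' @param params [scn_params()].
#' @param noise logical; disable the stochastic term for fixed-point
#'   checks.
#' @return an `scn_network` for [simulate_network()].
#' @export
build_inference_network <- function(pop, record, D, params, noise = TRUE) {
  stopifnot(inherits(record, "spike_record"))
  D <- validate_readout(D)
  if (nrow(D) != pop$M)
    stop("readout dimension of D must equal the stimulus dimension")
  if (pop$noise != "poisson")
    stop("inference networks are implemented for Poisson noise")
  counts <- record$counts
  storage.mode(counts) <- "integer"
  static <- nrow(counts) == 1L
  if (static) {
    stride <- .Machine$integer.max
    n_steps <- NULL
  } else {
    stride <- record$dt / params$dt
    if (abs(stride - round(stride)) > 1e-8)
      stop("record dt must be an integer multiple of params$dt")
    stride <- as.integer(round(stride))
    n_steps <- nrow(counts) * stride
  }
  amp <- if (noise) sqrt(2 / params$tau_s) else 0
  if (pop$kernel == "exponential") {
    return(new_network(D, params, "exp_inference",
                       list(beta = pop$beta, counts = counts,
                            stride = stride, tau_s = params$tau_s,
                            rate_scale = record$dt),
                       noise_amp = amp, n_steps = n_steps))
  }
  if (!static)
    stop("dynamic count streams are supported for the exponential kernel; ",
         "use a single-row record for ", pop$kernel, " kernels")
  g <- posterior_drift_poly(pop, counts[1L, ], record$dt)
  coeffs <- lapply(g$coeffs, function(A) -A / params$tau_s)
  if (length(coeffs) < 2) coeffs <- c(coeffs, list(matrix(0, pop$M, pop$M)))
  coeffs[[2]] <- coeffs[[2]] + params$lambda * diag(pop$M)
  new_network(D, params, "poly", list(coeffs = coeffs), noise_amp = amp)
}

#' Causal moving-window moments
#'
#' Running mean, variance and skewness of a sample stream over a causal
#' window, the separation-of-timescales readout for dynamically encoded
#' stimuli (the network samples much faster than the stimulus moves, so
#' a short trailing window estimates the instantaneous posterior
#' moments).
#'
#' @param x numeric sample stream.
#' @param window window length, s (must be at least `dt`).
#' @param dt sample spacing, s.
#' @return data frame with `mean`, `var`, `skewness`, one row per sample;
#'   leading rows use the partial window.
#' @export
moment_filter <- function(x, window, dt) {
  if (window < dt) stop("window must be at least dt")
  k <- max(1L, as.integer(round(window / dt)))
  n <- length(x)
  c1 <- cumsum(x)
  c2 <- cumsum(x^2)
  c3 <- cumsum(x^3)
  lagged <- function(cs) c(rep(0, k), cs)[seq_len(n)]
  cnt <- pmin(seq_len(n), k)
  s1 <- c1 - lagged(c1)
  s2 <- c2 - lagged(c2)
  s3 <- c3 - lagged(c3)
  m <- s1 / cnt
  v <- pmax(s2 / cnt - m^2, 0)
  m3 <- s3 / cnt - 3 * m * s2 / cnt + 2 * m^3
  sk <- ifelse(v > 0, m3 / v^1.5, 0)
  data.frame(mean = m, var = v, skewness = sk)
}
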