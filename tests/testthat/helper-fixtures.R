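# shared builders for small test networks and random energies

# random polynomial energy of dimension M and total degree <= deg,
# with an even positive leading radial part so it is normalizable
random_energy <- function(M, deg, seed) {
  set.seed(seed)
  expo <- as.matrix(expand.grid(rep(list(0:deg), M)))
  expo <- expo[rowSums(expo) <= deg & rowSums(expo) >= 1, , drop = FALSE]
  keep <- sort(sample(nrow(expo), min(nrow(expo), 6)))
  expo <- expo[keep, , drop = FALSE]
  coef <- round(stats::rnorm(nrow(expo)), 2)
  energy_poly(expo, coef, M = M)
}

# central finite-difference gradient of a scalar function
fd_grad <- function(f, z, h = 1e-5) {
  vapply(seq_along(z), function(m) {
    zp <- z; zm <- z
    zp[m] <- zp[m] + h
    zm[m] <- zm[m] - h
    (f(zp) - f(zm)) / (2 * h)
  }, numeric(1))
}

# standard small sampler configuration (1-D, 20 neurons)
sampler_setup <- function(tau_s = 0.01) {
  list(D = line_decoder(20, 0.1),
       params = scn_params(lambda = 10, dt = 1e-4, tau_s = tau_s))
}

# default head-direction network pieces
hd_setup <- function(N = 8, lambda = 10, b = 100) {
  cfg <- hd_config(b = b)
  D <- ring_decoder(N, rho = cfg$rho)
  list(cfg = cfg, D = D,
       params = scn_params(lambda = lambda, dt = 1e-4, tau_s = 1),
       r0 = init_trains_at(D, c(sqrt(2) * cfg$rho, 0)))
}

# constant-count record (sigma = 1) for fixed-point experiments
unit_record <- function(n, np = 10, dt = 1e-3) {
  structure(list(counts = matrix(1L, n, np), dt = dt),
            class = "spike_record")
}
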