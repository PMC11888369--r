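test_that("fast weights are -D^T D with the ring sign structure", {
  expect_equal(build_fast_weights(matrix(c(1, 0), 2, 1)),
               matrix(-1, 1, 1))
  expect_equal(build_fast_weights(diag(2)), -diag(2))

  D <- ring_decoder(8, rho = 1, norm = 0.5)
  of <- build_fast_weights(D)
  expect_equal(of, t(of))
  expect_true(all(diag(of) < 0))
  for (i in 1:8) {
    j_adj <- (i %% 8) + 1
    j_opp <- ((i + 3) %% 8) + 1
    expect_lt(of[i, j_adj], 0) # nearest-neighbour inhibition
    expect_gt(of[i, j_opp], 0) # long-range excitation
  }
  expect_error(build_fast_weights(matrix(numeric(0), 2, 0)), "non-empty")
  expect_error(build_fast_weights(cbind(c(1, 0), c(0, 0))), "all-zero")
})

test_that("thresholds combine spike costs and column norms", {
  expect_equal(thresholds(matrix(c(1, 0), 2, 1)), 0.5)
  expect_equal(thresholds(matrix(c(3, 4), 2, 1)), 12.5)
  expect_equal(thresholds(matrix(c(1, 0), 2, 1), lambda = 1, nu = 2), 1.5)
  # with zero costs, half the squared column norms
  D <- matrix(rnorm(12), 3, 4)
  expect_equal(thresholds(D), colSums(D^2) / 2)
  expect_true(all(thresholds(D) > 0))
})

test_that("greedy spike rule picks the maximal violation and flags NaN", {
  expect_identical(spike_rule(0.1, 0.5), integer(0))
  expect_identical(spike_rule(c(0.6, 0.2), c(0.5, 0.5)), 1L)
  expect_identical(spike_rule(c(0.7, 0.9), c(0.5, 0.5)), 2L)
  # tie broken by lowest index
  expect_identical(spike_rule(c(0.9, 0.9), c(0.5, 0.5)), 1L)
  expect_error(spike_rule(c(0.1, NaN), c(0.5, 0.5)), "neuron 2")
})

test_that("greedy spike minimizes the instantaneous reconstruction error", {
  # brute-force oracle: with v = D^T(z - zhat), the chosen spike must
  # reduce |z - zhat|^2 at least as much as any other candidate spike,
  # and must never increase it
  set.seed(11)
  for (rep in 1:50) {
    M <- sample(1:3, 1)
    N <- sample(2:10, 1)
    D <- matrix(rnorm(M * N), M, N)
    e <- rnorm(M) # current readout error z - zhat
    v <- drop(crossprod(D, e))
    thr <- thresholds(D)
    sp <- spike_rule(v, thr)
    if (length(sp)) {
      gain <- function(j) sum(e^2) - sum((e - D[, j])^2)
      gains <- vapply(seq_len(N), gain, numeric(1))
      expect_gte(gain(sp), 0)
      expect_gte(gain(sp), max(gains[v > thr]) - 1e-12)
    }
  }
})

test_that("step dynamics: fixed points and leak", {
  params <- scn_params(lambda = 10, dt = 1e-3, tau_s = 1)
  D <- diag(2)
  of <- build_fast_weights(D)
  thr <- thresholds(D)
  st <- scn_state(2)
  for (k in 1:100) st <- scn_step(st, c(0, 0), of, thr, params)
  expect_equal(st$v, c(0, 0))
  expect_equal(sum(st$o), 0)

  # constant subthreshold drift -> voltage converges to drift / lambda
  st <- scn_state(2)
  for (k in 1:5000) st <- scn_step(st, c(3, 0), of, thr, params)
  expect_equal(st$v[1], 3 / params$lambda, tolerance = 1e-3)
})

test_that("readout is the decoded filtered train in both variants", {
  D <- matrix(rnorm(8), 2, 4)
  expect_equal(readout(numeric(4), D), c(0, 0))
  r <- c(0, 1, 0, 0)
  expect_equal(readout(r, D), D[, 2])
  r <- runif(4)
  expect_equal(readout(r, D), drop(D %*% r))
  pm <- scn_params(lambda = 5, filter_variant = "methods")
  expect_equal(readout(r, D, pm), drop(D %*% r) / 5)
})

test_that("network readout tracks a harmonic oscillator", {
  # z' = (-w y, w x): counter-clockwise circular motion, closed form
  w <- 2 * pi
  A <- matrix(c(0, w, -w, 0), 2, 2)
  drift <- poly_drift(list(matrix(0, 2, 1), A), M = 2)
  errs <- sapply(c(4, 16, 64), function(N) {
    D <- ring_decoder(N, rho = 1, norm = 0.125) # fixed readout norm
    params <- scn_params(lambda = 10, dt = 1e-4, tau_s = 1)
    net <- build_dynamics_network(drift, D, params)
    sim <- simulate_network(net, duration = 1, r0 = init_trains_at(D, c(1, 0)))
    tt <- sim$t
    zstar <- cbind(cos(w * tt), sin(w * tt))
    mean(sqrt(rowSums((sim$readout - zstar)^2)))
  })
  expect_lt(errs[3], 0.3)              # bounded tracking error
  expect_true(all(diff(errs) < 0))     # error shrinks with N
})

test_that("voltage noise is rank <= M with covariance proportional to D^T D", {
  set.seed(21)
  D <- ring_decoder(6, 1, norm = 10) # thresholds huge: no spikes
  params <- scn_params(lambda = 1, dt = 1e-3, tau_s = 1)
  U <- energy_poly(rbind(c(2, 0), c(0, 2)), c(0.5, 0.5))
  net <- build_sampler_network(U, D, params)
  sim <- simulate_network(net, duration = 3, seed = 5, record_v = TRUE)
  expect_equal(sim$n_spikes, 0)
  dv <- diff(sim$v) # per-step increments are dominated by the noise
  sv <- svd(dv)$d
  expect_lt(sv[3] / sv[1], 0.05) # effectively rank 2
  Cv <- cov(dv)
  Ct <- crossprod(D)
  expect_gt(cor(Cv[upper.tri(Cv)], Ct[upper.tri(Ct)]), 0.99)
})

test_that("compiled and reference engines agree step for step", {
  U <- bimodal_energy()
  s <- sampler_setup()
  net <- build_sampler_network(U, s$D, s$params)
  np <- matrix(rnorm(400), 400, 1)
  set.seed(3)
  a <- simulate_network(net, duration = 0.04, noise_path = np, record_v = TRUE)
  set.seed(3)
  b <- simulate_network(net, duration = 0.04, noise_path = np, record_v = TRUE,
                        engine = "r")
  expect_equal(a$readout, b$readout, tolerance = 1e-12)
  expect_identical(a$spikes, b$spikes)
  expect_equal(a$v, b$v, tolerance = 1e-12)

  # head-direction drift agrees too (noise-free)
  h <- hd_setup()
  rec <- unit_record(30)
  params1 <- scn_params(lambda = 10, dt = 1e-3, tau_s = 1)
  neth <- build_hd_network(h$cfg, h$D, params1, rec, noise = FALSE)
  a <- simulate_network(neth, r0 = h$r0)
  b <- simulate_network(neth, r0 = h$r0, engine = "r")
  expect_equal(a$readout, b$readout, tolerance = 1e-12)
  expect_identical(a$spikes, b$spikes)
})

test_that("instability is reported with step and neuron", {
  # divergent drift: U with negative leading coefficient refused upstream,
  # so force instability through a dynamics network with positive feedback
  A <- matrix(50, 1, 1)
  drift <- poly_drift(list(matrix(0, 1, 1), A), M = 1)
  D <- line_decoder(2, 1)
  params <- scn_params(lambda = 1, dt = 1e-3, tau_s = 1)
  net <- build_dynamics_network(drift, D, params)
  net$divergence_bound <- 10
  expect_error(simulate_network(net, duration = 2, r0 = c(1, 0)),
               "instability")
})
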