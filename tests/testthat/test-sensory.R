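test_that("firing-rate kernels evaluate correctly", {
  pe <- sensory_population(1, kernel = "exponential")
  expect_equal(firing_rate(pe, 0), 1)
  pl <- sensory_population(2, kernel = "linear", r0 = 1)
  expect_equal(firing_rate(pl, 0.5), 2)
  pg <- sensory_population(3, kernel = "logistic")
  expect_equal(firing_rate(pg, 0), 0.5)
  # linear rates are floored, never negative
  expect_equal(firing_rate(pl, -10), pl$rate_floor)
  expect_error(firing_rate(pe, NaN), "finite")
  expect_error(sensory_population(1, noise = "binomial"), "size")
  expect_error(sensory_population(1, kernel = "exponential",
                                  noise = "bernoulli"), "logistic")
})

test_that("spike emission matches the configured count law", {
  p0 <- sensory_population(matrix(1), kernel = "linear", r0 = 0,
                           rate_floor = 0)
  rec0 <- emit_spikes(p0, rep(0, 100), dt = 1e-3, seed = 1)
  expect_true(all(rec0$counts == 0))

  p100 <- sensory_population(matrix(0), kernel = "linear", r0 = 100)
  rec <- emit_spikes(p100, rep(0, 1e5), dt = 1e-3, seed = 2)
  expect_equal(mean(rec$counts), 0.1, tolerance = 0.02)

  pb <- sensory_population(matrix(0), kernel = "logistic",
                           noise = "bernoulli")
  recb <- emit_spikes(pb, rep(0, 2e4), seed = 3)
  expect_true(all(recb$counts %in% 0:1))
  expect_equal(mean(recb$counts), 0.5, tolerance = 0.02)

  pbin <- sensory_population(matrix(0), kernel = "logistic",
                             noise = "binomial", size = 4)
  recbin <- emit_spikes(pbin, rep(0, 2e4), seed = 4)
  expect_true(all(recbin$counts <= 4))
  expect_equal(mean(recbin$counts), 2, tolerance = 0.05)

  # determinism under seed
  r1 <- emit_spikes(p100, rep(0, 100), dt = 1e-3, seed = 9)
  r2 <- emit_spikes(p100, rep(0, 100), dt = 1e-3, seed = 9)
  expect_identical(r1$counts, r2$counts)
})

test_that("posterior gradients match the written likelihoods", {
  # exponential kernel single neuron: grad U = beta (e^{beta z} - sigma)
  pe <- sensory_population(1, kernel = "exponential")
  expect_equal(posterior_grad(pe, 0, 1), 0)
  expect_equal(posterior_grad(pe, 0, 0), 1)

  # finite differences of the negative log likelihood, all families
  neg_loglik <- function(pop, counts, dt) function(z) {
    f <- firing_rate(pop, z)
    switch(pop$noise,
      poisson = sum(f * dt - counts * log(f * dt)),
      bernoulli = -sum(counts * log(f) + (1 - counts) * log(1 - f)),
      binomial = -sum(counts * log(f) + (pop$size - counts) * log(1 - f)),
      geometric = -sum(log(f) + counts * log(1 - f)))
  }
  set.seed(31)
  cases <- list(
    sensory_population(rnorm(5), kernel = "exponential"),
    sensory_population(matrix(rnorm(10), 5, 2), kernel = "exponential"),
    sensory_population(runif(4, 0.5, 2), kernel = "linear", r0 = 5),
    sensory_population(runif(4, 0.5, 2), kernel = "logistic"),
    sensory_population(runif(4, 0.5, 2), kernel = "logistic",
                       noise = "bernoulli"),
    sensory_population(runif(4, 0.5, 2), kernel = "logistic",
                       noise = "binomial", size = 6),
    sensory_population(runif(4, 0.5, 2), kernel = "logistic",
                       noise = "geometric")
  )
  for (pop in cases) {
    for (k in 1:10) {
      z <- runif(pop$M, -0.5, 0.5)
      counts <- switch(pop$noise,
        poisson = rpois(pop$Np, 1),
        bernoulli = rbinom(pop$Np, 1, 0.5),
        binomial = rbinom(pop$Np, pop$size, 0.5),
        geometric = rgeom(pop$Np, 0.5))
      expect_equal(posterior_grad(pop, z, counts, dt = 1, exact = TRUE),
                   fd_grad(neg_loglik(pop, counts, 1), z),
                   tolerance = 1e-5)
    }
  }
})

test_that("truncated kernel expansions approach the exact gradient", {
  set.seed(41)
  # linear kernel: high expansion order matches the exact form inside
  # the convergence radius |A z / r0| < 1
  popK <- sensory_population(runif(4, 0.5, 1.5), kernel = "linear",
                             r0 = 10, taylor_order = 12)
  for (k in 1:20) {
    z <- runif(1, -1, 1)
    counts <- rpois(4, 5)
    expect_equal(posterior_grad(popK, z, counts),
                 posterior_grad(popK, z, counts, exact = TRUE),
                 tolerance = 1e-4)
  }
  # default K = 2 reproduces the quadratic-in-z truncation explicitly
  pop2 <- sensory_population(c(1, 2), kernel = "linear", r0 = 5)
  counts <- c(3, 1)
  z <- 0.2
  manual <- sum(sapply(1:2, function(i) {
    A <- pop2$beta[i, 1]
    A * (1 - counts[i] / 5 * (1 - A * z / 5 + (A * z)^2 / 25))
  }))
  expect_equal(posterior_grad(pop2, z, counts), manual)

  # logistic kernel: the parabola/series truncation is close near z = 0
  popL <- sensory_population(c(0.8, 1.2), kernel = "logistic",
                             taylor_order = 6)
  for (z in c(-0.2, 0, 0.15)) {
    counts <- c(1, 0)
    expect_equal(posterior_grad(popL, z, counts),
                 posterior_grad(popL, z, counts, exact = TRUE),
                 tolerance = 0.02)
  }
})

test_that("quadrature posteriors concentrate where they should", {
  pe <- sensory_population(1, kernel = "exponential")
  post <- posterior_quadrature(pe, 5, lower = -2, upper = 5)
  expect_equal(post$z[which.max(post$density)], log(5), tolerance = 0.01)
  h <- post$z[2] - post$z[1]
  expect_equal(sum(post$density) * h, 1, tolerance = 1e-6)

  # two identical neurons pooling their counts = one neuron with the sums
  p2 <- sensory_population(c(1, 1), kernel = "exponential")
  post2 <- posterior_quadrature(p2, c(2, 3), lower = -2, upper = 5)
  # U_2(z) = 2 e^z - 5 z + const: same posterior as the combined statistic
  pref <- exp(-(2 * exp(post2$z) - 5 * post2$z))
  pref <- pref / (sum(pref) * h)
  expect_equal(post2$density, pref, tolerance = 1e-6)
})

test_that("Poisson posterior skewness flips with the encoded velocity", {
  cfg_beta <- rep(c(2, -2), 5)
  pop <- sensory_population(cfg_beta, kernel = "exponential")
  sk <- sapply(c(-0.8, 0.8), function(w) {
    counts <- round(firing_rate(pop, w)) # noise-free expected counts
    posterior_moments(posterior_quadrature(pop, counts, lower = -3,
                                           upper = 3))$skewness
  })
  expect_true(all(abs(sk) > 1e-3))
  expect_lt(sk[1] * sk[2], 0) # opposite signs for opposite velocities
})

test_that("moment filter tracks running moments", {
  expect_error(moment_filter(1:10, window = 0.5, dt = 1), "at least dt")
  mf <- moment_filter(rep(3, 100), window = 10, dt = 1)
  expect_equal(mf$mean, rep(3, 100))
  expect_equal(mf$var, rep(0, 100))
  mf <- moment_filter(rep(c(1, -1), 50), window = 10, dt = 1)
  expect_equal(tail(mf$mean, 1), 0)
  expect_equal(tail(mf$var, 1), 1)
  set.seed(51)
  x <- rnorm(5000, 2, 0.5)
  mf <- moment_filter(x, window = 1000, dt = 1)
  expect_equal(tail(mf$mean, 1), 2, tolerance = 0.05)
  expect_equal(tail(mf$var, 1), 0.25, tolerance = 0.12)
})

test_that("inference network samples the static posterior", {
  pop <- sensory_population(seq(-2, 2, length.out = 10),
                            kernel = "exponential")
  rec <- emit_spikes(pop, 1, dt = 1, seed = 5)
  D <- line_decoder(20, 0.1)
  params <- scn_params(lambda = 10, dt = 1e-4, tau_s = 0.1)
  net <- build_inference_network(pop, rec, D, params)
  post <- posterior_quadrature(pop, rec$counts[1, ], lower = -3, upper = 5)
  pm <- posterior_moments(post)

  # zero counts with an all-positive exponential kernel push the
  # readout toward low stimulus values
  pop_pos <- sensory_population(seq(0.5, 2, length.out = 5),
                                kernel = "exponential")
  rec0 <- emit_spikes(pop_pos, 1, dt = 1, seed = 5)
  rec0$counts[] <- 0L
  net0 <- build_inference_network(pop_pos, rec0, D, params, noise = FALSE)
  sim0 <- simulate_network(net0, duration = 1)
  expect_lt(tail(sim0$readout[, 1], 1), -0.5)

  # sample moments approach the quadrature posterior as the run grows
  errs <- sapply(c(2, 8, 24), function(dur) {
    sim <- simulate_network(net, duration = dur, seed = 6)
    th <- thin_samples(sim$readout[, 1], 1e-4, 0.1, burn_in = 0.5)
    abs(mean(th) - pm$mean) + abs(sd(th) - pm$sd)
  })
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.1 * abs(pm$mean) + 0.1 * pm$sd)
})

test_that("record dt must be compatible with the network step", {
  pop <- sensory_population(c(1, -1), kernel = "exponential")
  rec <- emit_spikes(pop, rep(0.5, 10), dt = 1e-3, seed = 1)
  D <- line_decoder(4, 0.2)
  expect_error(
    build_inference_network(pop, rec, D, scn_params(dt = 3e-4)),
    "integer multiple")
  net <- build_inference_network(pop, rec, D, scn_params(dt = 1e-3))
  sim <- simulate_network(net, seed = 2)
  expect_equal(length(sim$t), 10L)
})
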