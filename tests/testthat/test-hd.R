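test_that("1-D update integrates counts and wraps", {
  cfg <- hd_config(beta = 1, alpha = 1, dt = 0.01)
  expect_equal(hd_step_1d(0.3, 1, cfg), 0.3)          # sigma = 1: no move
  expect_equal(hd_step_1d(0, 2, cfg), 0.01)           # (beta/alpha)(2-1)dt
  th <- hd_step_1d(pi - 0.001, 2, cfg)
  expect_lt(th, -pi + 0.02)                           # wraps past +pi
  expect_error(hd_step_1d(0, c(1, 1), cfg), "one count per")
})

test_that("2-D update has the on-ring fixed point and radial map", {
  cfg <- hd_config(beta = 1, dt = 1e-3)
  r_fix <- sqrt(2) * cfg$rho
  pt <- c(r_fix / sqrt(2), r_fix / sqrt(2))
  expect_equal(hd_step_2d(pt, 1, cfg), pt)            # both terms vanish

  # below the ring the squared radius grows by the radial map
  xy <- c(0.5, 0)
  nxt <- hd_step_2d(xy, 1, cfg)
  s <- sum(xy^2)
  ds_pred <- -2 * cfg$gain * cfg$dt * s * (s - 2 * cfg$rho^2) / cfg$alpha
  expect_equal(sum(nxt^2) - s, ds_pred, tolerance = 0.005) # first order in dt
  expect_gt(sum(nxt^2), s)

  # rotation-only dynamics: angle advances ~ m dt beta k / alpha on-ring
  cfgb <- hd_config(beta = 5, dt = 1e-3)
  k <- 3; m <- 200
  xy <- c(r_fix, 0)
  for (i in 1:m) xy <- hd_step_2d(xy, 1 + k, cfgb)
  expect_equal(atan2(xy[2], xy[1]), m * cfgb$dt * 5 * k / cfgb$alpha,
               tolerance = 0.01)
  expect_equal(sqrt(sum(xy^2)), r_fix, tolerance = 0.01)
  expect_error(hd_step_2d(c(200, 0), 1, cfg), "divergence")
})

test_that("noise-free dynamics converge to the mode-specific radius", {
  for (mode in c("literal", "exact")) {
    cfg <- hd_config(mode = mode)
    target <- if (mode == "literal") sqrt(2) * cfg$rho else cfg$rho
    rec <- unit_record(150000)
    for (f in c(0.3, 0.5, 1.7, 3)) {
      p <- simulate_hd_map(rec, cfg, xy0 = c(f * target, 0), noise = FALSE)
      expect_equal(tail(p$radius, 1), target, tolerance = 0.02,
                   label = sprintf("%s mode from %.1fx", mode, f))
    }
  }
})

test_that("angles decode by atan2 with a zero-readout flag", {
  expect_equal(decode_angle(c(1, 0))$theta_hat, 0)
  expect_equal(decode_angle(c(0, 1))$theta_hat, pi / 2)
  expect_equal(decode_angle(c(-1, -1))$theta_hat, -3 * pi / 4)
  d0 <- decode_angle(c(0, 0))
  expect_true(is.na(d0$theta_hat))
  expect_equal(d0$radius, 0)
  # decoding filtered trains through D
  D <- ring_decoder(8, 1)
  r <- init_trains_at(D, c(0, 1.2))
  expect_equal(decode_angle(r, D)$theta_hat, pi / 2, tolerance = 1e-6)
})

test_that("encoder counts are seeded and centered on exp(beta omega dt)", {
  cfg <- hd_config()
  r1 <- encode_velocity(rep(4, 1000), cfg, seed = 3)
  r2 <- encode_velocity(rep(4, 1000), cfg, seed = 3)
  expect_identical(r1$counts, r2$counts)
  lam <- exp(cfg$beta * 4 * cfg$dt)
  expect_equal(colMeans(r1$counts), lam, tolerance = 0.12)
  # mean count 1 at zero velocity: standing still is a fixed point
  r0 <- encode_velocity(rep(0, 5000), cfg, seed = 4)
  expect_equal(mean(r0$counts), 1, tolerance = 0.03)
})

test_that("landmark reset term is literal and composes additively", {
  cfg <- hd_config(landmark = list(c = 20, r = 1))
  # far from the landmark with silent reset population: term vanishes
  expect_equal(reset_update(c(-1.4, 0.1), 0, cfg), c(0, 0),
               tolerance = 1e-3)
  # at the landmark the prefactor is zero regardless of counts
  expect_equal(reset_update(c(1, 0), 50, cfg), c(0, 0))
  # manual term-by-term composition reproduces the full update
  xy <- c(0.3, 1.2)
  sig <- c(2L, rep(1L, 9))
  base <- hd_step_2d(xy, sig, cfg)
  full <- multimodal_compose(base - xy, reset_update(xy, 3, cfg)) + xy
  d2 <- (xy[1] - 1)^2 + xy[2]^2
  manual <- base + 2 * cfg$dt * c(xy[1] - 1, xy[2]) * (exp(-d2) - 2 * 3)
  expect_equal(full, manual)
  # single population: compose is the identity
  expect_equal(multimodal_compose(base), base)
  # duplicated population doubles the inference term
  expect_equal(multimodal_compose(base - xy, base - xy), 2 * (base - xy))
  expect_error(reset_update(xy, 1, hd_config()), "no landmark")
})

test_that("strong landmark input drags the bump to the landmark", {
  cfg <- hd_config(landmark = list(c = 20))
  rec <- unit_record(500)
  p <- simulate_hd_map(rec, cfg, xy0 = c(0, sqrt(2)), seed = 9,
                       reset = TRUE)
  err <- circ_dist(p$theta_hat, 0)
  expect_lt(err[500], 0.1)
  ck <- err[c(1, 60, 120, 180)] # within the reset transient
  expect_true(all(diff(ck) < 0)) # monotone approach
})

test_that("spiking network and low-D map agree, tighter with more neurons", {
  cfg <- hd_config()
  traj <- make_trajectory("constant", list(omega = 2), duration = 5,
                          dt = cfg$dt)
  rec <- encode_velocity(traj, cfg, seed = 13)
  map <- simulate_hd_map(rec, cfg, noise = FALSE)
  err_n <- sapply(c(8, 32), function(N) {
    D <- ring_decoder(N, cfg$rho)
    params <- scn_params(lambda = 10, dt = 1e-4, tau_s = 1)
    net <- build_hd_network(cfg, D, params, rec, noise = FALSE)
    sim <- simulate_network(net, r0 = init_trains_at(D, c(sqrt(2), 0)))
    dec <- decode_angle(sim)
    thin <- seq(10, nrow(dec), by = 10)
    mean(circ_dist(dec$theta_hat[thin], map$theta_hat))
  })
  expect_lt(err_n[2], err_n[1])
  expect_lt(err_n[2], 0.1)
})

test_that("hd network demands a 2-D readout and compatible record", {
  cfg <- hd_config()
  rec <- unit_record(10)
  expect_error(build_hd_network(cfg, line_decoder(4), scn_params(), rec),
               "readout dimension 2")
  expect_error(build_hd_network(cfg, ring_decoder(8), scn_params(dt = 3e-4),
                                rec),
               "integer multiple")
})
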