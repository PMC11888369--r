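known_experiments <- c("bimodal-sampling", "velocity-inference",
                       "hd-darkness", "hd-reset", "predictions-suite")

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path")
  if (is.null(config$experiment))
    stop("config field 'experiment' is required (one of: ",
         paste(known_experiments, collapse = ", "), ")")
  if (!config$experiment %in% known_experiments)
    stop("config field 'experiment': unknown experiment '",
         config$experiment, "'")
  if (is.null(config$seed)) stop("config field 'seed' is required")
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    stop("config field 'seed' must be an integer")
  config$params <- config$params %||% list()
  config
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run a named end-to-end experiment
#'
#' Loads a configuration (list, YAML or JSON), runs one of the named
#' experiments and writes all artifacts — CSV outputs, a
#' `diagnostics.json`, and a `manifest.json` holding the full
#' configuration and seed so the directory is reconstructible — plus a
#' plain-text log.
#'
#' Experiments: `bimodal-sampling` (spiking sampler vs quadrature for the
#' double-well energy), `velocity-inference` (posterior sampling of a
#' static velocity from Poisson counts), `hd-darkness` (head-direction
#' tracking from velocity spikes alone), `hd-reset` (landmark-driven
#' realignment), `predictions-suite` (correlation / tuning / bump-velocity
#' statistics on a head-direction run).
#'
#' @param config list or path to a YAML/JSON file with fields
#'   `experiment`, `seed`, and optional `params` overriding experiment
#'   defaults.
#' @param out_dir output directory (default `config$out`, or a
#'   tempdir-based folder).
#' @return the output directory, invisibly; diagnostics as attribute
#'   `diagnostics`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  out_dir <- out_dir %||% config$out %||%
    file.path(tempdir(), paste0("ringsampler-", config$experiment))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)
  p <- config$params
  t0 <- proc.time()[["elapsed"]]

  diag <- switch(config$experiment,
    "bimodal-sampling" = exp_bimodal(p, seed, out_dir),
    "velocity-inference" = exp_velocity_inference(p, seed, out_dir),
    "hd-darkness" = exp_hd_darkness(p, seed, out_dir),
    "hd-reset" = exp_hd_reset(p, seed, out_dir),
    "predictions-suite" = exp_predictions(p, seed, out_dir)
  )

  write_json_file(diag, file.path(out_dir, "diagnostics.json"))
  write_json_file(list(experiment = config$experiment, seed = seed,
                       params = p,
                       package_version = as.character(
                         utils::packageVersion("ringsampler"))),
                  file.path(out_dir, "manifest.json"))
  writeLines(sprintf("experiment=%s seed=%d elapsed_s=%.2f",
                     config$experiment, seed,
                     proc.time()[["elapsed"]] - t0),
             file.path(out_dir, "log.txt"))
  attr(out_dir, "diagnostics") <- diag
  invisible(out_dir)
}

exp_bimodal <- function(p, seed, out_dir) {
  U <- bimodal_energy()
  params <- scn_params(lambda = p$lambda %||% 10, dt = p$dt %||% 1e-4,
                       tau_s = p$tau_s %||% 0.01)
  D <- line_decoder(p$N %||% 20, p$norm %||% 0.1)
  net <- build_sampler_network(U, D, params)
  sim <- simulate_network(net, duration = p$duration %||% 20, seed = seed)
  dens <- density_quadrature(U, -3, 3, 1201)
  th <- thin_samples(sim$readout[, 1], params$dt, params$tau_s,
                     burn_in = p$burn_in %||% 0.5)
  cmp <- compare_samples(th, dens)
  utils::write.csv(data.frame(t = sim$t, z = sim$readout[, 1]),
                   file.path(out_dir, "samples.csv"), row.names = FALSE)
  list(ks = cmp$ks, n_modes = cmp$n_modes,
       frac_positive = mean(th > 0), n_thinned = cmp$n,
       moments = as.list(as.data.frame(t(cmp$moments))),
       thinning_interval_s = params$tau_s, n_spikes = sim$n_spikes)
}

exp_velocity_inference <- function(p, seed, out_dir) {
  z_true <- p$z_true %||% 1
  set.seed(seed)
  pop <- sensory_population(beta = p$beta %||% seq(-2, 2, length.out = 10),
                            kernel = "exponential")
  rec <- emit_spikes(pop, z_true, dt = 1, seed = seed)
  params <- scn_params(lambda = p$lambda %||% 10, dt = p$dt %||% 1e-4,
                       tau_s = p$tau_s %||% 0.01)
  D <- line_decoder(p$N %||% 20, p$norm %||% 0.1)
  net <- build_inference_network(pop, rec, D, params)
  sim <- simulate_network(net, duration = p$duration %||% 20, seed = seed + 1)
  th <- thin_samples(sim$readout[, 1], params$dt, params$tau_s,
                     burn_in = p$burn_in %||% 0.5)
  post <- posterior_quadrature(pop, rec$counts[1, ], dt = 1, -3, 5, 2001)
  pm <- posterior_moments(post)
  utils::write.csv(data.frame(t = sim$t, z = sim$readout[, 1]),
                   file.path(out_dir, "samples.csv"), row.names = FALSE)
  utils::write.csv(post, file.path(out_dir, "posterior.csv"),
                   row.names = FALSE)
  list(z_true = z_true, counts = as.integer(rec$counts[1, ]),
       sample_mean = mean(th), sample_sd = stats::sd(th),
       posterior_mean = pm$mean, posterior_sd = pm$sd,
       mean_rel_err = abs(mean(th) - pm$mean) / abs(pm$mean),
       sd_rel_err = abs(stats::sd(th) - pm$sd) / pm$sd)
}

# shared head-direction run: returns sim + decoded data frame
hd_run <- function(p, seed, noise = TRUE) {
  cfg <- hd_config(rho = p$rho %||% 1, b = p$b %||% 100,
                   n_inputs = p$n_inputs %||% 10, dt = p$dt %||% 1e-3)
  traj <- make_trajectory("constant", list(omega = p$omega %||% 1),
                          duration = p$duration %||% 10, dt = cfg$dt)
  rec <- encode_velocity(traj, cfg, seed = seed)
  params <- scn_params(lambda = p$lambda %||% 10, dt = p$net_dt %||% 1e-4,
                       tau_s = 1)
  D <- ring_decoder(p$N %||% 8, rho = cfg$rho)
  net <- build_hd_network(cfg, D, params, rec, noise = noise)
  r_fix <- sqrt(cfg$ring_k) * cfg$rho
  r0 <- init_trains_at(D, c(r_fix, 0))
  sim <- simulate_network(net, seed = seed + 1, r0 = r0,
                          record_v = TRUE, record_r = TRUE)
  dec <- decode_angle(sim)
  list(cfg = cfg, traj = traj, rec = rec, D = D, params = params,
       sim = sim, dec = dec)
}

exp_hd_darkness <- function(p, seed, out_dir) {
  run <- hd_run(p, seed)
  # decoded series at the network step; align to the encoder step
  stride <- as.integer(round(run$cfg$dt / run$params$dt))
  dec <- run$dec[seq(stride, nrow(run$dec), by = stride), ]
  out <- data.frame(t = run$traj$t, theta_true = run$traj$theta,
                    theta_hat = dec$theta_hat, radius = dec$radius)
  utils::write.csv(out, file.path(out_dir, "decoded.csv"),
                   row.names = FALSE)
  burn <- run$traj$t > 0.5
  vel <- mean(wrap_diff(dec$theta_hat)) / run$cfg$dt
  list(omega = p$omega %||% 1, mean_decoded_velocity = vel,
       velocity_ratio = vel / (p$omega %||% 1),
       mean_abs_error = mean(circ_dist(dec$theta_hat[burn],
                                       run$traj$theta[burn])),
       mean_radius = mean(dec$radius[burn]), n_spikes = run$sim$n_spikes)
}

exp_hd_reset <- function(p, seed, out_dir) {
  cfg <- hd_config(rho = p$rho %||% 1, dt = p$dt %||% 1e-3,
                   landmark = list(c = p$landmark_gain %||% 20))
  n <- as.integer(round((p$duration %||% 0.5) / cfg$dt))
  rec <- structure(list(counts = matrix(1L, n, length(cfg$beta)),
                        dt = cfg$dt), class = "spike_record")
  r_fix <- sqrt(cfg$ring_k) * cfg$rho
  start <- c(0, r_fix) # displaced by pi/2 from the landmark at angle 0
  path <- simulate_hd_map(rec, cfg, xy0 = start, seed = seed, reset = TRUE)
  err <- circ_dist(path$theta_hat, 0)
  utils::write.csv(cbind(path, error = err),
                   file.path(out_dir, "reset.csv"), row.names = FALSE)
  qs <- seq(1, min(301, n), by = 50) # the reset transient
  list(initial_error = pi / 2, error_checkpoints = err[qs],
       final_error = err[n],
       reset_spikes = sum(attr(path, "reset_counts")))
}

exp_predictions <- function(p, seed, out_dir) {
  p$duration <- p$duration %||% 20
  run <- hd_run(p, seed)
  sim <- run$sim
  stride <- as.integer(round(run$cfg$dt / run$params$dt))
  idx <- seq(stride, length(sim$t), by = stride) # align to encoder steps
  S <- spike_matrix(sim)
  c2 <- spike_corr_two_scales(S, run$params$dt)
  vx <- voltage_xcorr(sim$v, max_lag = 0, dt = run$params$dt)
  tc <- tuning_curves(sim$r[idx, ], run$traj$theta,
                      n_bins = p$n_bins %||% 36)
  bv <- bump_velocity_stats(run$dec$theta_hat[idx], run$traj$omega,
                            run$cfg$dt, window = p$window %||% 20)
  utils::write.csv(vx, file.path(out_dir, "voltage_xcorr.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(tc), file.path(out_dir, "tuning.csv"),
                   row.names = FALSE)
  utils::write.csv(bv$stats, file.path(out_dir, "bump_velocity.csv"),
                   row.names = FALSE)
  lag0 <- vx[vx$i != vx$j, ]
  omega_f <- build_fast_weights(run$D)
  list(localization = bump_localization(sim$r),
       tuning_dispersion = tuning_dispersion(tc),
       bump_velocity = as.list(bv$stats[1, ]),
       n_opposite_pairs_negative =
         sum(lag0$cor[abs(lag0$j - lag0$i) == ncol(run$D) / 2] < 0),
       fast_weight_range = range(omega_f[upper.tri(omega_f)]))
}
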