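#' Synthetic head-direction trajectory
#'
#' Generates an angular-velocity series `omega(t)` and integrates it into
#' a wrapped heading `theta(t)`, `theta[k+1] = wrap(theta[k] + omega[k] dt)`.
#'
#' Kinds: `"constant"` (`params$omega`), `"piecewise"` (step function:
#' `params$times`, `params$values`), `"ou"` (Ornstein-Uhlenbeck velocity
#' with timescale `params$tau`, stationary sd `params$sigma`, mean
#' `params$mean`), `"sinusoid"` (`params$amplitude`, `params$period`,
#' `params$phase`).
#'
#' @param kind trajectory family.
#' @param params list of kind-specific parameters.
#' @param duration total time, s.
#' @param dt step, s.
#' @param seed integer seed (used by the `"ou"` kind).
#' @param theta0 initial heading, rad.
#' @return data frame `(t, theta, omega)` of class `hd_trajectory`,
#'   with `t` starting at 0.
#' @export
make_trajectory <- function(kind = c("constant", "piecewise", "ou",
                                     "sinusoid"),
                            params = list(), duration = 1, dt = 1e-3,
                            seed = NULL, theta0 = 0) {
  kind <- match.arg(kind)
  if (duration < dt) stop("duration must be at least dt")
  n <- as.integer(round(duration / dt))
  t <- (seq_len(n) - 1L) * dt
  if (!is.null(seed)) set.seed(seed)
  omega <- switch(kind,
    constant = rep(params$omega %||% 0, n),
    piecewise = {
      times <- params$times %||% 0
      values <- params$values %||% 0
      if (length(values) != length(times))
        stop("piecewise needs matching times and values")
      values[findInterval(t, times)]
    },
    ou = {
      tau <- params$tau %||% 0.5
      sigma <- params$sigma %||% 2
      mu <- params$mean %||% 0
      a <- exp(-dt / tau)
      innov <- sigma * sqrt(1 - a^2) * stats::rnorm(n)
      innov[1] <- sigma * stats::rnorm(1) # stationary start
      mu + as.numeric(stats::filter(innov, a, method = "recursive"))
    },
    sinusoid = {
      amp <- params$amplitude %||% 1
      per <- params$period %||% 1
      ph <- params$phase %||% 0
      amp * sin(2 * pi * t / per + ph)
    }
  )
  # stepwise wrapped integration == wrap of the cumulative sum (mod 2 pi)
  theta <- wrap_angle(theta0 + cumsum(c(0, omega[-n])) * dt)
  out <- data.frame(t = t, theta = theta, omega = omega)
  class(out) <- c("hd_trajectory", "data.frame")
  attr(out, "dt") <- dt
  attr(out, "seed") <- seed
  out
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write an end-to-end synthetic fixture
#'
#' Writes a trajectory CSV, a sparse spike-count CSV `(t, neuron, count)`
#' produced by a sensory population observing the trajectory's angular
#' velocity, and a JSON manifest holding every parameter and seed.  The
#' files round-trip bit-exactly through [read_trajectory()] and
#' [read_spike_record()].
#'
#' @param trajectory an `hd_trajectory`.
#' @param pop a [sensory_population()] observing `omega`, or an
#'   [hd_config()] whose encoder is used instead.
#' @param seed integer seed for the spike emission.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest as a list.
#' @export
make_fixture <- function(trajectory, pop, seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dt <- attr(trajectory, "dt") %||% (trajectory$t[2] - trajectory$t[1])

  traj_path <- file.path(dir, "trajectory.csv")
  df <- data.frame(t = fmt_num(trajectory$t), theta = fmt_num(trajectory$theta),
                   omega = fmt_num(trajectory$omega))
  utils::write.csv(df, traj_path, row.names = FALSE, quote = FALSE)

  if (inherits(pop, "hd_config")) {
    rec <- encode_velocity(trajectory$omega, pop, seed = seed)
    pop_desc <- list(type = "hd_encoder", beta = pop$beta, dt = pop$dt)
  } else {
    rec <- emit_spikes(pop, trajectory$omega, dt = dt, seed = seed)
    pop_desc <- list(type = "sensory_pop", kernel = pop$kernel,
                     noise = pop$noise, beta = pop$beta, r0 = pop$r0,
                     size = pop$size)
  }
  idx <- which(rec$counts > 0, arr.ind = TRUE)
  spikes_path <- file.path(dir, "spikes.csv")
  sp <- data.frame(t = fmt_num((idx[, 1] - 1L) * rec$dt),
                   neuron = idx[, 2],
                   count = rec$counts[idx])
  sp <- sp[order(idx[, 1], idx[, 2]), , drop = FALSE]
  utils::write.csv(sp, spikes_path, row.names = FALSE, quote = FALSE)

  manifest <- list(
    dt = dt, n_steps = nrow(trajectory), n_neurons = ncol(rec$counts),
    seed = seed, trajectory_seed = attr(trajectory, "seed"),
    population = pop_desc,
    files = list(trajectory = basename(traj_path),
                 spikes = basename(spikes_path))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a trajectory fixture
#' @param dir fixture directory (or a trajectory CSV path).
#' @return an `hd_trajectory` data frame.
#' @export
read_trajectory <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "trajectory.csv") else dir
  df <- utils::read.csv(path, colClasses = "character")
  out <- data.frame(t = as.numeric(df$t), theta = as.numeric(df$theta),
                    omega = as.numeric(df$omega))
  class(out) <- c("hd_trajectory", "data.frame")
  attr(out, "dt") <- out$t[2] - out$t[1]
  out
}

#' Read a spike-record fixture
#' @param dir fixture directory containing `spikes.csv` and
#'   `manifest.json`.
#' @return a `spike_record` (dense counts matrix).
#' @export
read_spike_record <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sp <- utils::read.csv(file.path(dir, "spikes.csv"),
                        colClasses = c("character", "integer", "integer"))
  counts <- matrix(0L, manifest$n_steps, manifest$n_neurons)
  if (nrow(sp) > 0) {
    rows <- as.integer(round(as.numeric(sp$t) / manifest$dt)) + 1L
    counts[cbind(rows, sp$neuron)] <- sp$count
  }
  structure(list(counts = counts, dt = manifest$dt, pop = NULL,
                 seed = manifest$seed),
            class = "spike_record")
}
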