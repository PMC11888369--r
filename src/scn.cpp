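#include <Rcpp.h>
using namespace Rcpp;

// Kronecker power of a vector: out = z^{(x) d}, length M^d (row-major block
// layout, consistent with base::kronecker()).
static std::vector<double> kron_power_vec(const std::vector<double>& z, int d) {
  std::vector<double> out(1, 1.0);
  for (int k = 0; k < d; ++k) {
    std::vector<double> nxt(out.size() * z.size());
    size_t idx = 0;
    for (size_t i = 0; i < out.size(); ++i)
      for (size_t j = 0; j < z.size(); ++j)
        nxt[idx++] = out[i] * z[j];
    out.swap(nxt);
  }
  return out;
}

// Greedy spike rule: index (0-based) of the neuron with the largest positive
// threshold violation v_i - T_i, or -1 if none; ties broken by lowest index.
static int greedy_spike(const std::vector<double>& v,
                        const NumericVector& thr) {
  int best = -1;
  double best_viol = 0.0;
  for (size_t i = 0; i < v.size(); ++i) {
    double viol = v[i] - thr[i];
    if (viol > 0.0 && viol > best_viol) {
      best_viol = viol;
      best = (int)i;
    }
  }
  return best;
}

// Euler-Maruyama integration of a spike-coding network.
//
// Voltage update (one spike at most per step, carried by the fast weights
// Omega_f = -D^T D; no explicit reset):
//   v <- v + dt * (-lambda v + D^T F(z, sigma_t) + mu lambda^2 r)
//        + Omega_f[, spike] - mu lambda e_spike + amp sqrt(dt) D^T xi
//   r <- r - dt lambda r + spike_increment * e_spike
//   z = readout_scale * D r
//
// Drift families F(z, sigma):
//  "poly":          F = sum_d C_d z^{(x)d}            (C_d prepared in R)
//  "exp_inference": F = -(1/tau_s) sum_i b_i (exp(b_i.z) - sigma_i) + lambda z
//  "hd":            F = (b^T (sigma - 1)/alpha) (z2, -z1) / 1
//                       - (gamma/alpha) z (|z|^2 - k rho^2) + lambda z
//                       [+ reset term, k = 2 literal / 1 exact-gradient]
// [[Rcpp::export(name = ".scn_simulate_cpp")]]
List scn_simulate_cpp(NumericMatrix D, int n_steps, double dt, double lambda,
                      NumericVector thresholds, double mu,
                      std::string drift_type, List drift_pars,
                      double noise_amp, Nullable<NumericMatrix> noise_path,
                      NumericVector v0, NumericVector r0,
                      double spike_increment, double readout_scale,
                      int record_every, bool record_v, bool record_r,
                      double divergence_bound) {
  const int M = D.nrow(), N = D.ncol();
  if ((int)v0.size() != N || (int)r0.size() != N)
    stop("v0/r0 length must equal the number of neurons");
  if (n_steps < 1) stop("n_steps must be >= 1");

  // fast weights Omega_f = -D^T D
  NumericMatrix omega_f(N, N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) {
      double s = 0.0;
      for (int m = 0; m < M; ++m) s += D(m, i) * D(m, j);
      omega_f(i, j) = -s;
    }

  // drift parameters
  enum { POLY, EXPINF, HD } type;
  std::vector<NumericMatrix> coeffs;  // poly
  int degree = 0;
  NumericMatrix beta;   // exp_inference: Np x M
  IntegerMatrix counts; // observation stream (n_obs x Np)
  int stride = 1;
  double rate_scale = 1.0; // observation-window factor on Poisson rates
  double tau_s = 1.0, alpha = 1.0, gamma = 4.0, rho = 1.0;
  double ring_k = 2.0;  // literal (2 rho^2) vs exact gradient (rho^2)
  bool reset_on = false;
  double c_reset = 0.0, r_lm = 0.0;
  NumericVector beta_hd; // hd: length Np

  if (drift_type == "poly") {
    type = POLY;
    List cl = drift_pars["coeffs"];
    degree = cl.size() - 1;
    for (int d = 0; d <= degree; ++d) {
      NumericMatrix A = cl[d];
      if (A.nrow() != M) stop("poly coefficient matrix row count must be M");
      coeffs.push_back(A);
    }
  } else if (drift_type == "exp_inference") {
    type = EXPINF;
    beta = as<NumericMatrix>(drift_pars["beta"]);
    counts = as<IntegerMatrix>(drift_pars["counts"]);
    stride = as<int>(drift_pars["stride"]);
    tau_s = as<double>(drift_pars["tau_s"]);
    rate_scale = as<double>(drift_pars["rate_scale"]);
    if (beta.ncol() != M) stop("beta column count must equal readout dim");
    if (counts.ncol() != beta.nrow()) stop("counts/beta dimension mismatch");
  } else if (drift_type == "hd") {
    type = HD;
    if (M != 2) stop("hd drift requires readout dimension 2");
    beta_hd = as<NumericVector>(drift_pars["beta"]);
    counts = as<IntegerMatrix>(drift_pars["counts"]);
    stride = as<int>(drift_pars["stride"]);
    alpha = as<double>(drift_pars["alpha"]);
    gamma = as<double>(drift_pars["gamma"]);
    rho = as<double>(drift_pars["rho"]);
    ring_k = as<double>(drift_pars["ring_k"]);
    reset_on = as<bool>(drift_pars["reset_on"]);
    if (reset_on) {
      c_reset = as<double>(drift_pars["c_reset"]);
      r_lm = as<double>(drift_pars["r_lm"]);
    }
    if (counts.ncol() != beta_hd.size()) stop("counts/beta dimension mismatch");
  } else {
    stop("unknown drift type '%s'", drift_type.c_str());
  }

  bool have_noise_path = noise_path.isNotNull();
  NumericMatrix np_mat;
  if (have_noise_path) {
    np_mat = as<NumericMatrix>(noise_path);
    if (np_mat.nrow() < n_steps || np_mat.ncol() != M)
      stop("noise_path must be n_steps x M");
  }

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> r(r0.begin(), r0.end());
  std::vector<double> z(M), drift_z(M), drift_v(N);

  NumericMatrix readout(n_steps, M);
  IntegerVector spikes(n_steps);
  int n_rec = record_every > 0 ? (n_steps + record_every - 1) / record_every : 0;
  NumericMatrix v_rec(record_v ? n_rec : 0, record_v ? N : 0);
  NumericMatrix r_rec(record_r ? n_rec : 0, record_r ? N : 0);
  IntegerVector reset_counts(reset_on ? counts.nrow() : 0);

  RNGScope rng;
  int obs_row = -1, sigma_reset = 0;
  long n_spikes = 0;

  for (int t = 0; t < n_steps; ++t) {
    // readout from current filtered trains
    for (int m = 0; m < M; ++m) {
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += D(m, i) * r[i];
      z[m] = readout_scale * s;
    }

    // advance the observation stream
    if (type != POLY && t % stride == 0) {
      obs_row = t / stride;
      if (obs_row >= counts.nrow())
        stop("observation stream shorter than the simulation");
      if (reset_on) {
        double d2 = (z[0] - r_lm) * (z[0] - r_lm) + z[1] * z[1];
        sigma_reset = (int)R::rpois(c_reset * std::exp(-d2));
        reset_counts[obs_row] = sigma_reset;
      }
    }

    // drift in readout space
    if (type == POLY) {
      std::fill(drift_z.begin(), drift_z.end(), 0.0);
      for (int d = 0; d <= degree; ++d) {
        std::vector<double> zd = kron_power_vec(z, d);
        const NumericMatrix& A = coeffs[d];
        for (int m = 0; m < M; ++m) {
          double s = 0.0;
          for (size_t j = 0; j < zd.size(); ++j) s += A(m, j) * zd[j];
          drift_z[m] += s;
        }
      }
    } else if (type == EXPINF) {
      std::fill(drift_z.begin(), drift_z.end(), 0.0);
      const int Np = beta.nrow();
      for (int i = 0; i < Np; ++i) {
        double bz = 0.0;
        for (int m = 0; m < M; ++m) bz += beta(i, m) * z[m];
        double w = rate_scale * std::exp(bz) - counts(obs_row, i);
        for (int m = 0; m < M; ++m) drift_z[m] += beta(i, m) * w;
      }
      for (int m = 0; m < M; ++m)
        drift_z[m] = -drift_z[m] / tau_s + lambda * z[m];
    } else { // HD
      double binp = 0.0;
      const int Np = beta_hd.size();
      for (int i = 0; i < Np; ++i)
        binp += beta_hd[i] * (counts(obs_row, i) - 1.0);
      binp /= alpha;
      double s2 = z[0] * z[0] + z[1] * z[1];
      // attractor enters the voltage equation unscaled by alpha (the
      // low-D map divides it by alpha; both share the same fixed point,
      // but the spiking network needs the full-strength restoring force
      // to hold its readout on the ring against spike quantization)
      double att = -gamma * (s2 - ring_k * rho * rho);
      // positive encoded velocity advances the decoded angle (CCW)
      drift_z[0] = -binp * z[1] + att * z[0] + lambda * z[0];
      drift_z[1] = binp * z[0] + att * z[1] + lambda * z[1];
      if (reset_on) {
        double dx = z[0] - r_lm;
        double g = std::exp(-dx * dx - z[1] * z[1]) - 2.0 * sigma_reset;
        drift_z[0] += 2.0 * dx * g;
        drift_z[1] += 2.0 * z[1] * g;
      }
    }

    // lift to neuron space
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int m = 0; m < M; ++m) s += D(m, i) * drift_z[m];
      drift_v[i] = s + mu * lambda * lambda * r[i];
    }

    // greedy spike from the current voltages
    int sp = greedy_spike(v, thresholds);
    spikes[t] = sp + 1; // 0 = no spike
    if (sp >= 0) ++n_spikes;

    // voltage / filtered-train update
    double xi_m;
    for (int i = 0; i < N; ++i) {
      double dv = dt * (-lambda * v[i] + drift_v[i]);
      if (sp >= 0) {
        // voltage kick tracks the readout jump: zhat jumps by
        // readout_scale * spike_increment * D_sp = D_sp in both variants
        dv += omega_f(i, sp) * spike_increment * readout_scale;
        if (i == sp) dv -= mu * lambda * spike_increment;
      }
      v[i] += dv;
    }
    if (noise_amp > 0.0) {
      for (int m = 0; m < M; ++m) {
        xi_m = have_noise_path ? np_mat(t, m) : R::norm_rand();
        double a = noise_amp * std::sqrt(dt) * xi_m;
        for (int i = 0; i < N; ++i) v[i] += D(m, i) * a;
      }
    }
    for (int i = 0; i < N; ++i) r[i] -= dt * lambda * r[i];
    if (sp >= 0) r[sp] += spike_increment;

    // record post-update readout
    for (int m = 0; m < M; ++m) {
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += D(m, i) * r[i];
      readout(t, m) = readout_scale * s;
    }
    if (record_every > 0 && t % record_every == 0) {
      int row = t / record_every;
      if (record_v) for (int i = 0; i < N; ++i) v_rec(row, i) = v[i];
      if (record_r) for (int i = 0; i < N; ++i) r_rec(row, i) = r[i];
    }

    // stability guard
    double znorm = 0.0;
    for (int m = 0; m < M; ++m) znorm += readout(t, m) * readout(t, m);
    if (!std::isfinite(znorm))
      stop("simulation instability: non-finite readout at step %d", t + 1);
    if (divergence_bound > 0.0 && znorm > divergence_bound * divergence_bound)
      stop("simulation instability: |readout| exceeded bound %.3g at step %d",
           divergence_bound, t + 1);
    for (int i = 0; i < N; ++i)
      if (!std::isfinite(v[i]))
        stop("simulation instability: non-finite voltage, neuron %d, step %d",
             i + 1, t + 1);
  }

  List out = List::create(
      _["readout"] = readout, _["spikes"] = spikes,
      _["n_spikes"] = (double)n_spikes,
      _["v_final"] = NumericVector(v.begin(), v.end()),
      _["r_final"] = NumericVector(r.begin(), r.end()));
  if (record_v) out["v"] = v_rec;
  if (record_r) out["r"] = r_rec;
  if (reset_on) out["reset_counts"] = reset_counts;
  return out;
}

// Direct Euler-Maruyama Langevin integrator (non-spiking reference):
//   dz = -(1/tau_s) grad U(z) dt + noise_amp sqrt(2 dt / tau_s) xi
// with grad U given as per-degree coefficient matrices.
// [[Rcpp::export(name = ".langevin_path_cpp")]]
NumericMatrix langevin_path_cpp(List coeffs, NumericVector z0, int n_steps,
                                double dt, double tau_s, double noise_amp,
                                double divergence_bound) {
  const int M = z0.size();
  int degree = coeffs.size() - 1;
  std::vector<NumericMatrix> A;
  for (int d = 0; d <= degree; ++d) A.push_back(as<NumericMatrix>(coeffs[d]));

  NumericMatrix path(n_steps, M);
  std::vector<double> z(z0.begin(), z0.end());
  double amp = noise_amp * std::sqrt(2.0 * dt / tau_s);
  RNGScope rng;

  for (int t = 0; t < n_steps; ++t) {
    std::vector<double> grad(M, 0.0);
    for (int d = 0; d <= degree; ++d) {
      std::vector<double> zd = kron_power_vec(z, d);
      for (int m = 0; m < M; ++m) {
        double s = 0.0;
        for (size_t j = 0; j < zd.size(); ++j) s += A[d](m, j) * zd[j];
        grad[m] += s;
      }
    }
    double nrm = 0.0;
    for (int m = 0; m < M; ++m) {
      z[m] += -dt / tau_s * grad[m];
      if (amp > 0.0) z[m] += amp * R::norm_rand();
      path(t, m) = z[m];
      nrm += z[m] * z[m];
    }
    if (!std::isfinite(nrm) ||
        (divergence_bound > 0 && nrm > divergence_bound * divergence_bound))
      stop("Langevin path diverged (|z| > %.3g) at step %d", divergence_bound,
           t + 1);
  }
  return path;
}

// Low-dimensional head-direction map (Cartesian sampler), Euler-discretized:
//   z <- z + dt (b^T (sigma - 1)/alpha) (y, -x)
//          - (gamma dt / alpha) z (|z|^2 - k rho^2)
//          [+ 2 dt (x - r_lm, y) (exp(-(x-r_lm)^2 - y^2) - 2 sigma_reset)]
//          + noise_amp sqrt(2 dt / alpha) xi
// One count row per step.
// [[Rcpp::export(name = ".hd_map_cpp")]]
List hd_map_cpp(NumericVector z0, IntegerMatrix counts, NumericVector beta,
                double dt, double alpha, double gamma, double rho,
                double ring_k, double noise_amp,
                Nullable<NumericMatrix> noise_path, bool reset_on,
                double c_reset, double r_lm,
                Nullable<IntegerVector> reset_stream) {
  const int n_steps = counts.nrow();
  const int Np = counts.ncol();
  if ((int)beta.size() != Np) stop("beta length must match counts columns");
  bool have_noise = noise_path.isNotNull();
  NumericMatrix np_mat;
  if (have_noise) {
    np_mat = as<NumericMatrix>(noise_path);
    if (np_mat.nrow() < n_steps || np_mat.ncol() != 2)
      stop("noise_path must be n_steps x 2");
  }
  bool have_reset_stream = reset_stream.isNotNull();
  IntegerVector rs;
  if (have_reset_stream) rs = as<IntegerVector>(reset_stream);

  NumericMatrix path(n_steps, 2);
  IntegerVector reset_counts(reset_on ? n_steps : 0);
  double x = z0[0], y = z0[1];
  double amp = noise_amp * std::sqrt(2.0 * dt / alpha);
  RNGScope rng;

  for (int t = 0; t < n_steps; ++t) {
    double binp = 0.0;
    for (int i = 0; i < Np; ++i) binp += beta[i] * (counts(t, i) - 1.0);
    binp /= alpha;
    double s2 = x * x + y * y;
    double att = -(gamma * dt / alpha) * (s2 - ring_k * rho * rho);
    double dx = -dt * binp * y + att * x;
    double dy = dt * binp * x + att * y;
    if (reset_on) {
      double ex = x - r_lm;
      double d2 = ex * ex + y * y;
      int sr = have_reset_stream ? rs[t]
                                 : (int)R::rpois(c_reset * std::exp(-d2));
      reset_counts[t] = sr;
      double g = std::exp(-d2) - 2.0 * sr;
      dx += 2.0 * dt * ex * g;
      dy += 2.0 * dt * y * g;
    }
    if (amp > 0.0) {
      dx += amp * (have_noise ? np_mat(t, 0) : R::norm_rand());
      dy += amp * (have_noise ? np_mat(t, 1) : R::norm_rand());
    }
    x += dx;
    y += dy;
    if (!std::isfinite(x) || !std::isfinite(y))
      stop("head-direction map diverged at step %d", t + 1);
    path(t, 0) = x;
    path(t, 1) = y;
  }
  List out = List::create(_["path"] = path);
  if (reset_on) out["reset_counts"] = reset_counts;
  return out;
}
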