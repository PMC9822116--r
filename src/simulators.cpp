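#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// softplus transfer f(h) = r*a*log(1+exp((h-h0)/a)), threshold-linear at a=0;
// piecewise form keeps 1e-12 relative accuracy without overflow
static inline double transfer(double h, double r, double a, double h0) {
  if (a == 0.0) {
    double d = h - h0;
    return d > 0.0 ? r * d : 0.0;
  }
  double z = (h - h0) / a;
  double sp = (z > 30.0) ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z));
  return r * a * sp;
}

// coupling drive c_a = (1/M) * sum_b J_ab * D_b with J = U V^T - J0
// evaluated in O(M*C) through the factors (C = 2K + DC)
static void coupling_lowrank(const NumericMatrix &U, const NumericMatrix &V,
                             double J0, const std::vector<double> &D,
                             std::vector<double> &out) {
  const int M = U.nrow(), C = U.ncol();
  double sumD = 0.0;
  for (int b = 0; b < M; ++b) sumD += D[b];
  std::vector<double> proj(C, 0.0);
  for (int c = 0; c < C; ++c) {
    double s = 0.0;
    for (int b = 0; b < M; ++b) s += V(b, c) * D[b];
    proj[c] = s;
  }
  for (int a = 0; a < M; ++a) {
    double s = -J0 * sumD;
    for (int c = 0; c < C; ++c) s += U(a, c) * proj[c];
    out[a] = s / M;
  }
}

static void coupling_dense(const NumericMatrix &J, const std::vector<double> &D,
                           std::vector<double> &out) {
  const int M = J.nrow();
  for (int a = 0; a < M; ++a) {
    double s = 0.0;
    for (int b = 0; b < M; ++b) s += J(a, b) * D[b];
    out[a] = s / M;
  }
}

// Mesoscopic / macroscopic integrator.
// kind: 0 = jump-diffusion (state m2 = y), 1 = diffusion (m2 = Q), 2 = macro.
// N = R_PosInf disables all noise (thermodynamic limit) for kinds 0/1.
// Ito convention: every drift and noise coefficient uses the state at t-.
// [[Rcpp::export]]
List sim_meso_cpp(int kind, double N, double T, double dt, int record_every,
                  double tau, double tauD, double U0,
                  double r, double a, double h0,
                  NumericVector mu,
                  NumericMatrix U, NumericMatrix V, double J0,
                  bool use_dense, NumericMatrix Jdense,
                  NumericVector h_init, NumericVector x_init,
                  NumericVector m2_init,
                  bool record_A, bool record_h, bool record_x,
                  bool record_m2) {
  const int M = h_init.size();
  const bool noise = (kind != 2) && R_finite(N);
  const long n_steps_raw = (long) std::floor(T / dt + 0.5);
  const long nrec = n_steps_raw / record_every;
  const long n_steps = nrec * record_every;
  const double sqdt = std::sqrt(dt);

  std::vector<double> h(h_init.begin(), h_init.end());
  std::vector<double> x(x_init.begin(), x_init.end());
  std::vector<double> m2(m2_init.begin(), m2_init.end());
  std::vector<double> fh(M), D(M), coup(M), Aacc(M, 0.0);

  NumericMatrix Arec(record_A ? nrec : 0, record_A ? M : 0);
  NumericMatrix hrec(record_h ? nrec : 0, record_h ? M : 0);
  NumericMatrix xrec(record_x ? nrec : 0, record_x ? M : 0);
  NumericMatrix m2rec(record_m2 ? nrec : 0, record_m2 ? M : 0);

  long clamp_x = 0, clamp_m2 = 0, fdt_warn = 0;
  long irec = 0;

  for (long k = 0; k < n_steps; ++k) {
    for (int b = 0; b < M; ++b) {
      fh[b] = transfer(h[b], r, a, h0);
      if (fh[b] * dt > 0.1) ++fdt_warn;
      double A;
      if (kind == 0 && noise) {
        double dn = R::rpois(N * fh[b] * dt);
        A = dn / (N * dt);
        double yb = m2[b] > 0.0 ? m2[b] : 0.0;
        D[b] = x[b] * A + std::sqrt(yb * fh[b] / N) * norm_rand() * sqdt / dt;
      } else if (kind == 1 && noise) {
        double Qb = m2[b] > 0.0 ? m2[b] : 0.0;
        A = fh[b];
        D[b] = x[b] * fh[b] +
               std::sqrt(Qb * fh[b] / N) * norm_rand() * sqdt / dt;
      } else {  // macro or N = Inf
        A = fh[b];
        D[b] = x[b] * fh[b];
      }
      Aacc[b] += A * dt;
    }
    if (use_dense) coupling_dense(Jdense, D, coup);
    else coupling_lowrank(U, V, J0, D, coup);

    for (int b = 0; b < M; ++b) {
      h[b] += (mu[b] - h[b]) / tau * dt + U0 * coup[b] * dt;
      double xn = x[b] + (1.0 - x[b]) / tauD * dt - U0 * D[b] * dt;
      if (xn < 0.0) { xn = 0.0; ++clamp_x; }
      else if (xn > 1.0) { xn = 1.0; ++clamp_x; }
      if (kind == 0) {
        double yn = m2[b] +
          (-(2.0 / tauD + U0 * (2.0 - U0) * fh[b]) * m2[b] +
           U0 * U0 * x[b] * x[b] * fh[b]) * dt;
        if (yn < 0.0) { yn = 0.0; ++clamp_m2; }
        m2[b] = yn;
      } else if (kind == 1) {
        double Qn = m2[b] + (2.0 * (x[b] - m2[b]) / tauD -
                             U0 * (2.0 - U0) * m2[b] * fh[b]) * dt;
        if (Qn < 0.0) { Qn = 0.0; ++clamp_m2; }
        else if (Qn > 1.0) { Qn = 1.0; ++clamp_m2; }
        m2[b] = Qn;
      }
      x[b] = xn;
      if (!R_finite(h[b]))
        stop("non-finite state at step %ld (population %d)", k + 1, b + 1);
    }

    if ((k + 1) % record_every == 0) {
      const double denom = record_every * dt;
      for (int b = 0; b < M; ++b) {
        if (record_A) Arec(irec, b) = Aacc[b] / denom;
        Aacc[b] = 0.0;
        if (record_h) hrec(irec, b) = h[b];
        if (record_x) xrec(irec, b) = x[b];
        if (record_m2) m2rec(irec, b) = m2[b];
      }
      ++irec;
    }
  }

  return List::create(_["A"] = Arec, _["h"] = hrec, _["x"] = xrec,
                      _["m2"] = m2rec, _["n_steps"] = (double) n_steps,
                      _["clamp_x"] = (double) clamp_x,
                      _["clamp_m2"] = (double) clamp_m2,
                      _["fdt_warn"] = (double) fdt_warn,
                      _["h_final"] = NumericVector(h.begin(), h.end()),
                      _["x_final"] = NumericVector(x.begin(), x.end()),
                      _["m2_final"] = NumericVector(m2.begin(), m2.end()));
}

// Microscopic LNP network with per-neuron depression (and optionally
// Tsodyks-Markram facilitation). Bernoulli spike generation per neuron per
// step; one shared input potential per population.
// [[Rcpp::export]]
List sim_micro_cpp(int N, double T, double dt, int record_every,
                   double tau, double tauD, double U0,
                   bool facil, double tauF, double Ufac,
                   double r, double a, double h0,
                   NumericVector mu,
                   NumericMatrix U, NumericMatrix V, double J0,
                   bool use_dense, NumericMatrix Jdense,
                   NumericVector h_init, double x_init_val,
                   bool record_h, bool record_x, bool record_Q,
                   bool record_raster) {
  const int M = h_init.size();
  const long n_steps_raw = (long) std::floor(T / dt + 0.5);
  const long nrec = n_steps_raw / record_every;
  const long n_steps = nrec * record_every;

  std::vector<double> h(h_init.begin(), h_init.end());
  std::vector<double> x((size_t) M * N, x_init_val);
  std::vector<double> u;
  if (facil) u.assign((size_t) M * N, U0);
  std::vector<double> fh(M), S(M), coup(M);
  std::vector<double> Aacc(M, 0.0);

  NumericMatrix Arec(nrec, M);
  NumericMatrix hrec(record_h ? nrec : 0, record_h ? M : 0);
  NumericMatrix xrec(record_x ? nrec : 0, record_x ? M : 0);
  NumericMatrix urec((facil && record_x) ? nrec : 0,
                     (facil && record_x) ? M : 0);
  NumericMatrix Qrec(record_Q ? nrec : 0, record_Q ? M : 0);
  std::vector<double> ras_t;
  std::vector<int> ras_id;

  long fdt_warn = 0, irec = 0;

  for (long k = 0; k < n_steps; ++k) {
    for (int b = 0; b < M; ++b) {
      fh[b] = transfer(h[b], r, a, h0);
      double p = fh[b] * dt;
      if (p > 1.0)
        stop("spike probability f(h)*dt > 1 at step %ld (population %d)",
             k + 1, b + 1);
      if (p > 0.1) ++fdt_warn;
      double s = 0.0;
      int dn = 0;
      const size_t off = (size_t) b * N;
      for (int j = 0; j < N; ++j) {
        if (unif_rand() < p) {
          const size_t ij = off + j;
          double rel = facil ? u[ij] * x[ij] : U0 * x[ij];  // at t-
          s += rel;
          x[ij] -= rel;
          if (facil) u[ij] += Ufac * (1.0 - u[ij]);
          ++dn;
          if (record_raster) {
            ras_t.push_back((k + 1) * dt);
            ras_id.push_back(b * N + j + 1);
          }
        }
      }
      S[b] = s / N;  // population-summed release per neuron
      Aacc[b] += (double) dn;
    }
    if (use_dense) coupling_dense(Jdense, S, coup);
    else coupling_lowrank(U, V, J0, S, coup);

    for (int b = 0; b < M; ++b) {
      h[b] += (mu[b] - h[b]) / tau * dt + coup[b];  // jumps carry no dt
      const size_t off = (size_t) b * N;
      for (int j = 0; j < N; ++j) {
        x[off + j] += (1.0 - x[off + j]) / tauD * dt;
        if (facil) u[off + j] += (U0 - u[off + j]) / tauF * dt;
      }
      if (!R_finite(h[b]))
        stop("non-finite state at step %ld (population %d)", k + 1, b + 1);
    }

    if ((k + 1) % record_every == 0) {
      const double denom = (double) N * record_every * dt;
      for (int b = 0; b < M; ++b) {
        Arec(irec, b) = Aacc[b] / denom;
        Aacc[b] = 0.0;
        if (record_h) hrec(irec, b) = h[b];
        const size_t off = (size_t) b * N;
        if (record_x) {
          double sx = 0.0;
          for (int j = 0; j < N; ++j) sx += x[off + j];
          xrec(irec, b) = sx / N;
          if (facil) {
            double su = 0.0;
            for (int j = 0; j < N; ++j) su += u[off + j];
            urec(irec, b) = su / N;
          }
        }
        if (record_Q) {
          double sq = 0.0;
          for (int j = 0; j < N; ++j) sq += x[off + j] * x[off + j];
          Qrec(irec, b) = sq / N;
        }
      }
      ++irec;
    }
  }

  List out = List::create(_["A"] = Arec, _["h"] = hrec, _["x"] = xrec,
                          _["u"] = urec, _["Q"] = Qrec,
                          _["n_steps"] = (double) n_steps,
                          _["fdt_warn"] = (double) fdt_warn,
                          _["h_final"] = NumericVector(h.begin(), h.end()));
  if (record_raster) {
    out["raster_t"] = NumericVector(ras_t.begin(), ras_t.end());
    out["raster_id"] = IntegerVector(ras_id.begin(), ras_id.end());
  }
  return out;
}

// Full short-term-plasticity mesoscopic Langevin model: six moments
// (h, u, x, P, Q, R) per population, Poisson population activity and two
// correlated Gaussian channels with correlation
// rho = (R - u x) / sqrt((P - u^2)(Q - x^2)), clipped to [-1, 1].
// [[Rcpp::export]]
List sim_fullstp_cpp(double N, double T, double dt, int record_every,
                     double tau, double tauD, double tauF,
                     double U0, double Ufac,
                     double r, double a, double h0,
                     NumericVector mu,
                     NumericMatrix Ub, NumericMatrix Vb, double J0,
                     bool use_dense, NumericMatrix Jdense,
                     NumericVector h_init, NumericVector u_init,
                     NumericVector x_init, NumericVector P_init,
                     NumericVector Q_init, NumericVector R_init) {
  const int M = h_init.size();
  const bool noise = R_finite(N);
  const long n_steps_raw = (long) std::floor(T / dt + 0.5);
  const long nrec = n_steps_raw / record_every;
  const long n_steps = nrec * record_every;
  const double sqdt = std::sqrt(dt);
  const double Uf = Ufac;

  std::vector<double> h(h_init.begin(), h_init.end());
  std::vector<double> u(u_init.begin(), u_init.end());
  std::vector<double> x(x_init.begin(), x_init.end());
  std::vector<double> P(P_init.begin(), P_init.end());
  std::vector<double> Q(Q_init.begin(), Q_init.end());
  std::vector<double> Rm(R_init.begin(), R_init.end());
  std::vector<double> D(M), coup(M), Aacc(M, 0.0);
  std::vector<double> Av(M), Ix(M), Iu(M), fhv(M);

  NumericMatrix Arec(nrec, M), hrec(nrec, M), urec(nrec, M), xrec(nrec, M),
      Prec(nrec, M), Qrec(nrec, M), Rrec(nrec, M);

  long clamp_var = 0, clip_rho = 0, irec = 0;

  for (long k = 0; k < n_steps; ++k) {
    for (int b = 0; b < M; ++b) {
      double fh = transfer(h[b], r, a, h0);
      fhv[b] = fh;
      double A, ix = 0.0, iu = 0.0;
      if (noise) {
        double dn = R::rpois(N * fh * dt);
        A = dn / (N * dt);
        double varu = P[b] - u[b] * u[b];
        double varx = Q[b] - x[b] * x[b];
        if (varu < 0.0) { varu = 0.0; ++clamp_var; }
        if (varx < 0.0) { varx = 0.0; ++clamp_var; }
        double rho = 0.0;
        if (varu > 0.0 && varx > 0.0) {
          rho = (Rm[b] - u[b] * x[b]) / std::sqrt(varu * varx);
          if (rho > 1.0) { rho = 1.0; ++clip_rho; }
          else if (rho < -1.0) { rho = -1.0; ++clip_rho; }
        }
        double Zx = norm_rand(), Zu = norm_rand();
        double sigx = std::sqrt(varx * fh / N);
        double sigu = std::sqrt(varu * fh / N);
        ix = sigx * Zx * sqdt;
        iu = sigu * (rho * Zx + std::sqrt(1.0 - rho * rho) * Zu) * sqdt;
      } else {
        A = fh;
      }
      Av[b] = A; Ix[b] = ix; Iu[b] = iu;
      // bracket of the h-equation, integrated over dt
      D[b] = Rm[b] * A * dt + u[b] * ix + x[b] * iu;
      Aacc[b] += A * dt;
    }
    if (use_dense) coupling_dense(Jdense, D, coup);
    else coupling_lowrank(Ub, Vb, J0, D, coup);

    for (int b = 0; b < M; ++b) {
      const double ub = u[b], xb = x[b], Pb = P[b], Qb = Q[b], Rb = Rm[b];
      const double A = Av[b], ix = Ix[b], iu = Iu[b];
      const double muP = Uf * (Pb * (Uf - 2.0) - 2.0 * ub * (Uf - 1.0) + Uf);
      const double muQ = Pb * Qb - 2.0 * Qb * ub +
                         2.0 * (Rb + (ub - 2.0) * xb) * (Rb - ub * xb);
      const double muR = (Uf * (1.0 - ub) * (1.0 - ub) - ub * ub) * xb +
                         (Uf - 1.0) * xb * (Pb - ub * ub) +
                         2.0 * (Uf * (ub - 1.0) - ub) * (Rb - ub * xb);
      h[b] += (mu[b] - h[b]) / tau * dt + coup[b];
      u[b] += (U0 - ub) / tauF * dt + Uf * (1.0 - ub) * A * dt - Uf * iu;
      x[b] += (1.0 - xb) / tauD * dt - D[b];
      P[b] += 2.0 * (U0 * ub - Pb) / tauF * dt + muP * A * dt +
              2.0 * Uf * (1.0 + ub * (Uf - 2.0) - Uf) * iu;
      Q[b] += 2.0 * (xb - Qb) / tauD * dt + muQ * A * dt +
              2.0 * (ub - 1.0) * xb * xb * iu +
              2.0 * ub * (ub - 2.0) * xb * ix;
      Rm[b] += ((U0 * xb - Rb) / tauF + (ub - Rb) / tauD) * dt +
               muR * A * dt + 2.0 * (Uf * (ub - 1.0) - ub) * xb * iu +
               (Uf * (1.0 - ub) * (1.0 - ub) - ub * ub) * ix;
      if (x[b] < 0.0) x[b] = 0.0;
      if (x[b] > 1.0) x[b] = 1.0;
      if (u[b] < 0.0) u[b] = 0.0;
      if (u[b] > 1.0) u[b] = 1.0;
      if (Q[b] < 0.0) Q[b] = 0.0;
      if (Q[b] > 1.0) Q[b] = 1.0;
      if (P[b] < 0.0) P[b] = 0.0;
      if (P[b] > 1.0) P[b] = 1.0;
      if (!R_finite(h[b]))
        stop("non-finite state at step %ld (population %d)", k + 1, b + 1);
    }

    if ((k + 1) % record_every == 0) {
      const double denom = record_every * dt;
      for (int b = 0; b < M; ++b) {
        Arec(irec, b) = Aacc[b] / denom; Aacc[b] = 0.0;
        hrec(irec, b) = h[b]; urec(irec, b) = u[b]; xrec(irec, b) = x[b];
        Prec(irec, b) = P[b]; Qrec(irec, b) = Q[b]; Rrec(irec, b) = Rm[b];
      }
      ++irec;
    }
  }

  return List::create(_["A"] = Arec, _["h"] = hrec, _["u"] = urec,
                      _["x"] = xrec, _["P"] = Prec, _["Q"] = Qrec,
                      _["R"] = Rrec, _["n_steps"] = (double) n_steps,
                      _["clamp_var"] = (double) clamp_var,
                      _["clip_rho"] = (double) clip_rho);
}
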