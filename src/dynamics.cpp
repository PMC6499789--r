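#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the mediator-explicit community dynamics.
//
//   dS_i/dt = [ r0_i + sum_l fac(C_l; rho+_il, K_il) - sum_l inh(C_l; rho-_il, K_il) ] S_i
//   dC_l/dt = sum_i beta_li S_i - sum_i alpha_li C_l/(C_l + K_il) S_i - decay_l C_l
//
// Orientations follow the R-side containers: rho and K are N x M (species x
// mediator); alpha, beta and the depletable mask are M x N.
//
// inh_law: 0 linear, 1 threshold, 2 growth_inhibition (saturating)
// fac_law: 0 monod, 1 moser
//
// The loop runs until total density crosses dil_threshold (reached = true),
// t - t0 >= t_max, or max_steps steps. Densities update multiplicatively,
// S <- S (1 + r dt) floored at 0; concentrations clamp at 0 (mass cannot go
// negative when an Euler step over-consumes). Species falling below
// ext_threshold (if > 0) are zeroed and stay extinct.

struct InflLink {
  int i, l;
  double rho; // signed
  double K;
};
struct ConsLink {
  int l, i;
  double alpha;
  double K;
};
struct ProdLink {
  int l, i;
  double beta;
};

// [[Rcpp::export]]
List cpp_simulate(NumericVector r0, NumericMatrix rho, NumericMatrix K,
                  NumericMatrix alpha, NumericMatrix beta,
                  LogicalMatrix depletable, NumericVector decay,
                  int inh_law, int fac_law, double moser_n, double c_th,
                  NumericVector S0, NumericVector C0, double t0, double dt,
                  double dil_threshold, double ext_threshold, double t_max,
                  double max_steps, int record_every) {
  const int N = r0.size();
  const int M = decay.size();

  std::vector<InflLink> infl;
  std::vector<ConsLink> cons;
  std::vector<ProdLink> prod;
  for (int i = 0; i < N; ++i)
    for (int l = 0; l < M; ++l)
      if (rho(i, l) != 0.0) infl.push_back({i, l, rho(i, l), K(i, l)});
  for (int l = 0; l < M; ++l)
    for (int i = 0; i < N; ++i) {
      if (alpha(l, i) > 0.0 && depletable(l, i))
        cons.push_back({l, i, alpha(l, i), K(i, l)});
      if (beta(l, i) > 0.0) prod.push_back({l, i, beta(l, i)});
    }
  bool any_decay = false;
  for (int l = 0; l < M; ++l)
    if (decay[l] != 0.0) any_decay = true;

  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> C(C0.begin(), C0.end());
  std::vector<double> g(N), flux(M);
  double t = t0;
  bool reached = false;
  double steps = 0;
  long long rec_countdown = record_every;

  std::vector<double> rec; // rows: t, S..., C...
  if (record_every > 0) {
    rec.push_back(t);
    for (int i = 0; i < N; ++i) rec.push_back(S[i]);
    for (int l = 0; l < M; ++l) rec.push_back(C[l]);
  }

  double totS = 0.0;
  for (int i = 0; i < N; ++i) totS += S[i];
  if (totS >= dil_threshold) reached = true;

  while (!reached && (t - t0) < t_max && steps < max_steps) {
    // per-capita growth rates
    for (int i = 0; i < N; ++i) g[i] = r0[i];
    for (size_t k = 0; k < infl.size(); ++k) {
      const InflLink &lk = infl[k];
      if (S[lk.i] == 0.0) continue;
      const double c = C[lk.l];
      if (lk.rho > 0.0) { // facilitation
        if (c > 0.0) {
          if (fac_law == 0) {
            g[lk.i] += lk.rho * c / (c + lk.K);
          } else {
            const double cn = std::pow(c, moser_n), kn = std::pow(lk.K, moser_n);
            g[lk.i] += lk.rho * cn / (cn + kn);
          }
        }
      } else { // inhibition, magnitude -rho
        const double m = -lk.rho;
        if (inh_law == 0) {
          g[lk.i] -= m * c / lk.K;
        } else if (inh_law == 1) {
          if (c > c_th) g[lk.i] -= m * (c - c_th) / lk.K;
        } else {
          if (c > c_th) g[lk.i] -= m / (1.0 + lk.K / (c - c_th));
        }
      }
    }
    // mediator fluxes
    if (any_decay) {
      for (int l = 0; l < M; ++l) flux[l] = -decay[l] * C[l];
    } else {
      for (int l = 0; l < M; ++l) flux[l] = 0.0;
    }
    for (size_t k = 0; k < prod.size(); ++k) {
      const ProdLink &lk = prod[k];
      if (S[lk.i] > 0.0) flux[lk.l] += lk.beta * S[lk.i];
    }
    for (size_t k = 0; k < cons.size(); ++k) {
      const ConsLink &lk = cons[k];
      const double c = C[lk.l];
      if (S[lk.i] > 0.0 && c > 0.0)
        flux[lk.l] -= lk.alpha * c / (c + lk.K) * S[lk.i];
    }
    // Euler update
    totS = 0.0;
    for (int i = 0; i < N; ++i) {
      if (!std::isfinite(g[i]))
        stop("non-finite growth rate encountered at t = %f (species %d)", t, i + 1);
      double s = S[i] * (1.0 + g[i] * dt);
      if (s < 0.0) s = 0.0;
      if (ext_threshold > 0.0 && s > 0.0 && s < ext_threshold) s = 0.0;
      S[i] = s;
      totS += s;
    }
    for (int l = 0; l < M; ++l) {
      if (!std::isfinite(flux[l]))
        stop("non-finite mediator flux encountered at t = %f (mediator %d)", t, l + 1);
      double c = C[l] + flux[l] * dt;
      if (c < 0.0) c = 0.0;
      C[l] = c;
    }
    t += dt;
    steps += 1;
    if (record_every > 0 && --rec_countdown == 0) {
      rec_countdown = record_every;
      rec.push_back(t);
      for (int i = 0; i < N; ++i) rec.push_back(S[i]);
      for (int l = 0; l < M; ++l) rec.push_back(C[l]);
    }
    if (totS >= dil_threshold) reached = true;
    if (totS == 0.0) break; // community collapse: nothing left to grow
  }

  List out = List::create(
      _["S"] = NumericVector(S.begin(), S.end()),
      _["C"] = NumericVector(C.begin(), C.end()), _["t"] = t,
      _["reached"] = reached, _["steps"] = steps);
  if (record_every > 0) {
    const int ncol = 1 + N + M;
    const int nrow = rec.size() / ncol;
    NumericMatrix recm(nrow, ncol);
    for (int r = 0; r < nrow; ++r)
      for (int cidx = 0; cidx < ncol; ++cidx)
        recm(r, cidx) = rec[r * ncol + cidx];
    out["record"] = recm;
  }
  return out;
}
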