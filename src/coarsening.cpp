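#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Explicit Euler integration of the HEI10 coarsening dynamics on one SC.
//
// State: concentration c_j on n equally spaced nodes spanning [0, L]
// (dx = L/(n-1)) and focus amounts M_i at fixed positions x_i.  Each focus
// exchanges material with its nearest grid node; the point exchange is
// discretised as a node-local sink/source of magnitude Lambda/dx so that the
// amount gained by a focus equals the amount lost by its host cell exactly,
// keeping the total dx*sum(c) + sum(M) conserved to round-off.
//
// The time step obeys dt = dt_safety * min(dx^2/(2D), dx/(Lambda*k_max))
// where k_max is the largest number of foci sharing a node, then is rounded
// down so an integer number of steps lands exactly on `duration`.
//
// If an Euler step would drive a focus amount negative, the outgoing flux is
// limited so that the focus empties exactly; empty foci stay in the system
// and may regrow (c^eq(0) = 0, so the local exchange turns absorbing).

// [[Rcpp::export(name = ".euler_coarsen")]]
List euler_coarsen(NumericVector conc, NumericVector foci_x, NumericVector foci_M,
                   double L, double D, double Lambda, double alpha, double c0_eq,
                   double duration, double dt_safety) {
  const int n = conc.size();
  const int N = foci_x.size();
  if (n < 3) stop("need at least 3 grid nodes");
  if (!(L > 0)) stop("SC length must be positive");
  if (duration < 0) stop("duration must be non-negative");
  const double dx = L / (n - 1);

  std::vector<double> c(conc.begin(), conc.end());
  std::vector<double> M(foci_M.begin(), foci_M.end());
  std::vector<int> node(N);
  std::vector<int> cnt(n, 0);
  for (int i = 0; i < N; ++i) {
    if (foci_x[i] < 0 || foci_x[i] > L) stop("focus position outside [0, L]");
    if (foci_M[i] < 0) stop("focus amount must be non-negative");
    int j = (int)std::floor(foci_x[i] / dx + 0.5); // nearest node
    if (j < 0) j = 0;
    if (j > n - 1) j = n - 1;
    node[i] = j;
    cnt[j]++;
  }
  int kmax = 0;
  for (int j = 0; j < n; ++j)
    if (cnt[j] > kmax) kmax = cnt[j];

  double dt0 = dx * dx / (2.0 * D);
  if (kmax > 0) {
    double dte = dx / (Lambda * kmax);
    if (dte < dt0) dt0 = dte;
  }
  dt0 *= dt_safety;
  if (!(dt0 > 0) || !std::isfinite(dt0)) stop("derived time step is not positive and finite");

  if (duration == 0.0) {
    return List::create(_["c"] = conc, _["M"] = foci_M,
                        _["dt"] = dt0, _["n_steps"] = 0.0);
  }

  const double nsteps_d = std::ceil(duration / dt0);
  const long nsteps = (long)nsteps_d;
  const double dt = duration / nsteps_d;
  const double r = D * dt / (dx * dx);
  const double dtL = dt * Lambda;
  const bool fast = (alpha == 0.25);

  std::vector<double> dc(n), cnew(n), cf(N), flux(N);
  double *pc = c.data(), *pcn = cnew.data(), *pdc = dc.data(),
         *pM = M.data(), *pcf = cf.data(), *pfl = flux.data();
  const int *pnode = node.data();

  for (long s = 0; s < nsteps; ++s) {
    // concentration seen by each focus (start-of-step values)
    for (int i = 0; i < N; ++i) pcf[i] = pc[pnode[i]];
    // exchange fluxes, limited so amounts cannot go negative
    if (fast) {
      for (int i = 0; i < N; ++i) {
        double m = pM[i];
        double ceq = c0_eq * m / (1.0 + m * std::sqrt(std::sqrt(m)));
        double dM = dtL * (pcf[i] - ceq);
        pfl[i] = (dM < -m) ? -m : dM;
      }
    } else {
      for (int i = 0; i < N; ++i) {
        double m = pM[i];
        double ceq = c0_eq * m / (1.0 + std::pow(m, 1.0 + alpha));
        double dM = dtL * (pcf[i] - ceq);
        pfl[i] = (dM < -m) ? -m : dM;
      }
    }
    for (int j = 0; j < n; ++j) pdc[j] = 0.0;
    for (int i = 0; i < N; ++i) {
      pM[i] += pfl[i];
      pdc[pnode[i]] -= pfl[i] / dx;
    }
    // diffusion in conservative (flux) form; boundary fluxes are zero.
    // the symmetric grouping (left+right) - 2*mid keeps the update exactly
    // mirror-invariant in floating point
    pcn[0] = pc[0] + r * (pc[1] - pc[0]) + pdc[0];
    for (int j = 1; j < n - 1; ++j)
      pcn[j] = pc[j] + r * ((pc[j - 1] + pc[j + 1]) - 2.0 * pc[j]) + pdc[j];
    pcn[n - 1] = pc[n - 1] + r * (pc[n - 2] - pc[n - 1]) + pdc[n - 1];
    std::swap(pc, pcn);

    if ((s & 0xFFFF) == 0xFFFF) {
      bool ok = true;
      for (int j = 0; j < n; ++j)
        if (!std::isfinite(pc[j])) ok = false;
      if (!ok)
        stop("numerical instability: non-finite concentration at t = %g s (dt = %g)",
             (s + 1) * dt, dt);
    }
  }

  for (int j = 0; j < n; ++j)
    if (!std::isfinite(pc[j]))
      stop("numerical instability: non-finite concentration in final state (dt = %g)", dt);
  for (int i = 0; i < N; ++i)
    if (!std::isfinite(pM[i]))
      stop("numerical instability: non-finite focus amount in final state (dt = %g)", dt);

  return List::create(_["c"] = NumericVector(pc, pc + n),
                      _["M"] = NumericVector(M.begin(), M.end()),
                      _["dt"] = dt, _["n_steps"] = (double)nsteps);
}
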