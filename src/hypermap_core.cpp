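#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double hyp_approx2(double r1, double t1, double r2, double t2) {
  double dth = std::fabs(t1 - t2);
  if (dth > M_PI) dth = 2.0 * M_PI - dth;
  if (dth <= 0.0) return std::fabs(r1 - r2);
  return r1 + r2 + 2.0 * std::log(dth / 2.0);
}

static inline double fermi2(double x, double R, double temp) {
  return 1.0 / (1.0 + std::exp((x - R) / (2.0 * temp)));
}

static double disc_radius_c2(double t, double m, double beta, double temp) {
  if (t <= 1.0) return 0.0;
  double rt = 2.0 * std::log(t);
  if (beta == 1.0)
    return rt - 2.0 * std::log(temp * rt / (m * std::sin(M_PI * temp)));
  double grow = 1.0 - std::exp(-(1.0 - beta) * rt / 2.0);
  return rt - 2.0 * std::log(2.0 * temp * grow /
                             (m * (1.0 - beta) * std::sin(M_PI * temp)));
}

// floor-based reductions (avoids fmod, which is versioned inconsistently
// across the glibc builds this package is compiled against)
static inline double wrap2pi(double a) {
  a -= 2.0 * M_PI * std::floor(a / (2.0 * M_PI));
  if (a >= 2.0 * M_PI) a = 0.0;
  return a;
}

static inline double circ_dist(double a, double b) {
  double d = wrap2pi(std::fabs(a - b));
  if (d > M_PI) d = 2.0 * M_PI - d;
  return d;
}

static const double P_CLAMP = 1e-12;
static const double SIG2_FLOOR = 1e-6;

// Replays hyperbolic growth in degree order and places each node at the
// angle maximising a model likelihood over a candidate grid of spacing 1/i.
//
// nbr:      neighbour lists in rank space (1-based ranks), one per node
// ncommon:  final common-neighbour counts among the first n_cn ranks
// n_cn:     ranks 1..n_cn use the common-neighbours likelihood (these are
//           the nodes with degree >= k_speedup); later ranks use the
//           link-based likelihood
// init:     draft angles per rank (refinement mode) or empty (full mode)
// window:   full width of the search window around init (refinement mode)
// local_hw: half-width of the local search region around the
//           neighbour-based initial estimate for low-degree nodes
// theta1:   angle for the rank-1 node in full mode
// [[Rcpp::export]]
List hypermap_core(List nbr, NumericMatrix ncommon, int n_cn,
                   double m, double beta, double temp,
                   NumericVector init, double window, double local_hw,
                   double theta1) {
  int n = nbr.size();
  bool refine = init.size() == n;
  NumericVector theta(n);
  NumericVector ll_best(n, 0.0), ll_center(n, NA_REAL);

  // adjacency flags in rank space, filled lazily per step
  std::vector< std::vector<int> > nb(n + 1);
  for (int i = 0; i < n; ++i) nb[i + 1] = as< std::vector<int> >(nbr[i]);

  std::vector<double> rr(n + 1);          // radii at current time
  std::vector<char> isnb(n + 1, 0);
  std::vector<double> cand; cand.reserve(4096);

  // Final-time quantities for the common-neighbours phase: the observed
  // counts n_ij live in the final network, so their model mean/variance are
  // evaluated with final radii and disc radius. Nodes not yet placed
  // contribute in expectation over their (still unknown) angles.
  std::vector<double> rf(n + 1);
  for (int v = 1; v <= n; ++v)
    rf[v] = beta * 2.0 * std::log((double)v) + (1.0 - beta) * 2.0 * std::log((double)n);
  const double RN = disc_radius_c2((double)n, m, beta, temp);
  // Pf[j][k]: final-configuration link probability between placed j,k
  int npf = n_cn > 0 ? n_cn : 0;
  std::vector< std::vector<double> > Pf(npf + 1, std::vector<double>(npf + 1, 0.0));
  // Expected common-neighbour mass through a not-yet-placed node k with
  // final radius rf[k] and uniform angle. In the approximate-distance
  // metric the Fermi probability towards a node at radius r is
  // p(dtheta) = 1 / (1 + (dtheta / (a * b_k))^(1/T)) with a = 2 exp((RN - r)/2)
  // and b_k = exp(-rf[k]/2); its angular mass is 2*a*b_k * pi*T/sin(pi*T).
  // The product expectation is approximated by the two-peak form
  //   E[p_i p_j] ~ (p_j(dtheta_ij) * I_i + p_i(dtheta_ij) * I_j) / (2 pi),
  // capped by min(I_i, I_j)/(2 pi) and 1.
  const double temp_scale = M_PI * temp / std::sin(M_PI * temp);
  const double inv_t = 1.0 / temp;
  std::vector<double> bvec(n + 1), wvec(n + 1);
  for (int v = 1; v <= n; ++v) {
    bvec[v] = std::exp(-rf[v] / 2.0);
    wvec[v] = std::pow(bvec[v], -inv_t);
  }
  auto a_of = [&](double r) { return 2.0 * std::exp((RN - r) / 2.0); };

  for (int i = 1; i <= n; ++i) {
    double ri = 2.0 * std::log((double)i);
    for (int j = 1; j < i; ++j)
      rr[j] = beta * 2.0 * std::log((double)j) + (1.0 - beta) * ri;
    rr[i] = ri;

    // --- candidate grid ---------------------------------------------------
    cand.clear();
    double center = NA_REAL;
    bool have_center = false;
    if (refine) { center = init[i - 1]; have_center = true; }

    if (i == 1) {
      theta[0] = have_center ? wrap2pi(center) : wrap2pi(theta1);
      ll_best[0] = 0.0;
      if (have_center) ll_center[0] = 0.0;
      continue;
    }

    bool use_cn = i <= n_cn;
    double spacing = 1.0 / (double)i;
    double Ri_pre = disc_radius_c2((double)i, m, beta, temp);
    if (!refine && !use_cn) {
      // neighbour-based initial estimate: grid-search the link likelihood
      // restricted to the placed-neighbour terms (cheap: O(grid * degree))
      std::vector<int> placed;
      for (int j : nb[i]) if (j < i) placed.push_back(j);
      if (!placed.empty()) {
        double ri_ = 2.0 * std::log((double)i);
        int K0 = (int)std::ceil(2.0 * M_PI * i);
        double bll = -std::numeric_limits<double>::infinity(), bth = 0.0;
        for (int k = 0; k < K0; ++k) {
          double th = k * spacing;
          double ll = 0.0;
          for (int j : placed) {
            double x = hyp_approx2(rr[j], theta[j - 1], ri_, th);
            double p = fermi2(x, Ri_pre, temp);
            if (p < P_CLAMP) p = P_CLAMP;
            ll += std::log(p);
          }
          if (ll > bll) { bll = ll; bth = th; }
        }
        center = wrap2pi(bth);
        have_center = true;
      }
    }
    if (have_center) {
      double hw = refine ? window / 2.0 : local_hw;
      if (hw >= M_PI) {
        int K = (int)std::ceil(2.0 * M_PI * i);
        for (int k = 0; k < K; ++k) cand.push_back(wrap2pi(k * spacing));
        cand.push_back(wrap2pi(center));   // tie-break anchor stays reachable
      } else {
        int K = (int)std::floor(hw * i + 1e-9);
        for (int k = -K; k <= K; ++k)
          cand.push_back(wrap2pi(center + k * spacing));
      }
    } else {
      int K = (int)std::ceil(2.0 * M_PI * i);
      for (int k = 0; k < K; ++k) cand.push_back(wrap2pi(k * spacing));
    }

    double Ri = Ri_pre;

    // --- likelihood of each candidate ------------------------------------
    double best = -std::numeric_limits<double>::infinity();
    double best_th = cand[0];
    double center_ll = NA_REAL;
    // ties: prefer the candidate closest to the centre/init angle, then the
    // smallest angle, for deterministic output
    auto better = [&](double ll, double th) {
      if (ll > best) return true;
      if (ll < best) return false;
      if (have_center) {
        double a = circ_dist(th, center), b = circ_dist(best_th, center);
        if (a < b) return true;
        if (a > b) return false;
      }
      return th < best_th;
    };

    for (int j : nb[i]) if (j < i) isnb[j] = 1;

    if (use_cn) {
      // Gaussian likelihood of the final common-neighbour counts, evaluated
      // in the final configuration: placed nodes contribute exact Bernoulli
      // terms, not-yet-placed nodes contribute in expectation over their
      // unknown angles (cold-limit arc overlap).
      const double cst = (i - 1) * std::log(1.0 / std::sqrt(2.0 * M_PI));
      const int nc = (int)cand.size();
      std::vector<double> pf((size_t)nc * i, 0.0);
      for (int c = 0; c < nc; ++c)
        for (int k = 1; k < i; ++k) {
          double x = hyp_approx2(rf[k], theta[k - 1], rf[i], cand[c]);
          pf[(size_t)c * i + k] = fermi2(x, RN, temp);
        }
      std::vector<double> ll(nc, cst);
      const double a_i = a_of(rf[i]);
      for (int j = 1; j < i; ++j) {
        const double a_j = a_of(rf[j]);
        const double amin = a_i < a_j ? a_i : a_j;
        const std::vector<double>& Pj = Pf[j];
        const double nij = ncommon(i - 1, j - 1);
        for (int c = 0; c < nc; ++c) {
          double mu = 0.0, s2 = 0.0;
          const double* pc = &pf[(size_t)c * i];
          for (int k = 1; k < i; ++k) {
            if (k == j) continue;
            double q = pc[k] * Pj[k];
            mu += q; s2 += q * (1.0 - q);
          }
          double dth = circ_dist(cand[c], theta[j - 1]);
          double z_i = std::pow(dth / a_i, inv_t);
          double z_j = std::pow(dth / a_j, inv_t);
          for (int k = i + 1; k <= n; ++k) {
            double g_jk = 1.0 / (1.0 + z_j * wvec[k]);
            double g_ik = 1.0 / (1.0 + z_i * wvec[k]);
            double q = (a_i * g_jk + a_j * g_ik) * bvec[k] * temp_scale / M_PI;
            double cap = amin * bvec[k] * temp_scale / M_PI;
            if (q > cap) q = cap;
            if (q > 1.0) q = 1.0;
            mu += q; s2 += q * (1.0 - q);
          }
          if (s2 < SIG2_FLOOR) s2 = SIG2_FLOOR;
          double d = nij - mu;
          ll[c] += -0.5 * std::log(s2) - d * d / (2.0 * s2);
        }
      }
      for (int c = 0; c < nc; ++c) {
        if (have_center && circ_dist(cand[c], center) < 1e-12) center_ll = ll[c];
        if (better(ll[c], cand[c])) { best = ll[c]; best_th = cand[c]; }
      }
    } else {
      for (double th : cand) {
        double ll = 0.0;
        for (int j = 1; j < i; ++j) {
          double x = hyp_approx2(rr[j], theta[j - 1], ri, th);
          double p = fermi2(x, Ri, temp);
          if (p < P_CLAMP) p = P_CLAMP;
          if (p > 1.0 - P_CLAMP) p = 1.0 - P_CLAMP;
          ll += isnb[j] ? std::log(p) : std::log1p(-p);
        }
        if (have_center && circ_dist(th, center) < 1e-12) center_ll = ll;
        if (better(ll, th)) { best = ll; best_th = th; }
      }
    }

    for (int j : nb[i]) if (j < i) isnb[j] = 0;

    theta[i - 1] = best_th;
    ll_best[i - 1] = best;
    ll_center[i - 1] = center_ll;
    if (i <= n_cn) {
      for (int j = 1; j < i; ++j) {
        double x = hyp_approx2(rf[j], theta[j - 1], rf[i], best_th);
        double p = fermi2(x, RN, temp);
        Pf[i][j] = p; Pf[j][i] = p;
      }
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["theta"] = theta, _["loglik"] = ll_best,
                      _["loglik_center"] = ll_center);
}
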