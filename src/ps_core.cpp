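#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Approximate hyperbolic distance in the native disc; co-angular pairs fall
// back to |r1 - r2| (the true distance in that degenerate case).
static inline double hyp_approx(double r1, double t1, double r2, double t2) {
  double dth = std::fabs(t1 - t2);
  if (dth > M_PI) dth = 2.0 * M_PI - dth;
  if (dth <= 0.0) return std::fabs(r1 - r2);
  return r1 + r2 + 2.0 * std::log(dth / 2.0);
}

static inline double fermi_p(double x, double R, double temp) {
  return 1.0 / (1.0 + std::exp((x - R) / (2.0 * temp)));
}

static double disc_radius_c(double t, double m, double beta, double temp) {
  if (t <= 1.0) return 0.0;
  double rt = 2.0 * std::log(t);
  if (beta == 1.0) {
    if (temp == 0.0) return rt - 2.0 * std::log(rt / (M_PI * m));
    return rt - 2.0 * std::log(temp * rt / (m * std::sin(M_PI * temp)));
  }
  double grow = 1.0 - std::exp(-(1.0 - beta) * rt / 2.0);
  if (temp == 0.0)
    return rt - 2.0 * std::log(2.0 * grow / (M_PI * m * (1.0 - beta)));
  return rt - 2.0 * std::log(2.0 * temp * grow /
                             (m * (1.0 - beta) * std::sin(M_PI * temp)));
}

// Popularity-similarity growth. Nodes are birth ranks 1..n; node t appears
// at radius 2*log(t) and pre-drawn angle theta[t-1], older radii fade via
// the closed form r_s(t) = 2*beta*log(s) + 2*(1-beta)*log(t). At temp = 0
// node t links to its m_t hyperbolically nearest predecessors; at temp > 0
// links are drawn by rejection sampling with Fermi acceptance, with a
// capped-attempt fallback to weighted sampling without replacement.
// [[Rcpp::export]]
List ps_generate_core(int n, IntegerVector m_t, double m, double beta,
                      double temp, NumericVector theta) {
  std::vector<int> eu, ev;
  eu.reserve((size_t)n * 3);
  ev.reserve((size_t)n * 3);
  std::vector< std::vector<int> > adj(n + 1);

  std::vector<double> dist(n + 1), rr(n + 1);
  std::vector<int> idx(n + 1);

  for (int t = 2; t <= n; ++t) {
    int mt = m_t[t - 1];
    if (mt <= 0) continue;
    double rt = 2.0 * std::log((double)t);
    double tht = theta[t - 1];
    // interim radii of predecessors at time t
    for (int s = 1; s < t; ++s)
      rr[s] = beta * 2.0 * std::log((double)s) + (1.0 - beta) * rt;

    if (t - 1 <= mt) {            // too few predecessors: connect to all
      for (int s = 1; s < t; ++s) {
        eu.push_back(s); ev.push_back(t);
        adj[s].push_back(t); adj[t].push_back(s);
      }
      continue;
    }

    if (temp == 0.0) {            // cold regime: m_t nearest predecessors
      for (int s = 1; s < t; ++s) {
        dist[s - 1] = hyp_approx(rr[s], theta[s - 1], rt, tht);
        idx[s - 1] = s;
      }
      std::partial_sort(idx.begin(), idx.begin() + mt, idx.begin() + (t - 1),
                        [&](int a, int b) {
                          if (dist[a - 1] != dist[b - 1])
                            return dist[a - 1] < dist[b - 1];
                          return a < b;
                        });
      // note: dist is indexed by s-1 while idx holds s; keep both in sync
      for (int k = 0; k < mt; ++k) {
        int s = idx[k];
        eu.push_back(s); ev.push_back(t);
        adj[s].push_back(t); adj[t].push_back(s);
      }
    } else {                      // warm regime: rejection sampling
      double Rt = disc_radius_c((double)t, m, beta, temp);
      std::vector<char> linked(t, 0);
      int made = 0;
      long attempts = 0, cap = 100L * t;
      while (made < mt && attempts < cap) {
        int s = 1 + (int)std::floor(unif_rand() * (t - 1));
        if (s >= t) s = t - 1;
        if (linked[s]) { ++attempts; continue; }
        double x = hyp_approx(rr[s], theta[s - 1], rt, tht);
        if (unif_rand() < fermi_p(x, Rt, temp)) {
          linked[s] = 1; ++made;
          eu.push_back(s); ev.push_back(t);
          adj[s].push_back(t); adj[t].push_back(s);
        }
        ++attempts;
      }
      if (made < mt) {
        // fallback: sample remaining partners by acceptance probability
        std::vector<int> rest;
        std::vector<double> w;
        for (int s = 1; s < t; ++s) {
          if (linked[s]) continue;
          rest.push_back(s);
          double x = hyp_approx(rr[s], theta[s - 1], rt, tht);
          w.push_back(fermi_p(x, Rt, temp));
        }
        while (made < mt && !rest.empty()) {
          double tot = 0.0;
          for (double wi : w) tot += wi;
          size_t pick;
          if (tot <= 0.0) {       // all-zero weights: take the nearest
            pick = 0;
            double best = hyp_approx(rr[rest[0]], theta[rest[0] - 1], rt, tht);
            for (size_t q = 1; q < rest.size(); ++q) {
              double x = hyp_approx(rr[rest[q]], theta[rest[q] - 1], rt, tht);
              if (x < best) { best = x; pick = q; }
            }
          } else {
            double u = unif_rand() * tot, acc = 0.0;
            pick = rest.size() - 1;
            for (size_t q = 0; q < rest.size(); ++q) {
              acc += w[q];
              if (u <= acc) { pick = q; break; }
            }
          }
          int s = rest[pick];
          eu.push_back(s); ev.push_back(t);
          adj[s].push_back(t); adj[t].push_back(s);
          ++made;
          rest.erase(rest.begin() + pick);
          w.erase(w.begin() + pick);
        }
      }
    }
  }
  return List::create(_["from"] = wrap(eu), _["to"] = wrap(ev));
}
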