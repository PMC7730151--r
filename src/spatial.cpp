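#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Random sequential adsorption (hard-core point process) inside an annulus
// centred on the origin. Candidate positions are drawn uniformly on the
// annulus and accepted when no previously accepted point lies closer than
// min_dist; acceptance is checked against a bucket grid with cell width
// min_dist so only the 3x3 neighbourhood needs scanning. All randomness goes
// through R's RNG, so set.seed() on the R side governs reproducibility.
// Returns the accepted points (possibly fewer than n_target if max_attempts
// proposals are exhausted; the caller decides whether that is an error).
// [[Rcpp::export]]
NumericMatrix rsa_annulus_cpp(int n_target, double r_outer, double r_inner,
                              double min_dist, double max_attempts) {
  RNGScope scope;
  std::vector<double> px, py;
  px.reserve(n_target);
  py.reserve(n_target);

  const double r_in2 = r_inner * r_inner;
  const double r_out2 = r_outer * r_outer;

  if (min_dist <= 0.0) {
    // Binomial (Poisson-conditioned) process: no interaction, accept all.
    for (int i = 0; i < n_target; ++i) {
      double r = std::sqrt(r_in2 + unif_rand() * (r_out2 - r_in2));
      double th = unif_rand() * 2.0 * M_PI;
      px.push_back(r * std::cos(th));
      py.push_back(r * std::sin(th));
    }
  } else {
    const double cell = min_dist;
    const int ncell = std::max(1, (int)std::ceil(2.0 * r_outer / cell));
    const double x0 = -r_outer, y0 = -r_outer;
    std::vector<std::vector<int> > grid((size_t)ncell * ncell);
    const double d2min = min_dist * min_dist;

    double attempts = 0.0;
    while ((int)px.size() < n_target && attempts < max_attempts) {
      attempts += 1.0;
      double r = std::sqrt(r_in2 + unif_rand() * (r_out2 - r_in2));
      double th = unif_rand() * 2.0 * M_PI;
      double x = r * std::cos(th), y = r * std::sin(th);
      int cx = (int)((x - x0) / cell), cy = (int)((y - y0) / cell);
      if (cx < 0) cx = 0; if (cx >= ncell) cx = ncell - 1;
      if (cy < 0) cy = 0; if (cy >= ncell) cy = ncell - 1;
      bool ok = true;
      for (int ix = std::max(0, cx - 1); ok && ix <= std::min(ncell - 1, cx + 1); ++ix) {
        for (int iy = std::max(0, cy - 1); ok && iy <= std::min(ncell - 1, cy + 1); ++iy) {
          const std::vector<int>& bucket = grid[(size_t)ix * ncell + iy];
          for (size_t k = 0; k < bucket.size(); ++k) {
            double dx = x - px[bucket[k]], dy = y - py[bucket[k]];
            if (dx * dx + dy * dy < d2min) { ok = false; break; }
          }
        }
      }
      if (ok) {
        grid[(size_t)cx * ncell + cy].push_back((int)px.size());
        px.push_back(x);
        py.push_back(y);
      }
    }
  }

  NumericMatrix out((int)px.size(), 2);
  for (int i = 0; i < (int)px.size(); ++i) {
    out(i, 0) = px[i];
    out(i, 1) = py[i];
  }
  return out;
}

// Nearest-neighbour distance for every point within one pattern, by a
// plane-sweep on x-sorted order: for each point, scan outwards in sorted x
// until the x-gap alone exceeds the best distance found.
// [[Rcpp::export]]
NumericVector nnd_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  NumericVector out(n);
  if (n < 2) {
    for (int i = 0; i < n; ++i) out[i] = NA_REAL;
    return out;
  }
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  for (int i = 0; i < n; ++i) {
    const int pi = ord[i];
    double best = R_PosInf;
    for (int j = i - 1; j >= 0; --j) {
      const int pj = ord[j];
      double dx = x[pi] - x[pj];
      if (dx * dx >= best) break;
      double dy = y[pi] - y[pj];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    for (int j = i + 1; j < n; ++j) {
      const int pj = ord[j];
      double dx = x[pj] - x[pi];
      if (dx * dx >= best) break;
      double dy = y[pj] - y[pi];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[pi] = std::sqrt(best);
  }
  return out;
}

// For every query point, the index (1-based) of its nearest reference point
// and the distance to it. Same sweep idea: references sorted by x, queries
// located by binary search.
// [[Rcpp::export]]
List cross_nn_cpp(NumericVector xq, NumericVector yq,
                  NumericVector xr, NumericVector yr) {
  const int nq = xq.size(), nr = xr.size();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  std::vector<int> ord(nr);
  for (int i = 0; i < nr; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return xr[a] < xr[b]; });
  std::vector<double> xs(nr);
  for (int i = 0; i < nr; ++i) xs[i] = xr[ord[i]];

  for (int q = 0; q < nq; ++q) {
    const double qx = xq[q], qy = yq[q];
    int pos = (int)(std::lower_bound(xs.begin(), xs.end(), qx) - xs.begin());
    double best = R_PosInf;
    int bi = -1;
    for (int j = pos; j < nr; ++j) {
      double dx = xs[j] - qx;
      if (dx * dx >= best) break;
      double dy = yr[ord[j]] - qy;
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bi = ord[j]; }
    }
    for (int j = pos - 1; j >= 0; --j) {
      double dx = qx - xs[j];
      if (dx * dx >= best) break;
      double dy = yr[ord[j]] - qy;
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bi = ord[j]; }
    }
    idx[q] = bi + 1;
    dist[q] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
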