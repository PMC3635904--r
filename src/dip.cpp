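#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Hartigan & Hartigan dip statistic: the minimal sup-norm distance between
// the empirical CDF and the closest unimodal CDF.
//
// For a candidate mode at the j-th distinct data point, the closest unimodal
// CDF is convex to the left of the mode and concave to the right (a jump at
// the mode itself is allowed, so the mode can carry an atom).  Feasibility of
// a convex curve threading the ecdf band within +/- eps reduces to a lower
// convex hull condition on the pre-jump ecdf values; symmetrically on the
// right with the upper concave hull of the post-jump values.  The dip is the
// minimum over modes of the larger one-sided requirement.  Hulls are grown
// incrementally so the scan is near-linear after sorting.

static void make_ecdf(const std::vector<double>& x, std::vector<double>& xs,
                      std::vector<double>& Fhi, std::vector<double>& Flo) {
  const int n = (int)x.size();
  xs.clear(); Fhi.clear(); Flo.clear();
  int i = 0, cum = 0;
  while (i < n) {
    int j = i;
    while (j < n && x[j] == x[i]) ++j;
    xs.push_back(x[i]);
    Flo.push_back((double)cum / n);
    cum += (j - i);
    Fhi.push_back((double)cum / n);
    i = j;
  }
}

static double dip_sorted(const std::vector<double>& x) {
  std::vector<double> xs, Fhi, Flo;
  make_ecdf(x, xs, Fhi, Flo);
  const int K = (int)xs.size();
  if (K <= 1) return 0.0;

  // M[j]: twice the left-side eps when the mode sits at xs[j]
  std::vector<double> M(K), N(K);
  {
    std::vector<int> hull; hull.reserve(K);
    std::vector<double> Mst; Mst.reserve(K);
    hull.push_back(0); Mst.push_back(0.0);
    M[0] = 0.0;
    for (int j = 1; j < K; ++j) {
      while (hull.size() >= 2) {
        int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
        double cr = (Flo[j] - Flo[a]) * (xs[b] - xs[a]) -
                    (Flo[b] - Flo[a]) * (xs[j] - xs[a]);
        if (cr > 0) break;           // b strictly below chord a->j: keep
        hull.pop_back(); Mst.pop_back();
      }
      int p = hull.back();
      double mx = Mst.back();
      double slope = (Flo[j] - Flo[p]) / (xs[j] - xs[p]);
      for (int i = p; i < j; ++i) {
        double hv = Flo[p] + slope * (xs[i] - xs[p]);
        double d = Fhi[i] - hv;
        if (d > mx) mx = d;
      }
      hull.push_back(j); Mst.push_back(mx);
      M[j] = mx;
    }
  }
  // N[j]: twice the right-side eps (upper concave hull of post-jump ecdf)
  {
    std::vector<int> hull; hull.reserve(K);
    std::vector<double> Nst; Nst.reserve(K);
    hull.push_back(K - 1); Nst.push_back(0.0);
    N[K - 1] = 0.0;
    for (int j = K - 2; j >= 0; --j) {
      while (hull.size() >= 2) {
        int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
        double cr = (Fhi[j] - Fhi[a]) * (xs[b] - xs[a]) -
                    (Fhi[b] - Fhi[a]) * (xs[j] - xs[a]);
        if (cr > 0) break;           // b strictly above chord j->a: keep
        hull.pop_back(); Nst.pop_back();
      }
      int p = hull.back();
      double mx = Nst.back();
      double slope = (Fhi[j] - Fhi[p]) / (xs[j] - xs[p]);
      for (int i = p; i > j; --i) {
        double hv = Fhi[p] + slope * (xs[i] - xs[p]);
        double d = hv - Flo[i];
        if (d > mx) mx = d;
      }
      hull.push_back(j); Nst.push_back(mx);
      N[j] = mx;
    }
  }
  double dip = R_PosInf;
  for (int j = 0; j < K; ++j) {
    double d = std::max(M[j], N[j]);
    if (d < dip) dip = d;
  }
  return 0.5 * dip;
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  std::sort(v.begin(), v.end());
  return dip_sorted(v);
}

// Null distribution of the dip under samples of size n from U(0,1),
// using R's RNG so set.seed() controls the draws.
// [[Rcpp::export]]
NumericVector dip_boot_cpp(int n, int nboot) {
  NumericVector out(nboot);
  std::vector<double> v((size_t)n);
  for (int b = 0; b < nboot; ++b) {
    for (int i = 0; i < n; ++i) v[i] = unif_rand();
    std::sort(v.begin(), v.end());
    out[b] = dip_sorted(v);
  }
  return out;
}
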