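#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Factorial capped at 10! so the factorial terms cannot dominate by overflow.
static double capped_factorial(int n) {
  if (n > 10) n = 10;
  double f = 1.0;
  for (int i = 2; i <= n; ++i) f *= i;
  return f;
}

struct MatchPair {
  double err;   // |ppm error|
  int frag;     // fragment index
  int peak;     // peak index
  bool operator<(const MatchPair& o) const {
    if (err != o.err) return err < o.err;
    if (frag != o.frag) return frag < o.frag;
    return peak < o.peak;
  }
};

// Score one candidate: singly charged b/y ladders from per-residue masses.
// Each peak matches at most one fragment and vice versa; when several
// fragment-peak pairs compete, the smallest |ppm error| wins (greedy).
static void score_one(const NumericVector& pmz, const NumericVector& pint,
                      const NumericVector& res, double tol_ppm,
                      double proton, double water,
                      double* score, int* nb, int* ny, double* dot) {
  const int L = res.size();
  const int np = pmz.size();
  *score = 0.0; *nb = 0; *ny = 0; *dot = 0.0;
  if (L < 2 || np == 0) return;
  const int nf = 2 * (L - 1);
  std::vector<double> frag(nf);
  double acc = proton;
  for (int i = 0; i < L - 1; ++i) {           // b ions
    acc += res[i];
    frag[i] = acc;
  }
  acc = proton + water;
  for (int i = 0; i < L - 1; ++i) {           // y ions
    acc += res[L - 1 - i];
    frag[L - 1 + i] = acc;
  }
  std::vector<MatchPair> pairs;
  for (int f = 0; f < nf; ++f) {
    const double m = frag[f];
    const double tol = m * tol_ppm * 1e-6;
    // peaks within [m - tol, m + tol] (pmz sorted ascending)
    int lo = std::lower_bound(pmz.begin(), pmz.end(), m - tol) - pmz.begin();
    for (int p = lo; p < np && pmz[p] <= m + tol; ++p) {
      MatchPair mp;
      mp.err = std::fabs(pmz[p] - m) / m * 1e6;
      mp.frag = f;
      mp.peak = p;
      pairs.push_back(mp);
    }
  }
  std::sort(pairs.begin(), pairs.end());
  std::vector<char> frag_used(nf, 0), peak_used(np, 0);
  for (size_t k = 0; k < pairs.size(); ++k) {
    const MatchPair& mp = pairs[k];
    if (frag_used[mp.frag] || peak_used[mp.peak]) continue;
    frag_used[mp.frag] = 1;
    peak_used[mp.peak] = 1;
    *dot += pint[mp.peak];
    if (mp.frag < L - 1) ++*nb; else ++*ny;
  }
  *score = *dot * capped_factorial(*nb) * capped_factorial(*ny);
}

// [[Rcpp::export]]
DataFrame score_batch_cpp(NumericVector peak_mz, NumericVector peak_int,
                          List residue_masses, double frag_tol_ppm,
                          double proton, double water) {
  const int n = residue_masses.size();
  NumericVector score(n), dot(n);
  IntegerVector nb(n), ny(n);
  for (int i = 0; i < n; ++i) {
    NumericVector res = residue_masses[i];
    double s, d; int b, y;
    score_one(peak_mz, peak_int, res, frag_tol_ppm, proton, water,
              &s, &b, &y, &d);
    score[i] = s; nb[i] = b; ny[i] = y; dot[i] = d;
  }
  return DataFrame::create(_["score"] = score, _["n_b"] = nb,
                           _["n_y"] = ny, _["dot"] = dot);
}
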