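#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// log(exp(x) + exp(y)) without leaving log space
static inline double logadd(double x, double y) {
  if (x == R_NegInf) return y;
  if (y == R_NegInf) return x;
  double m = std::max(x, y);
  return m + log1p(std::exp(std::min(x, y) - m));
}

// ln of unsigned Stirling numbers of the first kind, row n: s(n, a), a = 1..n.
// Recurrence s(n+1, a) = s(n, a-1) + n * s(n, a), run entirely in log space;
// s(n, 1) = (n-1)!, s(n, n) = 1.
// [[Rcpp::export]]
NumericVector log_stirling_row_cpp(int n) {
  if (n < 1) stop("n must be >= 1");
  std::vector<double> row(1, 0.0); // row for n = 1: s(1,1) = 1
  for (int k = 1; k < n; ++k) {
    std::vector<double> nxt(k + 1);
    double logk = std::log((double)k);
    for (int a = 0; a <= k; ++a) { // a is 0-based index for abundance class a+1
      double from_left = (a >= 1) ? row[a - 1] : R_NegInf;
      double from_same = (a < k) ? logk + row[a] : R_NegInf;
      nxt[a] = logadd(from_left, from_same);
    }
    row.swap(nxt);
  }
  return NumericVector(row.begin(), row.end());
}

// ln K(D, A) for A = S..J. Per species i the coefficient vector is
// c_i(a) = ln s(n_i, a) + lgamma(a) - lgamma(n_i), a = 1..n_i
// (lgamma(a) = ln s(a,1), lgamma(n_i) = ln s(n_i,1)); the S vectors are
// convolved sequentially in log space.
// [[Rcpp::export]]
NumericVector etienne_logK_cpp(IntegerVector abund) {
  int S = abund.size();
  if (S < 1) stop("need at least one species");
  std::vector<int> n(abund.begin(), abund.end());
  for (int i = 0; i < S; ++i)
    if (n[i] < 1) stop("abundances must be positive integers");
  // descending abundance: convolution order fixed for determinism
  std::sort(n.begin(), n.end(), std::greater<int>());
  int nmax = n[0];

  // roll the Stirling triangle once up to nmax, capturing the coefficient
  // vector for each distinct abundance present
  std::vector<std::vector<double> > coef(nmax + 1);
  std::vector<bool> need(nmax + 1, false);
  for (int i = 0; i < S; ++i) need[n[i]] = true;
  {
    std::vector<double> row(1, 0.0);
    for (int k = 1; k <= nmax; ++k) {
      if (k > 1) {
        std::vector<double> nxt(k);
        double logk = std::log((double)(k - 1));
        for (int a = 0; a < k; ++a) {
          double from_left = (a >= 1) ? row[a - 1] : R_NegInf;
          double from_same = (a < k - 1) ? logk + row[a] : R_NegInf;
          nxt[a] = logadd(from_left, from_same);
        }
        row.swap(nxt);
      }
      if (need[k]) {
        std::vector<double> c(k);
        for (int a = 1; a <= k; ++a)
          c[a - 1] = row[a - 1] + lgamma((double)a) - lgamma((double)k);
        coef[k] = c;
      }
    }
  }

  // sequential log-sum-exp convolution; v[t] = ln K for A = (#species) + t
  std::vector<double> v = coef[n[0]];
  for (int i = 1; i < S; ++i) {
    const std::vector<double>& c = coef[n[i]];
    std::vector<double> out(v.size() + c.size() - 1, R_NegInf);
    for (size_t t = 0; t < v.size(); ++t) {
      if (v[t] == R_NegInf) continue;
      for (size_t u = 0; u < c.size(); ++u)
        out[t + u] = logadd(out[t + u], v[t] + c[u]);
    }
    v.swap(out);
    if (i % 64 == 0) checkUserInterrupt();
  }
  return NumericVector(v.begin(), v.end());
}

// Sequential-urn sampler for a dispersal-limited local community: individual
// j is an immigrant with probability I/(I + j - 1), otherwise a copy of a
// uniformly chosen earlier individual; each immigrant lineage draws its
// species from a Chinese-restaurant process with parameter theta over the
// lineages so far. I = +Inf means every individual immigrates (pure
// Ewens/CRP limit). Uses R's RNG so set.seed() governs the output.
// [[Rcpp::export]]
IntegerVector simulate_urn_cpp(double theta, double I, int J) {
  if (theta <= 0) stop("theta must be positive");
  if (J < 1) stop("J must be >= 1");
  bool all_immigrate = !R_FINITE(I);
  if (!all_immigrate && I <= 0) stop("I must be positive");

  std::vector<int> sp_ind(J);       // species of each individual
  std::vector<int> sp_lin;          // species of each immigrant lineage
  int n_species = 0;

  for (int j = 1; j <= J; ++j) {
    bool immigrant = all_immigrate || (unif_rand() < I / (I + (double)(j - 1)));
    int sp;
    if (immigrant) {
      int a = (int)sp_lin.size() + 1; // this lineage's arrival index
      if (unif_rand() < theta / (theta + (double)(a - 1))) {
        sp = n_species++;
      } else {
        int pick = (int)(unif_rand() * (a - 1));
        if (pick >= a - 1) pick = a - 2;
        sp = sp_lin[pick];
      }
      sp_lin.push_back(sp);
    } else {
      int pick = (int)(unif_rand() * (j - 1));
      if (pick >= j - 1) pick = j - 2;
      sp = sp_ind[pick];
    }
    sp_ind[j - 1] = sp;
  }

  IntegerVector counts(n_species, 0);
  for (int j = 0; j < J; ++j) counts[sp_ind[j]]++;
  return counts;
}
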