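#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double cheb(const double* a, const double* b, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double v = std::fabs(a[k] - b[k]);
    if (v > d) d = v;
  }
  return d;
}

// Template-match counts for sample entropy: number of pairs (i < j) whose
// length-m and length-(m+1) templates are within Chebyshev distance r.
// Self-matches excluded by construction.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int np = n - m;            // number of (m+1)-templates; m-templates: n - m + 1,
                             // but both counts use the first n - m to keep B and A
                             // drawn from the same template set (Richman & Moorman)
  double B = 0.0, A = 0.0;
  const double* p = x.begin();
  for (int i = 0; i < np - 1; ++i) {
    for (int j = i + 1; j < np; ++j) {
      if (cheb(p + i, p + j, m) <= r) {
        B += 1.0;
        if (std::fabs(p[i + m] - p[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(_["B"] = B, _["A"] = A);
}

// Phi_m for approximate entropy: mean over i of log(C_i), where C_i is the
// fraction of templates (self included) within r of template i.
// [[Rcpp::export(name = ".apen_phi")]]
double apen_phi(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m + 1;
  const double* p = x.begin();
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    int c = 0;
    for (int j = 0; j < nt; ++j) {
      if (cheb(p + i, p + j, m) <= r) ++c;
    }
    acc += std::log((double)c / (double)nt);
  }
  return acc / (double)nt;
}

// Mean fuzzy membership over ordered pairs i != j for mean-subtracted
// templates of length m, membership exp(-(d/r)^grad).
// [[Rcpp::export(name = ".fuzzen_phi")]]
double fuzzen_phi(NumericVector x, int m, double r, double grad) {
  int n = x.size();
  int nt = n - m;            // as in Chen et al.: use N - m templates for both m, m+1
  std::vector<double> tpl((size_t)nt * m);
  const double* p = x.begin();
  for (int i = 0; i < nt; ++i) {
    double mu = 0.0;
    for (int k = 0; k < m; ++k) mu += p[i + k];
    mu /= m;
    for (int k = 0; k < m; ++k) tpl[(size_t)i * m + k] = p[i + k] - mu;
  }
  double acc = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = cheb(&tpl[(size_t)i * m], &tpl[(size_t)j * m], m);
      acc += std::exp(-std::pow(d / r, grad));
    }
  }
  return 2.0 * acc / ((double)nt * (nt - 1.0));
}

// Histogram of diagonal line lengths (upper triangle, main diagonal excluded)
// of the recurrence matrix of the (m, tau) delay embedding under Chebyshev
// distance <= eps. Returns counts for lengths 1..max observed.
// [[Rcpp::export(name = ".rqa_diag_hist")]]
IntegerVector rqa_diag_hist(NumericVector x, int m, int tau, double eps) {
  int n = x.size();
  int ne = n - (m - 1) * tau;
  const double* p = x.begin();
  std::vector<int> hist;
  for (int k = 1; k < ne; ++k) {   // diagonal offset
    int run = 0;
    for (int i = 0; i + k < ne; ++i) {
      double d = 0.0;
      for (int q = 0; q < m; ++q) {
        double v = std::fabs(p[i + q * tau] - p[i + k + q * tau]);
        if (v > d) d = v;
      }
      if (d <= eps) {
        ++run;
      } else if (run > 0) {
        if ((int)hist.size() < run) hist.resize(run, 0);
        hist[run - 1] += 1;
        run = 0;
      }
    }
    if (run > 0) {
      if ((int)hist.size() < run) hist.resize(run, 0);
      hist[run - 1] += 1;
    }
  }
  return wrap(hist);
}

// Maximum pairwise Chebyshev distance between embedded points (attractor
// diameter used for the recurrence threshold).
// [[Rcpp::export(name = ".embed_diameter")]]
double embed_diameter(NumericVector x, int m, int tau) {
  int n = x.size();
  int ne = n - (m - 1) * tau;
  const double* p = x.begin();
  double dmax = 0.0;
  for (int i = 0; i < ne - 1; ++i) {
    for (int j = i + 1; j < ne; ++j) {
      double d = 0.0;
      for (int q = 0; q < m; ++q) {
        double v = std::fabs(p[i + q * tau] - p[i + q * tau + (j - i)]);
        if (v > d) d = v;
      }
      if (d > dmax) dmax = d;
    }
  }
  return dmax;
}

// Kennel false-nearest-neighbour fractions for embedding dimensions
// 1..max_m (Euclidean nearest neighbour, self excluded).
// [[Rcpp::export(name = ".fnn_fractions")]]
NumericVector fnn_fractions(NumericVector x, int max_m, int tau,
                            double rtol, double atol) {
  int n = x.size();
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  double sd = 0.0;
  for (int i = 0; i < n; ++i) sd += (x[i] - mu) * (x[i] - mu);
  sd = std::sqrt(sd / (n - 1.0));
  const double* p = x.begin();
  NumericVector out(max_m);
  for (int m = 1; m <= max_m; ++m) {
    int ne = n - m * tau;     // need sample at i + m*tau for the test
    if (ne < 10) { out[m - 1] = NA_REAL; continue; }
    long false_nn = 0, total = 0;
    for (int i = 0; i < ne; ++i) {
      double best = R_PosInf;
      int bi = -1;
      for (int j = 0; j < ne; ++j) {
        if (j == i) continue;
        double d2 = 0.0;
        for (int q = 0; q < m; ++q) {
          double v = p[i + q * tau] - p[j + q * tau];
          d2 += v * v;
          if (d2 >= best) break;
        }
        if (d2 < best) { best = d2; bi = j; }
      }
      if (bi < 0) continue;
      double rd = std::sqrt(best);
      if (rd <= 0) continue;
      double extra = std::fabs(p[i + m * tau] - p[bi + m * tau]);
      double rd1 = std::sqrt(best + extra * extra);
      bool isfalse = (extra / rd > rtol) || (rd1 / sd > atol);
      if (isfalse) ++false_nn;
      ++total;
    }
    out[m - 1] = total > 0 ? (double)false_nn / (double)total : NA_REAL;
  }
  return out;
}
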