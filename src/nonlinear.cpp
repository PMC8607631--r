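#include <Rcpp.h>
using namespace Rcpp;

// LZ76 exhaustive-history parsing: number of distinct words in the
// production-style decomposition of a symbol sequence.
// LZ76 word count via the Kaspar-Schuster scan. Each word is the longest
// block reproducible from the extended history plus one innovation symbol;
// a trailing fully-reproducible block counts as a final word.
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  if (n == 1) return 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// First return times of embedded points to their eps-ball after leaving it
// (recurrence period sequence used by RPDE).
// [[Rcpp::export(name = ".rpde_returns")]]
IntegerVector rpde_returns(NumericVector x, int m, int tau, double eps,
                           int max_base = 4000, int max_scan = 4000) {
  int n = x.size() - (m - 1) * tau;
  if (n < 2) return IntegerVector(0);
  int stride = 1;
  if (max_base > 1 && n > max_base) stride = (n + max_base - 1) / max_base;
  std::vector<int> rets;
  double eps2 = eps * eps;
  for (int i = 0; i < n - 1; i += stride) {
    int horizon = (max_scan > 0 && i + max_scan < n) ? i + max_scan : n;
    // leave the ball
    int j = i + 1;
    bool left = false;
    for (; j < horizon; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = x[j + k * tau] - x[i + k * tau];
        d2 += d * d;
        if (d2 > eps2) break;
      }
      if (d2 > eps2) { left = true; break; }
    }
    if (!left) continue;
    // first re-entry (within the scan horizon; longer excursions censored)
    for (++j; j < horizon; ++j) {
      double d2 = 0.0;
      bool inside = true;
      for (int k = 0; k < m; ++k) {
        double d = x[j + k * tau] - x[i + k * tau];
        d2 += d * d;
        if (d2 > eps2) { inside = false; break; }
      }
      if (inside) { rets.push_back(j - i); break; }
    }
  }
  return wrap(rets);
}

// Pairwise distances between delay-embedded points separated by more than a
// Theiler window; points strided so at most max_points enter the sum.
// [[Rcpp::export(name = ".embed_pairdist")]]
NumericVector embed_pairdist(NumericVector x, int m, int tau, int theiler,
                             int max_points) {
  int n = x.size() - (m - 1) * tau;
  if (n < 2) return NumericVector(0);
  int stride = 1;
  if (max_points > 1 && n > max_points) stride = (n + max_points - 1) / max_points;
  std::vector<int> idx;
  for (int i = 0; i < n; i += stride) idx.push_back(i);
  int np = idx.size();
  std::vector<double> out;
  out.reserve((size_t)np * (np - 1) / 4);
  for (int a = 0; a < np; ++a) {
    for (int b = a + 1; b < np; ++b) {
      if (idx[b] - idx[a] <= theiler) continue;
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = x[idx[b] + k * tau] - x[idx[a] + k * tau];
        d2 += d * d;
      }
      out.push_back(std::sqrt(d2));
    }
  }
  return wrap(out);
}

// Averaged perceptron. y in {-1, +1}; order: 0-based visit order per epoch
// (epochs * n entries). Returns c(intercept, weights).
// [[Rcpp::export(name = ".perceptron_fit")]]
NumericVector perceptron_fit(NumericMatrix X, NumericVector y,
                             IntegerVector order, int epochs) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 0.0), wavg(p, 0.0);
  double b = 0.0, bavg = 0.0;
  long long count = 0;
  int pos = 0;
  for (int e = 0; e < epochs; ++e) {
    for (int t = 0; t < n; ++t, ++pos) {
      int i = order[pos];
      double s = b;
      for (int k = 0; k < p; ++k) s += w[k] * X(i, k);
      if (y[i] * s <= 0) {
        for (int k = 0; k < p; ++k) w[k] += y[i] * X(i, k);
        b += y[i];
      }
      for (int k = 0; k < p; ++k) wavg[k] += w[k];
      bavg += b;
      ++count;
    }
  }
  NumericVector out(p + 1);
  out[0] = bavg / count;
  for (int k = 0; k < p; ++k) out[k + 1] = wavg[k] / count;
  return out;
}

// Passive-Aggressive I (hinge, aggressiveness C). Returns c(intercept, weights).
// [[Rcpp::export(name = ".pa_fit")]]
NumericVector pa_fit(NumericMatrix X, NumericVector y,
                     IntegerVector order, int epochs, double C) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 0.0);
  double b = 0.0;
  int pos = 0;
  for (int e = 0; e < epochs; ++e) {
    for (int t = 0; t < n; ++t, ++pos) {
      int i = order[pos];
      double s = b;
      double norm2 = 1.0; // intercept counts in the squared norm
      for (int k = 0; k < p; ++k) {
        s += w[k] * X(i, k);
        norm2 += X(i, k) * X(i, k);
      }
      double loss = 1.0 - y[i] * s;
      if (loss > 0) {
        double tau = loss / norm2;
        if (tau > C) tau = C; // PA-I clipping
        for (int k = 0; k < p; ++k) w[k] += tau * y[i] * X(i, k);
        b += tau * y[i];
      }
    }
  }
  NumericVector out(p + 1);
  out[0] = b;
  for (int k = 0; k < p; ++k) out[k + 1] = w[k];
  return out;
}
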