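#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty and no free
// end gaps. Scores are kept in doubles; with integer-valued parameters all
// arithmetic is exact, so equality tests in the traceback are safe.

struct NWResult {
  double score;
  int matches;
  int columns;
};

static NWResult nw_pair(const std::string &a, const std::string &b,
                        double match, double mismatch, double gap) {
  const int m = a.size(), n = b.size();
  std::vector<double> S((m + 1) * (n + 1));
  const int W = n + 1;
  S[0] = 0.0;
  for (int i = 1; i <= m; ++i) S[i * W] = i * gap;
  for (int j = 1; j <= n; ++j) S[j] = j * gap;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double d = S[(i - 1) * W + (j - 1)] +
        (a[i - 1] == b[j - 1] ? match : mismatch);
      const double u = S[(i - 1) * W + j] + gap;
      const double l = S[i * W + (j - 1)] + gap;
      double best = d;
      if (u > best) best = u;
      if (l > best) best = l;
      S[i * W + j] = best;
    }
  }
  // Traceback from (m, n); among score-tied moves prefer diagonal, then a gap
  // in the second sequence (up), then a gap in the first (left).
  int i = m, j = n, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i * W + j] == S[(i - 1) * W + (j - 1)] +
          (a[i - 1] == b[j - 1] ? match : mismatch)) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && S[i * W + j] == S[(i - 1) * W + j] + gap) {
      --i;
    } else {
      --j;
    }
    ++columns;
  }
  NWResult r;
  r.score = S[m * W + n];
  r.matches = matches;
  r.columns = columns;
  return r;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  NWResult r = nw_pair(a, b, match, mismatch, gap);
  return List::create(_["score"] = r.score,
                      _["matches"] = r.matches,
                      _["columns"] = r.columns,
                      _["identity"] = (double)r.matches / (double)r.columns);
}

// Pairwise identity matrix between two sets of sequences.
// [[Rcpp::export]]
NumericMatrix nw_identity_cross_cpp(CharacterVector x, CharacterVector y,
                                    double match, double mismatch, double gap) {
  const int nx = x.size(), ny = y.size();
  NumericMatrix out(nx, ny);
  std::vector<std::string> xs(nx), ys(ny);
  for (int i = 0; i < nx; ++i) xs[i] = as<std::string>(x[i]);
  for (int j = 0; j < ny; ++j) ys[j] = as<std::string>(y[j]);
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      NWResult r = nw_pair(xs[i], ys[j], match, mismatch, gap);
      out(i, j) = (double)r.matches / (double)r.columns;
    }
  }
  return out;
}

// Symmetric identity matrix within one set (computes each pair once).
// [[Rcpp::export]]
NumericMatrix nw_identity_self_cpp(CharacterVector x,
                                   double match, double mismatch, double gap) {
  const int n = x.size();
  NumericMatrix out(n, n);
  std::vector<std::string> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = as<std::string>(x[i]);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      NWResult r = nw_pair(xs[i], xs[j], match, mismatch, gap);
      double id = (double)r.matches / (double)r.columns;
      out(i, j) = id;
      out(j, i) = id;
    }
  }
  return out;
}

// Hamming distances between each observed string and each reference string.
// Strings of unequal length get NA.
// [[Rcpp::export]]
IntegerMatrix hamming_cross_cpp(CharacterVector obs, CharacterVector ref) {
  const int no = obs.size(), nr = ref.size();
  IntegerMatrix out(no, nr);
  std::vector<std::string> os(no), rs(nr);
  for (int i = 0; i < no; ++i) os[i] = as<std::string>(obs[i]);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(ref[j]);
  for (int i = 0; i < no; ++i) {
    for (int j = 0; j < nr; ++j) {
      if (os[i].size() != rs[j].size()) {
        out(i, j) = NA_INTEGER;
        continue;
      }
      int d = 0;
      for (size_t k = 0; k < os[i].size(); ++k)
        if (os[i][k] != rs[j][k]) ++d;
      out(i, j) = d;
    }
  }
  return out;
}

// Largest k >= min_overlap such that the length-k suffix of fwd equals the
// length-k prefix of rev_rc (the reverse-complemented reverse mate); 0 if no
// qualifying overlap exists. Vectorized over read pairs.
// [[Rcpp::export]]
IntegerVector find_overlap_cpp(CharacterVector fwd, CharacterVector rev_rc,
                               int min_overlap) {
  const int n = fwd.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const std::string f = as<std::string>(fwd[r]);
    const std::string g = as<std::string>(rev_rc[r]);
    const int kmax = std::min(f.size(), g.size());
    int found = 0;
    for (int k = kmax; k >= min_overlap && k > 0; --k) {
      bool ok = true;
      const size_t off = f.size() - k;
      for (int p = 0; p < k; ++p) {
        if (f[off + p] != g[p]) { ok = false; break; }
      }
      if (ok) { found = k; break; }
    }
    out[r] = found;
  }
  return out;
}

// Mean Phred+33 quality per record.
// [[Rcpp::export]]
NumericVector phred_mean_cpp(CharacterVector qual) {
  const int n = qual.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const std::string q = as<std::string>(qual[i]);
    if (q.empty()) { out[i] = NA_REAL; continue; }
    double s = 0.0;
    for (size_t k = 0; k < q.size(); ++k) s += (double)(q[k] - 33);
    out[i] = s / q.size();
  }
  return out;
}
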