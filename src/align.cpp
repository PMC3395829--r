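#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Needleman-Wunsch global alignment with linear gap scoring and a
// deterministic traceback that prefers diagonal, then up (gap in b),
// then left (gap in a) among equally scoring moves.
//
// Characters are compared by equality: identical characters (including
// N == N) score `match`, everything else `mismatch`.

static void nw_one(const std::string& a, const std::string& b,
                   double match, double mismatch, double gap,
                   std::string& row_a, std::string& row_b, double& score) {
  const int m = a.size(), n = b.size();
  std::vector<double> prev(n + 1), cur(n + 1);
  // dir: 0 = diag, 1 = up (consume a), 2 = left (consume b)
  std::vector<unsigned char> dir((m + 1) * (n + 1));
  prev[0] = 0.0;
  for (int j = 1; j <= n; ++j) { prev[j] = j * gap; dir[j] = 2; }
  for (int i = 1; i <= m; ++i) {
    cur[0] = i * gap;
    dir[i * (n + 1)] = 1;
    const char ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      double d = prev[j - 1] + (ai == b[j - 1] ? match : mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double best; unsigned char bd;
      if (d >= u && d >= l) { best = d; bd = 0; }
      else if (u >= l)      { best = u; bd = 1; }
      else                  { best = l; bd = 2; }
      cur[j] = best;
      dir[i * (n + 1) + j] = bd;
    }
    std::swap(prev, cur);
  }
  score = prev[n];
  std::string ra, rb;
  ra.reserve(m + n); rb.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    unsigned char d = dir[i * (n + 1) + j];
    if (i > 0 && j > 0 && d == 0) {
      ra.push_back(a[--i]); rb.push_back(b[--j]);
    } else if (i > 0 && (d == 1 || j == 0)) {
      ra.push_back(a[--i]); rb.push_back('-');
    } else {
      ra.push_back('-'); rb.push_back(b[--j]);
    }
  }
  row_a.assign(ra.rbegin(), ra.rend());
  row_b.assign(rb.rbegin(), rb.rend());
}

// [[Rcpp::export(name = ".nw_align_pairs")]]
List nw_align_pairs(CharacterVector a, CharacterVector b,
                    double match, double mismatch, double gap) {
  if (a.size() != b.size())
    stop("a and b must have the same length");
  const int np = a.size();
  CharacterVector ra(np), rb(np);
  NumericVector sc(np);
  for (int k = 0; k < np; ++k) {
    std::string row_a, row_b;
    double score;
    nw_one(as<std::string>(a[k]), as<std::string>(b[k]),
           match, mismatch, gap, row_a, row_b, score);
    ra[k] = row_a; rb[k] = row_b; sc[k] = score;
  }
  return List::create(_["row_a"] = ra, _["row_b"] = rb, _["score"] = sc);
}
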