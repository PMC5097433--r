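#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment score (Smith-Waterman, Gotoh recurrences).
// A gap of length L costs gap_open + (L - 1) * gap_extend. Score only; the
// similarity graph needs nothing else.
// [[Rcpp::export(name = ".sw_score_affine")]]
double sw_score_affine(std::string a, std::string b,
                       double match = 2.0, double mismatch = -1.0,
                       double gap_open = 4.0, double gap_extend = 1.0) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const double NEG = -1e18;
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0;
    Fcur[0] = NEG;
    double E = NEG; // gap in a (consumes b); in-row recurrence
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      E = std::max(Hcur[j - 1] - gap_open, E - gap_extend);
      Fcur[j] = std::max(Hprev[j] - gap_open, Fprev[j] - gap_extend);
      double h = Hprev[j - 1] + s;
      h = std::max(h, E);
      h = std::max(h, Fcur[j]);
      h = std::max(h, 0.0);
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  return best;
}

// Global alignment (Needleman-Wunsch) with linear gap penalty and a fixed
// traceback preference diagonal > up > left ("up" consumes a residue of the
// first sequence). Returns score, identity (identical positions over
// alignment length including gaps), alignment length and identical count.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = -1.0,
                  double gap = -2.0) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  NumericMatrix S(n + 1, m + 1);
  for (int i = 0; i <= n; ++i) S(i, 0) = i * gap;
  for (int j = 0; j <= m; ++j) S(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sd = S(i - 1, j - 1) + ((a[i - 1] == b[j - 1]) ? match : mismatch);
      double su = S(i - 1, j) + gap;
      double sl = S(i, j - 1) + gap;
      S(i, j) = std::max(sd, std::max(su, sl));
    }
  }
  // traceback, preference diagonal > up > left
  int i = n, j = m;
  int len = 0, ident = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double sd = S(i - 1, j - 1) + ((a[i - 1] == b[j - 1]) ? match : mismatch);
      if (S(i, j) == sd) {
        if (a[i - 1] == b[j - 1]) ++ident;
        --i; --j; ++len;
        continue;
      }
    }
    if (i > 0 && S(i, j) == S(i - 1, j) + gap) {
      --i; ++len;
      continue;
    }
    --j; ++len;
  }
  return List::create(_["score"] = S(n, m),
                      _["identity"] = (double)ident / (double)len,
                      _["align_length"] = len,
                      _["n_identical"] = ident);
}
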