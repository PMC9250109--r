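#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman. Gap of length k costs gap_open + k * gap_extend
// (both negative), i.e. the opening penalty is charged on top of the per-base
// extension for the first gapped base. 'N' (or any non-ACGT byte) scores as a
// mismatch against everything, including itself.

static inline bool is_match(char a, char b) {
  if (a == 'N' || b == 'N') return false;
  return a == b;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  // H: best local score ending at (i,j); E: gap in a (consumes b); F: gap in b.
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, R_NegInf), Ecur(m + 1, R_NegInf);
  std::vector<double> Fprev(m + 1, R_NegInf), Fcur(m + 1, R_NegInf);
  // traceback state per cell: 0 stop, 1 diag, 2 from E (gap in a), 3 from F.
  // plus whether E/F continued an existing gap.
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0); // 1 = extend
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  const size_t W = (size_t)(m + 1);

  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = R_NegInf; Fcur[0] = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      // E: gap in a, coming from the left
      double e_open = Hcur[j - 1] + gap_open + gap_extend;
      double e_ext  = Ecur[j - 1] + gap_extend;
      if (e_ext > e_open) { Ecur[j] = e_ext; tbE[i * W + j] = 1; }
      else { Ecur[j] = e_open; tbE[i * W + j] = 0; }
      // F: gap in b, coming from above
      double f_open = Hprev[j] + gap_open + gap_extend;
      double f_ext  = Fprev[j] + gap_extend;
      if (f_ext > f_open) { Fcur[j] = f_ext; tbF[i * W + j] = 1; }
      else { Fcur[j] = f_open; tbF[i * W + j] = 0; }

      double s = is_match(a[i - 1], b[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + s;
      double h = 0.0; unsigned char st = 0;
      if (diag > h) { h = diag; st = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; st = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; st = 3; }
      Hcur[j] = h; tbH[i * W + j] = st;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER, _["a_gapped"] = "",
                        _["b_gapped"] = "");
  }

  // Traceback needs full matrices; redo DP storing H rows is avoided by the
  // state matrices above, which are complete. Walk back from (bi, bj).
  std::string ag, bg;
  int i = bi, j = bj;
  int state = 0; // 0 = in H
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char st = tbH[i * W + j];
      if (st == 0) break;
      if (st == 1) { ag.push_back(a[i - 1]); bg.push_back(b[j - 1]); --i; --j; }
      else if (st == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // gap in a
      ag.push_back('-'); bg.push_back(b[j - 1]);
      unsigned char ext = tbE[i * W + j];
      --j;
      if (!ext) state = 0;
    } else { // gap in b
      ag.push_back(a[i - 1]); bg.push_back('-');
      unsigned char ext = tbF[i * W + j];
      --i;
      if (!ext) state = 0;
    }
  }
  std::reverse(ag.begin(), ag.end());
  std::reverse(bg.begin(), bg.end());

  return List::create(_["score"] = best,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["a_gapped"] = ag, _["b_gapped"] = bg);
}
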