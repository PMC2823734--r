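#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment of a protein against a position-specific
// score matrix with affine gaps (cost of a length-k gap: open + k * extend).
// Residue codes: 0..19 index pssm rows; -1 = unknown residue (scores 0);
// -2 = masked position (strongly negative, used to find sub-optimal hits).
// Returns c(score, prot_start, prot_end, prof_start, prof_end) with 0-based
// half-open coordinates. Alignment start positions are propagated through the
// DP so no traceback matrix is kept.
// [[Rcpp::export]]
NumericVector sw_pssm_core(IntegerVector seq, NumericMatrix pssm,
                           double gap_open, double gap_extend) {
  const int L = seq.size();
  const int m = pssm.ncol();
  const double NEG = -1e30;
  const double MASKED = -1e9;

  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  std::vector<int> HprevOi(m + 1, 0), HcurOi(m + 1, 0);
  std::vector<int> HprevOj(m + 1, 0), HcurOj(m + 1, 0);
  std::vector<int> EprevOi(m + 1, 0), EcurOi(m + 1, 0);
  std::vector<int> EprevOj(m + 1, 0), EcurOj(m + 1, 0);

  double best = 0.0;
  int bi = 0, bj = 0, boi = 0, boj = 0;

  for (int i = 1; i <= L; ++i) {
    int code = seq[i - 1];
    double F = NEG;
    int Foi = 0, Foj = 0;
    Hcur[0] = 0.0; Ecur[0] = NEG;
    HcurOi[0] = i; HcurOj[0] = 0;
    for (int j = 1; j <= m; ++j) {
      double sub;
      if (code >= 0) sub = pssm(code, j - 1);
      else if (code == -1) sub = 0.0;
      else sub = MASKED;

      // E: gap in profile (protein residue skipped), vertical move
      double e_open = Hprev[j] - gap_open - gap_extend;
      double e_ext  = Eprev[j] - gap_extend;
      double e; int eoi, eoj;
      if (e_open >= e_ext) { e = e_open; eoi = HprevOi[j]; eoj = HprevOj[j]; }
      else                 { e = e_ext;  eoi = EprevOi[j]; eoj = EprevOj[j]; }

      // F: gap in protein (profile position skipped), horizontal move
      double f_open = Hcur[j - 1] - gap_open - gap_extend;
      double f_ext  = F - gap_extend;
      if (f_open >= f_ext) { F = f_open; Foi = HcurOi[j - 1]; Foj = HcurOj[j - 1]; }
      else                 { F = f_ext; }

      // diagonal
      double diag = Hprev[j - 1] + sub;
      int doi = HprevOi[j - 1], doj = HprevOj[j - 1];
      // a zero cell starts a fresh local alignment just before this match
      if (Hprev[j - 1] == 0.0) { doi = i - 1; doj = j - 1; }

      double h = 0.0; int hoi = i, hoj = j;  // restart
      if (diag > h) { h = diag; hoi = doi; hoj = doj; }
      if (e > h)    { h = e;    hoi = eoi; hoj = eoj; }
      if (F > h)    { h = F;    hoi = Foi; hoj = Foj; }

      Hcur[j] = h; HcurOi[j] = hoi; HcurOj[j] = hoj;
      Ecur[j] = e; EcurOi[j] = eoi; EcurOj[j] = eoj;

      if (h > best) { best = h; bi = i; bj = j; boi = hoi; boj = hoj; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
    std::swap(HprevOi, HcurOi); std::swap(HprevOj, HcurOj);
    std::swap(EprevOi, EcurOi); std::swap(EprevOj, EcurOj);
  }

  return NumericVector::create(best, boi, bi, boj, bj);
}
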