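#include <Rcpp.h>
using namespace Rcpp;

// Pairwise FC kernels.  Each mirrors the scalar R implementation (aec, pli,
// plt, jpe) exactly; equality is asserted in the test suite.

static double pearson(const std::vector<double>& a,
                      const std::vector<double>& b) {
  const int m = a.size();
  double ma = 0, mb = 0;
  for (int k = 0; k < m; ++k) { ma += a[k]; mb += b[k]; }
  ma /= m; mb /= m;
  double sab = 0, saa = 0, sbb = 0;
  for (int k = 0; k < m; ++k) {
    double da = a[k] - ma, db = b[k] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

// Amplitude envelope correlation for all channel pairs from the analytic
// signals (zr + i*zi, channels in rows).  corrected = pairwise time-domain
// orthogonalization (remove the least-squares projection of the real
// signals; the analytic residual is zy - beta*zx by linearity of the
// Hilbert transform), both directions averaged.  A numerically null
// residual contributes 0 (volume-conduction convention).
// [[Rcpp::export]]
NumericMatrix aec_all_pairs_cpp(NumericMatrix zr, NumericMatrix zi,
                                bool corrected) {
  const int n = zr.nrow(), m = zr.ncol();
  NumericMatrix out(n, n);
  std::vector<double> ex(m), ey(m), er(m);
  std::vector<double> xx(n);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int k = 0; k < m; ++k) s += zr(i, k) * zr(i, k);
    xx[i] = s;
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double val;
      if (!corrected) {
        for (int k = 0; k < m; ++k) {
          ex[k] = std::hypot(zr(i, k), zi(i, k));
          ey[k] = std::hypot(zr(j, k), zi(j, k));
        }
        val = pearson(ex, ey);
      } else {
        double acc = 0;
        int ab[2][2] = {{i, j}, {j, i}};
        for (int dir = 0; dir < 2; ++dir) {
          int x = ab[dir][0], y = ab[dir][1];
          double sxy = 0;
          for (int k = 0; k < m; ++k) sxy += zr(x, k) * zr(y, k);
          double beta = sxy / xx[x];
          double ss = 0;
          for (int k = 0; k < m; ++k) {
            double rr = zr(y, k) - beta * zr(x, k);
            double ri = zi(y, k) - beta * zi(x, k);
            er[k] = std::hypot(rr, ri);
            ex[k] = std::hypot(zr(x, k), zi(x, k));
            ss += rr * rr;
          }
          double r;
          if (ss < 1e-20 * xx[y]) r = 0.0;  // null residual
          else r = pearson(ex, er);
          if (!R_finite(r)) r = 0.0;  // degenerate envelope, as in aec()
          acc += r;
        }
        val = acc / 2.0;
      }
      out(i, j) = out(j, i) = val;
    }
  }
  return out;
}

// PLI and PLT for all pairs from instantaneous phases (channels in rows).
// PLI = |time average of sign(sin(dphi))|, sign(0) contributing 0.
// PLT: T = mean duration (s) of intervals between successive sign changes
// of sin(dphi) (boundary-truncated intervals included; zero samples carry
// the preceding nonzero sign); PLT = 1 - exp(-T); identically-zero phase
// difference gives 0.
// [[Rcpp::export]]
List pli_plt_all_pairs_cpp(NumericMatrix phase, double fs) {
  const int n = phase.nrow(), m = phase.ncol();
  NumericMatrix pli(n, n), plt(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double acc = 0;
      int changes = 0, prev = 0;
      bool anynz = false;
      for (int k = 0; k < m; ++k) {
        double s = std::sin(phase(i, k) - phase(j, k));
        int sg = (s > 1e-12) - (s < -1e-12);  // dead zone matches sign_eps()
        acc += sg;
        if (sg != 0) {
          anynz = true;
          if (prev != 0 && sg != prev) ++changes;
          prev = sg;
        }
      }
      pli(i, j) = pli(j, i) = std::fabs(acc / m);
      double v;
      if (!anynz) v = 0.0;
      else {
        double T = (m / fs) / (changes + 1);
        v = 1.0 - std::exp(-T);
      }
      plt(i, j) = plt(j, i) = v;
    }
  }
  return List::create(_["pli"] = pli, _["plt"] = plt);
}

// Joint permutation entropy for all pairs from ordinal pattern codes
// (1-based, channels in rows).  revmap[c-1] is the code of the
// amplitude-reversed pattern; pairs with cy == cx (symmetric) or
// cy == revmap[cx] (anti-symmetric) are excluded.  H is the Shannon entropy
// (natural log) of the remaining joint histogram; the value returned is
// 1 - H/hmax (or -H/hmax in literal mode).  All-excluded pairs give 1
// (fully symmetric degenerate case).
// [[Rcpp::export]]
NumericMatrix jpe_all_pairs_cpp(IntegerMatrix codes, IntegerVector revmap,
                                int npat, double hmax, bool literal) {
  const int n = codes.nrow(), m = codes.ncol();
  NumericMatrix out(n, n);
  std::vector<int> counts(npat * npat);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      std::fill(counts.begin(), counts.end(), 0);
      int tot = 0;
      for (int k = 0; k < m; ++k) {
        int cx = codes(i, k), cy = codes(j, k);
        if (cy == cx || cy == revmap[cx - 1]) continue;
        ++counts[(cx - 1) * npat + (cy - 1)];
        ++tot;
      }
      double val;
      if (tot == 0) val = 1.0;  // degenerate: fully (anti)symmetric
      else {
        double H = 0;
        for (int c = 0; c < npat * npat; ++c)
          if (counts[c] > 0) {
            double p = (double)counts[c] / tot;
            H -= p * std::log(p);
          }
        val = literal ? -H / hmax : 1.0 - H / hmax;
      }
      out(i, j) = out(j, i) = val;
    }
  }
  return out;
}
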