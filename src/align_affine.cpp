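#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (end-to-end) pairwise alignment with affine gap costs, Gotoh
// three-state dynamic programme.  A gap run of length L costs
// gap_open + L * gap_extend.  Ties are broken deterministically during
// traceback: diagonal (match state), then up (gap in b), then left
// (gap in a), applied both to the state chosen at a cell and to the
// predecessor state recorded for it.

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List align_affine_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  // state 0 = M (a[i] ~ b[j]); 1 = X (gap in b, consumes a); 2 = Y (gap in a)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> tM((n + 1) * (m + 1), -1);
  std::vector<signed char> tX((n + 1) * (m + 1), -1);
  std::vector<signed char> tY((n + 1) * (m + 1), -1);
  const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[IDX(i, 0)] = gap_open + i * gap_extend;
    tX[IDX(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[IDX(0, j)] = gap_open + j * gap_extend;
    tY[IDX(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M
      {
        double best = M[IDX(i - 1, j - 1)];
        signed char arg = 0;
        if (X[IDX(i - 1, j - 1)] > best) { best = X[IDX(i - 1, j - 1)]; arg = 1; }
        if (Y[IDX(i - 1, j - 1)] > best) { best = Y[IDX(i - 1, j - 1)]; arg = 2; }
        if (best > NEG_INF / 2) {
          M[IDX(i, j)] = best + s;
          tM[IDX(i, j)] = arg;
        }
      }
      // X: consume a[i-1], gap in b
      {
        double best = NEG_INF;
        signed char arg = -1;
        if (M[IDX(i - 1, j)] > NEG_INF / 2 &&
            M[IDX(i - 1, j)] + gap_open + gap_extend > best) {
          best = M[IDX(i - 1, j)] + gap_open + gap_extend; arg = 0;
        }
        if (X[IDX(i - 1, j)] > NEG_INF / 2 &&
            X[IDX(i - 1, j)] + gap_extend > best) {
          best = X[IDX(i - 1, j)] + gap_extend; arg = 1;
        }
        if (Y[IDX(i - 1, j)] > NEG_INF / 2 &&
            Y[IDX(i - 1, j)] + gap_open + gap_extend > best) {
          best = Y[IDX(i - 1, j)] + gap_open + gap_extend; arg = 2;
        }
        if (arg >= 0) { X[IDX(i, j)] = best; tX[IDX(i, j)] = arg; }
      }
      // Y: consume b[j-1], gap in a
      {
        double best = NEG_INF;
        signed char arg = -1;
        if (M[IDX(i, j - 1)] > NEG_INF / 2 &&
            M[IDX(i, j - 1)] + gap_open + gap_extend > best) {
          best = M[IDX(i, j - 1)] + gap_open + gap_extend; arg = 0;
        }
        if (X[IDX(i, j - 1)] > NEG_INF / 2 &&
            X[IDX(i, j - 1)] + gap_open + gap_extend > best) {
          best = X[IDX(i, j - 1)] + gap_open + gap_extend; arg = 1;
        }
        if (Y[IDX(i, j - 1)] > NEG_INF / 2 &&
            Y[IDX(i, j - 1)] + gap_extend > best) {
          best = Y[IDX(i, j - 1)] + gap_extend; arg = 2;
        }
        if (arg >= 0) { Y[IDX(i, j)] = best; tY[IDX(i, j)] = arg; }
      }
    }
  }

  double score = M[IDX(n, m)];
  int state = 0;
  if (X[IDX(n, m)] > score) { score = X[IDX(n, m)]; state = 1; }
  if (Y[IDX(n, m)] > score) { score = Y[IDX(n, m)]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      const signed char prev = tM[IDX(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      const signed char prev = tX[IDX(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      const signed char prev = tY[IDX(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::string oa(ra.rbegin(), ra.rend()), ob(rb.rbegin(), rb.rend());
#undef IDX
  return List::create(_["aligned_a"] = oa, _["aligned_b"] = ob,
                      _["score"] = score);
}
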