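// Computational kernels for the one-factor LTRC model.
//
// Conventions: all latent component pmfs (pA, pB, pC) live on 0-based
// integer grids; SV[j] = P(V > j) with SV[len-1] = 0 (closed grid).
// Out-of-range lookups follow the natural extensions: pmf 0 outside the
// grid, survival 1 below and 0 above.

#include <Rcpp.h>
using namespace Rcpp;

static inline double pm(const NumericVector& p, int k) {
  return (k >= 0 && k < p.size()) ? p[k] : 0.0;
}
static inline double sv(const NumericVector& S, int k) {
  if (k < 0) return 1.0;
  return (k < S.size()) ? S[k] : 0.0;
}

// Joint pmf table of (X, Y) = (A + B, A + C) by discrete convolution.
// Rows index x = 0..(nA + nB - 2), columns y = 0..(nA + nC - 2).
// [[Rcpp::export]]
NumericMatrix cpp_joint_pmf(NumericVector pA, NumericVector pB,
                            NumericVector pC) {
  int nA = pA.size(), nB = pB.size(), nC = pC.size();
  NumericMatrix P(nA + nB - 1, nA + nC - 1);
  for (int a = 0; a < nA; ++a) {
    double pa = pA[a];
    if (pa == 0.0) continue;
    for (int b = 0; b < nB; ++b) {
      double pab = pa * pB[b];
      if (pab == 0.0) continue;
      for (int c = 0; c < nC; ++c)
        P(a + b, a + c) += pab * pC[c];
    }
  }
  return P;
}

// One E-step pass over (grouped) observations: for each record
// (x, y, dX, dY) with multiplicity w, form the conditional pmf of each
// latent component given the observed event, normalize it by the sum of
// its numerator (which equals the probability of the observed event), and
// accumulate w * conditional into the per-component aggregates.
// Returns the aggregates and the per-record event probability.
// [[Rcpp::export]]
List cpp_estep_obs(NumericVector pA, NumericVector SA,
                   NumericVector pB, NumericVector SB,
                   NumericVector pC, NumericVector SC,
                   IntegerVector x, IntegerVector y,
                   IntegerVector dX, IntegerVector dY,
                   NumericVector w) {
  int nA = pA.size(), nB = pB.size(), nC = pC.size(), n = x.size();
  NumericVector aggA(nA), aggB(nB), aggC(nC), denom(n);
  std::vector<double> numA(nA), numB(nB), numC(nC), suf(nA + 1);

  for (int i = 0; i < n; ++i) {
    int xi = x[i], yi = y[i];
    bool ex = dX[i] == 1, ey = dY[i] == 1;

    // conditional of the common component A
    double sumA = 0.0;
    for (int a = 0; a < nA; ++a) {
      double v = pA[a];
      if (v != 0.0) {
        v *= ex ? pm(pB, xi - a) : sv(SB, xi - a);
        if (v != 0.0) v *= ey ? pm(pC, yi - a) : sv(SC, yi - a);
      }
      numA[a] = v; sumA += v;
    }

    // conditional of B; when X is censored the numerator involves a
    // suffix sum over A, precomputed once per record
    double sumB = 0.0;
    if (ex) {
      for (int b = 0; b < nB; ++b) {
        double v = pB[b] * pm(pA, xi - b);
        if (v != 0.0)
          v *= ey ? pm(pC, yi - xi + b) : sv(SC, yi - xi + b);
        numB[b] = v; sumB += v;
      }
    } else {
      suf[nA] = 0.0;
      for (int a = nA - 1; a >= 0; --a)
        suf[a] = suf[a + 1] +
          pA[a] * (ey ? pm(pC, yi - a) : sv(SC, yi - a));
      for (int b = 0; b < nB; ++b) {
        int a0 = xi - b + 1; if (a0 < 0) a0 = 0;
        double v = (a0 < nA) ? pB[b] * suf[a0] : 0.0;
        numB[b] = v; sumB += v;
      }
    }

    // conditional of C, symmetric to B
    double sumC = 0.0;
    if (ey) {
      for (int c = 0; c < nC; ++c) {
        double v = pC[c] * pm(pA, yi - c);
        if (v != 0.0)
          v *= ex ? pm(pB, xi - yi + c) : sv(SB, xi - yi + c);
        numC[c] = v; sumC += v;
      }
    } else {
      suf[nA] = 0.0;
      for (int a = nA - 1; a >= 0; --a)
        suf[a] = suf[a + 1] +
          pA[a] * (ex ? pm(pB, xi - a) : sv(SB, xi - a));
      for (int c = 0; c < nC; ++c) {
        int a0 = yi - c + 1; if (a0 < 0) a0 = 0;
        double v = (a0 < nA) ? pC[c] * suf[a0] : 0.0;
        numC[c] = v; sumC += v;
      }
    }

    denom[i] = sumA;
    if (sumA <= 0.0 || sumB <= 0.0 || sumC <= 0.0) continue;
    double wi = w[i];
    for (int a = 0; a < nA; ++a) aggA[a] += wi * numA[a] / sumA;
    for (int b = 0; b < nB; ++b) aggB[b] += wi * numB[b] / sumB;
    for (int c = 0; c < nC; ++c) aggC[c] += wi * numC[c] / sumC;
  }
  return List::create(_["aggA"] = aggA, _["aggB"] = aggB,
                      _["aggC"] = aggC, _["denom"] = denom);
}

// Weights of the observation-event conditionals of the latent components:
// DA[a] = sum_{b,c} pB(b) pC(c) H(a+b, a+c) and analogously for B and C,
// where H(x, y) = P(T^X <= x, T^Y <= y) on the model grid.  Then
// p_V(v | observed) = p_V(v) DV[v] / p(obs event).
// [[Rcpp::export]]
List cpp_obs_cond_weights(NumericVector pA, NumericVector pB,
                          NumericVector pC, NumericMatrix H) {
  int nA = pA.size(), nB = pB.size(), nC = pC.size();
  if (H.nrow() != nA + nB - 1 || H.ncol() != nA + nC - 1)
    stop("H must be on the model grid");
  NumericVector DA(nA), DB(nB), DC(nC);
  for (int a = 0; a < nA; ++a) {
    double pa = pA[a];
    for (int b = 0; b < nB; ++b) {
      double pb = pB[b], pab = pa * pb;
      int xi = a + b;
      double da = 0.0;  // accumulate over c for this (a, b)
      for (int c = 0; c < nC; ++c) {
        double h = H(xi, a + c), pc = pC[c];
        da += pb * pc * h;
        DB[b] += pa * pc * h;
        DC[c] += pab * h;
      }
      DA[a] += da;
    }
  }
  return List::create(_["DA"] = DA, _["DB"] = DB, _["DC"] = DC);
}
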