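// Normalised mutual information with differentiable soft binning.
//
// Intensities are expected in [0, 1] (values outside are clamped).  Each
// voxel contributes to the two neighbouring bins with linear (triangular
// Parzen window) weights, which makes the joint histogram — and hence the
// NMI — piecewise-differentiable in the intensities of the second image.
// NMI is the Studholme form (H(A) + H(B)) / H(A,B), in [1, 2].
#include <Rcpp.h>
using namespace Rcpp;

static inline void bin_weights(double v, int nbins, int& i0, double& w1) {
  double t = v < 0 ? 0 : (v > 1 ? 1 : v);
  t *= (nbins - 1);
  i0 = (int)std::floor(t);
  if (i0 >= nbins - 1) i0 = nbins - 2;
  w1 = t - i0;
}

static double entropy(const std::vector<double>& p) {
  double h = 0;
  for (double q : p) if (q > 0) h -= q * std::log(q);
  return h;
}

// Returns list(nmi, grad_b?) where grad_b = d NMI / d b_v (per voxel).
// For constant inputs (zero marginal entropy) NMI is undefined; the
// documented fallback is nmi = 1 (the independence floor) with zero grad.
// [[Rcpp::export]]
List cpp_nmi_soft(NumericVector a, NumericVector b, int nbins, bool want_grad) {
  R_xlen_t n = a.size();
  std::vector<double> P((size_t)nbins * nbins, 0.0);
  std::vector<int> ia(n), ib(n);
  std::vector<double> wa(n), wb(n);
  for (R_xlen_t v = 0; v < n; ++v) {
    bin_weights(a[v], nbins, ia[v], wa[v]);
    bin_weights(b[v], nbins, ib[v], wb[v]);
    double wa0 = 1 - wa[v], wb0 = 1 - wb[v];
    P[ia[v]     + nbins * ib[v]]       += wa0 * wb0;
    P[ia[v] + 1 + nbins * ib[v]]       += wa[v] * wb0;
    P[ia[v]     + nbins * (ib[v] + 1)] += wa0 * wb[v];
    P[ia[v] + 1 + nbins * (ib[v] + 1)] += wa[v] * wb[v];
  }
  for (auto& q : P) q /= (double)n;
  std::vector<double> pa(nbins, 0.0), pb(nbins, 0.0);
  for (int jb = 0; jb < nbins; ++jb)
    for (int ja = 0; ja < nbins; ++ja) {
      pa[ja] += P[ja + nbins * jb];
      pb[jb] += P[ja + nbins * jb];
    }
  double Ha = entropy(pa), Hb = entropy(pb), Hab = entropy(P);
  List res;
  if (Ha < 1e-12 || Hb < 1e-12 || Hab < 1e-12) {
    res["nmi"] = 1.0;
    if (want_grad) {
      NumericVector g(n);
      res["grad_b"] = g;
    }
    return res;
  }
  double nmi = (Ha + Hb) / Hab;
  res["nmi"] = nmi;
  if (want_grad) {
    // d NMI / d P_ij = (dHa/dpa_i + dHb/dpb_j)/Hab - nmi/Hab * dHab/dP_ij
    // with dH/dp = -(log p + 1); constants cancel since sum dP = 0, but we
    // keep them: they are absorbed exactly for weight variations that sum
    // to zero per voxel (they do: the four bin weights always sum to 1).
    std::vector<double> G((size_t)nbins * nbins, 0.0);
    for (int jb = 0; jb < nbins; ++jb)
      for (int ja = 0; ja < nbins; ++ja) {
        double dHa = pa[ja] > 0 ? -(std::log(pa[ja]) + 1) : 0.0;
        double dHb = pb[jb] > 0 ? -(std::log(pb[jb]) + 1) : 0.0;
        double pij = P[ja + nbins * jb];
        double dHab = pij > 0 ? -(std::log(pij) + 1) : 0.0;
        G[ja + nbins * jb] = (dHa + dHb) / Hab - nmi / Hab * dHab;
      }
    NumericVector g(n);
    double scale = (double)(nbins - 1) / n;
    for (R_xlen_t v = 0; v < n; ++v) {
      double bval = b[v];
      if (bval <= 0.0 || bval >= 1.0) continue;  // clamped: zero gradient
      double wa0 = 1 - wa[v];
      int j0 = ib[v];
      // dP/db moves weight from bin j0 to j0+1 at rate (nbins-1)/n
      double d =
          wa0  * (G[ia[v]     + nbins * (j0 + 1)] - G[ia[v]     + nbins * j0]) +
          wa[v]* (G[ia[v] + 1 + nbins * (j0 + 1)] - G[ia[v] + 1 + nbins * j0]);
      g[v] = d * scale;
    }
    res["grad_b"] = g;
  }
  return res;
}

// Hard-binned NMI (equal-width bins on [0,1]) for evaluation.
// [[Rcpp::export]]
double cpp_nmi_hard(NumericVector a, NumericVector b, int nbins) {
  R_xlen_t n = a.size();
  std::vector<double> P((size_t)nbins * nbins, 0.0);
  for (R_xlen_t v = 0; v < n; ++v) {
    double ta = a[v] < 0 ? 0 : (a[v] > 1 ? 1 : a[v]);
    double tb = b[v] < 0 ? 0 : (b[v] > 1 ? 1 : b[v]);
    int ja = (int)(ta * nbins); if (ja >= nbins) ja = nbins - 1;
    int jb = (int)(tb * nbins); if (jb >= nbins) jb = nbins - 1;
    P[ja + nbins * jb] += 1.0;
  }
  for (auto& q : P) q /= (double)n;
  std::vector<double> pa(nbins, 0.0), pb(nbins, 0.0);
  for (int jb = 0; jb < nbins; ++jb)
    for (int ja = 0; ja < nbins; ++ja) {
      pa[ja] += P[ja + nbins * jb];
      pb[jb] += P[ja + nbins * jb];
    }
  double Ha = entropy(pa), Hb = entropy(pb), Hab = entropy(P);
  if (Ha < 1e-12 || Hb < 1e-12 || Hab < 1e-12) return 1.0;
  return (Ha + Hb) / Hab;
}
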