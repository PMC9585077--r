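#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Diploid Li-Stephens forward-backward over ordered pairs of reference
// haplotypes. The transition between adjacent typed sites factorises per
// haplotype: switch with probability rho = 1 - exp(-theta * gap), destination
// uniform over the K reference haplotypes (self included). Applying the
// factorised transition to a K x K table V costs O(K^2):
//   (T V)(k1,k2) = (1-rho)^2 V(k1,k2)
//                + (1-rho)(rho/K) (rowSum_V(k1) + colSum_V(k2))
//                + (rho/K)^2 totalSum_V.
// Emission at a typed site with observed genotype g in {0,1,2} treats each
// observed allele as an independent read of one state haplotype with
// per-allele error eps. Recursions are rescaled per typed site; dosages at
// untyped sites use the haplotype posterior marginals of the flanking typed
// sites, linearly interpolated by distance.
//
// g        : genotypes at the T typed sites (0/1/2, no missing)
// typedIdx : 1-based row index of each typed site within the M panel sites
// H        : M x K reference haplotype alleles (0/1)
// pos      : bp positions of the M panel sites (ascending)
// returns  : list(dosage = length-M expected ALT dosage,
//                 marginals = T x K haplotype posterior marginals
//                             (each row sums to 2),
//                 scales = per-typed-site forward scaling factors)
// [[Rcpp::export]]
List ls_impute_cpp(IntegerVector g, IntegerVector typedIdx, IntegerMatrix H,
                   NumericVector pos, double theta, double eps,
                   double numericalFloor) {
  const int T = g.size();
  const int M = H.nrow();
  const int K = H.ncol();
  if (K < 2) stop("need at least 2 reference haplotypes");
  if (T < 1) stop("no typed sites");

  // emission factors per typed site: probability of observing one ALT read
  // from a haplotype carrying allele a
  std::vector<double> pAlt(static_cast<size_t>(T) * K);
  for (int t = 0; t < T; ++t) {
    const int m = typedIdx[t] - 1;
    for (int k = 0; k < K; ++k) {
      const double a = static_cast<double>(H(m, k));
      pAlt[static_cast<size_t>(t) * K + k] = a * (1.0 - eps) + (1.0 - a) * eps;
    }
  }

  auto emit = [&](int t, int k1, int k2) -> double {
    const double p1 = pAlt[static_cast<size_t>(t) * K + k1];
    const double p2 = pAlt[static_cast<size_t>(t) * K + k2];
    switch (g[t]) {
      case 0: return (1.0 - p1) * (1.0 - p2);
      case 1: return p1 * (1.0 - p2) + (1.0 - p1) * p2;
      default: return p1 * p2;
    }
  };

  const size_t KK = static_cast<size_t>(K) * K;
  std::vector<double> fwd(static_cast<size_t>(T) * KK);
  NumericVector scales(T);

  // forward, scaled to sum 1 at each typed site
  {
    double s = 0.0;
    double *f0 = fwd.data();
    const double prior = 1.0 / (static_cast<double>(K) * K);
    for (int k1 = 0; k1 < K; ++k1)
      for (int k2 = 0; k2 < K; ++k2) {
        const double v = prior * emit(0, k1, k2);
        f0[static_cast<size_t>(k1) * K + k2] = v;
        s += v;
      }
    if (s < numericalFloor) s = numericalFloor;
    scales[0] = s;
    for (size_t i = 0; i < KK; ++i) f0[i] /= s;
  }

  std::vector<double> rowS(K), colS(K);
  for (int t = 1; t < T; ++t) {
    const double *fp = fwd.data() + static_cast<size_t>(t - 1) * KK;
    double *fc = fwd.data() + static_cast<size_t>(t) * KK;
    const double gap = pos[typedIdx[t] - 1] - pos[typedIdx[t - 1] - 1];
    const double rho = 1.0 - std::exp(-theta * gap);
    const double stay = 1.0 - rho;
    const double q = rho / K;
    std::fill(rowS.begin(), rowS.end(), 0.0);
    std::fill(colS.begin(), colS.end(), 0.0);
    double tot = 0.0;
    for (int k1 = 0; k1 < K; ++k1)
      for (int k2 = 0; k2 < K; ++k2) {
        const double v = fp[static_cast<size_t>(k1) * K + k2];
        rowS[k1] += v;
        colS[k2] += v;
        tot += v;
      }
    double s = 0.0;
    for (int k1 = 0; k1 < K; ++k1)
      for (int k2 = 0; k2 < K; ++k2) {
        const double trans = stay * stay * fp[static_cast<size_t>(k1) * K + k2]
          + stay * q * (rowS[k1] + colS[k2]) + q * q * tot;
        const double v = trans * emit(t, k1, k2);
        fc[static_cast<size_t>(k1) * K + k2] = v;
        s += v;
      }
    if (s < numericalFloor) s = numericalFloor;
    scales[t] = s;
    for (size_t i = 0; i < KK; ++i) fc[i] /= s;
  }

  // backward on the fly; accumulate normalised posterior haplotype marginals
  NumericMatrix marg(T, K);
  std::vector<double> bwd(KK, 1.0), vtmp(KK);
  for (int t = T - 1; t >= 0; --t) {
    const double *fc = fwd.data() + static_cast<size_t>(t) * KK;
    double psum = 0.0;
    for (size_t i = 0; i < KK; ++i) psum += fc[i] * bwd[i];
    if (psum < numericalFloor) psum = numericalFloor;
    for (int k1 = 0; k1 < K; ++k1)
      for (int k2 = 0; k2 < K; ++k2) {
        const double p = fc[static_cast<size_t>(k1) * K + k2] *
          bwd[static_cast<size_t>(k1) * K + k2] / psum;
        marg(t, k1) += p;
        marg(t, k2) += p;
      }
    if (t == 0) break;
    // propagate: bwd_{t-1} = Transition applied to (emit_t * bwd_t)
    for (int k1 = 0; k1 < K; ++k1)
      for (int k2 = 0; k2 < K; ++k2)
        vtmp[static_cast<size_t>(k1) * K + k2] =
          emit(t, k1, k2) * bwd[static_cast<size_t>(k1) * K + k2];
    const double gap = pos[typedIdx[t] - 1] - pos[typedIdx[t - 1] - 1];
    const double rho = 1.0 - std::exp(-theta * gap);
    const double stay = 1.0 - rho;
    const double q = rho / K;
    std::fill(rowS.begin(), rowS.end(), 0.0);
    std::fill(colS.begin(), colS.end(), 0.0);
    double tot = 0.0;
    for (int k1 = 0; k1 < K; ++k1)
      for (int k2 = 0; k2 < K; ++k2) {
        const double v = vtmp[static_cast<size_t>(k1) * K + k2];
        rowS[k1] += v;
        colS[k2] += v;
        tot += v;
      }
    double s = 0.0;
    for (int k1 = 0; k1 < K; ++k1)
      for (int k2 = 0; k2 < K; ++k2) {
        const double v = stay * stay * vtmp[static_cast<size_t>(k1) * K + k2]
          + stay * q * (rowS[k1] + colS[k2]) + q * q * tot;
        bwd[static_cast<size_t>(k1) * K + k2] = v;
        s += v;
      }
    if (s < numericalFloor) s = numericalFloor;
    for (size_t i = 0; i < KK; ++i) bwd[i] /= s;
  }

  // dosages over all panel sites: interpolate flanking typed-site marginals
  NumericVector dosage(M);
  int t = 0; // index of the typed site at or after the current panel site
  for (int m = 0; m < M; ++m) {
    while (t < T && typedIdx[t] - 1 < m) ++t;
    int tl, tr;
    double wRight;
    if (t < T && typedIdx[t] - 1 == m) {
      tl = tr = t;
      wRight = 0.0;
    } else if (t == 0) {
      tl = tr = 0;
      wRight = 0.0;
    } else if (t >= T) {
      tl = tr = T - 1;
      wRight = 0.0;
    } else {
      tl = t - 1;
      tr = t;
      const double pl = pos[typedIdx[tl] - 1], pr = pos[typedIdx[tr] - 1];
      wRight = (pos[m] - pl) / (pr - pl);
    }
    double d = 0.0;
    for (int k = 0; k < K; ++k) {
      const double mk = (1.0 - wRight) * marg(tl, k) + wRight * marg(tr, k);
      const double a = static_cast<double>(H(m, k));
      d += mk * (a * (1.0 - 2.0 * eps) + eps);
    }
    dosage[m] = d;
  }

  return List::create(
    _["dosage"] = dosage, _["marginals"] = marg, _["scales"] = scales
  );
}
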