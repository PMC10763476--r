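#include <Rcpp.h>
using namespace Rcpp;

// Haploid Li-Stephens copying model, forward-backward with per-site rescaling.
//
// ref      : L x K integer matrix, reference alleles in {0,1}
// obs      : length-L integer vector of target alleles; NA = no emission
// dist_kb  : length-(L-1) inter-site distances in kb
// rho      : recombination intensity per kb
// eps      : emission mismatch (copy error) probability
//
// Transition across an interval of d kb with K states:
//   t = 1 - exp(-rho * d / K);  stay = exp(-rho*d/K) + t/K;  jump = t/K each.
// Emission: 1 - eps on allele match, eps on mismatch, 1 when obs is NA.

static inline void emissions(const IntegerMatrix& ref, const IntegerVector& obs,
                             int l, double eps, std::vector<double>& e) {
  int K = ref.ncol();
  if (IntegerVector::is_na(obs[l])) {
    std::fill(e.begin(), e.end(), 1.0);
  } else {
    int o = obs[l];
    for (int k = 0; k < K; ++k) e[k] = (ref(l, k) == o) ? (1.0 - eps) : eps;
  }
}

// [[Rcpp::export(name = ".ls_forward_backward")]]
NumericMatrix ls_forward_backward(IntegerMatrix ref, IntegerVector obs,
                                  NumericVector dist_kb, double rho, double eps) {
  int L = ref.nrow(), K = ref.ncol();
  if (obs.size() != L) stop("obs length must equal number of sites");
  if (L > 1 && dist_kb.size() != L - 1) stop("dist_kb must have length L-1");
  NumericMatrix fwd(L, K), bwd(L, K), post(L, K);
  std::vector<double> e(K);

  // forward, normalised to sum 1 at every site
  emissions(ref, obs, 0, eps, e);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { fwd(0, k) = e[k] / K; s += fwd(0, k); }
  for (int k = 0; k < K; ++k) fwd(0, k) /= s;
  for (int l = 1; l < L; ++l) {
    double nr = std::exp(-rho * dist_kb[l - 1] / K);
    double jump = (1.0 - nr) / K;  // t/K
    emissions(ref, obs, l, eps, e);
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      // previous column sums to 1, so the mixed-in mass is exactly jump
      fwd(l, k) = e[k] * (nr * fwd(l - 1, k) + jump);
      s += fwd(l, k);
    }
    if (s <= 0) stop("forward underflow");
    for (int k = 0; k < K; ++k) fwd(l, k) /= s;
  }

  // backward, rescaled to sum 1 at every site (scale cancels in the posterior)
  for (int k = 0; k < K; ++k) bwd(L - 1, k) = 1.0 / K;
  for (int l = L - 2; l >= 0; --l) {
    double nr = std::exp(-rho * dist_kb[l] / K);
    double jump = (1.0 - nr) / K;
    emissions(ref, obs, l + 1, eps, e);
    double mix = 0.0;
    for (int k = 0; k < K; ++k) mix += e[k] * bwd(l + 1, k);
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      bwd(l, k) = nr * e[k] * bwd(l + 1, k) + jump * mix;
      s += bwd(l, k);
    }
    if (s <= 0) stop("backward underflow");
    for (int k = 0; k < K; ++k) bwd(l, k) /= s;
  }

  for (int l = 0; l < L; ++l) {
    s = 0.0;
    for (int k = 0; k < K; ++k) { post(l, k) = fwd(l, k) * bwd(l, k); s += post(l, k); }
    for (int k = 0; k < K; ++k) post(l, k) /= s;
  }
  return post;
}

// Batched allele-1 posteriors: one row of `targets` per haplotype to impute.
// Masked rows of each target must already be NA. Returns an n x M matrix of
// alt-allele posteriors at the (1-based) `sites1` positions.
// [[Rcpp::export(name = ".ls_impute_many")]]
NumericMatrix ls_impute_many(IntegerMatrix ref, IntegerMatrix targets,
                             NumericVector dist_kb, double rho, double eps,
                             IntegerVector sites1) {
  int L = ref.nrow(), K = ref.ncol(), n = targets.nrow(), M = sites1.size();
  if (targets.ncol() != L) stop("targets must have one column per site");
  std::vector<double> nr(L > 0 ? L - 1 : 0), jump(L > 0 ? L - 1 : 0);
  for (int l = 0; l + 1 < L; ++l) {
    nr[l] = std::exp(-rho * dist_kb[l] / K);
    jump[l] = (1.0 - nr[l]) / K;
  }
  std::vector<bool> want(L, false);
  for (int m = 0; m < M; ++m) {
    int l = sites1[m] - 1;
    if (l < 0 || l >= L) stop("site index out of range");
    want[l] = true;
  }
  NumericMatrix out(n, M);
  std::vector<double> fwd((size_t)L * K), e(K), bw(K), bw_next(K), p1(L);
  for (int i = 0; i < n; ++i) {
    IntegerVector obs = targets(i, _);
    emissions(ref, obs, 0, eps, e);
    double s = 0.0;
    for (int k = 0; k < K; ++k) { fwd[k] = e[k] / K; s += fwd[k]; }
    for (int k = 0; k < K; ++k) fwd[k] /= s;
    for (int l = 1; l < L; ++l) {
      emissions(ref, obs, l, eps, e);
      s = 0.0;
      double *fp = &fwd[(size_t)(l - 1) * K], *fc = &fwd[(size_t)l * K];
      for (int k = 0; k < K; ++k) { fc[k] = e[k] * (nr[l - 1] * fp[k] + jump[l - 1]); s += fc[k]; }
      if (s <= 0) stop("forward underflow");
      for (int k = 0; k < K; ++k) fc[k] /= s;
    }
    std::fill(bw.begin(), bw.end(), 1.0 / K);
    for (int l = L - 1; l >= 0; --l) {
      if (l < L - 1) {
        emissions(ref, obs, l + 1, eps, e);
        double mix = 0.0;
        for (int k = 0; k < K; ++k) mix += e[k] * bw_next[k];
        s = 0.0;
        for (int k = 0; k < K; ++k) { bw[k] = nr[l] * e[k] * bw_next[k] + jump[l] * mix; s += bw[k]; }
        for (int k = 0; k < K; ++k) bw[k] /= s;
      }
      if (want[l]) {
        double tot = 0.0, one = 0.0;
        const double *fc = &fwd[(size_t)l * K];
        for (int k = 0; k < K; ++k) {
          double g = fc[k] * bw[k];
          tot += g;
          if (ref(l, k) == 1) one += g;
        }
        double pref1 = one / tot;
        p1[l] = pref1 * (1.0 - eps) + (1.0 - pref1) * eps;
      }
      bw_next = bw;
    }
    for (int m = 0; m < M; ++m) out(i, m) = p1[sites1[m] - 1];
  }
  return out;
}

// Allele-1 posterior at selected sites, without materialising the full
// state-posterior matrix: p(1) = sum_k gamma_k * [1-eps if ref==1 else eps].
// sites1 is 1-based.
// [[Rcpp::export(name = ".ls_allele_posteriors")]]
NumericVector ls_allele_posteriors(IntegerMatrix ref, IntegerVector obs,
                                   NumericVector dist_kb, double rho, double eps,
                                   IntegerVector sites1) {
  int L = ref.nrow(), K = ref.ncol(), M = sites1.size();
  if (obs.size() != L) stop("obs length must equal number of sites");
  NumericMatrix fwd(L, K);
  std::vector<double> e(K), bw(K), bw_next(K);
  emissions(ref, obs, 0, eps, e);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { fwd(0, k) = e[k] / K; s += fwd(0, k); }
  for (int k = 0; k < K; ++k) fwd(0, k) /= s;
  for (int l = 1; l < L; ++l) {
    double nr = std::exp(-rho * dist_kb[l - 1] / K);
    double jump = (1.0 - nr) / K;
    emissions(ref, obs, l, eps, e);
    s = 0.0;
    for (int k = 0; k < K; ++k) { fwd(l, k) = e[k] * (nr * fwd(l - 1, k) + jump); s += fwd(l, k); }
    if (s <= 0) stop("forward underflow");
    for (int k = 0; k < K; ++k) fwd(l, k) /= s;
  }

  std::vector<bool> want(L, false);
  for (int m = 0; m < M; ++m) {
    int l = sites1[m] - 1;
    if (l < 0 || l >= L) stop("site index out of range");
    want[l] = true;
  }
  NumericVector out(M);
  std::vector<double> p1(L, NA_REAL);

  std::fill(bw.begin(), bw.end(), 1.0 / K);
  for (int l = L - 1; l >= 0; --l) {
    if (l < L - 1) {
      double nr = std::exp(-rho * dist_kb[l] / K);
      double jump = (1.0 - nr) / K;
      emissions(ref, obs, l + 1, eps, e);
      double mix = 0.0;
      for (int k = 0; k < K; ++k) mix += e[k] * bw_next[k];
      s = 0.0;
      for (int k = 0; k < K; ++k) { bw[k] = nr * e[k] * bw_next[k] + jump * mix; s += bw[k]; }
      for (int k = 0; k < K; ++k) bw[k] /= s;
    }
    if (want[l]) {
      double tot = 0.0, one = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = fwd(l, k) * bw[k];
        tot += g;
        if (ref(l, k) == 1) one += g;
      }
      double pref1 = one / tot;  // posterior mass on haplotypes carrying allele 1
      p1[l] = pref1 * (1.0 - eps) + (1.0 - pref1) * eps;
    }
    bw_next = bw;
  }
  for (int m = 0; m < M; ++m) out[m] = p1[sites1[m] - 1];
  return out;
}
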