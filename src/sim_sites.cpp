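#include <Rcpp.h>
using namespace Rcpp;

// Site-level trio simulator: Hardy-Weinberg parental genotypes at a drawn
// population allele frequency, Mendelian transmission of one allele per
// parent, optional germline de novo flips of transmitted reference
// alleles, and a sequencing observation layer (Poisson depth truncated at
// 1, binomial alt-read counts, a deterministic depth-driven
// genotype-quality surrogate).
//
// Both exported entry points below draw through sim_site() in the same
// order, so with equal parameters and seed they realise the same data.
// Uses R's RNG throughout: set.seed() in R fixes the full stream.
//
// Genotype coding: 0 = hom-ref, 1 = het, 2 = hom-alt.

struct SimParams {
  double af_min, af_max, dnm_rate, depth_mean, error_rate, gq_slope;
  int gq_cap, gq_low, gq_low_dp;
};

struct SiteDraw {
  double af;
  int fgt, mgt, cgt, tp, tm;
  bool dnm_p, dnm_m;
  int dpf, dpm, dpc, adf, adm, adc, gqf, gqm, gqc;
};

static inline int hw_gt(double p) {
  return (R::unif_rand() < p) + (R::unif_rand() < p);
}

static inline int depth1(double mean) {
  int d = (int) R::rpois(mean);
  return d < 1 ? 1 : d;
}

static inline int alt_reads(int gt, int dp, double err) {
  if (gt == 0) return (int) R::rbinom(dp, err);
  if (gt == 1) return (int) R::rbinom(dp, 0.5);
  return dp - (int) R::rbinom(dp, err);
}

static inline int gq_of(int dp, const SimParams &P) {
  if (dp < P.gq_low_dp) return P.gq_low;
  int g = (int) std::lround(P.gq_slope * dp);
  return g > P.gq_cap ? P.gq_cap : g;
}

static inline void sim_site(const SimParams &P, double af_fixed,
                            SiteDraw &s) {
  double p = af_fixed >= 0.0 ? af_fixed : R::unif_rand() * (P.af_max - P.af_min) + P.af_min;
  s.af = p;
  s.fgt = hw_gt(p);
  s.mgt = hw_gt(p);

  // one transmitted allele per parent; hets transmit either with prob 1/2
  s.tp = (s.fgt == 1) ? (R::unif_rand() < 0.5 ? 1 : 0) : s.fgt / 2;
  s.tm = (s.mgt == 1) ? (R::unif_rand() < 0.5 ? 1 : 0) : s.mgt / 2;

  // de novo mutation: a transmitted ref allele flips to alt
  s.dnm_p = s.dnm_m = false;
  if (P.dnm_rate > 0.0) {
    if (s.tp == 0 && R::unif_rand() < P.dnm_rate) { s.tp = 1; s.dnm_p = true; }
    if (s.tm == 0 && R::unif_rand() < P.dnm_rate) { s.tm = 1; s.dnm_m = true; }
  }
  s.cgt = s.tp + s.tm;

  s.dpf = depth1(P.depth_mean);
  s.dpm = depth1(P.depth_mean);
  s.dpc = depth1(P.depth_mean);
  s.adf = alt_reads(s.fgt, s.dpf, P.error_rate);
  s.adm = alt_reads(s.mgt, s.dpm, P.error_rate);
  s.adc = alt_reads(s.cgt, s.dpc, P.error_rate);
  s.gqf = gq_of(s.dpf, P);
  s.gqm = gq_of(s.dpm, P);
  s.gqc = gq_of(s.dpc, P);
}

static SimParams make_params(double af_min, double af_max, double dnm_rate,
                             double depth_mean, double error_rate,
                             double gq_slope, int gq_cap, int gq_low,
                             int gq_low_dp) {
  SimParams P;
  P.af_min = af_min; P.af_max = af_max; P.dnm_rate = dnm_rate;
  P.depth_mean = depth_mean; P.error_rate = error_rate;
  P.gq_slope = gq_slope; P.gq_cap = gq_cap; P.gq_low = gq_low;
  P.gq_low_dp = gq_low_dp;
  return P;
}

// [[Rcpp::export]]
List sim_trio_sites_cpp(int n,
                        double af_min, double af_max,
                        double dnm_rate,
                        double depth_mean,
                        double error_rate,
                        double gq_slope, int gq_cap,
                        int gq_low, int gq_low_dp,
                        NumericVector af_fixed) {
  bool use_fixed = af_fixed.size() > 0;
  if (use_fixed && af_fixed.size() != n)
    stop("af_fixed must be empty or length n");
  SimParams P = make_params(af_min, af_max, dnm_rate, depth_mean,
                            error_rate, gq_slope, gq_cap, gq_low, gq_low_dp);
  IntegerVector fgt(n), mgt(n), cgt(n), pat(n), mat(n);
  IntegerVector dpf(n), dpm(n), dpc(n);
  IntegerVector adf(n), adm(n), adc(n);
  IntegerVector gqf(n), gqm(n), gqc(n);
  LogicalVector dnm_pat(n), dnm_mat(n);
  NumericVector af(n);

  RNGScope scope;
  SiteDraw s;
  for (int i = 0; i < n; ++i) {
    sim_site(P, use_fixed ? af_fixed[i] : -1.0, s);
    af[i] = s.af;
    fgt[i] = s.fgt; mgt[i] = s.mgt; cgt[i] = s.cgt;
    pat[i] = s.tp; mat[i] = s.tm;
    dnm_pat[i] = s.dnm_p; dnm_mat[i] = s.dnm_m;
    dpf[i] = s.dpf; dpm[i] = s.dpm; dpc[i] = s.dpc;
    adf[i] = s.adf; adm[i] = s.adm; adc[i] = s.adc;
    gqf[i] = s.gqf; gqm[i] = s.gqm; gqc[i] = s.gqc;
  }

  return List::create(
    _["af"] = af,
    _["father_gt"] = fgt, _["mother_gt"] = mgt, _["child_gt"] = cgt,
    _["paternal_allele"] = pat, _["maternal_allele"] = mat,
    _["dnm_paternal"] = dnm_pat, _["dnm_maternal"] = dnm_mat,
    _["father_dp"] = dpf, _["mother_dp"] = dpm, _["child_dp"] = dpc,
    _["father_ad_alt"] = adf, _["mother_ad_alt"] = adm, _["child_ad_alt"] = adc,
    _["father_gq"] = gqf, _["mother_gq"] = gqm, _["child_gq"] = gqc);
}

// Streaming counterpart for large-scale rate recovery: simulates the same
// stream as sim_trio_sites_cpp but only accumulates (planted de novo
// count, detected de novo count, callability sum) without materialising
// per-site vectors.  The detection filter is the five-criterion cascade
// with no masks; ab_table[d] must hold the probability that a true
// heterozygote at depth d shows a passing allele balance (computed in R,
// shared with site_callability()).
// [[Rcpp::export]]
NumericVector sim_rate_accum_cpp(int n,
                                 double af_min, double af_max,
                                 double dnm_rate,
                                 double depth_mean,
                                 double error_rate,
                                 double gq_slope, int gq_cap,
                                 int gq_low, int gq_low_dp,
                                 NumericVector ab_table,
                                 double dp_min, double dp_max,
                                 double gq_min,
                                 double ab_min, double ab_max) {
  SimParams P = make_params(af_min, af_max, dnm_rate, depth_mean,
                            error_rate, gq_slope, gq_cap, gq_low, gq_low_dp);
  int tmax = ab_table.size() - 1;
  double n_planted = 0, n_pass = 0, csum = 0;
  RNGScope scope;
  SiteDraw s;
  for (int i = 0; i < n; ++i) {
    sim_site(P, -1.0, s);
    if (s.dnm_p) n_planted += 1;
    if (s.dnm_m) n_planted += 1;

    bool dp_c = s.dpc >= dp_min && s.dpc <= dp_max;
    bool gq_all = s.gqf >= gq_min && s.gqm >= gq_min && s.gqc >= gq_min;
    bool par_ad0 = s.adf == 0 && s.adm == 0;

    // callability additionally gates on parental depth windows
    if (dp_c && gq_all && par_ad0 &&
        s.dpf >= dp_min && s.dpf <= dp_max &&
        s.dpm >= dp_min && s.dpm <= dp_max)
      csum += ab_table[s.dpc > tmax ? tmax : s.dpc];

    // detection: criteria ii (offspring depth + allele balance),
    // iii (GQ in all members), iv (no parental alt reads),
    // v (parents hom-ref, offspring carries the alt)
    if (dp_c && gq_all && par_ad0 &&
        s.fgt == 0 && s.mgt == 0 && s.cgt >= 1) {
      double ab = (double) s.adc / (double) s.dpc;
      if (ab >= ab_min && ab <= ab_max) n_pass += 1;
    }
  }
  return NumericVector::create(_["n_planted"] = n_planted,
                               _["n_pass"] = n_pass,
                               _["callability_sum"] = csum);
}
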