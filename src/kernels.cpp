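#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Kolmogorov-Smirnov and 1-Wasserstein distances between the ECDFs of two
// sorted samples a, b.  K = sup_z |F_a(z) - F_b(z)| evaluated at every pooled
// jump; W = integral |F_a - F_b| dz over the merged step functions (exact for
// unequal sample sizes; reduces to mean |a_(i) - b_(i)| when na == nb).
static void kw_sorted(const double *a, int na, const double *b, int nb,
                      double &K, double &W) {
  int ia = 0, ib = 0;
  double fa = 0.0, fb = 0.0;
  double prev = NA_REAL;
  K = 0.0;
  W = 0.0;
  while (ia < na || ib < nb) {
    double z;
    if (ia < na && (ib >= nb || a[ia] <= b[ib])) z = a[ia];
    else z = b[ib];
    if (!ISNA(prev) && z > prev) W += std::abs(fa - fb) * (z - prev);
    while (ia < na && a[ia] == z) ++ia;
    while (ib < nb && b[ib] == z) ++ib;
    fa = (double)ia / na;
    fb = (double)ib / nb;
    double d = std::abs(fa - fb);
    if (d > K) K = d;
    prev = z;
  }
}

// [[Rcpp::export(name = ".kw_stat_cpp")]]
NumericVector kw_stat_cpp(NumericVector a, NumericVector b) {
  std::vector<double> sa(a.begin(), a.end()), sb(b.begin(), b.end());
  std::sort(sa.begin(), sa.end());
  std::sort(sb.begin(), sb.end());
  double K, W;
  kw_sorted(sa.data(), sa.size(), sb.data(), sb.size(), K, W);
  return NumericVector::create(_["K"] = K, _["W"] = W);
}

// Fisher-Yates shuffle driven by R's RNG so results are reproducible under
// set.seed().
static void shuffle_int(std::vector<int> &v) {
  int n = v.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;  // guard against unif_rand() == 1.0
    std::swap(v[i], v[j]);
  }
}

// Core permutation kernel for the label-permutation scheme.
//
// dvec:   strictly-upper-triangle distances, dvec[k] = d(ii[k], jj[k])
// ii, jj: 0-based sample indices, ii[k] < jj[k]
// labels: 0-based group labels, one per sample
// G:      number of groups
// R:      number of permutation replicates
//
// Returns, for r = 0 (observed labels) and r = 1..R (uniformly permuted
// labels), the K and W statistics for every group pair g < g', and the
// per-group mean of phi^2/2 over within-group distances (the U-statistic
// dispersion used by the GO-type comparator, sharing the same replicates).
// [[Rcpp::export(name = ".dth_perm_kernel_cpp")]]
List dth_perm_kernel_cpp(NumericVector dvec, IntegerVector ii, IntegerVector jj,
                         IntegerVector labels, int G, int R) {
  int n = labels.size();
  int m = dvec.size();
  int P = G * (G - 1) / 2;
  NumericMatrix K(R + 1, P), W(R + 1, P), V(R + 1, G);

  std::vector<int> lab(labels.begin(), labels.end());

  // Pre-sort the distances once; extracting per-group sets in this order
  // yields already-sorted sets, so no per-replicate sorting is needed.
  std::vector<int> ord(m);
  for (int k = 0; k < m; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return dvec[a] < dvec[b]; });
  std::vector<double> dv_s(m);
  std::vector<int> ii_s(m), jj_s(m);
  for (int k = 0; k < m; ++k) {
    dv_s[k] = dvec[ord[k]];
    ii_s[k] = ii[ord[k]];
    jj_s[k] = jj[ord[k]];
  }

  std::vector<std::vector<double>> sets(G);
  std::vector<int> card(G, 0);
  {  // reserve with observed cardinalities (preserved by every permutation)
    for (int k = 0; k < m; ++k)
      if (lab[ii[k]] == lab[jj[k]]) card[lab[ii[k]]]++;
    for (int g = 0; g < G; ++g) sets[g].reserve(card[g]);
  }

  GetRNGstate();
  for (int r = 0; r <= R; ++r) {
    if (r > 0) shuffle_int(lab);
    for (int g = 0; g < G; ++g) sets[g].clear();
    std::vector<double> ss(G, 0.0);
    for (int k = 0; k < m; ++k) {
      int gi = lab[ii_s[k]];
      if (gi == lab[jj_s[k]]) {
        sets[gi].push_back(dv_s[k]);
        ss[gi] += dv_s[k] * dv_s[k];
      }
    }
    for (int g = 0; g < G; ++g)
      V(r, g) = 0.5 * ss[g] / sets[g].size();
    int p = 0;
    for (int g = 0; g < G - 1; ++g)
      for (int h = g + 1; h < G; ++h, ++p) {
        double Kst, Wst;
        kw_sorted(sets[g].data(), sets[g].size(),
                  sets[h].data(), sets[h].size(), Kst, Wst);
        K(r, p) = Kst;
        W(r, p) = Wst;
      }
  }
  PutRNGstate();

  return List::create(_["K"] = K, _["W"] = W, _["V"] = V);
}

// Permutation loop for the Levene-on-centroid-distances comparator.
//
// Xpos (n x kp) and Xneg (n x kn) are principal-coordinate scores on the
// positive- and negative-eigenvalue axes.  For each replicate the group
// labels are permuted, group centroids recomputed, squared distances to the
// own-group centroid taken as (pos part) - (neg part) clamped at zero, and a
// one-way ANOVA F computed on the square-rooted distances.  Row r = 0 is the
// observed labelling.
// [[Rcpp::export(name = ".betadisper_perm_kernel_cpp")]]
NumericVector betadisper_perm_kernel_cpp(NumericMatrix Xpos, NumericMatrix Xneg,
                                         IntegerVector labels, int G, int R) {
  int n = labels.size();
  NumericVector F(R + 1);
  std::vector<int> lab(labels.begin(), labels.end());
  std::vector<double> cpos(G), cneg(G), dists(n);
  std::vector<int> cnt(G);

  GetRNGstate();
  for (int r = 0; r <= R; ++r) {
    if (r > 0) shuffle_int(lab);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) cnt[lab[i]]++;
    // d2 accumulated column-by-column (matrices are column-major)
    std::vector<double> d2(n, 0.0);
    for (int part = 0; part < 2; ++part) {
      const NumericMatrix &X = part == 0 ? Xpos : Xneg;
      std::vector<double> &cen = part == 0 ? cpos : cneg;
      double sign = part == 0 ? 1.0 : -1.0;
      int kc = X.ncol();
      for (int c = 0; c < kc; ++c) {
        const double *col = &X(0, c);
        for (int g = 0; g < G; ++g) cen[g] = 0.0;
        for (int i = 0; i < n; ++i) cen[lab[i]] += col[i];
        for (int g = 0; g < G; ++g) cen[g] /= cnt[g];
        for (int i = 0; i < n; ++i) {
          double t = col[i] - cen[lab[i]];
          d2[i] += sign * t * t;
        }
      }
    }
    for (int i = 0; i < n; ++i)
      dists[i] = d2[i] > 0.0 ? std::sqrt(d2[i]) : 0.0;  // clamp: non-Euclidean correction
    // one-way ANOVA F on dists
    double grand = 0.0;
    std::vector<double> gm(G, 0.0);
    for (int i = 0; i < n; ++i) {
      gm[lab[i]] += dists[i];
      grand += dists[i];
    }
    grand /= n;
    double ssb = 0.0;
    for (int g = 0; g < G; ++g) {
      double mg = gm[g] / cnt[g];
      gm[g] = mg;
      ssb += cnt[g] * (mg - grand) * (mg - grand);
    }
    double ssw = 0.0;
    for (int i = 0; i < n; ++i) {
      double t = dists[i] - gm[lab[i]];
      ssw += t * t;
    }
    double df1 = G - 1, df2 = n - G;
    F[r] = ssw > 0.0 ? (ssb / df1) / (ssw / df2) : (ssb > 0.0 ? R_PosInf : 0.0);
  }
  PutRNGstate();
  return F;
}
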