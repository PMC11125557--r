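#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dynamic program over read-to-fragment assignments. P is an L x M matrix of
// per-read likelihoods, one column per fragment type. For the fragment triple
// (i1, i2, i3) it fills D[a, b] = P(reads | n1 = a, n3 = b, n2 = L - a - b),
// i.e. the assignment sum divided by the multinomial coefficient, so that the
// result is a proper distribution over unordered read multisets.
static void assignment_dp(const NumericMatrix& P, int i1, int i2, int i3,
                          std::vector<double>& D) {
  const int L = P.nrow();
  const int S = L + 1;
  std::vector<double> g(S * S, 0.0), h(S * S, 0.0);
  g[0] = 1.0;
  for (int l = 0; l < L; ++l) {
    const double p1 = P(l, i1);
    const double p2 = P(l, i2);
    const double p3 = (i3 >= 0) ? P(l, i3) : 0.0;
    std::fill(h.begin(), h.end(), 0.0);
    for (int a = 0; a <= l; ++a) {
      for (int b = 0; b <= l - a; ++b) {
        const double v = g[a * S + b];
        if (v == 0.0) continue;
        h[(a + 1) * S + b] += v * p1;
        h[a * S + b]       += v * p2;
        h[a * S + (b + 1)] += v * p3;
      }
    }
    std::swap(g, h);
  }
  D.assign(S * S, 0.0);
  for (int a = 0; a <= L; ++a) {
    for (int b = 0; b <= L - a; ++b) {
      const double lmult = R::lgammafn(L + 1.0) - R::lgammafn(a + 1.0) -
                           R::lgammafn(b + 1.0) - R::lgammafn(L - a - b + 1.0);
      D[a * S + b] = g[a * S + b] / std::exp(lmult);
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_read_dp(const NumericMatrix& P) {
  if (P.ncol() != 3) stop("P must have exactly 3 fragment columns");
  const int L = P.nrow();
  std::vector<double> D;
  assignment_dp(P, 0, 1, 2, D);
  NumericMatrix out(L + 1, L + 1);
  for (int a = 0; a <= L; ++a)
    for (int b = 0; b <= L; ++b) out(a, b) = D[a * (L + 1) + b];
  return out;
}

// Per-cell, per-genotype branch sums. All quantities that do not depend on
// (p_ado, p_ae) are collapsed into six scalars:
//   s00a0, s00a1 : no-ADO branch, 0 or 1 amplification error
//   s10a0, s10a1 : allele 1 dropped
//   s01a0, s01a1 : allele 2 dropped
// i1, i2: 1-based columns of P for the genotype's two allele fragments.
// nb1, nb2: 1-based columns for the Hamming-1 neighbours of each allele.
// w: matrix with w[n, k] = C(n, k) / C(n), the expected number of k-edges in
// an order-labelled amplification tree with n fragments (root edge included).
// err_den: 3 for singleton sites, 6 for paired sites.
// [[Rcpp::export]]
NumericVector cpp_branch_sums(const NumericMatrix& P, int i1, int i2,
                              IntegerVector nb1, IntegerVector nb2,
                              const NumericMatrix& w, double err_den) {
  const int L = P.nrow();
  const int S = L + 1;
  if (L < 1) stop("branch sums need at least one read");
  double s00a0 = 0.0, s00a1 = 0.0, s10a0 = 1.0, s10a1 = 0.0,
         s01a0 = 1.0, s01a1 = 0.0;
  for (int l = 0; l < L; ++l) {
    s10a0 *= P(l, i2 - 1);
    s01a0 *= P(l, i1 - 1);
  }
  std::vector<double> D;
  if (L >= 2) {
    assignment_dp(P, i1 - 1, i2 - 1, -1, D);
    double s = 0.0;
    for (int j = 1; j <= L - 1; ++j) s += D[j * S + 0];
    s00a0 = s / (L - 1.0);
  }
  const double E00 = 2.0 * L - 2.0;
  const double E10 = 2.0 * L - 1.0;
  std::map<int, std::pair<bool, bool> > f3s;
  for (int i = 0; i < nb1.size(); ++i) f3s[nb1[i] - 1].first = true;
  for (int i = 0; i < nb2.size(); ++i) f3s[nb2[i] - 1].second = true;
  for (std::map<int, std::pair<bool, bool> >::iterator it = f3s.begin();
       it != f3s.end(); ++it) {
    const int i3 = it->first;
    assignment_dp(P, i1 - 1, i2 - 1, i3, D);
    if (it->second.first) {  // error originating from allele 1
      if (L >= 2) {
        double s = 0.0;
        for (int j = 1; j <= L - 1; ++j)
          for (int k = 1; k <= j; ++k) s += w(j, k) * D[(j - k) * S + k];
        s00a1 += s / err_den / (L - 1.0) / E00;
      }
      double s = 0.0;
      for (int k = 1; k <= L; ++k) s += w(L, k) * D[(L - k) * S + k];
      s01a1 += s / err_den / E10;
    }
    if (it->second.second) {  // error originating from allele 2
      if (L >= 2) {
        double s = 0.0;
        for (int j = 1; j <= L - 1; ++j)
          for (int k = 1; k <= L - j; ++k) s += w(L - j, k) * D[j * S + k];
        s00a1 += s / err_den / (L - 1.0) / E00;
      }
      double s = 0.0;
      for (int k = 1; k <= L; ++k) s += w(L, k) * D[0 * S + k];
      s10a1 += s / err_den / E10;
    }
  }
  return NumericVector::create(s00a0, s00a1, s10a0, s10a1, s01a0, s01a1);
}

// Cheap parameter-dependent completion of the branch sums.
static double cell_lik(const double* s, int L, double pado, double pae) {
  if (L == 0) return 1.0;
  const double E00 = 2.0 * L - 2.0;
  const double E10 = 2.0 * L - 1.0;
  const double b0_00 = std::pow(1.0 - pae, E00);
  const double b1_00 = (L >= 2) ? E00 * pae * std::pow(1.0 - pae, E00 - 1.0) : 0.0;
  const double b0_10 = std::pow(1.0 - pae, E10);
  const double b1_10 = E10 * pae * std::pow(1.0 - pae, E10 - 1.0);
  const double q = 1.0 - pado;
  return q * q * (s[0] * b0_00 + s[1] * b1_00) +
         pado * q * (s[2] * b0_10 + s[3] * b1_10) +
         q * pado * (s[4] * b0_10 + s[5] * b1_10);
}

// [[Rcpp::export]]
NumericMatrix cpp_lik_matrix(const List& site, double pado, double pae) {
  IntegerVector L = site["L"];
  NumericVector S = site["S"];
  IntegerVector dim = S.attr("dim");
  const int C = dim[0], G = dim[1];
  NumericMatrix out(C, G);
  for (int g = 0; g < G; ++g) {
    for (int c = 0; c < C; ++c) {
      double s[6];
      for (int j = 0; j < 6; ++j) s[j] = S[c + C * g + C * G * j];
      out(c, g) = cell_lik(s, L[c], pado, pae);
    }
  }
  return out;
}

// Joint log-likelihood of the reads at all cached sites, marginalizing the
// mutation type (Dirichlet-Categorical prior), the mutation statuses of all
// cells (Beta-Binomial subset-sum DP) and the amplification latent variables.
// [[Rcpp::export]]
double cpp_sites_loglik(const List& cache, double pado, double pae,
                        double aa, double bb) {
  double total = 0.0;
  const int n_sites = cache.size();
  for (int si = 0; si < n_sites; ++si) {
    List site = cache[si];
    IntegerVector L = site["L"];
    NumericVector prior = site["prior"];
    NumericMatrix lik = cpp_lik_matrix(site, pado, pae);
    const int C = L.size();
    const int K = lik.ncol() - 1;  // genotype 0 is the bulk genotype
    const double lbab = R::lbeta(aa, bb);
    std::vector<double> logw(C + 1);
    for (int m = 0; m <= C; ++m)
      logw[m] = R::lbeta(m + aa, C - m + bb) - lbab;
    double best = R_NegInf;
    std::vector<double> logsz(K);
    for (int z = 0; z < K; ++z) {
      double logscale = 0.0;
      std::vector<double> T(C + 1, 0.0);
      T[0] = 1.0;
      int used = 0;
      for (int c = 0; c < C; ++c) {
        double lb = lik(c, 0), lz = lik(c, z + 1);
        double M = std::max(lb, lz);
        if (M <= 0.0) { lb = 1.0; lz = 1.0; M = 1.0; }  // degenerate cell: no info
        logscale += std::log(M);
        lb /= M;
        lz /= M;
        ++used;
        for (int m = used; m >= 1; --m) T[m] = T[m] * lb + T[m - 1] * lz;
        T[0] *= lb;
      }
      double s = 0.0;
      for (int m = 0; m <= C; ++m) s += T[m] * std::exp(logw[m]);
      logsz[z] = std::log(prior[z]) + std::log(s) + logscale;
      if (logsz[z] > best) best = logsz[z];
    }
    double acc = 0.0;
    for (int z = 0; z < K; ++z) acc += std::exp(logsz[z] - best);
    total += best + std::log(acc);
  }
  return total;
}
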