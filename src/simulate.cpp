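#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Forward generalized Polya-urn amplification of one site. The urn starts
// with the surviving original allele molecules; a draw-copy-return step is
// repeated until the urn holds `L` fragments (originals are themselves
// sequencing-eligible and counted inside L). Each copy independently
// corrupts one position with probability pae; multiple errors may accumulate
// along a lineage of copies. If L is smaller than the initial ball count the
// originals are subsampled without replacement.
static void urn_amplify(std::vector<std::vector<int> >& frags,
                        std::vector<int>& origin, int L, double pae) {
  const int n0 = (int)frags.size();
  if (n0 == 0 || L <= 0) {
    frags.clear();
    origin.clear();
    return;
  }
  if (L < n0) {
    // subsample originals without replacement
    std::vector<std::vector<int> > kept;
    std::vector<int> korig;
    std::vector<int> idx(n0);
    for (int i = 0; i < n0; ++i) idx[i] = i;
    for (int t = 0; t < L; ++t) {
      int j = t + (int)std::floor(unif_rand() * (n0 - t));
      std::swap(idx[t], idx[j]);
      kept.push_back(frags[idx[t]]);
      korig.push_back(origin[idx[t]]);
    }
    frags = kept;
    origin = korig;
    return;
  }
  while ((int)frags.size() < L) {
    int i = (int)std::floor(unif_rand() * frags.size());
    std::vector<int> copy = frags[i];
    if (unif_rand() < pae) {
      int pos = (int)std::floor(unif_rand() * copy.size());
      int shift = 1 + (int)std::floor(unif_rand() * 3.0);
      copy[pos] = (copy[pos] + shift) % 4;
    }
    frags.push_back(copy);
    origin.push_back(origin[i]);
  }
}

// [[Rcpp::export]]
List cpp_amplify_site(const IntegerMatrix& init, int L, double pae) {
  std::vector<std::vector<int> > frags;
  std::vector<int> origin;
  for (int i = 0; i < init.nrow(); ++i) {
    std::vector<int> f(init.ncol());
    for (int j = 0; j < init.ncol(); ++j) f[j] = init(i, j);
    frags.push_back(f);
    origin.push_back(i);
  }
  urn_amplify(frags, origin, L, pae);
  const int n = (int)frags.size();
  const int p = init.ncol();
  IntegerMatrix out(n, p);
  IntegerVector orig(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) out(i, j) = frags[i][j];
    orig[i] = origin[i] + 1;
  }
  return List::create(_["fragments"] = out, _["origin"] = orig);
}

// Phred-scored sequencing of fragments: per covered position an integer
// Phred score is drawn uniformly on [lo, hi]; with probability 10^(-0.1 rho)
// the base is replaced by a uniformly chosen different nucleotide.
// [[Rcpp::export]]
List cpp_sequence_fragments(const IntegerMatrix& frags, int lo, int hi) {
  const int n = frags.nrow(), p = frags.ncol();
  IntegerMatrix bases(n, p), phred(n, p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) {
      int rho = lo + (int)std::floor(unif_rand() * (hi - lo + 1));
      if (rho > hi) rho = hi;
      double q = std::pow(10.0, -0.1 * rho);
      int b = frags(i, j);
      if (unif_rand() < q) {
        int shift = 1 + (int)std::floor(unif_rand() * 3.0);
        b = (b + shift) % 4;
      }
      bases(i, j) = b;
      phred(i, j) = rho;
    }
  }
  return List::create(_["bases"] = bases, _["phred"] = phred);
}

// Whole-dataset forward simulation over consecutive (even, odd) site pairs.
// h1, h2: bulk haplotypes as 0..3 codes (gSNVs already placed). Mutations are
// given per locus with the carrying haplotype, the alternative base and the
// set of inheriting cells. ado1/ado2 are C x n_pairs dropout masks.
// Returns one read per amplified fragment, read_len >= 2 bases starting at
// the pair's even position (positions beyond the pair are filled from the
// originating haplotype).
// [[Rcpp::export]]
List cpp_simulate_cell_reads(const IntegerVector& h1, const IntegerVector& h2,
                             const IntegerVector& mut_locus,
                             const IntegerVector& mut_hap,
                             const IntegerVector& mut_alt,
                             const LogicalMatrix& mut_cells,
                             const LogicalMatrix& ado1,
                             const LogicalMatrix& ado2,
                             double lambda, double pae, int lo, int hi,
                             int read_len) {
  const int G = h1.size();
  const int n_pairs = G / 2;
  const int C = ado1.nrow();
  const int n_mut = mut_locus.size();
  std::vector<int> out_cell, out_pair;
  std::vector<int> out_b, out_q;  // row-major read_len-wide
  for (int c = 0; c < C; ++c) {
    // cell-specific substitutions: locus*2 + (hap-1) -> alt base
    std::map<int, int> subs;
    for (int m = 0; m < n_mut; ++m)
      if (mut_cells(m, c)) subs[mut_locus[m] * 2 + (mut_hap[m] - 1)] = mut_alt[m];
    for (int p = 0; p < n_pairs; ++p) {
      const bool d1 = ado1(c, p), d2 = ado2(c, p);
      if (d1 && d2) continue;  // both alleles dropped: no fragments at all
      int L = (int)R::rpois(lambda);
      if (L <= 0) continue;
      std::vector<std::vector<int> > frags;
      std::vector<int> origin;
      const int s = 2 * p;
      for (int hap = 0; hap < 2; ++hap) {
        if (hap == 0 && d1) continue;
        if (hap == 1 && d2) continue;
        std::vector<int> f(2);
        for (int j = 0; j < 2; ++j) {
          int base = (hap == 0) ? h1[s + j] : h2[s + j];
          std::map<int, int>::iterator it = subs.find((s + j) * 2 + hap);
          if (it != subs.end()) base = it->second;
          f[j] = base;
        }
        frags.push_back(f);
        origin.push_back(hap);
      }
      urn_amplify(frags, origin, L, pae);
      for (size_t i = 0; i < frags.size(); ++i) {
        out_cell.push_back(c + 1);
        out_pair.push_back(p + 1);
        for (int j = 0; j < read_len; ++j) {
          int pos = s + j;
          int b;
          if (j < 2) {
            b = frags[i][j];
          } else if (pos < G) {
            const int hap = origin[i];
            b = (hap == 0) ? h1[pos] : h2[pos];
            std::map<int, int>::iterator it = subs.find(pos * 2 + hap);
            if (it != subs.end()) b = it->second;
          } else {
            b = 0;
          }
          int rho = lo + (int)std::floor(unif_rand() * (hi - lo + 1));
          if (rho > hi) rho = hi;
          double q = std::pow(10.0, -0.1 * rho);
          if (unif_rand() < q) {
            int shift = 1 + (int)std::floor(unif_rand() * 3.0);
            b = (b + shift) % 4;
          }
          out_b.push_back(b);
          out_q.push_back(rho);
        }
      }
    }
  }
  const int n = (int)out_cell.size();
  IntegerMatrix B(n, read_len), Q(n, read_len);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < read_len; ++j) {
      B(i, j) = out_b[i * read_len + j];
      Q(i, j) = out_q[i * read_len + j];
    }
  return List::create(_["cell"] = wrap(out_cell), _["pair"] = wrap(out_pair),
                      _["bases"] = B, _["phred"] = Q);
}
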