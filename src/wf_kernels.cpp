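#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gamete formation for a set of parents.  H holds haplotypes (one byte per
// allele) in block layout: parent p owns rows p and N+p (1-based from R).
// Per chromosome each gamete draws a Poisson number of crossovers (rate
// `morgans`) and a random starting haplotype; sites take the haplotype of the
// segment they fall in.  Uses R's RNG so results are reproducible under
// set.seed().
// [[Rcpp::export]]
RawMatrix make_gametes_cpp(const RawMatrix& H,
                           const IntegerVector& parents,
                           const IntegerVector& chrom_idx,
                           const NumericVector& pos,
                           double morgans, int n_chrom, double chrom_len) {
  const int n = parents.size();
  const int S = H.ncol();
  const int N = H.nrow() / 2;
  RawMatrix G(n, S);
  std::vector<int> k(n), start(n);
  std::vector< std::vector<double> > bps(n);
  for (int cc = 1; cc <= n_chrom; ++cc) {
    for (int i = 0; i < n; ++i) k[i] = (int) R::rpois(morgans);
    for (int i = 0; i < n; ++i) start[i] = (unif_rand() < 0.5) ? 0 : 1;
    for (int i = 0; i < n; ++i) {
      bps[i].clear();
      if (k[i] > 0) {
        bps[i].resize(k[i]);
        for (int j = 0; j < k[i]; ++j) bps[i][j] = unif_rand() * chrom_len;
        std::sort(bps[i].begin(), bps[i].end());
      }
    }
    // precomputed source rows for the common zero-crossover gametes
    std::vector<int> src0(n);
    for (int i = 0; i < n; ++i) src0[i] = parents[i] - 1 + N * start[i];
    const Rbyte* hp = RAW(H);
    Rbyte* gp = RAW(G);
    const int nrowH = H.nrow();
    for (int j = 0; j < S; ++j) {
      if (chrom_idx[j] != cc) continue;
      const double p = pos[j];
      const Rbyte* hcol = hp + (size_t) j * nrowH;
      Rbyte* gcol = gp + (size_t) j * n;
      for (int i = 0; i < n; ++i) {
        if (k[i] == 0) {
          gcol[i] = hcol[src0[i]];
        } else {
          const int seg = std::upper_bound(bps[i].begin(), bps[i].end(), p) -
            bps[i].begin();
          gcol[i] = hcol[parents[i] - 1 + N * ((start[i] + seg) & 1)];
        }
      }
    }
  }
  return G;
}

// Per-column count of non-zero (derived) alleles in a byte haplotype matrix.
// [[Rcpp::export]]
IntegerVector hap_col_counts(const RawMatrix& H) {
  const int nr = H.nrow(), nc = H.ncol();
  IntegerVector out(nc);
  const Rbyte* hp = RAW(H);
  for (int j = 0; j < nc; ++j) {
    const Rbyte* col = hp + (size_t) j * nr;
    int s = 0;
    for (int i = 0; i < nr; ++i) s += col[i];
    out[j] = s;
  }
  return out;
}

// Diploid genotypes (0/1/2) for selected sites: individual i (1..N) is rows
// i and N+i of H; `cols` is 1-based.  Returns an N x length(cols) matrix.
// [[Rcpp::export]]
IntegerMatrix hap_genotypes(const RawMatrix& H, const IntegerVector& cols) {
  const int N = H.nrow() / 2;
  const int nc = cols.size();
  IntegerMatrix G(N, nc);
  const Rbyte* hp = RAW(H);
  const int nrowH = H.nrow();
  for (int j = 0; j < nc; ++j) {
    const Rbyte* col = hp + (size_t) (cols[j] - 1) * nrowH;
    int* gcol = INTEGER(G) + (size_t) j * N;
    for (int i = 0; i < N; ++i) gcol[i] = col[i] + col[N + i];
  }
  return G;
}

// One-generation kinship recursion: offspring i has parents m[i], f[i]
// (1-based).  K holds parental kinships with self-kinship 0.5*(1+F) on the
// diagonal.  Returns the offspring kinship matrix and pedigree inbreeding
// F_i = kinship(m_i, f_i).
// [[Rcpp::export]]
List kinship_update_cpp(const NumericMatrix& K, const IntegerVector& m,
                        const IntegerVector& f) {
  const int n = m.size();
  const int NP = K.nrow();
  NumericMatrix K2(n, n);
  NumericVector Fv(n);
  const double* kp = REAL(K);
  double* k2p = REAL(K2);
  std::vector<int> mi(n), fi(n);
  for (int i = 0; i < n; ++i) { mi[i] = m[i] - 1; fi[i] = f[i] - 1; }
  for (int i = 0; i < n; ++i) Fv[i] = kp[mi[i] + (size_t) fi[i] * NP];
  for (int j = 0; j < n; ++j) {
    const double* kmj = kp + (size_t) mi[j] * NP;
    const double* kfj = kp + (size_t) fi[j] * NP;
    double* out = k2p + (size_t) j * n;
    for (int i = 0; i < n; ++i)
      out[i] = 0.25 * (kmj[mi[i]] + kfj[mi[i]] + kmj[fi[i]] + kfj[fi[i]]);
    out[j] = 0.5 * (1.0 + Fv[j]);
  }
  return List::create(_["K"] = K2, _["f_ped"] = Fv);
}
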