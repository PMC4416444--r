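#include <Rcpp.h>
using namespace Rcpp;

// Weighted between-community mean nearest taxon distance.
// D: full patristic matrix; ik/im: 0-based row/col indices of the taxa
// present in communities k and m; fk/fm: within-community relative
// abundances aligned with ik/im.
static double bmntd_core(const NumericMatrix& D,
                         const std::vector<int>& ik,
                         const std::vector<int>& im,
                         const NumericVector& fk,
                         const NumericVector& fm) {
  const int nk = ik.size(), nm = im.size();
  double sk = 0.0, sm = 0.0;
  std::vector<double> mincol(nm, R_PosInf);
  for (int i = 0; i < nk; ++i) {
    const int ri = ik[i];
    double minrow = R_PosInf;
    for (int j = 0; j < nm; ++j) {
      const double d = D(ri, im[j]);
      if (d < minrow) minrow = d;
      if (d < mincol[j]) mincol[j] = d;
    }
    sk += fk[i] * minrow;
  }
  for (int j = 0; j < nm; ++j) sm += fm[j] * mincol[j];
  return 0.5 * (sk + sm);
}

// [[Rcpp::export(name = ".bmntd_pair_cpp")]]
double bmntd_pair_cpp(const NumericMatrix& D,
                      const IntegerVector& ik, const IntegerVector& im,
                      const NumericVector& fk, const NumericVector& fm) {
  std::vector<int> vk(ik.begin(), ik.end()), vm(im.begin(), im.end());
  return bmntd_core(D, vk, vm, fk, fm);
}

// Null bMNTD values under tip-label permutation. pool: 0-based taxon indices
// of the shuffle pool; perms: pool-position permutations, one column per null
// replicate (0-based); posk/posm: 0-based positions of the two communities'
// taxa within the pool.
// [[Rcpp::export(name = ".bmntd_null_cpp")]]
NumericVector bmntd_null_cpp(const NumericMatrix& D,
                             const IntegerVector& pool,
                             const IntegerMatrix& perms,
                             const IntegerVector& posk,
                             const IntegerVector& posm,
                             const NumericVector& fk,
                             const NumericVector& fm) {
  const int n_null = perms.ncol();
  const int nk = posk.size(), nm = posm.size();
  NumericVector out(n_null);
  std::vector<int> ik(nk), im(nm);
  for (int r = 0; r < n_null; ++r) {
    for (int i = 0; i < nk; ++i) ik[i] = pool[perms(posk[i], r)];
    for (int j = 0; j < nm; ++j) im[j] = pool[perms(posm[j], r)];
    out[r] = bmntd_core(D, ik, im, fk, fm);
  }
  return out;
}
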