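// Neighborhood rank-sum accumulation for KCC-ReHo.
// ranks: n x V matrix (V = nx*ny*nz, column-major grid); mask: V ints.
// For each in-mask voxel, sums the rank series of its in-mask neighbors
// (offsets includes the voxel itself) and returns the concordance sum of
// squares S = sum_t (R_t - K (n+1)/2)^2, the neighbor count K, and the
// neighborhood tie-term sum.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// [[Rcpp::export]]
Rcpp::List reho_kernel(const arma::mat& ranks, const arma::ivec& mask,
                       int nx, int ny, int nz, const arma::imat& offsets,
                       const arma::vec& tie_terms) {
  const int n = ranks.n_rows;
  const int V = nx * ny * nz;
  arma::vec S(V, arma::fill::value(NA_REAL));
  arma::ivec K(V, arma::fill::zeros);
  arma::vec T(V, arma::fill::zeros);
  arma::vec buf(n);
  const double mr = (n + 1.0) / 2.0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const int v = ix + nx * (iy + ny * iz);
        if (!mask[v]) continue;
        buf.zeros();
        int k = 0;
        double tsum = 0.0;
        for (arma::uword o = 0; o < offsets.n_rows; ++o) {
          const int jx = ix + offsets(o, 0);
          const int jy = iy + offsets(o, 1);
          const int jz = iz + offsets(o, 2);
          if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
            continue;
          const int w = jx + nx * (jy + ny * jz);
          if (!mask[w]) continue;
          buf += ranks.col(w);
          tsum += tie_terms[w];
          ++k;
        }
        K[v] = k;
        T[v] = tsum;
        double s = 0.0;
        const double c = k * mr;
        for (int t = 0; t < n; ++t) {
          const double d = buf[t] - c;
          s += d * d;
        }
        S[v] = s;
      }
  return Rcpp::List::create(Rcpp::Named("S") = S, Rcpp::Named("K") = K,
                            Rcpp::Named("T") = T);
}
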