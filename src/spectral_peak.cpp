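// Band-restricted spectral peak search for the sliding-window HR stage.
//
// M is the precomputed band DFT operator: the first K rows are the cosine
// (real) part and the last K rows the sine (imaginary) part of the Hann-
// tapered, zero-padded DFT evaluated on the analysis-band frequency grid.
// X holds one detrended analysis window per column. The peak index of the
// spectral power |M x|^2 is returned per window (1-based within the grid).
// Single precision is ample: only the argmax location is consumed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_band_peak(const arma::mat& M, const arma::mat& X) {
  const arma::uword K = M.n_rows / 2;
  arma::fmat Mf = arma::conv_to<arma::fmat>::from(M);
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  arma::fmat S = Mf * Xf; // (2K) x W
  const arma::uword W = S.n_cols;
  Rcpp::IntegerVector peak(W);
  for (arma::uword j = 0; j < W; ++j) {
    float best = -1.0f;
    arma::uword ibest = 0;
    const float* re = S.colptr(j);
    const float* im = re + K;
    for (arma::uword i = 0; i < K; ++i) {
      const float p = re[i] * re[i] + im[i] * im[i];
      if (p > best) {
        best = p;
        ibest = i;
      }
    }
    peak[j] = static_cast<int>(ibest) + 1;
  }
  return peak;
}
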