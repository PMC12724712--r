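// Surrogate engine for the max-statistic coherence test. Per surrogate, the
// firing-rate series is phase-randomized block-wise: each non-overlapping
// segment-length block keeps its amplitude spectrum but gets fresh phases.
// The surrogate series is then re-segmented (with overlap) and demeaned
// exactly like the observed series, so the correlation between overlapping
// segments -- present in the observed taper/segment averages -- is
// preserved under the null, while phase consistency across distant
// segments is destroyed. The full taper/segment-averaged coherence is
// recomputed and its maximum over frequencies recorded. Uses R's RNG so
// results follow set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// x: full series (demeaned globally or not; segments are demeaned here)
// fyre/fyim: tapered y segment spectra, dim nf x S x K (DC excluded)
// seg_starts: 0-based start index of each segment in x
// early_stop_m > 0 enables sequential stopping: once that many surrogate
// maxima reach early_stop_obs, significance is impossible and the loop
// exits (identical accept/reject decision to the full run).
// [[Rcpp::export]]
Rcpp::NumericVector surrogate_max_coherence(const arma::vec& x,
                                            const Rcpp::NumericVector& fyre,
                                            const Rcpp::NumericVector& fyim,
                                            const arma::mat& tapers,
                                            const arma::uvec& seg_starts,
                                            int nsurr,
                                            double early_stop_obs = -1.0,
                                            int early_stop_m = 0) {
  const uword n = tapers.n_rows;      // samples per segment
  const uword S = seg_starts.n_elem;  // segments
  const uword K = tapers.n_cols;      // tapers
  const uword nf = n / 2;             // one-sided bins excluding DC
  const uword N = x.n_elem;           // full series length

  Rcpp::IntegerVector dims = fyre.attr("dim");
  if (dims.size() != 3 || (uword)dims[0] != nf || (uword)dims[1] != S ||
      (uword)dims[2] != K)
    Rcpp::stop("tapered y spectra have unexpected dimensions");
  for (uword s = 0; s < S; ++s)
    if (seg_starts(s) + n > N) Rcpp::stop("segment exceeds series length");

  cx_cube Fy(nf, S, K);
  for (uword k = 0; k < K; ++k)
    for (uword s = 0; s < S; ++s)
      for (uword f = 0; f < nf; ++f) {
        const uword idx = f + nf * (s + S * k);
        Fy(f, s, k) = std::complex<double>(fyre[idx], fyim[idx]);
      }
  vec Syy(nf, fill::zeros);
  for (uword k = 0; k < K; ++k)
    for (uword s = 0; s < S; ++s)
      for (uword f = 0; f < nf; ++f)
        Syy(f) += std::norm(Fy(f, s, k));

  // block decomposition: non-overlapping blocks of one segment length (a
  // short tail block keeps its own spectrum); amplitudes reused per block
  std::vector<uword> blk_start, blk_len;
  for (uword b0 = 0; b0 < N; b0 += n) {
    blk_start.push_back(b0);
    blk_len.push_back(std::min<uword>(n, N - b0));
  }
  const uword nblk = blk_start.size();
  std::vector<cx_vec> Bf(nblk);
  for (uword b = 0; b < nblk; ++b)
    Bf[b] = fft(conv_to<cx_vec>::from(
      x.subvec(blk_start[b], blk_start[b] + blk_len[b] - 1)));

  std::vector<double> out;
  out.reserve(nsurr);
  vec xs(N);
  vec Sxx(nf);
  cx_vec Sxy(nf);
  int n_ge = 0;

  for (int r = 0; r < nsurr; ++r) {
    for (uword b = 0; b < nblk; ++b) {
      const uword L = blk_len[b];
      if (L < 4) {  // too short to randomize meaningfully
        xs.subvec(blk_start[b], blk_start[b] + L - 1) =
          x.subvec(blk_start[b], blk_start[b] + L - 1);
        continue;
      }
      cx_vec Z(L);
      const uword halfb = (L - 1) / 2;
      Z(0) = Bf[b](0);
      for (uword j = 1; j <= halfb; ++j) {
        const double phi = 2.0 * M_PI * R::unif_rand();
        Z(j) = std::polar(std::abs(Bf[b](j)), phi);
        Z(L - j) = std::conj(Z(j));
      }
      if (L % 2 == 0) {
        const double sgn = (R::unif_rand() < 0.5) ? -1.0 : 1.0;
        Z(L / 2) = Bf[b](L / 2) * sgn;
      }
      xs.subvec(blk_start[b], blk_start[b] + L - 1) = real(ifft(Z));
    }
    Sxx.zeros();
    Sxy.zeros();
    for (uword s = 0; s < S; ++s) {
      vec seg = xs.subvec(seg_starts(s), seg_starts(s) + n - 1);
      seg -= mean(seg);
      for (uword k = 0; k < K; ++k) {
        const cx_vec F = fft(conv_to<cx_vec>::from(seg % tapers.col(k)));
        for (uword f = 0; f < nf; ++f) {
          const std::complex<double> v = F(f + 1);
          Sxx(f) += std::norm(v);
          Sxy(f) += v * std::conj(Fy(f, s, k));
        }
      }
    }
    double mx = 0.0;
    for (uword f = 0; f < nf; ++f) {
      const double denom = Sxx(f) * Syy(f);
      const double c = denom > 0 ? std::norm(Sxy(f)) / denom : 0.0;
      if (c > mx) mx = c;
    }
    out.push_back(mx > 1.0 ? 1.0 : mx);
    if (early_stop_m > 0 && mx >= early_stop_obs) {
      ++n_ge;
      if (n_ge >= early_stop_m) break;
    }
  }
  return Rcpp::wrap(out);
}
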