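// Project-and-replace iteration core.
//
// State F lives in the spatial domain. One step, with P the
// reproducing-kernel projection and Q the feature-map selection:
//   H_n = P F_{n-1}   (frequency domain:  T = chi/C * sum_l Fhat_l psi_l,
//                      Hhat_j = T * psi_j)
//   F_n = (1 - Q) H_n + F0   (replace graph entries with the data)
// The read-out image W*_gamma H_n has spectrum sum_j Hhat_j gamma_j =
// T * chi/C * sum_j psi_j^2 = T exactly (gamma_j = chi psi_j / C), so
// recording the percent error costs one extra inverse FFT.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".cppProjectReplace")]]
Rcpp::List cppProjectReplace(const arma::cx_cube &F0,
                             const arma::cube &psis,
                             const arma::mat &mult,
                             const arma::uvec &selIdx0,
                             const int nIter,
                             const int recordStride,
                             const arma::mat &reference,
                             const double stopTol) {
  const uword N = F0.n_rows;
  const uword M = F0.n_slices;
  const bool haveRef = reference.n_rows == N;
  const bool wantStop = stopTol > 0.0;

  const cx_cube psisC(psis, cube(N, N, M, fill::zeros));
  const cx_mat multC(mult, mat(N, N, fill::zeros));

  cx_cube F = F0;
  cx_cube H(N, N, M);
  cx_mat S(N, N), T(N, N);
  const cx_vec F0sel = F0.elem(selIdx0);

  std::vector<double> deltas;
  std::vector<int> iters;

  int nDone = nIter;
  for (int n = 1; n <= nIter; ++n) {
    S.zeros();
    for (uword j = 0; j < M; ++j)
      S += fft2(F.slice(j)) % psisC.slice(j);
    T = S % multC;
    for (uword j = 0; j < M; ++j)
      H.slice(j) = ifft2(T % psisC.slice(j));

    double change = datum::inf;
    if (wantStop) {
      // ||F_n - F_{n-1}||: F_n equals H off the graph and F0 on it.
      cx_cube D = H - F;
      D.elem(selIdx0) = F0sel - F.elem(selIdx0);
      change = norm(vectorise(D), 2);
    }
    F = H;
    F.elem(selIdx0) = F0sel;

    const bool stopping = wantStop && change < stopTol;
    const bool last = (n == nIter) || stopping;
    if ((recordStride > 0 && n % recordStride == 0) || last) {
      iters.push_back(n);
      if (haveRef) {
        const mat frec = real(ifft2(T));
        deltas.push_back(100.0 * norm(reference - frec, "fro") /
                         (255.0 * double(N)));
      }
    }
    if (stopping) {
      nDone = n;
      break;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("F") = F, Rcpp::Named("H") = H,
      Rcpp::Named("deltas") = deltas, Rcpp::Named("iterations") = iters,
      Rcpp::Named("nIter") = nDone);
}
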