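// Numerical kernels for the EEG feature pipeline: zero-phase FFT filtering,
// analytic band signals, Welch segment FFTs, decimated Morlet-CWT band
// descriptors, Hjorth parameters, PLV matrices, and the diagonal
// (feature-selection) NCA optimizer. FFTs use FFTW (double, single thread).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <fftw3.h>

using namespace arma;

static int next_pow2_int(int n) {
  int p = 1;
  while (p < n) p <<= 1;
  return p;
}

// smallest 5-smooth (2^a 3^b 5^c) integer >= n, for efficient FFT lengths
static int next_fast_len(int n) {
  int best = next_pow2_int(n);
  for (long f5 = 1; f5 < best; f5 *= 5)
    for (long f35 = f5; f35 < best; f35 *= 3) {
      long m = f35;
      while (m < n) m *= 2;
      if (m < best) best = (int)m;
    }
  return best;
}

// complex FFT helper with its own in-place buffer
struct CplxFFT {
  int n;
  cx_vec buf;
  fftw_plan fwd, inv;
  explicit CplxFFT(int n_) : n(n_), buf(n_) {
    fwd = fftw_plan_dft_1d(n, (fftw_complex*)buf.memptr(),
                           (fftw_complex*)buf.memptr(), FFTW_FORWARD, FFTW_ESTIMATE);
    inv = fftw_plan_dft_1d(n, (fftw_complex*)buf.memptr(),
                           (fftw_complex*)buf.memptr(), FFTW_BACKWARD, FFTW_ESTIMATE);
  }
  ~CplxFFT() { fftw_destroy_plan(fwd); fftw_destroy_plan(inv); }
};

// squared magnitude response |H|^2 of kernel h on an npad-point grid
static vec kernel_h2(const vec& h, int npad, CplxFFT& fft) {
  fft.buf.zeros();
  for (uword i = 0; i < h.n_elem; ++i) fft.buf(i) = h(i);
  fftw_execute(fft.fwd);
  vec H2(npad);
  for (int k = 0; k < npad; ++k) H2(k) = std::norm(fft.buf(k));
  return H2;
}

// [[Rcpp::export]]
arma::cx_mat cpp_fft_cols(const arma::cx_mat& X, bool inverse) {
  CplxFFT fft(X.n_rows);
  cx_mat out(X.n_rows, X.n_cols);
  for (uword c = 0; c < X.n_cols; ++c) {
    fft.buf = X.col(c);
    fftw_execute(inverse ? fft.inv : fft.fwd);
    out.col(c) = inverse ? cx_vec(fft.buf / double(X.n_rows)) : fft.buf;
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_zero_phase_filter(const arma::mat& X, const arma::vec& h) {
  const int n = X.n_rows, nc = X.n_cols;
  if (n < (int)h.n_elem) Rcpp::stop("signal shorter than filter kernel");
  const int npad = next_fast_len(n + h.n_elem);
  CplxFFT fft(npad);
  vec H2 = kernel_h2(h, npad, fft);
  mat out(n, nc);
  for (int c = 0; c < nc; ++c) {
    fft.buf.zeros();
    for (int i = 0; i < n; ++i) fft.buf(i) = X(i, c);
    fftw_execute(fft.fwd);
    for (int k = 0; k < npad; ++k) fft.buf(k) *= H2(k);
    fftw_execute(fft.inv);
    for (int i = 0; i < n; ++i) out(i, c) = fft.buf(i).real() / npad;
  }
  return out;
}

// zero-phase band filter + analytic (Hilbert) signal in one pass
// [[Rcpp::export]]
arma::cx_mat cpp_band_analytic(const arma::mat& X, const arma::vec& h) {
  const int n = X.n_rows, nc = X.n_cols;
  if (n < (int)h.n_elem) Rcpp::stop("signal shorter than filter kernel");
  const int npad = next_pow2_int(n + h.n_elem);
  const int half = npad / 2;
  CplxFFT fft(npad);
  vec H2 = kernel_h2(h, npad, fft);
  cx_mat out(n, nc);
  for (int c = 0; c < nc; ++c) {
    fft.buf.zeros();
    for (int i = 0; i < n; ++i) fft.buf(i) = X(i, c);
    fftw_execute(fft.fwd);
    fft.buf(0) *= H2(0);
    for (int k = 1; k < half; ++k) fft.buf(k) *= 2.0 * H2(k);
    fft.buf(half) *= H2(half);
    for (int k = half + 1; k < npad; ++k) fft.buf(k) = 0.0;
    fftw_execute(fft.inv);
    for (int i = 0; i < n; ++i) out(i, c) = fft.buf(i) / double(npad);
  }
  return out;
}

// Hamming-windowed overlapping segment r2c FFTs.
// Returns cube: (wlen/2 + 1) x n_channels x n_segments (complex).
// [[Rcpp::export]]
arma::cx_cube cpp_segment_ffts(const arma::mat& X, int wlen, int step) {
  const int n = X.n_rows, nc = X.n_cols;
  if (wlen > n) Rcpp::stop("window longer than signal");
  const int nseg = (n - wlen) / step + 1;
  const int nf = wlen / 2 + 1;
  vec win(wlen);
  if (wlen == 1) win(0) = 1.0;
  else for (int i = 0; i < wlen; ++i)
    win(i) = 0.54 - 0.46 * std::cos(2.0 * M_PI * i / (wlen - 1));
  vec in(wlen);
  cx_vec outv(nf);
  fftw_plan plan = fftw_plan_dft_r2c_1d(wlen, in.memptr(),
                                        (fftw_complex*)outv.memptr(), FFTW_ESTIMATE);
  cx_cube out(nf, nc, nseg);
  for (int s = 0; s < nseg; ++s) {
    for (int c = 0; c < nc; ++c) {
      for (int i = 0; i < wlen; ++i) in(i) = X(s * step + i, c) * win(i);
      fftw_execute(plan);
      out.slice(s).col(c) = outv;
    }
  }
  fftw_destroy_plan(plan);
  return out;
}

// Full-rate Morlet scalogram amplitude for a single channel (reference path
// behind the exported scalogram operation). Returns (n x n_freqs) matrix.
// [[Rcpp::export]]
arma::mat cpp_cwt_amplitude(const arma::vec& x, double fs,
                            const arma::vec& freqs, double omega0) {
  const int n = x.n_elem;
  const double fmin = freqs.min();
  const int wav_half = (int)std::ceil(5.0 * omega0 / (2.0 * M_PI * fmin) * fs);
  const int npad = next_pow2_int(n + wav_half);
  const double df = fs / npad;
  CplxFFT fft(npad);
  fft.buf.zeros();
  for (int i = 0; i < n; ++i) fft.buf(i) = x(i);
  fftw_execute(fft.fwd);
  cx_vec spec = fft.buf;
  mat out(n, freqs.n_elem);
  for (uword j = 0; j < freqs.n_elem; ++j) {
    const double f = freqs(j), sf = f / omega0;
    fft.buf.zeros();
    const int klo = std::max(1, (int)std::floor((f - 5.0 * sf) / df));
    const int khi = std::min(npad / 2 - 1, (int)std::ceil((f + 5.0 * sf) / df));
    for (int k = klo; k <= khi; ++k) {
      const double g = 2.0 * std::exp(-0.5 * std::pow((k * df - f) / sf, 2));
      fft.buf(k) = spec(k) * g;
    }
    fftw_execute(fft.inv);
    for (int i = 0; i < n; ++i) out(i, j) = std::abs(fft.buf(i)) / npad;
  }
  return out;
}

// excess-kurtosis/skewness moments of a series; zero-variance -> (0, 0)
static void am_moments(const vec& am, double& skew, double& kurt) {
  const double n = am.n_elem;
  const double mu = mean(am);
  vec d = am - mu;
  const double m2 = dot(d, d) / n;
  if (m2 <= 1e-24 * (mu * mu + 1e-300)) { skew = 0.0; kurt = 0.0; return; }
  const double m3 = accu(d % d % d) / n;
  vec d2 = d % d;
  const double m4 = dot(d2, d2) / n;
  skew = m3 / std::pow(m2, 1.5);
  kurt = m4 / (m2 * m2) - 3.0;
}

static void hjorth_cpp(const double* x, int m, double fs,
                       double& mob, double& cmplx) {
  if (m < 3) { mob = 0.0; cmplx = 0.0; return; }
  double s0 = 0, s1 = 0;
  for (int i = 0; i < m; ++i) s0 += x[i];
  const double mu = s0 / m;
  double v0 = 0;
  for (int i = 0; i < m; ++i) v0 += (x[i] - mu) * (x[i] - mu);
  v0 /= m;
  double mu1 = (x[m - 1] - x[0]) / (m - 1);
  double v1 = 0;
  for (int i = 1; i < m; ++i) { const double d = x[i] - x[i - 1] - mu1; v1 += d * d; }
  v1 /= (m - 1);
  // second difference
  double mu2 = 0;
  for (int i = 2; i < m; ++i) mu2 += x[i] - 2 * x[i - 1] + x[i - 2];
  mu2 /= (m - 2);
  double v2 = 0;
  for (int i = 2; i < m; ++i) {
    const double d = x[i] - 2 * x[i - 1] + x[i - 2] - mu2;
    v2 += d * d;
  }
  v2 /= (m - 2);
  (void)s1;
  if (v0 <= 0 || v1 <= 0) { mob = 0.0; cmplx = 0.0; return; }
  mob = fs / (2.0 * M_PI) * std::sqrt(v1 / v0);
  cmplx = (v2 > 0) ? std::sqrt(v2 / v1) / std::sqrt(v1 / v0) : 0.0;
}

// Per-epoch band kit: one forward FFT per channel feeds
//  (1) decimated Morlet-CWT band descriptors (8 per channel x band),
//  (2) zero-phase analytic band signals -> Hjorth mobility/complexity on the
//      real part and PLV matrices from unit phasors at ~64 Hz stride,
// all within a single padded grid. CWT coefficients per analysis frequency
// are band-limited, so only the bins carrying the Gaussian's +-5 sd support
// are folded modulo a per-band power-of-two length M (>= support width) and
// inverse-transformed: this yields exact samples of the analytic CWT
// coefficient decimated by npad/M (the implied frequency shift leaves the
// amplitude untouched).
//
// kernels: list of FIR band kernels; freqs/band_id: analysis grid and
// 1-based band membership; trim_cwt: per-band edge trim (s) for CWT stats;
// trim_conn: edge trim (s) for Hjorth/PLV; plv_max_fs: phasor sampling rate
// ceiling (Hz).
// [[Rcpp::export]]
Rcpp::List cpp_epoch_band_kit(const arma::mat& X, double fs,
                              const Rcpp::List& kernels,
                              const arma::vec& freqs,
                              const arma::ivec& band_id, int n_bands,
                              const arma::vec& trim_cwt, double trim_conn,
                              double omega0, const arma::vec& plv_fs) {
  const int n = X.n_rows, nc = X.n_cols;
  const double fmin = freqs.min();
  const int wav_half = (int)std::ceil(5.0 * omega0 / (2.0 * M_PI * fmin) * fs);
  int need = n + wav_half;
  for (int b = 0; b < n_bands; ++b) {
    vec h = Rcpp::as<vec>(kernels[b]);
    need = std::max(need, n + (int)h.n_elem);
  }
  const int npad = next_pow2_int(need);
  const int half = npad / 2;
  const double df = fs / npad;

  CplxFFT fft(npad);
  cx_mat spec(npad, nc);
  for (int c = 0; c < nc; ++c) {
    fft.buf.zeros();
    for (int i = 0; i < n; ++i) fft.buf(i) = X(i, c);
    fftw_execute(fft.fwd);
    spec.col(c) = fft.buf;
  }

  mat tf(nc, 8 * n_bands, fill::zeros);
  mat hj(nc, 2 * n_bands, fill::zeros);
  Rcpp::List plv_list(n_bands);

  // ---- analytic band signals: Hjorth + PLV phasors ----
  const int i0 = (int)std::round(trim_conn * fs);
  const int i1 = n - i0; // half-open [i0, i1)
  vec xr(n);
  for (int b = 0; b < n_bands; ++b) {
    const int stride = std::max(1, (int)std::round(fs / plv_fs(b)));
    std::vector<int> pidx;
    for (int i = i0; i < i1; i += stride) pidx.push_back(i);
    const int np = pidx.size();
    vec h = Rcpp::as<vec>(kernels[b]);
    vec H2 = kernel_h2(h, npad, fft);
    cx_mat U(np, nc);
    for (int c = 0; c < nc; ++c) {
      fft.buf = spec.col(c);
      fft.buf(0) *= H2(0);
      for (int k = 1; k < half; ++k) fft.buf(k) *= 2.0 * H2(k);
      fft.buf(half) *= H2(half);
      for (int k = half + 1; k < npad; ++k) fft.buf(k) = 0.0;
      fftw_execute(fft.inv);
      for (int i = 0; i < n; ++i) xr(i) = fft.buf(i).real() / npad;
      double mob, cx;
      hjorth_cpp(xr.memptr() + i0, i1 - i0, fs, mob, cx);
      hj(c, 2 * b) = mob;
      hj(c, 2 * b + 1) = cx;
      for (int t = 0; t < np; ++t) {
        const std::complex<double> z = fft.buf(pidx[t]);
        const double a = std::sqrt(z.real() * z.real() + z.imag() * z.imag());
        U(t, c) = (a > 1e-300) ? z / a : std::complex<double>(0.0, 0.0);
      }
    }
    // PLV(i,j) = |mean_t u_i conj(u_j)|
    cx_mat G = U.t() * U; // conjugate transpose
    mat P = abs(G) / np;
    P.diag().zeros();
    P = 0.5 * (P + P.t());
    plv_list[b] = P;
  }

  // ---- decimated CWT band descriptors ----
  for (int b = 0; b < n_bands; ++b) {
    uvec fidx = find(band_id == b + 1);
    const int nf = fidx.n_elem;
    if (nf == 0) Rcpp::stop("empty band slice in CWT grid");
    std::vector<int> k0(nf), k1(nf);
    std::vector<vec> gw(nf);
    int max_span = 0;
    for (int j = 0; j < nf; ++j) {
      const double f = freqs(fidx(j));
      const double sf = f / omega0;
      k0[j] = std::max(1, (int)std::floor((f - 5.0 * sf) / df));
      k1[j] = std::min(half - 1, (int)std::ceil((f + 5.0 * sf) / df));
      const int span = k1[j] - k0[j] + 1;
      max_span = std::max(max_span, span);
      vec g(span);
      for (int k = 0; k < span; ++k) {
        const double fk = (k0[j] + k) * df;
        g(k) = 2.0 * std::exp(-0.5 * std::pow((fk - f) / sf, 2));
      }
      gw[j] = g;
    }
    const int M = next_pow2_int(max_span);
    const int D = npad / M;
    CplxFFT bfft(M);

    const double tr = trim_cwt(b);
    std::vector<int> keep;
    for (int m = 0; m < M; ++m) {
      const double t = m * (double)D / fs;
      if (t >= tr && t < n / fs - tr) keep.push_back(m);
    }
    const int nt = keep.size();
    vec fb(nf);
    for (int j = 0; j < nf; ++j) fb(j) = freqs(fidx(j));

    mat A(nt, nf);
    const double inv_npad = 1.0 / npad;
    for (int c = 0; c < nc; ++c) {
      for (int j = 0; j < nf; ++j) {
        bfft.buf.zeros();
        const int span = k1[j] - k0[j] + 1;
        const vec& g = gw[j];
        std::complex<double>* bb = bfft.buf.memptr();
        const std::complex<double>* sp = spec.colptr(c);
        for (int k = 0; k < span; ++k)
          bb[(k0[j] + k) & (M - 1)] += sp[k0[j] + k] * g(k);
        fftw_execute(bfft.inv);
        double* aj = A.colptr(j);
        for (int t = 0; t < nt; ++t) {
          const std::complex<double> z = bb[keep[t]];
          aj[t] = std::sqrt(z.real() * z.real() + z.imag() * z.imag()) * inv_npad;
        }
      }
      vec AM = mean(A, 1);
      mat P = A % A;
      vec rp = sum(P, 1);
      vec Pf = P * fb;
      vec cen(nt);
      for (int t = 0; t < nt; ++t)
        cen(t) = (rp(t) > 0) ? Pf(t) / rp(t) : 0.5 * (fb(0) + fb(nf - 1));
      mat Pd = P;
      for (int j = 0; j < nf; ++j) {
        double* pj = Pd.colptr(j);
        for (int t = 0; t < nt; ++t) {
          const double d = fb(j) - cen(t);
          pj[t] *= d * d;
        }
      }
      vec bmv = sum(Pd, 1);
      vec bm(nt);
      for (int t = 0; t < nt; ++t)
        bm(t) = (rp(t) > 0) ? std::sqrt(bmv(t) / rp(t)) : 0.0;

      rowvec pbar = mean(P, 0);
      const double ptot = accu(pbar);
      double entropy = 0.0, fcen = 0.5 * (fb(0) + fb(nf - 1));
      if (ptot > 0) {
        fcen = dot(pbar.t(), fb) / ptot;
        if (nf > 1) {
          for (int j = 0; j < nf; ++j) {
            const double p = pbar(j) / ptot;
            if (p > 0) entropy -= p * std::log(p);
          }
          entropy /= std::log((double)nf);
        }
      }
      vec peak = max(A, 1);
      rowvec psum = sum(P, 0);
      const uword pk = psum.index_max();
      double skew, kurt;
      am_moments(AM, skew, kurt);

      tf(c, 8 * b + 0) = mean(AM);
      tf(c, 8 * b + 1) = mean(bm);
      tf(c, 8 * b + 2) = entropy;
      tf(c, 8 * b + 3) = fcen;
      tf(c, 8 * b + 4) = mean(peak);
      tf(c, 8 * b + 5) = fb(pk);
      tf(c, 8 * b + 6) = skew;
      tf(c, 8 * b + 7) = kurt;
    }
  }

  return Rcpp::List::create(Rcpp::Named("tf") = tf,
                            Rcpp::Named("hjorth") = hj,
                            Rcpp::Named("plv") = plv_list);
}

// mean over segments of |FFT|^2 from a segment-FFT cube -> (bins x channels)
// [[Rcpp::export]]
arma::mat cpp_cube_meanpow(const arma::cx_cube& cube) {
  mat acc(cube.n_rows, cube.n_cols, fill::zeros);
  for (uword s = 0; s < cube.n_slices; ++s) {
    const cx_mat& sl = cube.slice(s);
    for (uword c = 0; c < cube.n_cols; ++c)
      for (uword f = 0; f < cube.n_rows; ++f)
        acc(f, c) += std::norm(sl(f, c));
  }
  return acc / double(cube.n_slices);
}

// Mean magnitude-squared coherence over channel pairs and in-band bins,
// from a segment-FFT cube (bins x channels x segments).
// [[Rcpp::export]]
double cpp_msc_mean(const arma::cx_cube& cube, double fs, int wlen,
                    double lo, double hi) {
  const int nf = cube.n_rows, nc = cube.n_cols, ns = cube.n_slices;
  mat acc(nc, nc, fill::zeros);
  int nbins = 0;
  for (int f = 0; f < nf; ++f) {
    const double fr = f * fs / wlen;
    if (fr < lo || fr >= hi) continue;
    ++nbins;
    cx_mat Xf(nc, ns);
    for (int s = 0; s < ns; ++s) Xf.col(s) = cube.slice(s).row(f).st();
    cx_mat S = Xf * Xf.t(); // segment-summed cross-spectra (conjugate transpose)
    vec d = real(S.diag());
    for (int i = 0; i < nc; ++i)
      for (int j = i + 1; j < nc; ++j) {
        const double den = d(i) * d(j);
        if (den > 0) acc(i, j) += std::norm(S(i, j)) / den;
      }
  }
  if (nbins == 0) return 0.0;
  double s = 0.0;
  for (int i = 0; i < nc; ++i)
    for (int j = i + 1; j < nc; ++j) s += acc(i, j);
  return s / nbins / (nc * (nc - 1) / 2.0);
}

// All-pairs shortest-path distances on a dense weighted graph with
// distances d = 1/w (w <= 0 means no edge). Floyd-Warshall.
// [[Rcpp::export]]
arma::mat cpp_shortest_dists(const arma::mat& W) {
  const int n = W.n_rows;
  mat D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      D(i, j) = (i == j) ? 0.0 : (W(i, j) > 0 ? 1.0 / W(i, j) : datum::inf);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) {
      const double dik = D(i, k);
      if (!std::isfinite(dik)) continue;
      for (int j = 0; j < n; ++j) {
        const double alt = dik + D(k, j);
        if (alt < D(i, j)) D(i, j) = alt;
      }
    }
  return D;
}

// Diagonal NCA for feature selection: maximizes the expected leave-one-out
// stochastic nearest-neighbour accuracy with weighted L1 distances
// d_ik = sum_j w_j^2 |x_ij - x_kj|, minus lambda * sum_j w_j^2.
// Gradient ascent from w = 1 with adaptive step size and early stopping.
// [[Rcpp::export]]
Rcpp::List cpp_nca_weights(const arma::mat& X, const arma::ivec& y,
                           double lambda, int max_iter, double tol) {
  const int n = X.n_rows, p = X.n_cols;
  if (n < 2) Rcpp::stop("need at least 2 rows");
  vec w(p, fill::ones);

  mat D(n, n), Pr(n, n), S(n, n);
  auto objective_and_grad = [&](const vec& wv, vec& g) -> double {
    D.zeros();
    for (int j = 0; j < p; ++j) {
      const double w2 = wv(j) * wv(j);
      if (w2 < 1e-30) continue;
      const double* xj = X.colptr(j);
      for (int i = 0; i < n; ++i) {
        const double xi = xj[i];
        double* dcol = D.colptr(i);
        for (int k = i + 1; k < n; ++k)
          dcol[k] += w2 * std::fabs(xi - xj[k]);
      }
    }
    vec pi(n);
    for (int i = 0; i < n; ++i) {
      double dmin = datum::inf;
      for (int k = 0; k < n; ++k) {
        if (k == i) continue;
        const double d = (k > i) ? D(k, i) : D(i, k);
        dmin = std::min(dmin, d);
      }
      double z = 0.0;
      for (int k = 0; k < n; ++k) {
        if (k == i) { Pr(i, k) = 0.0; continue; }
        const double d = (k > i) ? D(k, i) : D(i, k);
        const double e = std::exp(-(d - dmin));
        Pr(i, k) = e;
        z += e;
      }
      double s = 0.0;
      for (int k = 0; k < n; ++k) {
        Pr(i, k) /= z;
        if (y(k) == y(i)) s += Pr(i, k);
      }
      pi(i) = s;
    }
    const double F = mean(pi) - lambda * dot(wv, wv);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < n; ++k)
        S(i, k) = pi(i) * Pr(i, k) - ((y(k) == y(i)) ? Pr(i, k) : 0.0);
    for (int i = 0; i < n; ++i)
      for (int k = i + 1; k < n; ++k)
        S(i, k) += S(k, i);
    g.zeros();
    for (int j = 0; j < p; ++j) {
      const double* xj = X.colptr(j);
      double acc_j = 0.0;
      for (int i = 0; i < n; ++i) {
        const double xi = xj[i];
        for (int k = i + 1; k < n; ++k)
          acc_j += S(i, k) * std::fabs(xi - xj[k]);
      }
      g(j) = 2.0 * wv(j) * acc_j / n - 2.0 * lambda * wv(j);
    }
    return F;
  };

  double eta = 0.5;
  vec g(p), g_new(p);
  double F = objective_and_grad(w, g);
  bool converged = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    Rcpp::checkUserInterrupt();
    vec w_new = w + eta * g;
    double F_new = objective_and_grad(w_new, g_new);
    if (F_new >= F) {
      const double rel = std::fabs(F_new - F) / (std::fabs(F) + 1e-12);
      w = w_new;
      g = g_new;
      F = F_new;
      eta *= 1.1;
      if (rel < tol) { converged = true; break; }
    } else {
      eta *= 0.5;
      if (eta < 1e-10) { converged = true; break; }
    }
  }
  return Rcpp::List::create(Rcpp::Named("weights") = w,
                            Rcpp::Named("objective") = F,
                            Rcpp::Named("iterations") = it + 1,
                            Rcpp::Named("converged") = converged);
}
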