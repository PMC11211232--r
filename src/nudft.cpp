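// Exact non-uniform DFT along radial readouts.
//
// Every readout samples k-space at k_i = dk * (i - ns/2) * dir, i = 0..ns-1
// (symmetric diameter through k = 0).  Because the samples along one readout
// are equally spaced, the per-voxel phasors form a geometric sequence:
//   exp(-2*pi*i * k_i . x_j) = exp(-2*pi*i * dk * (i - ns/2) * u_j),
//   u_j = dir . x_j  (projection of the voxel position on the readout axis).
// One cos/sin pair per voxel per readout then yields all ns samples through
// a complex-multiply recurrence, which keeps the exact transform tractable
// at desk scale without any gridding approximation.  The recurrence is
// written with explicit real/imaginary scalars so the hot loops stay free
// of library complex-arithmetic calls and vectorize over voxels.  Forward
// and adjoint are exact transposes of each other by construction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// images: nvox x nstates complex (one column per frozen motion state)
// coords: nvox x 3 voxel centre positions (mm, iso-centre origin)
// dirs:   nro x 3 unit readout directions
// state:  nro integer (0-based column of `images` seen by each readout)
// dk:     radial sample spacing (cycles/mm); ns: samples per readout
// [[Rcpp::export]]
arma::cx_mat radial_nudft_forward(const arma::cx_mat& images,
                                  const arma::mat& coords,
                                  const arma::mat& dirs,
                                  const arma::ivec& state,
                                  const double dk,
                                  const int ns) {
  const uword nvox = coords.n_rows;
  const uword nro = dirs.n_rows;
  if (images.n_rows != nvox) Rcpp::stop("images/coords voxel count mismatch");
  if (state.n_elem != nro) Rcpp::stop("state length != number of readouts");

  cx_mat out(ns, nro, fill::zeros);
  const double half = ns / 2.0;
  const double twopi = 2.0 * datum::pi;
  std::vector<double> wr(nvox), wi(nvox), zr(nvox), zi(nvox);
  std::vector<double> outr(ns), outi(ns);
  vec u(nvox);

  for (uword r = 0; r < nro; ++r) {
    const int st = state(r);
    if (st < 0 || st >= (int)images.n_cols) Rcpp::stop("state index out of range");
    u = coords * dirs.row(r).t();
    const std::complex<double>* img = images.colptr(st);
    for (uword j = 0; j < nvox; ++j) {
      const double p0 = twopi * dk * u[j];
      wr[j] = std::cos(p0);
      wi[j] = -std::sin(p0);
      const double h = half * p0;
      const double ch = std::cos(h), sh = std::sin(h);
      const double ar = img[j].real(), ai = img[j].imag();
      zr[j] = ar * ch - ai * sh;  // img * exp(+i * half * p0)
      zi[j] = ar * sh + ai * ch;
    }
    std::fill(outr.begin(), outr.end(), 0.0);
    std::fill(outi.begin(), outi.end(), 0.0);
    for (int i = 0; i < ns; ++i) {
      double sr = 0.0, si = 0.0;
      for (uword j = 0; j < nvox; ++j) {
        const double a = zr[j], b = zi[j];
        sr += a;
        si += b;
        zr[j] = a * wr[j] - b * wi[j];
        zi[j] = a * wi[j] + b * wr[j];
      }
      outr[i] = sr;
      outi[i] = si;
    }
    for (int i = 0; i < ns; ++i) out(i, r) = std::complex<double>(outr[i], outi[i]);
  }
  return out;
}

// Exact adjoint of radial_nudft_forward (conjugate-transposed phasors).
// y: ns x nro complex samples (apply any density weights before calling).
// [[Rcpp::export]]
arma::cx_vec radial_nudft_adjoint(const arma::cx_mat& y,
                                  const arma::mat& coords,
                                  const arma::mat& dirs,
                                  const double dk,
                                  const int ns) {
  const uword nvox = coords.n_rows;
  const uword nro = dirs.n_rows;
  if ((int)y.n_rows != ns || y.n_cols != nro) Rcpp::stop("sample matrix shape mismatch");

  const double half = ns / 2.0;
  const double twopi = 2.0 * datum::pi;
  std::vector<double> accr(nvox, 0.0), acci(nvox, 0.0);
  std::vector<double> wr(nvox), wi(nvox), zr(nvox), zi(nvox);
  std::vector<double> yrv(ns), yiv(ns);
  vec u(nvox);

  for (uword r = 0; r < nro; ++r) {
    u = coords * dirs.row(r).t();
    for (uword j = 0; j < nvox; ++j) {
      const double p0 = twopi * dk * u[j];
      wr[j] = std::cos(p0);   // conjugate recurrence: exp(+i p0)
      wi[j] = std::sin(p0);
      const double h = half * p0;
      zr[j] = std::cos(h);    // exp(-i * half * p0)
      zi[j] = -std::sin(h);
    }
    for (int i = 0; i < ns; ++i) {
      yrv[i] = y(i, r).real();
      yiv[i] = y(i, r).imag();
    }
    for (int i = 0; i < ns; ++i) {
      const double cr = yrv[i], ci = yiv[i];
      if (cr != 0.0 || ci != 0.0) {
        for (uword j = 0; j < nvox; ++j) {
          const double a = zr[j], b = zi[j];
          accr[j] += cr * a - ci * b;
          acci[j] += cr * b + ci * a;
          zr[j] = a * wr[j] - b * wi[j];
          zi[j] = a * wi[j] + b * wr[j];
        }
      } else {
        for (uword j = 0; j < nvox; ++j) {
          const double a = zr[j], b = zi[j];
          zr[j] = a * wr[j] - b * wi[j];
          zi[j] = a * wi[j] + b * wr[j];
        }
      }
    }
  }
  cx_vec acc(nvox);
  for (uword j = 0; j < nvox; ++j) acc(j) = std::complex<double>(accr[j], acci[j]);
  return acc;
}
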