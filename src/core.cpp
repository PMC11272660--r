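// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

// Inverse-mapped bilinear warp of pixels and alpha about the image centre,
// with the same coefficients for both (so coverage stays aligned with
// luminance). For each output pixel p, the source location is
//   q = Ainv %*% (p - centre) + centre
// with Ainv = (a11 a12; a21 a22) acting on (row, col); taps outside the
// source support contribute 0 (transparent fill).
// [[Rcpp::export]]
List cpp_warp_pair(const NumericMatrix& pixels, const NumericMatrix& alpha,
                   double a11, double a12, double a21, double a22) {
  const int nr = pixels.nrow(), nc = pixels.ncol();
  const double cr = (nr + 1) / 2.0, cc = (nc + 1) / 2.0;
  NumericMatrix outp(nr, nc), outa(nr, nc);
  const double* px = REAL(pixels);
  const double* al = REAL(alpha);
  double* op = REAL(outp);
  double* oa = REAL(outa);
  for (int j = 0; j < nc; ++j) {
    const double dc = (j + 1) - cc;
    const double base_r = a12 * dc + cr, base_c = a22 * dc + cc;
    double* opj = op + (size_t)j * nr;
    double* oaj = oa + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      const double dr = (i + 1) - cr;
      const double sr = a11 * dr + base_r;
      const double sc = a21 * dr + base_c;
      const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      if (r0 >= 1 && r0 < nr && c0 >= 1 && c0 < nc) {
        // all four taps inside
        const double fr = sr - r0, fc = sc - c0;
        const double w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc);
        const double w01 = (1 - fr) * fc, w11 = fr * fc;
        const size_t k00 = (size_t)(c0 - 1) * nr + (r0 - 1);
        const size_t k01 = k00 + nr;
        opj[i] = w00 * px[k00] + w10 * px[k00 + 1] +
                 w01 * px[k01] + w11 * px[k01 + 1];
        oaj[i] = w00 * al[k00] + w10 * al[k00 + 1] +
                 w01 * al[k01] + w11 * al[k01 + 1];
      } else if (r0 >= 0 && r0 <= nr && c0 >= 0 && c0 <= nc) {
        // border: per-tap containment
        const double fr = sr - r0, fc = sc - c0;
        double vp = 0, va = 0;
        for (int di = 0; di < 2; ++di) {
          const int rr = r0 + di;
          if (rr < 1 || rr > nr) continue;
          const double wr = di ? fr : 1 - fr;
          for (int dj = 0; dj < 2; ++dj) {
            const int ccol = c0 + dj;
            if (ccol < 1 || ccol > nc) continue;
            const double w = wr * (dj ? fc : 1 - fc);
            const size_t k = (size_t)(ccol - 1) * nr + (rr - 1);
            vp += w * px[k];
            va += w * al[k];
          }
        }
        opj[i] = vp; oaj[i] = va;
      } // else: fully outside, stays 0
    }
  }
  return List::create(_["pixels"] = outp, _["alpha"] = outa);
}

// Strided filter-bank correlation over all spatial-frequency channels of a
// bank, using a joint separable factorisation of each channel's kernels:
//   K_k = U %*% B_k,   B_k = t(U) %*% K_k
// with U (S x r) a common orthonormal row basis (r ~ 8-10: the kernels of
// one channel share their Gaussian envelope and carrier frequencies), so
// a placement's response is <vec(B_k), vec(t(U) %*% Patch)>.
// `canvas` is the n x n image already mapped to [0, 1]; each channel is a
// list with integer fields support, pad, offsets (0-based placement
// offsets in padded coordinates, shared by rows and columns), the basis
// `rowbasis` (S x r) and `colweights` ((r*S) x K, vec(B_k) per column).
// Zero padding is realised implicitly by restricting to valid row/column
// ranges. Placements are ordered row-major (grid row slowest). Returns
// one P x K response matrix per channel equal, to ~1e-13 relative, to the
// raw patch dot products.
// [[Rcpp::export]]
List cpp_encode_channels(const arma::mat& canvas, const List& channels) {
  const int n = canvas.n_rows;
  if ((int)canvas.n_cols != n) stop("canvas must be square");
  const arma::mat Ct = canvas.t();   // columns of Ct are canvas rows
  const int nch = channels.size();
  List out(nch);
  for (int c = 0; c < nch; ++c) {
    List ch = channels[c];
    const int S = as<int>(ch["support"]);
    const int pad = as<int>(ch["pad"]);
    const IntegerVector offs = ch["offsets"];
    const arma::mat& U = as<arma::mat>(ch["rowbasis"]);
    const arma::mat& B = as<arma::mat>(ch["colweights"]);
    const int r = U.n_cols;
    const int n1 = offs.size();
    const int P = n1 * n1;
    const int K = B.n_cols;
    if ((int)B.n_rows != r * S) stop("colweights shape mismatch");
    arma::mat R(P, K, arma::fill::zeros);
    for (int ir = 0; ir < n1; ++ir) {
      const int orow = offs[ir] - pad;          // top row in canvas coords
      const int r0 = std::max(0, -orow);        // valid patch row range
      const int r1 = std::min(S, n - orow);
      if (r1 <= r0) continue;
      // row pass: T[f, c] = sum_i U[i, f] * canvas[orow + i, c]
      const arma::mat view(const_cast<double*>(Ct.colptr(orow + r0)),
                           n, r1 - r0, false, true);
      arma::mat T;
      if (r0 == 0 && r1 == S) {
        T = (view * U).t();                     // r x n
      } else {
        T = (view * U.rows(r0, r1 - 1)).t();
      }
      for (int ic = 0; ic < n1; ++ic) {
        const int ocol = offs[ic] - pad;
        const int c0 = std::max(0, -ocol);
        const int c1 = std::min(S, n - ocol);
        if (c1 <= c0) continue;
        const int p = ir * n1 + ic;
        // both the window of T and each B column are f-fastest contiguous
        const double* tv = T.colptr(ocol + c0);
        const int len = r * (c1 - c0);
        const int boff = r * c0;
        for (int k = 0; k < K; ++k) {
          const double* b = B.colptr(k) + boff;
          double s = 0;
          for (int i = 0; i < len; ++i) s += b[i] * tv[i];
          R(p, k) = s;
        }
      }
    }
    out[c] = R;
  }
  return out;
}

// Fused warp + composite: bilinearly warps the stimulus (pixels and
// alpha) by the inverse map (a11 a12; a21 a22) about the 256-window
// centre and alpha-blends it into a clone of `bg` at 0-based offset
// (off_r, off_c), without materialising the warped stimulus. Produces
// bit-identical results to cpp_warp_pair followed by cpp_composite.
// [[Rcpp::export]]
NumericMatrix cpp_warp_composite(const NumericMatrix& pixels,
                                 const NumericMatrix& alpha,
                                 const NumericMatrix& bg,
                                 double a11, double a12,
                                 double a21, double a22,
                                 int off_r, int off_c, bool identity) {
  const int nr = pixels.nrow(), nc = pixels.ncol();
  const int bnr = bg.nrow();
  if (off_r < 0 || off_c < 0 || off_r + nr > bnr || off_c + nc > bg.ncol())
    stop("foreground window not contained in background canvas");
  NumericMatrix out = clone(bg);
  const double cr = (nr + 1) / 2.0, cc = (nc + 1) / 2.0;
  const double* px = REAL(pixels);
  const double* al = REAL(alpha);
  double* op = REAL(out);
  for (int j = 0; j < nc; ++j) {
    double* oj = op + (size_t)(off_c + j) * bnr + off_r;
    if (identity) {
      const double* fj = px + (size_t)j * nr;
      const double* aj = al + (size_t)j * nr;
      for (int i = 0; i < nr; ++i) {
        const double a = aj[i];
        if (a > 0) oj[i] = a * fj[i] + (1.0 - a) * oj[i];
      }
      continue;
    }
    const double dc = (j + 1) - cc;
    const double base_r = a12 * dc + cr, base_c = a22 * dc + cc;
    for (int i = 0; i < nr; ++i) {
      const double dr = (i + 1) - cr;
      const double sr = a11 * dr + base_r;
      const double sc = a21 * dr + base_c;
      const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      double vp = 0, va = 0;
      if (r0 >= 1 && r0 < nr && c0 >= 1 && c0 < nc) {
        const double fr = sr - r0, fc = sc - c0;
        const double w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc);
        const double w01 = (1 - fr) * fc, w11 = fr * fc;
        const size_t k00 = (size_t)(c0 - 1) * nr + (r0 - 1);
        const size_t k01 = k00 + nr;
        vp = w00 * px[k00] + w10 * px[k00 + 1] +
             w01 * px[k01] + w11 * px[k01 + 1];
        va = w00 * al[k00] + w10 * al[k00 + 1] +
             w01 * al[k01] + w11 * al[k01 + 1];
      } else if (r0 >= 0 && r0 <= nr && c0 >= 0 && c0 <= nc) {
        const double fr = sr - r0, fc = sc - c0;
        for (int di = 0; di < 2; ++di) {
          const int rr = r0 + di;
          if (rr < 1 || rr > nr) continue;
          const double wr = di ? fr : 1 - fr;
          for (int dj = 0; dj < 2; ++dj) {
            const int ccol = c0 + dj;
            if (ccol < 1 || ccol > nc) continue;
            const double w = wr * (dj ? fc : 1 - fc);
            const size_t k = (size_t)(ccol - 1) * nr + (rr - 1);
            vp += w * px[k];
            va += w * al[k];
          }
        }
      }
      if (va > 0) oj[i] = va * vp + (1.0 - va) * oj[i];
    }
  }
  return out;
}

// Assemble one model kind's feature vector from the per-channel raw
// response list (P x K matrices). Kind codes: 0 = simple, 1 = complex,
// 2 = linear, 3 = lgn. For the Gabor kinds the first 8 columns are the
// theta-major (phase0, phase90) pairs; for lgn `dog_col` (0-based) selects
// the DoG response column.
// [[Rcpp::export]]
NumericVector cpp_assemble_features(const List& raw, int kind, int dog_col) {
  // total length
  size_t total = 0;
  const int nch = raw.size();
  for (int c = 0; c < nch; ++c) {
    const arma::mat& R = as<arma::mat>(raw[c]);
    const size_t P = R.n_rows;
    total += P * (kind == 0 ? 16 : kind == 1 ? 4 : kind == 2 ? 8 : 2);
  }
  NumericVector out((R_xlen_t)total);
  double* o = REAL(out);
  for (int c = 0; c < nch; ++c) {
    const arma::mat& R = as<arma::mat>(raw[c]);
    const int P = R.n_rows;
    if (kind == 3) {
      const double* r = R.colptr(dog_col);
      for (int p = 0; p < P; ++p) {
        o[0] = r[p] > 0 ? r[p] : 0;
        o[1] = r[p] < 0 ? -r[p] : 0;
        o += 2;
      }
    } else {
      for (int p = 0; p < P; ++p) {
        for (int t = 0; t < 4; ++t) {
          const double r0 = R(p, 2 * t);
          const double r90 = R(p, 2 * t + 1);
          if (kind == 0) {            // phases 0, 90, 180, 270 rectified
            o[0] = r0 > 0 ? r0 : 0;
            o[1] = r90 > 0 ? r90 : 0;
            o[2] = r0 < 0 ? -r0 : 0;
            o[3] = r90 < 0 ? -r90 : 0;
            o += 4;
          } else if (kind == 1) {     // energy: |r0| + |r90|
            *o++ = std::abs(r0) + std::abs(r90);
          } else {                    // linear: raw quadrature pair
            o[0] = r0; o[1] = r90; o += 2;
          }
        }
      }
    }
  }
  return out;
}

// Alpha compositing of a foreground window onto a background canvas.
// off_r/off_c are 0-based offsets of the window's top-left corner.
// [[Rcpp::export]]
NumericMatrix cpp_composite(const NumericMatrix& bg,
                            const NumericMatrix& fg,
                            const NumericMatrix& alpha,
                            int off_r, int off_c) {
  NumericMatrix out = clone(bg);
  const int nr = fg.nrow(), nc = fg.ncol();
  const int bnr = bg.nrow();
  if (off_r < 0 || off_c < 0 || off_r + nr > bnr || off_c + nc > bg.ncol())
    stop("foreground window not contained in background canvas");
  const double* fp = REAL(fg);
  const double* ap = REAL(alpha);
  double* op = REAL(out);
  for (int j = 0; j < nc; ++j) {
    const double* fj = fp + (size_t)j * nr;
    const double* aj = ap + (size_t)j * nr;
    double* oj = op + (size_t)(off_c + j) * bnr + off_r;
    for (int i = 0; i < nr; ++i) {
      const double a = aj[i];
      if (a > 0) oj[i] = a * fj[i] + (1.0 - a) * oj[i];
    }
  }
  return out;
}
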