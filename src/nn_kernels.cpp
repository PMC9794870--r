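// Batched 3D convolution / pooling primitives for the volumetric age
// regression network.  A batch is an array [V, C, B] (voxels in R's
// column-major order, channels, samples).  3x3x3 convolutions use padding 1
// (im2col + GEMM); max pooling uses 2x2x2 windows with stride 2 and floor
// output sizes.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// column matrix V x K with K = 27 * Cin; column index k = o + 27*c where o
// runs over the 3x3x3 offsets in x-fastest order and c over input channels.
// V-major layout keeps both the writes and the GEMMs cache-friendly.
static void im2col3(const arma::mat& x, int nx, int ny, int nz, arma::mat& col) {
  const int Cin = x.n_cols;
  for (int c = 0; c < Cin; c++) {
    const double* xc = x.colptr(c);
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          int o = (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
          double* cp = col.colptr(o + 27 * c);
          for (int z = 0; z < nz; z++) {
            int zz = z + dz;
            bool zok = zz >= 0 && zz < nz;
            for (int y = 0; y < ny; y++) {
              int yy = y + dy;
              bool yok = yy >= 0 && yy < ny;
              double* dst = cp + nx * (y + (size_t)ny * z);
              if (!zok || !yok) {
                std::memset(dst, 0, sizeof(double) * nx);
                continue;
              }
              const double* src = xc + nx * (yy + (size_t)ny * zz);
              // interior span is a straight copy shifted by dx
              int lo = std::max(0, -dx), hi = std::min(nx, nx - dx);
              if (dx > 0) dst[nx - 1] = 0.0;
              if (dx < 0) dst[0] = 0.0;
              if (hi > lo)
                std::memcpy(dst + lo, src + lo + dx, sizeof(double) * (hi - lo));
            }
          }
        }
  }
}

static void col2im3(const arma::mat& col, int nx, int ny, int nz, arma::mat& x) {
  const int Cin = x.n_cols;
  x.zeros();
  for (int c = 0; c < Cin; c++) {
    double* xc = x.colptr(c);
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          int o = (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
          const double* cp = col.colptr(o + 27 * c);
          for (int z = 0; z < nz; z++) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            for (int y = 0; y < ny; y++) {
              int yy = y + dy;
              if (yy < 0 || yy >= ny) continue;
              const double* src = cp + nx * (y + (size_t)ny * z);
              double* dst = xc + nx * (yy + (size_t)ny * zz);
              int lo = std::max(0, -dx), hi = std::min(nx, nx - dx);
              for (int xp = lo; xp < hi; xp++) dst[xp + dx] += src[xp];
            }
          }
        }
  }
}

// x: [V, Cin, B]; W: [Cout, 27*Cin]; b: length Cout -> y: [V, Cout, B]
// [[Rcpp::export]]
arma::cube cpp_conv3_forward(const arma::cube& x, const arma::mat& W,
                             const arma::vec& b, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int V = nx * ny * nz, Cin = x.n_cols, B = x.n_slices, Cout = W.n_rows;
  arma::cube y(V, Cout, B);
  arma::mat col(V, 27 * Cin);
  arma::mat Wt = W.t();
  for (int s = 0; s < B; s++) {
    im2col3(x.slice(s), nx, ny, nz, col);
    arma::mat out = col * Wt;          // V x Cout
    out.each_row() += b.t();
    y.slice(s) = out;
  }
  return y;
}

// gradients for conv: returns list(dx, dW, db)
// [[Rcpp::export]]
List cpp_conv3_backward(const arma::cube& x, const arma::mat& W,
                        const arma::cube& dy, IntegerVector dim,
                        bool need_dx) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int V = nx * ny * nz, Cin = x.n_cols, B = x.n_slices;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(W.n_rows, arma::fill::zeros);
  arma::cube dx;
  if (need_dx) dx.set_size(V, Cin, B);
  arma::mat col(V, 27 * Cin), dcol;
  for (int s = 0; s < B; s++) {
    im2col3(x.slice(s), nx, ny, nz, col);
    dW += dy.slice(s).t() * col;       // (Cout x V) (V x K)
    db += arma::sum(dy.slice(s), 0).t();
    if (need_dx) {
      dcol = dy.slice(s) * W;          // V x K
      arma::mat dxs(V, Cin);
      col2im3(dcol, nx, ny, nz, dxs);
      dx.slice(s) = dxs;
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2x2 max pooling, stride 2, floor sizes.  Returns y [V', C, B] and the
// 1-based argmax linear voxel index into the input grid for each output.
// [[Rcpp::export]]
List cpp_maxpool3_forward(const arma::cube& x, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  int Vo = ox * oy * oz, C = x.n_cols, B = x.n_slices;
  arma::cube y(Vo, C, B);
  IntegerVector idx((R_xlen_t)Vo * C * B);
  for (int s = 0; s < B; s++)
    for (int c = 0; c < C; c++) {
      const double* xc = x.slice(s).colptr(c);
      for (int z = 0; z < oz; z++)
        for (int yv = 0; yv < oy; yv++)
          for (int xv = 0; xv < ox; xv++) {
            double best = -std::numeric_limits<double>::infinity();
            int bi = -1;
            for (int k = 0; k <= 1; k++)
              for (int j = 0; j <= 1; j++)
                for (int i = 0; i <= 1; i++) {
                  int xx = 2 * xv + i, yy = 2 * yv + j, zz = 2 * z + k;
                  int li = xx + nx * (yy + ny * zz);
                  if (xc[li] > best) { best = xc[li]; bi = li; }
                }
            int vo = xv + ox * (yv + oy * z);
            y(vo, c, s) = best;
            idx[(R_xlen_t)vo + (R_xlen_t)Vo * (c + (R_xlen_t)C * s)] = bi + 1;
          }
    }
  return List::create(_["y"] = y, _["idx"] = idx,
                      _["dim"] = IntegerVector::create(ox, oy, oz));
}

// [[Rcpp::export]]
arma::cube cpp_maxpool3_backward(const arma::cube& dy, IntegerVector idx,
                                 int Vin) {
  int Vo = dy.n_rows, C = dy.n_cols, B = dy.n_slices;
  arma::cube dx(Vin, C, B, arma::fill::zeros);
  for (int s = 0; s < B; s++)
    for (int c = 0; c < C; c++) {
      const double* pd = dy.slice(s).colptr(c);
      double* px = dx.slice(s).colptr(c);
      const int* pi = &idx[(R_xlen_t)Vo * (c + (R_xlen_t)C * s)];
      for (int v = 0; v < Vo; v++) px[pi[v] - 1] += pd[v];
    }
  return dx;
}

// ---------------------------------------------------------------------------
// Batch normalization over (voxels, samples) per channel, x: [V, C, B].

// [[Rcpp::export]]
List cpp_bn_train(const arma::cube& x, const arma::vec& gamma,
                  const arma::vec& beta, double eps) {
  int V = x.n_rows, C = x.n_cols, B = x.n_slices;
  arma::vec m(C, arma::fill::zeros), v(C, arma::fill::zeros);
  for (int c = 0; c < C; c++) {
    double s = 0, s2 = 0;
    for (int b = 0; b < B; b++) {
      const double* p = x.slice(b).colptr(c);
      for (int i = 0; i < V; i++) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double n = (double)V * B;
    m[c] = s / n;
    v[c] = s2 / n - m[c] * m[c];
  }
  arma::vec invstd = 1.0 / arma::sqrt(v + eps);
  arma::cube xhat(V, C, B), out(V, C, B);
  for (int c = 0; c < C; c++)
    for (int b = 0; b < B; b++) {
      const double* p = x.slice(b).colptr(c);
      double* xh = xhat.slice(b).colptr(c);
      double* o = out.slice(b).colptr(c);
      for (int i = 0; i < V; i++) {
        xh[i] = (p[i] - m[c]) * invstd[c];
        o[i] = gamma[c] * xh[i] + beta[c];
      }
    }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mean"] = m,
                      _["var"] = v, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_bn_backward(const arma::cube& dout, const arma::cube& xhat,
                     const arma::vec& invstd, const arma::vec& gamma) {
  int V = dout.n_rows, C = dout.n_cols, B = dout.n_slices;
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  arma::cube dx(V, C, B);
  double n = (double)V * B;
  for (int c = 0; c < C; c++) {
    double sg = 0, sb = 0;
    for (int b = 0; b < B; b++) {
      const double* pd = dout.slice(b).colptr(c);
      const double* ph = xhat.slice(b).colptr(c);
      for (int i = 0; i < V; i++) { sg += pd[i] * ph[i]; sb += pd[i]; }
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    // means of dxhat and dxhat*xhat (dxhat = gamma * dout)
    double m1 = gamma[c] * sb / n, m2 = gamma[c] * sg / n;
    for (int b = 0; b < B; b++) {
      const double* pd = dout.slice(b).colptr(c);
      const double* ph = xhat.slice(b).colptr(c);
      double* px = dx.slice(b).colptr(c);
      for (int i = 0; i < V; i++)
        px[i] = invstd[c] * (gamma[c] * pd[i] - m1 - ph[i] * m2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
arma::cube cpp_bn_infer(const arma::cube& x, const arma::vec& scale,
                        const arma::vec& shift) {
  int V = x.n_rows, C = x.n_cols, B = x.n_slices;
  arma::cube out(V, C, B);
  for (int c = 0; c < C; c++)
    for (int b = 0; b < B; b++) {
      const double* p = x.slice(b).colptr(c);
      double* o = out.slice(b).colptr(c);
      for (int i = 0; i < V; i++) o[i] = p[i] * scale[c] + shift[c];
    }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_relu(const arma::cube& x) {
  arma::cube out = x;
  out.for_each([](arma::mat::elem_type& v) { if (v < 0) v = 0; });
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_relu_backward(const arma::cube& dy, const arma::cube& pre) {
  int V = dy.n_rows, C = dy.n_cols, B = dy.n_slices;
  arma::cube out(V, C, B);
  for (int b = 0; b < B; b++)
    for (int c = 0; c < C; c++) {
      const double* pd = dy.slice(b).colptr(c);
      const double* pp = pre.slice(b).colptr(c);
      double* o = out.slice(b).colptr(c);
      for (int i = 0; i < V; i++) o[i] = pp[i] > 0 ? pd[i] : 0.0;
    }
  return out;
}
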