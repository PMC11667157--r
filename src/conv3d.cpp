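// 3D convolution kernels for the pseudo-3D network.
//
// Arrays are column-major with dims (X, Y, Z, C, N): X fastest, batch
// slowest, matching R's array layout after aperm in the model code.
// "Valid" convolution only; any padding is applied by the caller.

#include <Rcpp.h>
using namespace Rcpp;

static inline R_xlen_t off4(int x, int y, int z, int c, int n,
                            int X, int Y, int Z, int C) {
  return x + (R_xlen_t)X * (y + (R_xlen_t)Y *
         (z + (R_xlen_t)Z * (c + (R_xlen_t)C * n)));
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xd,
                         NumericVector w, IntegerVector wd,
                         NumericVector bias, IntegerVector stride) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], N = xd[4];
  const int kx = wd[0], ky = wd[1], kz = wd[2], Co = wd[4];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int OX = (X - kx) / sx + 1, OY = (Y - ky) / sy + 1,
            OZ = (Z - kz) / sz + 1;
  NumericVector out((R_xlen_t)OX * OY * OZ * Co * N);
  double *po = REAL(out);
  const double *px = REAL(x), *pw = REAL(w), *pb = REAL(bias);
  std::vector<double> buf(OX);
  for (int n = 0; n < N; n++)
    for (int co = 0; co < Co; co++) {
      const double *wc = pw + (R_xlen_t)kx * ky * kz * Ci * co;
      for (int oz = 0; oz < OZ; oz++)
        for (int oy = 0; oy < OY; oy++) {
          for (int ox = 0; ox < OX; ox++) buf[ox] = pb[co];
          const double *wk = wc;
          for (int ci = 0; ci < Ci; ci++)
            for (int z = 0; z < kz; z++)
              for (int y = 0; y < ky; y++) {
                const double *xrow = px + off4(0, oy * sy + y, oz * sz + z,
                                               ci, n, X, Y, Z, Ci);
                for (int xk = 0; xk < kx; xk++, wk++) {
                  const double wv = *wk;
                  if (wv == 0.0) continue;
                  const double *xr = xrow + xk;
                  if (sx == 1)
                    for (int ox = 0; ox < OX; ox++) buf[ox] += wv * xr[ox];
                  else
                    for (int ox = 0; ox < OX; ox++)
                      buf[ox] += wv * xr[ox * sx];
                }
              }
          double *orow = po + off4(0, oy, oz, co, n, OX, OY, OZ, Co);
          for (int ox = 0; ox < OX; ox++) orow[ox] = buf[ox];
        }
    }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, Co, N);
  return out;
}

// [[Rcpp::export]]
NumericVector conv3d_bwd_input(NumericVector gy, IntegerVector gd,
                               NumericVector w, IntegerVector wd,
                               IntegerVector xd, IntegerVector stride) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], N = xd[4];
  const int kx = wd[0], ky = wd[1], kz = wd[2], Co = wd[4];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int OX = gd[0], OY = gd[1], OZ = gd[2];
  NumericVector gx((R_xlen_t)X * Y * Z * Ci * N);
  double *pgx = REAL(gx);
  const double *pg = REAL(gy), *pw = REAL(w);
  std::vector<double> buf(OX);
  for (int n = 0; n < N; n++)
    for (int oz = 0; oz < OZ; oz++)
      for (int oy = 0; oy < OY; oy++)
        for (int ci = 0; ci < Ci; ci++)
          for (int z = 0; z < kz; z++)
            for (int y = 0; y < ky; y++)
              for (int xk = 0; xk < kx; xk++) {
                // sum the contribution of all output channels first
                for (int ox = 0; ox < OX; ox++) buf[ox] = 0.0;
                bool any = false;
                for (int co = 0; co < Co; co++) {
                  const double wv = pw[xk + (R_xlen_t)kx * (y +
                      (R_xlen_t)ky * (z + (R_xlen_t)kz *
                      (ci + (R_xlen_t)Ci * co)))];
                  if (wv == 0.0) continue;
                  any = true;
                  const double *grow = pg + off4(0, oy, oz, co, n,
                                                 OX, OY, OZ, Co);
                  for (int ox = 0; ox < OX; ox++) buf[ox] += wv * grow[ox];
                }
                if (!any) continue;
                double *xrow = pgx + off4(xk, oy * sy + y, oz * sz + z,
                                          ci, n, X, Y, Z, Ci);
                if (sx == 1)
                  for (int ox = 0; ox < OX; ox++) xrow[ox] += buf[ox];
                else
                  for (int ox = 0; ox < OX; ox++) xrow[ox * sx] += buf[ox];
              }
  gx.attr("dim") = xd;
  return gx;
}

// [[Rcpp::export]]
List conv3d_bwd_weights(NumericVector x, IntegerVector xd,
                        NumericVector gy, IntegerVector gd,
                        IntegerVector wd, IntegerVector stride) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], N = xd[4];
  const int kx = wd[0], ky = wd[1], kz = wd[2], Co = wd[4];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int OX = gd[0], OY = gd[1], OZ = gd[2];
  const R_xlen_t nw = (R_xlen_t)kx * ky * kz * Ci;
  NumericVector dw(nw * Co);
  NumericVector db(Co);
  double *pdw = REAL(dw), *pdb = REAL(db);
  const double *px = REAL(x), *pg = REAL(gy);
  for (int n = 0; n < N; n++)
    for (int co = 0; co < Co; co++) {
      double bacc = 0.0;
      double *dwc = pdw + nw * co;
      for (int oz = 0; oz < OZ; oz++)
        for (int oy = 0; oy < OY; oy++) {
          const double *grow = pg + off4(0, oy, oz, co, n, OX, OY, OZ, Co);
          for (int ox = 0; ox < OX; ox++) bacc += grow[ox];
          double *dk = dwc;
          for (int ci = 0; ci < Ci; ci++)
            for (int z = 0; z < kz; z++)
              for (int y = 0; y < ky; y++) {
                const double *xrow = px + off4(0, oy * sy + y, oz * sz + z,
                                               ci, n, X, Y, Z, Ci);
                for (int xk = 0; xk < kx; xk++, dk++) {
                  const double *xr = xrow + xk;
                  double acc = 0.0;
                  if (sx == 1)
                    for (int ox = 0; ox < OX; ox++) acc += grow[ox] * xr[ox];
                  else
                    for (int ox = 0; ox < OX; ox++)
                      acc += grow[ox] * xr[ox * sx];
                  *dk += acc;
                }
              }
        }
      pdb[co] += bacc;
    }
  dw.attr("dim") = wd;
  return List::create(_["dw"] = dw, _["db"] = db);
}
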