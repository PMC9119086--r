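#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Images are H x W matrices in R's column-major layout; pixel (x, y)
// (0-based, x = column, y = row) has linear index y + x*H. Descriptor
// fields are (H*W) x D matrices with rows in that pixel order.

static const int DESC_CELLS = 4;   // 4x4 spatial cells
static const int DESC_BINS = 8;    // orientation bins
static const int DESC_DIM = DESC_CELLS * DESC_CELLS * DESC_BINS;
static const int DESC_HALF = 8;    // 16x16 support

// [[Rcpp::export(name = ".denseSiftCpp")]]
NumericMatrix denseSiftCpp(NumericMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  if (H < 2 * DESC_HALF || W < 2 * DESC_HALF)
    stop("image smaller than the 16x16 descriptor support");
  std::vector<double> mag(H * W), obin(H * W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int xm = x > 0 ? x - 1 : 0, xp = x < W - 1 ? x + 1 : W - 1;
      int ym = y > 0 ? y - 1 : 0, yp = y < H - 1 ? y + 1 : H - 1;
      double gx = (img(y, xp) - img(y, xm)) * 0.5;
      double gy = (img(yp, x) - img(ym, x)) * 0.5;
      double m = std::sqrt(gx * gx + gy * gy);
      double o = std::atan2(gy, gx);
      if (o < 0) o += 2.0 * M_PI;
      mag[y + x * H] = m;
      obin[y + x * H] = o / (2.0 * M_PI) * DESC_BINS;
    }
  }
  NumericMatrix out(H * W, DESC_DIM);
  std::vector<double> d(DESC_DIM);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      std::fill(d.begin(), d.end(), 0.0);
      for (int dx = -DESC_HALF; dx < DESC_HALF; ++dx) {
        int sx = x + dx;
        if (sx < 0 || sx >= W) continue;
        int cx = (dx + DESC_HALF) / DESC_CELLS;
        for (int dy = -DESC_HALF; dy < DESC_HALF; ++dy) {
          int sy = y + dy;
          if (sy < 0 || sy >= H) continue;
          int cy = (dy + DESC_HALF) / DESC_CELLS;
          double m = mag[sy + sx * H];
          if (m <= 0) continue;
          double ob = obin[sy + sx * H];
          int b0 = (int)std::floor(ob) % DESC_BINS;
          double f = ob - std::floor(ob);
          int cell = (cy * DESC_CELLS + cx) * DESC_BINS;
          d[cell + b0] += m * (1.0 - f);
          d[cell + (b0 + 1) % DESC_BINS] += m * f;
        }
      }
      double nrm = 0;
      for (int k = 0; k < DESC_DIM; ++k) nrm += d[k] * d[k];
      nrm = std::sqrt(nrm);
      int row = y + x * H;
      if (nrm < 1e-12) continue;   // empty cell: zero descriptor
      for (int k = 0; k < DESC_DIM; ++k) {
        double v = d[k] / nrm;
        d[k] = v > 0.2 ? 0.2 : v;   // clip and renormalize
      }
      nrm = 0;
      for (int k = 0; k < DESC_DIM; ++k) nrm += d[k] * d[k];
      nrm = std::sqrt(nrm);
      for (int k = 0; k < DESC_DIM; ++k) out(row, k) = d[k] / nrm;
    }
  }
  return out;
}

// Truncated L1 data cost of matching pixel (x, y) in d1 to (x+u, y+v) in d2.
static inline double dataCost(const double* d1, const double* d2,
                              int H, int W, int D, int npix,
                              int x, int y, int u, int v, double trunc) {
  int tx = x + u, ty = y + v;
  if (tx < 0 || tx >= W || ty < 0 || ty >= H) return trunc;
  int p = y + x * H, q = ty + tx * H;
  double s = 0;
  for (int k = 0; k < D; ++k) {
    s += std::fabs(d1[p + (size_t)k * npix] - d2[q + (size_t)k * npix]);
    if (s >= trunc) return trunc;
  }
  return s;
}

static inline double pairCost(int u1, int v1, int u2, int v2,
                              double sw, double st) {
  double cu = sw * std::abs(u1 - u2); if (cu > st) cu = st;
  double cv = sw * std::abs(v1 - v2); if (cv > st) cv = st;
  return cu + cv;
}

// [[Rcpp::export(name = ".flowEnergyCpp")]]
double flowEnergyCpp(NumericMatrix d1, NumericMatrix d2,
                     IntegerMatrix u, IntegerMatrix v,
                     double trunc, double eta, double sw, double st) {
  const int H = u.nrow(), W = u.ncol();
  const int npix = H * W, D = d1.ncol();
  if (d1.nrow() != npix || d2.nrow() != npix)
    stop("descriptor fields and flow geometry mismatch");
  const double* p1 = REAL(d1);
  const double* p2 = REAL(d2);
  double e = 0;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int uu = u(y, x), vv = v(y, x);
      e += dataCost(p1, p2, H, W, D, npix, x, y, uu, vv, trunc);
      e += eta * (std::abs(uu) + std::abs(vv));
      if (x + 1 < W) e += pairCost(uu, vv, u(y, x + 1), v(y, x + 1), sw, st);
      if (y + 1 < H) e += pairCost(uu, vv, u(y + 1, x), v(y + 1, x), sw, st);
    }
  }
  return e;
}

// Best constant flow over the (2r+1)^2 window by data + magnitude cost,
// evaluated on a stride-subsampled pixel grid.
// [[Rcpp::export(name = ".bestConstantFlowCpp")]]
IntegerVector bestConstantFlowCpp(NumericMatrix d1, NumericMatrix d2,
                                  int H, int W, int r,
                                  double trunc, double eta, int stride = 1) {
  const int npix = H * W, D = d1.ncol();
  const double* p1 = REAL(d1);
  const double* p2 = REAL(d2);
  if (stride < 1) stride = 1;
  double best = R_PosInf;
  int bu = 0, bv = 0;
  for (int v = -r; v <= r; ++v) {
    for (int u = -r; u <= r; ++u) {
      long cnt = 0;
      double e = 0;
      for (int x = 0; x < W && e < best; x += stride)
        for (int y = 0; y < H; y += stride, ++cnt)
          e += dataCost(p1, p2, H, W, D, npix, x, y, u, v, trunc);
      if (cnt > 0)
        e += eta * (std::abs(u) + std::abs(v)) * cnt;
      if (e < best) { best = e; bu = u; bv = v; }
    }
  }
  return IntegerVector::create(bu, bv);
}

// local (unary + incident pairwise) cost of label (u, v) at (x, y),
// optionally excluding one incident neighbor (ex = 0 none, 1 left,
// 2 right, 3 up, 4 down)
static double siteCost(const double* p1, const double* p2,
                       int H, int W, int D, int npix,
                       const IntegerMatrix& u, const IntegerMatrix& v,
                       int x, int y, int nu, int nv,
                       double trunc, double eta, double sw, double st,
                       int ex = 0) {
  double e = dataCost(p1, p2, H, W, D, npix, x, y, nu, nv, trunc) +
    eta * (std::abs(nu) + std::abs(nv));
  if (x > 0 && ex != 1) e += pairCost(nu, nv, u(y, x - 1), v(y, x - 1), sw, st);
  if (x + 1 < W && ex != 2) e += pairCost(nu, nv, u(y, x + 1), v(y, x + 1), sw, st);
  if (y > 0 && ex != 3) e += pairCost(nu, nv, u(y - 1, x), v(y - 1, x), sw, st);
  if (y + 1 < H && ex != 4) e += pairCost(nu, nv, u(y + 1, x), v(y + 1, x), sw, st);
  return e;
}

// Iterated conditional improvement sweeps: each accepted move strictly
// lowers the global energy; deterministic raster order. When pairMoves is
// set (small instances), converged single-site sweeps are followed by
// joint moves of 4-neighbor pixel pairs, which escape pairwise-coupled
// local minima.
// [[Rcpp::export(name = ".flowIcmCpp")]]
List flowIcmCpp(NumericMatrix d1, NumericMatrix d2,
                IntegerMatrix u0, IntegerMatrix v0,
                int window, int searchRadius, int maxSweeps,
                double trunc, double eta, double sw, double st,
                bool pairMoves = false) {
  const int H = u0.nrow(), W = u0.ncol();
  const int npix = H * W, D = d1.ncol();
  if (d1.nrow() != npix || d2.nrow() != npix)
    stop("descriptor fields and flow geometry mismatch");
  const double* p1 = REAL(d1);
  const double* p2 = REAL(d2);
  IntegerMatrix u = clone(u0), v = clone(v0);
  std::vector<double> trace;
  trace.push_back(flowEnergyCpp(d1, d2, u, v, trunc, eta, sw, st));
  for (int sweep = 0; sweep < maxSweeps; ++sweep) {
    bool changed = false;
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        int cu = u(y, x), cv = v(y, x);
        double bestLocal = R_PosInf;
        int bu = cu, bv = cv;
        for (int dv = -window; dv <= window; ++dv) {
          for (int du = -window; du <= window; ++du) {
            int nu = cu + du, nv = cv + dv;
            if (std::abs(nu) > searchRadius || std::abs(nv) > searchRadius)
              continue;
            double e = dataCost(p1, p2, H, W, D, npix, x, y, nu, nv, trunc) +
              eta * (std::abs(nu) + std::abs(nv));
            if (x > 0) e += pairCost(nu, nv, u(y, x - 1), v(y, x - 1), sw, st);
            if (x + 1 < W) e += pairCost(nu, nv, u(y, x + 1), v(y, x + 1), sw, st);
            if (y > 0) e += pairCost(nu, nv, u(y - 1, x), v(y - 1, x), sw, st);
            if (y + 1 < H) e += pairCost(nu, nv, u(y + 1, x), v(y + 1, x), sw, st);
            // strict improvement with deterministic tie-break (first found)
            if (e < bestLocal - 1e-12 ||
                (bestLocal == R_PosInf && nu == cu && nv == cv)) {
              bestLocal = e; bu = nu; bv = nv;
            }
          }
        }
        if (bu != cu || bv != cv) {
          double cur = dataCost(p1, p2, H, W, D, npix, x, y, cu, cv, trunc) +
            eta * (std::abs(cu) + std::abs(cv));
          if (x > 0) cur += pairCost(cu, cv, u(y, x - 1), v(y, x - 1), sw, st);
          if (x + 1 < W) cur += pairCost(cu, cv, u(y, x + 1), v(y, x + 1), sw, st);
          if (y > 0) cur += pairCost(cu, cv, u(y - 1, x), v(y - 1, x), sw, st);
          if (y + 1 < H) cur += pairCost(cu, cv, u(y + 1, x), v(y + 1, x), sw, st);
          if (bestLocal < cur - 1e-12) {
            u(y, x) = bu; v(y, x) = bv;
            changed = true;
          }
        }
      }
    }
    if (pairMoves && !changed) {
      // joint moves over 4-neighbor pairs (right and down edges)
      for (int y = 0; y < H; ++y) {
        for (int x = 0; x < W; ++x) {
          for (int dir = 0; dir < 2; ++dir) {
            int x2 = x + (dir == 0 ? 1 : 0), y2 = y + (dir == 0 ? 0 : 1);
            if (x2 >= W || y2 >= H) continue;
            int exA = dir == 0 ? 2 : 4;   // neighbor excluded at first site
            int exB = dir == 0 ? 1 : 3;
            int cuA = u(y, x), cvA = v(y, x);
            int cuB = u(y2, x2), cvB = v(y2, x2);
            double cur =
              siteCost(REAL(d1), REAL(d2), H, W, d1.ncol(), H * W, u, v,
                       x, y, cuA, cvA, trunc, eta, sw, st, exA) +
              siteCost(REAL(d1), REAL(d2), H, W, d1.ncol(), H * W, u, v,
                       x2, y2, cuB, cvB, trunc, eta, sw, st, exB) +
              pairCost(cuA, cvA, cuB, cvB, sw, st);
            double best = cur;
            int bA[2] = {cuA, cvA}, bB[2] = {cuB, cvB};
            for (int dvA = -window; dvA <= window; ++dvA)
              for (int duA = -window; duA <= window; ++duA) {
                int nuA = cuA + duA, nvA = cvA + dvA;
                if (std::abs(nuA) > searchRadius ||
                    std::abs(nvA) > searchRadius) continue;
                double eA = siteCost(REAL(d1), REAL(d2), H, W, d1.ncol(),
                                     H * W, u, v, x, y, nuA, nvA,
                                     trunc, eta, sw, st, exA);
                if (eA >= best) continue;
                for (int dvB = -window; dvB <= window; ++dvB)
                  for (int duB = -window; duB <= window; ++duB) {
                    int nuB = cuB + duB, nvB = cvB + dvB;
                    if (std::abs(nuB) > searchRadius ||
                        std::abs(nvB) > searchRadius) continue;
                    double e = eA +
                      siteCost(REAL(d1), REAL(d2), H, W, d1.ncol(), H * W,
                               u, v, x2, y2, nuB, nvB, trunc, eta, sw, st,
                               exB) +
                      pairCost(nuA, nvA, nuB, nvB, sw, st);
                    if (e < best - 1e-12) {
                      best = e;
                      bA[0] = nuA; bA[1] = nvA; bB[0] = nuB; bB[1] = nvB;
                    }
                  }
              }
            if (bA[0] != cuA || bA[1] != cvA || bB[0] != cuB || bB[1] != cvB) {
              u(y, x) = bA[0]; v(y, x) = bA[1];
              u(y2, x2) = bB[0]; v(y2, x2) = bB[1];
              changed = true;
            }
          }
        }
      }
      // exhaustive 2x2 block moves for very small search radii
      if (!changed && searchRadius <= 1) {
        const int side2 = 2 * searchRadius + 1, L2 = side2 * side2;
        std::vector<int> lu2(L2), lv2(L2);
        for (int l = 0; l < L2; ++l) {
          lu2[l] = l % side2 - searchRadius;
          lv2[l] = l / side2 - searchRadius;
        }
        for (int y = 0; y + 1 < H; ++y) {
          for (int x = 0; x + 1 < W; ++x) {
            int bx[4] = {x, x + 1, x, x + 1}, by[4] = {y, y, y + 1, y + 1};
            int curl[4];
            for (int i = 0; i < 4; ++i) {
              int l = (v(by[i], bx[i]) + searchRadius) * side2 +
                      (u(by[i], bx[i]) + searchRadius);
              curl[i] = l;
            }
            // external cost of label l at block slot i (block-internal
            // edges excluded); unaries included
            std::vector<double> ext(4 * L2);
            for (int i = 0; i < 4; ++i)
              for (int l = 0; l < L2; ++l) {
                double e = siteCost(REAL(d1), REAL(d2), H, W, d1.ncol(),
                                    H * W, u, v, bx[i], by[i],
                                    lu2[l], lv2[l], trunc, eta, sw, st);
                // strip block-internal contributions (added back jointly)
                for (int j = 0; j < 4; ++j) {
                  if (j == i) continue;
                  if ((bx[j] == bx[i] + 1 && by[j] == by[i]) ||
                      (bx[j] == bx[i] - 1 && by[j] == by[i]) ||
                      (bx[j] == bx[i] && by[j] == by[i] + 1) ||
                      (bx[j] == bx[i] && by[j] == by[i] - 1))
                    e -= pairCost(lu2[l], lv2[l], u(by[j], bx[j]),
                                  v(by[j], bx[j]), sw, st);
                }
                ext[i * L2 + l] = e;
              }
            double best = R_PosInf;
            int bl[4];
            for (int l0 = 0; l0 < L2; ++l0)
              for (int l1 = 0; l1 < L2; ++l1)
                for (int l2 = 0; l2 < L2; ++l2)
                  for (int l3 = 0; l3 < L2; ++l3) {
                    double e = ext[0 * L2 + l0] + ext[1 * L2 + l1] +
                      ext[2 * L2 + l2] + ext[3 * L2 + l3] +
                      pairCost(lu2[l0], lv2[l0], lu2[l1], lv2[l1], sw, st) +
                      pairCost(lu2[l0], lv2[l0], lu2[l2], lv2[l2], sw, st) +
                      pairCost(lu2[l1], lv2[l1], lu2[l3], lv2[l3], sw, st) +
                      pairCost(lu2[l2], lv2[l2], lu2[l3], lv2[l3], sw, st);
                    if (e < best - 1e-12) {
                      best = e;
                      bl[0] = l0; bl[1] = l1; bl[2] = l2; bl[3] = l3;
                    }
                  }
            if (bl[0] != curl[0] || bl[1] != curl[1] ||
                bl[2] != curl[2] || bl[3] != curl[3]) {
              double curE = ext[0 * L2 + curl[0]] + ext[1 * L2 + curl[1]] +
                ext[2 * L2 + curl[2]] + ext[3 * L2 + curl[3]] +
                pairCost(lu2[curl[0]], lv2[curl[0]], lu2[curl[1]], lv2[curl[1]], sw, st) +
                pairCost(lu2[curl[0]], lv2[curl[0]], lu2[curl[2]], lv2[curl[2]], sw, st) +
                pairCost(lu2[curl[1]], lv2[curl[1]], lu2[curl[3]], lv2[curl[3]], sw, st) +
                pairCost(lu2[curl[2]], lv2[curl[2]], lu2[curl[3]], lv2[curl[3]], sw, st);
              if (best < curE - 1e-12) {
                for (int i = 0; i < 4; ++i) {
                  u(by[i], bx[i]) = lu2[bl[i]];
                  v(by[i], bx[i]) = lv2[bl[i]];
                }
                changed = true;
              }
            }
          }
        }
      }
      trace.push_back(flowEnergyCpp(d1, d2, u, v, trunc, eta, sw, st));
    }
    if (!changed) break;
  }
  return List::create(_["u"] = u, _["v"] = v, _["trace"] = wrap(trace));
}

// Exact global minimum of the discrete flow energy by a frontier dynamic
// program over scanline states. Provably suboptimal labels are pruned
// first: with U = energy of the best constant flow (an upper bound
// computed independently of the returned optimum) and LB = sum of
// per-pixel unary minima, any labeling using label l at pixel p has
// energy >= unary(p, l) + LB - unary_min(p); if that exceeds U the label
// cannot be optimal. The remaining variable-radix DP is exact. Feasible
// for tiny instances (e.g. 8x8 at search radius 1).
// [[Rcpp::export(name = ".flowDpExactCpp")]]
double flowDpExactCpp(NumericMatrix d1, NumericMatrix d2,
                      int H, int W, int r,
                      double trunc, double eta, double sw, double st) {
  const int npix = H * W, D = d1.ncol();
  const int side = 2 * r + 1, L = side * side;
  if (std::pow((double)L, (double)W) > 6e7)
    stop("frontier too large: label^width must stay below 6e7");
  const double* p1 = REAL(d1);
  const double* p2 = REAL(d2);
  std::vector<int> lu(L), lv(L);
  for (int l = 0; l < L; ++l) { lu[l] = l % side - r; lv[l] = l / side - r; }
  std::vector<double> V(L * L);
  for (int a = 0; a < L; ++a)
    for (int b = 0; b < L; ++b)
      V[a * L + b] = pairCost(lu[a], lv[a], lu[b], lv[b], sw, st);
  // unary cost per pixel per label (data + magnitude)
  std::vector<double> Dt((size_t)npix * L);
  for (int k = 0; k < npix; ++k) {
    int y = k / W, x = k % W;   // row-major scan order
    for (int l = 0; l < L; ++l)
      Dt[(size_t)k * L + l] =
        dataCost(p1, p2, H, W, D, npix, x, y, lu[l], lv[l], trunc) +
        eta * (std::abs(lu[l]) + std::abs(lv[l]));
  }
  // upper bound: the cheaper of (a) the best constant labeling (pairwise
  // terms vanish) and (b) the per-pixel unary-argmin labeling at full
  // energy - both feasible labelings, so valid bounds
  double ub = R_PosInf;
  for (int l = 0; l < L; ++l) {
    double e = 0;
    for (int k = 0; k < npix; ++k) e += Dt[(size_t)k * L + l];
    if (e < ub) ub = e;
  }
  {
    std::vector<int> greedy(npix);
    double e = 0;
    for (int k = 0; k < npix; ++k) {
      int bestL = 0;
      double m = R_PosInf;
      for (int l = 0; l < L; ++l)
        if (Dt[(size_t)k * L + l] < m) { m = Dt[(size_t)k * L + l]; bestL = l; }
      greedy[k] = bestL;
      e += m;
    }
    for (int k = 0; k < npix; ++k) {
      int y = k / W, x = k % W;
      if (x + 1 < W)
        e += V[(size_t)greedy[k] * L + greedy[k + 1]];
      if (y + 1 < H)
        e += V[(size_t)greedy[k] * L + greedy[k + W]];
    }
    if (e < ub) ub = e;
  }
  // per-pixel unary minima and the pruning gap
  std::vector<double> umin(npix);
  double lb = 0;
  for (int k = 0; k < npix; ++k) {
    double m = R_PosInf;
    for (int l = 0; l < L; ++l) m = std::min(m, Dt[(size_t)k * L + l]);
    umin[k] = m;
    lb += m;
  }
  const double gap = ub - lb + 1e-9;
  // pruned label sets
  std::vector<std::vector<int> > keep(npix);
  double work = 0;
  {
    double prod = 1;
    std::vector<double> win;   // radices of the sliding window
    for (int k = 0; k < npix; ++k) {
      for (int l = 0; l < L; ++l)
        if (Dt[(size_t)k * L + l] - umin[k] <= gap) keep[k].push_back(l);
      double Rk = (double)keep[k].size();
      if ((int)win.size() == W) { prod /= win.front(); win.erase(win.begin()); }
      work += prod * Rk;
      win.push_back(Rk);
      prod *= Rk;
      if (prod > 5e7 || work > 5e8) { work = -1; break; }
    }
  }
  if (work < 0) {
    // fall back: no pruning, full label set everywhere
    for (int k = 0; k < npix; ++k) {
      keep[k].resize(L);
      for (int l = 0; l < L; ++l) keep[k][l] = l;
    }
  }
  // variable-radix frontier DP; state digits ordered oldest..newest
  std::vector<double> cur(1, 0.0), nxt;
  std::vector<int> radix;   // radices of the pixels in the window
  for (int k = 0; k < npix; ++k) {
    int y = k / W, x = k % W;
    const double* Dk = &Dt[(size_t)k * L];
    const std::vector<int>& Lk = keep[k];
    const int Rk = (int)Lk.size();
    const bool full = (int)radix.size() == W;
    size_t oldSize = cur.size();
    if (!full) {
      nxt.assign(oldSize * Rk, 0.0);
      const std::vector<int>* Lprev = k > 0 ? &keep[k - 1] : 0;
      int Rlast = k > 0 ? (int)Lprev->size() : 1;
      for (size_t s = 0; s < oldSize; ++s) {
        int lastIdx = k > 0 ? (int)(s % Rlast) : 0;
        for (int i = 0; i < Rk; ++i) {
          double e = cur[s] + Dk[Lk[i]];
          if (x > 0) e += V[(size_t)Lk[i] * L + (*Lprev)[lastIdx]];
          nxt[s * Rk + i] = e;
        }
      }
      cur.swap(nxt);
      radix.push_back(Rk);
    } else {
      const int Rold = radix.front();
      const std::vector<int>& Lup = keep[k - W];
      const std::vector<int>& Lleft = keep[k - 1];
      const int Rlast = radix.back();
      const size_t rest = oldSize / Rold;
      nxt.assign(rest * Rk, R_PosInf);
      for (size_t a = 0; a < (size_t)Rold; ++a) {
        const double* slab = &cur[a * rest];
        for (int i = 0; i < Rk; ++i) {
          const double vup = y > 0 ? V[(size_t)Lk[i] * L + Lup[a]] : 0.0;
          double* out = &nxt[0];
          for (size_t t = 0; t < rest; ++t) {
            double cand = slab[t] + vup;
            double& cell = out[t * Rk + i];
            if (cand < cell) cell = cand;
          }
        }
      }
      for (size_t t = 0; t < rest; ++t) {
        int lastIdx = (int)(t % Rlast);
        for (int i = 0; i < Rk; ++i) {
          double e = Dk[Lk[i]];
          if (x > 0) e += V[(size_t)Lk[i] * L + Lleft[lastIdx]];
          nxt[t * Rk + i] += e;
        }
      }
      cur.swap(nxt);
      radix.erase(radix.begin());
      radix.push_back(Rk);
    }
  }
  double best = R_PosInf;
  for (size_t s = 0; s < cur.size(); ++s) if (cur[s] < best) best = cur[s];
  return best;
}

// 4-connected components of a binary mask, labels 1..K in scan order.
// [[Rcpp::export(name = ".ccLabel4Cpp")]]
IntegerMatrix ccLabel4Cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (mask(y, x) == 0 || lab(y, x) != 0) continue;
      ++next;
      stack.push_back(std::make_pair(y, x));
      lab(y, x) = next;
      while (!stack.empty()) {
        int cy = stack.back().first, cx = stack.back().second;
        stack.pop_back();
        const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int ny = cy + dy[d], nx = cx + dx[d];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (mask(ny, nx) != 0 && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            stack.push_back(std::make_pair(ny, nx));
          }
        }
      }
    }
  }
  return lab;
}
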