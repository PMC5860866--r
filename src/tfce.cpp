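#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Threshold-free cluster enhancement on a 3-D statistic volume.
//
// For each voxel v: TFCE(v) = sum over heights h = dh, 2dh, ... of
// e(h)^E * h^H * dh, where e(h) is the size of the connected
// supra-threshold (stat >= h) cluster containing v. Negative values are
// enhanced by applying the same transform to -stat and negating.
// Non-finite entries are treated as outside the mask and returned as-is.

static void neighbor_offsets(int connectivity, std::vector<int>& dx,
                             std::vector<int>& dy, std::vector<int>& dz) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int manhattan = std::abs(a) + std::abs(b) + std::abs(c);
        if (manhattan == 0) continue;
        if ((connectivity == 6 && manhattan > 1) ||
            (connectivity == 18 && manhattan > 2)) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

static void tfce_pass(const std::vector<double>& val,
                      const std::vector<int>& inmask,
                      int nx, int ny, int nz,
                      double E, double H, double dh, int connectivity,
                      std::vector<double>& out) {
  int n = nx * ny * nz;
  double vmax = 0.0;
  for (int i = 0; i < n; ++i)
    if (inmask[i] && val[i] > vmax) vmax = val[i];
  if (vmax <= 0.0) return;

  std::vector<int> ddx, ddy, ddz;
  neighbor_offsets(connectivity, ddx, ddy, ddz);
  int noff = (int)ddx.size();

  std::vector<int> stamp(n, -1);
  std::vector<int> queue(n);
  std::vector<int> members(n);

  int nsteps = (int)std::floor(vmax / dh + 1e-12);
  for (int s = 1; s <= nsteps; ++s) {
    double h = s * dh;
    double hH = std::pow(h, H) * dh;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = x + nx * (y + ny * z);
          if (!inmask[i] || val[i] < h || stamp[i] == s) continue;
          // BFS the cluster containing voxel i at height h
          int head = 0, tail = 0, sz = 0;
          queue[tail++] = i; stamp[i] = s;
          while (head < tail) {
            int cur = queue[head++];
            members[sz++] = cur;
            int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
            for (int k = 0; k < noff; ++k) {
              int px = cx + ddx[k], py = cy + ddy[k], pz = cz + ddz[k];
              if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
                continue;
              int j = px + nx * (py + ny * pz);
              if (inmask[j] && val[j] >= h && stamp[j] != s) {
                stamp[j] = s;
                queue[tail++] = j;
              }
            }
          }
          double inc = std::pow((double)sz, E) * hH;
          for (int k = 0; k < sz; ++k) out[members[k]] += inc;
        }
  }
}

// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims,
                       double E, double H, double dh, int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  if (dh <= 0) stop("dh must be positive");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if (stat.size() != n) stop("stat length does not match dims");

  std::vector<double> pos(n, 0.0), neg(n, 0.0), outp(n, 0.0), outn(n, 0.0);
  std::vector<int> inmask(n, 0);
  for (int i = 0; i < n; ++i) {
    double v = stat[i];
    if (R_finite(v)) {
      inmask[i] = 1;
      if (v > 0) pos[i] = v;
      else if (v < 0) neg[i] = -v;
    }
  }
  tfce_pass(pos, inmask, nx, ny, nz, E, H, dh, connectivity, outp);
  tfce_pass(neg, inmask, nx, ny, nz, E, H, dh, connectivity, outn);

  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (!inmask[i]) out[i] = stat[i];           // keep NA/Inf markers
    else out[i] = outp[i] - outn[i];
  }
  return out;
}
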