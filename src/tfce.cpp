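#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Neighbourhood offsets for 6/18/26-connectivity in a 3D grid.
static std::vector<std::array<int, 3> > make_offsets(int conn) {
  std::vector<std::array<int, 3> > nb;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (conn == 6 && s > 1) continue;
        if (conn == 18 && s > 2) continue;
        std::array<int, 3> o = {{dx, dy, dz}};
        nb.push_back(o);
      }
  return nb;
}

// TFCE for the positive tail of a statistic image (column-major 3D array).
// Voxels outside the analysis mask must already be zero. If dh <= 0 the
// step is set to max(stat)/nsteps.
//
// Thresholds are processed in descending order with an incremental
// cluster merge: each voxel is activated once, clusters are merged
// small-into-large with per-voxel accumulator offsets, and at every
// threshold each live cluster receives size^E * h^H * dh. This is
// algebraically identical to per-threshold connected-component labelling
// (the brute-force oracle in the tests) but costs O(V log V) instead of
// O(nsteps * V).
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims,
                       double E, double H, double dh, int nsteps, int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  if (stat.size() != V) stop("stat length does not match grid dims");
  NumericVector out(V);
  double mx = 0.0;
  for (int v = 0; v < V; ++v) if (stat[v] > mx) mx = stat[v];
  if (mx <= 0.0) return out;
  if (dh <= 0.0) dh = mx / nsteps;
  const int K = (int)std::floor(mx / dh + 1e-9);
  if (K < 1) return out;
  std::vector<std::array<int, 3> > nb = make_offsets(conn);

  // positive voxels sorted by value descending
  std::vector<int> vox;
  vox.reserve(V / 4);
  for (int v = 0; v < V; ++v) if (stat[v] > 0.0) vox.push_back(v);
  std::sort(vox.begin(), vox.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  std::vector<int> cluster(V, -1);          // voxel -> cluster id
  std::vector<double> base(V, 0.0);         // accumulator offset at join
  std::vector<std::vector<int> > members;   // cluster id -> voxels
  std::vector<double> acc;                  // cluster id -> accumulated sum
  std::vector<char> alive;
  std::vector<int> live;                    // list of live cluster ids

  size_t next = 0; // pointer into vox
  for (int k = K; k >= 1; --k) {
    double h = k * dh;
    // activate voxels with stat >= h
    while (next < vox.size() && stat[vox[next]] >= h - 1e-12) {
      int v = vox[next++];
      int c = (int)members.size();
      members.push_back(std::vector<int>(1, v));
      acc.push_back(0.0);
      alive.push_back(1);
      live.push_back(c);
      cluster[v] = c;
      int kz = v / (nx * ny), rem = v % (nx * ny), j = rem / nx, i = rem % nx;
      for (size_t q = 0; q < nb.size(); ++q) {
        int ii = i + nb[q][0], jj = j + nb[q][1], kk = kz + nb[q][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        int w = ii + nx * (jj + ny * kk);
        int cw = cluster[w];
        int cv = cluster[v];
        if (cw < 0 || cw == cv) continue;
        // merge smaller into larger, preserving per-voxel histories
        int big = cv, small = cw;
        if (members[big].size() < members[small].size()) std::swap(big, small);
        double shift = acc[big] - acc[small];
        for (size_t m = 0; m < members[small].size(); ++m) {
          int u = members[small][m];
          base[u] += shift;
          cluster[u] = big;
          members[big].push_back(u);
        }
        members[small].clear();
        alive[small] = 0;
      }
    }
    // contribution at this threshold for every live cluster
    double hH = std::pow(h, H) * dh;
    size_t w_i = 0;
    for (size_t li = 0; li < live.size(); ++li) {
      int c = live[li];
      if (!alive[c]) continue;
      acc[c] += std::pow((double)members[c].size(), E) * hH;
      live[w_i++] = c;
    }
    live.resize(w_i);
  }
  for (size_t q = 0; q < vox.size(); ++q) {
    int v = vox[q];
    if (cluster[v] >= 0) out[v] = acc[cluster[v]] - base[v];
  }
  return out;
}

// Connected-component labels of a binary 3D image (0 = background),
// flood-fill per component.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector bin, IntegerVector dims, int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  if (bin.size() != V) stop("binary image length does not match grid dims");
  std::vector<std::array<int, 3> > nb = make_offsets(conn);
  IntegerVector out(V);
  std::vector<int> stack;
  int next = 0;
  for (int v = 0; v < V; ++v) {
    if (bin[v] && out[v] == 0) {
      ++next;
      out[v] = next;
      stack.clear();
      stack.push_back(v);
      while (!stack.empty()) {
        int u = stack.back();
        stack.pop_back();
        int k = u / (nx * ny), rem = u % (nx * ny), j = rem / nx, i = rem % nx;
        for (size_t q = 0; q < nb.size(); ++q) {
          int ii = i + nb[q][0], jj = j + nb[q][1], kk = k + nb[q][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          int w = ii + nx * (jj + ny * kk);
          if (bin[w] && out[w] == 0) {
            out[w] = next;
            stack.push_back(w);
          }
        }
      }
    }
  }
  return out;
}
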