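#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Curve thinning of a binary volume to a one-voxel-wide skeleton.
//
// A foreground voxel is "simple" (deletable without changing topology, in the
// standard 26/6 foreground/background connectivity pairing) iff
//   (a) the foreground of its 26-neighbourhood forms exactly one 26-connected
//       component, and
//   (b) the background restricted to its 18-neighbourhood forms exactly one
//       6-connected component that is 6-adjacent to the voxel.
// Border voxels in six face directions are deleted sequentially (simplicity
// re-checked at deletion time, which guarantees homotopy preservation) while
// curve endpoints (<= 1 foreground neighbour) are retained.

namespace {

inline int lidx(int x, int y, int z) { return (x + 1) + 3 * ((y + 1) + 3 * (z + 1)); }

// number of 26-connected foreground components among the 26 neighbours
int fg_components_26(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++comps;
    int top = 0;
    stack[top++] = i;
    seen[i] = true;
    while (top > 0) {
      const int c = stack[--top];
      const int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            const int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < -1 || x > 1 || y < -1 || y > 1 || z < -1 || z > 1) continue;
            const int j = lidx(x, y, z);
            if (j == 13 || j == c || seen[j] || !nb[j]) continue;
            seen[j] = true;
            stack[top++] = j;
          }
    }
  }
  return comps;
}

// number of 6-connected background components within the 18-neighbourhood
// that touch the centre by a face
int bg_components_6(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  static const int face[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  for (int fi = 0; fi < 6; ++fi) {
    const int start = lidx(face[fi][0], face[fi][1], face[fi][2]);
    if (nb[start] || seen[start]) continue;
    ++comps;
    int top = 0;
    stack[top++] = start;
    seen[start] = true;
    while (top > 0) {
      const int c = stack[--top];
      const int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int fj = 0; fj < 6; ++fj) {
        const int x = cx + face[fj][0], y = cy + face[fj][1], z = cz + face[fj][2];
        if (x < -1 || x > 1 || y < -1 || y > 1 || z < -1 || z > 1) continue;
        if (std::abs(x) + std::abs(y) + std::abs(z) > 2) continue; // 18-neighbourhood only
        const int j = lidx(x, y, z);
        if (j == 13 || seen[j] || nb[j]) continue;
        seen[j] = true;
        stack[top++] = j;
      }
    }
  }
  return comps;
}

struct Vol {
  std::vector<char> v;
  int nx, ny, nz;
  inline bool at(int x, int y, int z) const {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return false;
    return v[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] != 0;
  }
  void fill_nb(int x, int y, int z, bool nb[27]) const {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[lidx(dx, dy, dz)] = at(x + dx, y + dy, z + dz);
  }
};

inline int n26_count(const bool nb[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++c;
  return c;
}

inline bool is_simple(const bool nb[27]) {
  return fg_components_26(nb) == 1 && bg_components_6(nb) == 1;
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_skeletonize_3d(LogicalVector mask, IntegerVector dim) {
  Vol vol;
  vol.nx = dim[0]; vol.ny = dim[1]; vol.nz = dim[2];
  const R_xlen_t n = (R_xlen_t)vol.nx * vol.ny * vol.nz;
  vol.v.assign(n, 0);
  std::vector<R_xlen_t> fg;
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) { vol.v[i] = 1; fg.push_back(i); }

  static const int face[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool nb[27];
  // candidates are deleted subfield by subfield (8 parity classes of
  // (x%2, y%2, z%2)): purely sequential deletion would otherwise "unzip"
  // two-voxel-wide columns along the scan order, erasing whole branches
  // before the endpoint guard can engage
  std::vector<R_xlen_t> cand[8];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      for (int s = 0; s < 8; ++s) cand[s].clear();
      for (size_t i = 0; i < fg.size(); ++i) {
        const R_xlen_t idx = fg[i];
        if (!vol.v[idx]) continue;
        const int x = (int)(idx % vol.nx);
        const int y = (int)((idx / vol.nx) % vol.ny);
        const int z = (int)(idx / ((R_xlen_t)vol.nx * vol.ny));
        if (vol.at(x + face[d][0], y + face[d][1], z + face[d][2])) continue; // not a d-border voxel
        vol.fill_nb(x, y, z, nb);
        if (n26_count(nb) <= 1) continue; // endpoint or isolated
        if (is_simple(nb)) cand[(x % 2) + 2 * (y % 2) + 4 * (z % 2)].push_back(idx);
      }
      for (int s = 0; s < 8; ++s) {
        // sequential deletion with re-check at deletion time
        for (size_t i = 0; i < cand[s].size(); ++i) {
          const R_xlen_t idx = cand[s][i];
          const int x = (int)(idx % vol.nx);
          const int y = (int)((idx / vol.nx) % vol.ny);
          const int z = (int)(idx / ((R_xlen_t)vol.nx * vol.ny));
          if (vol.at(x + face[d][0], y + face[d][1], z + face[d][2])) continue;
          vol.fill_nb(x, y, z, nb);
          if (n26_count(nb) <= 1) continue;
          if (!is_simple(nb)) continue;
          vol.v[idx] = 0;
          changed = true;
        }
      }
    }
    // compact the active list
    size_t keep = 0;
    for (size_t i = 0; i < fg.size(); ++i)
      if (vol.v[fg[i]]) fg[keep++] = fg[i];
    fg.resize(keep);
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = vol.v[i] != 0;
  return out;
}
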