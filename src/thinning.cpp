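#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Topology-preserving sequential 3D thinning.
//
// A border voxel is deletable when it is "simple" in the sense of
// Malandain & Bertrand: exactly one 26-connected component of object voxels
// in its 26-neighborhood, and exactly one 6-connected component of
// background voxels in its 18-neighborhood touching a face neighbor.
// Curve endpoints (exactly one object neighbor) are never deleted.
// Deletion proceeds in six directional subcycles (U/D/N/S/E/W) with
// sequential re-checking, which keeps the result a centered unit-width curve
// for tubular objects.

static const int OFF26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}};

static const int FACE6[6][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};

struct Grid {
  const std::vector<unsigned char>& m;
  int nx, ny, nz;
  inline bool at(int x, int y, int z) const {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
    return m[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] != 0;
  }
};

static int object_neighbors(const Grid& g, int x, int y, int z) {
  int c = 0;
  for (int k = 0; k < 26; ++k)
    if (g.at(x + OFF26[k][0], y + OFF26[k][1], z + OFF26[k][2])) ++c;
  return c;
}

// count 26-connected components of object voxels within the 26-neighborhood
static int count_cstar(const Grid& g, int x, int y, int z) {
  bool obj[3][3][3];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        obj[dx + 1][dy + 1][dz + 1] =
          !(dx == 0 && dy == 0 && dz == 0) && g.at(x + dx, y + dy, z + dz);
  bool seen[3][3][3] = {{{false}}};
  int ncomp = 0;
  int stack[27][3];
  for (int sz = 0; sz < 3; ++sz)
    for (int sy = 0; sy < 3; ++sy)
      for (int sx = 0; sx < 3; ++sx) {
        if (!obj[sx][sy][sz] || seen[sx][sy][sz]) continue;
        ++ncomp;
        int top = 0;
        stack[top][0] = sx; stack[top][1] = sy; stack[top][2] = sz;
        seen[sx][sy][sz] = true;
        ++top;
        while (top > 0) {
          --top;
          int cx = stack[top][0], cy = stack[top][1], cz = stack[top][2];
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int px = cx + dx, py = cy + dy, pz = cz + dz;
                if (px < 0 || py < 0 || pz < 0 || px > 2 || py > 2 || pz > 2) continue;
                if (obj[px][py][pz] && !seen[px][py][pz]) {
                  seen[px][py][pz] = true;
                  stack[top][0] = px; stack[top][1] = py; stack[top][2] = pz;
                  ++top;
                }
              }
        }
      }
  return ncomp;
}

// count 6-connected components of background in the 18-neighborhood that
// contain a face neighbor of the center
static int count_cbar(const Grid& g, int x, int y, int z) {
  // 18-neighborhood: |dx|+|dy|+|dz| <= 2, excluding center and corners
  bool in18[3][3][3], bg[3][3][3], seen[3][3][3];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        in18[dx + 1][dy + 1][dz + 1] = (s >= 1 && s <= 2);
        bg[dx + 1][dy + 1][dz + 1] = !g.at(x + dx, y + dy, z + dz);
        seen[dx + 1][dy + 1][dz + 1] = false;
      }
  int ncomp = 0;
  int stack[18][3];
  // seed only from face neighbors
  for (int f = 0; f < 6; ++f) {
    int sx = FACE6[f][0] + 1, sy = FACE6[f][1] + 1, sz = FACE6[f][2] + 1;
    if (!in18[sx][sy][sz] || !bg[sx][sy][sz] || seen[sx][sy][sz]) continue;
    ++ncomp;
    int top = 0;
    stack[top][0] = sx; stack[top][1] = sy; stack[top][2] = sz;
    seen[sx][sy][sz] = true;
    ++top;
    while (top > 0) {
      --top;
      int cx = stack[top][0], cy = stack[top][1], cz = stack[top][2];
      static const int F[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int px = cx + F[k][0], py = cy + F[k][1], pz = cz + F[k][2];
        if (px < 0 || py < 0 || pz < 0 || px > 2 || py > 2 || pz > 2) continue;
        if (in18[px][py][pz] && bg[px][py][pz] && !seen[px][py][pz]) {
          seen[px][py][pz] = true;
          stack[top][0] = px; stack[top][1] = py; stack[top][2] = pz;
          ++top;
        }
      }
    }
  }
  return ncomp;
}

static bool is_simple(const Grid& g, int x, int y, int z) {
  return count_cstar(g, x, y, z) == 1 && count_cbar(g, x, y, z) == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<unsigned char> m(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) m[i] = mask[i] ? 1 : 0;
  Grid g{m, nx, ny, nz};

  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      int fx = FACE6[dir][0], fy = FACE6[dir][1], fz = FACE6[dir][2];
      std::vector<size_t> cand;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            size_t id = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
            if (!m[id]) continue;
            if (g.at(x + fx, y + fy, z + fz)) continue; // not a border pt this dir
            cand.push_back(id);
          }
      // sequential deletion with re-check
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        size_t id = cand[ci];
        if (!m[id]) continue;
        int x = (int)(id % nx);
        int y = (int)((id / nx) % ny);
        int z = (int)(id / ((size_t)nx * ny));
        int nb = object_neighbors(g, x, y, z);
        if (nb <= 1) continue;          // endpoint or isolated voxel
        if (!is_simple(g, x, y, z)) continue;
        m[id] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}
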