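#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdlib>
using namespace Rcpp;

// Neighbor offsets for 6/18/26-connectivity on a 3D grid.
static std::vector<std::array<int, 3>> make_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Flood-fill labeling over a binary volume; labels written into `lab`
// (0 = background). Returns cluster sizes indexed by label - 1.
static std::vector<int> label_core(const std::vector<char> &bin,
                                   std::vector<int> &lab,
                                   int nx, int ny, int nz,
                                   const std::vector<std::array<int, 3>> &off,
                                   std::vector<int> &stack) {
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> sizes;
  int next = 0;
  const int n = nx * ny * nz;
  for (int v = 0; v < n; ++v) {
    if (!bin[v] || lab[v]) continue;
    ++next;
    int size = 0;
    stack.clear();
    stack.push_back(v);
    lab[v] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (const auto &d : off) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (bin[w] && !lab[w]) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
    sizes.push_back(size);
  }
  return sizes;
}

// [[Rcpp::export]]
List label_components_cpp(LogicalVector vol, IntegerVector dims,
                          int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if (vol.size() != n) stop("volume length does not match dims");
  std::vector<char> bin(n);
  for (int i = 0; i < n; ++i) bin[i] = vol[i] == TRUE;
  std::vector<int> lab(n), stack;
  auto off = make_offsets(connectivity);
  std::vector<int> sizes = label_core(bin, lab, nx, ny, nz, off, stack);
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) labels[i] = lab[i];
  return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes));
}

// Max cluster size of (t > thresh) for each row of a matrix of statistic
// maps; used for the permutation null of the max cluster size.
// [[Rcpp::export]]
IntegerVector max_cluster_sizes_cpp(NumericMatrix t_mat, double thresh,
                                    IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if (t_mat.ncol() != n) stop("map length does not match dims");
  auto off = make_offsets(connectivity);
  std::vector<char> bin(n);
  std::vector<int> lab(n), stack;
  IntegerVector out(t_mat.nrow());
  for (int r = 0; r < t_mat.nrow(); ++r) {
    for (int i = 0; i < n; ++i) bin[i] = t_mat(r, i) > thresh;
    std::vector<int> sizes = label_core(bin, lab, nx, ny, nz, off, stack);
    int mx = 0;
    for (int s : sizes) if (s > mx) mx = s;
    out[r] = mx;
  }
  return out;
}
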