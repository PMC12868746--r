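#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// Vietoris-Rips persistent homology over Z/2 by boundary-matrix reduction.
//
// Simplices up to dimension maxdim + 1 with diameter <= threshold are
// enumerated, sorted by (diameter, dimension, vertex order), and the
// boundary matrix is reduced left to right with the standard pivot rule.
// A pair (i, j) with diam(j) > diam(i) yields a finite feature of the
// dimension of simplex i; positive simplices of dimension <= maxdim that
// are never killed yield essential features (death = +Inf).
//
// Vertices are limited to 250 so a simplex fits in a 64-bit key
// (callers subsample point clouds well below that).

namespace {

struct Simplex {
  std::array<uint8_t, 4> v;  // vertices, ascending; unused slots = 255
  uint8_t dim;
  double diam;
};

inline uint64_t simplex_key(const std::array<uint8_t, 4>& v, int dim) {
  uint64_t key = 0;
  for (int i = 0; i <= dim; ++i) key = (key << 8) | uint64_t(v[i]);
  return (key << 3) | uint64_t(dim + 1);
}

// symmetric difference of two ascending row-index vectors (Z/2 column add)
void xor_cols(std::vector<int>& a, const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) out.push_back(a[i++]);
    else if (b[j] < a[i]) out.push_back(b[j++]);
    else { ++i; ++j; }
  }
  while (i < a.size()) out.push_back(a[i++]);
  while (j < b.size()) out.push_back(b[j++]);
  a.swap(out);
}

}  // namespace

// [[Rcpp::export(name = ".rips_cpp")]]
NumericMatrix rips_cpp(NumericMatrix dist, int maxdim, double threshold) {
  const int n = dist.nrow();
  if (n < 1) stop("empty point cloud");
  if (n > 250) stop("too many points for the reduction backend (max 250)");
  if (maxdim < 0 || maxdim > 2) stop("maxdim must be 0, 1 or 2");

  std::vector<std::vector<bool>> adj(n, std::vector<bool>(n, false));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (dist(i, j) <= threshold) { adj[i][j] = true; adj[j][i] = true; }

  std::vector<Simplex> simplices;
  simplices.reserve(size_t(n) * 8);
  for (int i = 0; i < n; ++i)
    simplices.push_back({{uint8_t(i), 255, 255, 255}, 0, 0.0});

  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj[i][j])
        simplices.push_back({{uint8_t(i), uint8_t(j), 255, 255}, 1, dist(i, j)});

  if (maxdim >= 1) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (!adj[i][j]) continue;
        for (int k = j + 1; k < n; ++k) {
          if (adj[i][k] && adj[j][k]) {
            double d = std::max({dist(i, j), dist(i, k), dist(j, k)});
            simplices.push_back({{uint8_t(i), uint8_t(j), uint8_t(k), 255}, 2, d});
          }
        }
      }
  }
  if (maxdim >= 2) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (!adj[i][j]) continue;
        for (int k = j + 1; k < n; ++k) {
          if (!(adj[i][k] && adj[j][k])) continue;
          for (int l = k + 1; l < n; ++l) {
            if (adj[i][l] && adj[j][l] && adj[k][l]) {
              double d = std::max({dist(i, j), dist(i, k), dist(i, l),
                                   dist(j, k), dist(j, l), dist(k, l)});
              simplices.push_back(
                  {{uint8_t(i), uint8_t(j), uint8_t(k), uint8_t(l)}, 3, d});
            }
          }
        }
      }
  }

  const size_t m = simplices.size();
  std::vector<int> order(m);
  for (size_t i = 0; i < m; ++i) order[i] = int(i);
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (simplices[a].diam != simplices[b].diam)
      return simplices[a].diam < simplices[b].diam;
    if (simplices[a].dim != simplices[b].dim)
      return simplices[a].dim < simplices[b].dim;
    return simplices[a].v < simplices[b].v;
  });

  std::unordered_map<uint64_t, int> pos;  // simplex key -> filtration position
  pos.reserve(m * 2);
  for (size_t p = 0; p < m; ++p) {
    const Simplex& s = simplices[order[p]];
    pos[simplex_key(s.v, s.dim)] = int(p);
  }

  std::vector<int> pivot_col(m, -1);          // row -> reduced column index
  std::vector<std::vector<int>> stored(m);    // reduced columns by column index
  std::vector<char> positive(m, 0);
  std::vector<char> paired(m, 0);

  std::vector<std::array<double, 3>> feats;   // birth, death, dim

  for (size_t p = 0; p < m; ++p) {
    const Simplex& s = simplices[order[p]];
    if (s.dim == 0) { positive[p] = 1; continue; }
    std::vector<int> col;
    col.reserve(s.dim + 1);
    for (int drop = 0; drop <= s.dim; ++drop) {
      std::array<uint8_t, 4> face = {255, 255, 255, 255};
      int w = 0;
      for (int q = 0; q <= s.dim; ++q)
        if (q != drop) face[w++] = s.v[q];
      col.push_back(pos.at(simplex_key(face, s.dim - 1)));
    }
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      int piv = col.back();
      int other = pivot_col[piv];
      if (other < 0) break;
      xor_cols(col, stored[other]);
    }
    if (col.empty()) {
      positive[p] = 1;
    } else {
      int piv = col.back();
      pivot_col[piv] = int(p);
      stored[p] = std::move(col);
      paired[piv] = 1;
      const Simplex& b = simplices[order[piv]];
      if (s.diam > b.diam)
        feats.push_back({b.diam, s.diam, double(b.dim)});
    }
  }

  for (size_t p = 0; p < m; ++p) {
    if (!positive[p] || paired[p]) continue;
    const Simplex& s = simplices[order[p]];
    if (s.dim <= maxdim)
      feats.push_back({s.diam, R_PosInf, double(s.dim)});
  }

  NumericMatrix out(int(feats.size()), 3);
  for (size_t i = 0; i < feats.size(); ++i) {
    out(int(i), 0) = feats[i][0];
    out(int(i), 1) = feats[i][1];
    out(int(i), 2) = feats[i][2];
  }
  colnames(out) = CharacterVector::create("birth", "death", "dim");
  return out;
}
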