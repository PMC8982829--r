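#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Superlevel-set merge-tree computation of the degree-2 (cavity) persistence
// pairs of the sublevel filtration of a 3D image.
//
// Voxels are processed in decreasing value. Bright voxels are connected with
// 26-adjacency; a virtual "outside" node, joined by every voxel on the image
// boundary, represents the unbounded complement so that only structures fully
// enclosed by in-image voxels count as cavities. When two components merge at
// level s the one with the lower peak p dies and yields the pair
// (birth = s, death = p); the outside node has peak +Inf and never dies.
// Zero-persistence pairs (death == birth) are dropped.

namespace {

struct UF {
  std::vector<int> parent;
  std::vector<int> rank_;
  explicit UF(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
};

// lexicographic (i, j, k) comparison of linear voxel indices
inline bool lex_less(int v, int w, int d1, int d2) {
  const int vi = v % d1, vj = (v / d1) % d2, vk = v / (d1 * d2);
  const int wi = w % d1, wj = (w / d1) % d2, wk = w / (d1 * d2);
  if (vi != wi) return vi < wi;
  if (vj != wj) return vj < wj;
  return vk < wk;
}

} // namespace

// [[Rcpp::export(name = ".cpp_sublevel_2cycles")]]
DataFrame cpp_sublevel_2cycles(NumericVector vol, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int n = d1 * d2 * d3;
  if (n != vol.size()) stop("volume length does not match dims");

  // order voxels by decreasing value; ties by increasing linear index
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (vol[a] != vol[b]) return vol[a] > vol[b];
    return a < b;
  });

  // node n is the virtual outside component (peak +Inf)
  UF uf(n + 1);
  std::vector<double> peak(n + 1, 0.0);
  std::vector<int> peakvox(n + 1, -1);
  std::vector<char> present(n + 1, 0);
  peak[n] = R_PosInf;
  present[n] = 1;

  std::vector<double> births, deaths;
  std::vector<int> dievox;

  // elder-rule union at merge level s; returns surviving root
  auto unite = [&](int ra, int rb, double s) {
    if (ra == rb) return ra;
    int surv = ra, die = rb;
    if (peak[rb] > peak[ra] ||
        (peak[rb] == peak[ra] && peakvox[rb] != -1 && peakvox[ra] != -1 &&
         lex_less(peakvox[rb], peakvox[ra], d1, d2))) {
      surv = rb;
      die = ra;
    }
    if (peak[die] > s) { // zero-persistence merges are not recorded
      births.push_back(s);
      deaths.push_back(peak[die]);
      dievox.push_back(peakvox[die]);
    }
    // union by rank, then fix the stored summary on the new root
    double sp = peak[surv];
    int sv = peakvox[surv];
    int r1 = uf.find(surv), r2 = uf.find(die);
    int root;
    if (uf.rank_[r1] < uf.rank_[r2]) {
      uf.parent[r1] = r2;
      root = r2;
    } else if (uf.rank_[r1] > uf.rank_[r2]) {
      uf.parent[r2] = r1;
      root = r1;
    } else {
      uf.parent[r2] = r1;
      uf.rank_[r1]++;
      root = r1;
    }
    peak[root] = sp;
    peakvox[root] = sv;
    return root;
  };

  for (int k = 0; k < n; ++k) {
    const int v = ord[k];
    const double t = vol[v];
    const int i = v % d1;
    const int j = (v / d1) % d2;
    const int l = v / (d1 * d2);
    present[v] = 1;
    peak[v] = t;
    peakvox[v] = v;

    int root = v;
    if (i == 0 || i == d1 - 1 || j == 0 || j == d2 - 1 || l == 0 || l == d3 - 1)
      root = unite(uf.find(v), uf.find(n), t);

    for (int di = -1; di <= 1; ++di) {
      const int ii = i + di;
      if (ii < 0 || ii >= d1) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= d2) continue;
        for (int dl = -1; dl <= 1; ++dl) {
          if (di == 0 && dj == 0 && dl == 0) continue;
          const int ll = l + dl;
          if (ll < 0 || ll >= d3) continue;
          const int w = ii + d1 * (jj + d2 * ll);
          if (!present[w]) continue;
          root = unite(uf.find(root), uf.find(w), t);
        }
      }
    }
  }

  const int m = (int)births.size();
  NumericVector b(m), d(m);
  IntegerVector pi(m), pj(m), pk(m);
  for (int q = 0; q < m; ++q) {
    b[q] = births[q];
    d[q] = deaths[q];
    const int v = dievox[q];
    pi[q] = v % d1 + 1; // 1-based, R convention
    pj[q] = (v / d1) % d2 + 1;
    pk[q] = v / (d1 * d2) + 1;
  }
  return DataFrame::create(_["birth"] = b, _["death"] = d, _["peak_i"] = pi,
                           _["peak_j"] = pj, _["peak_k"] = pk,
                           _["stringsAsFactors"] = false);
}
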