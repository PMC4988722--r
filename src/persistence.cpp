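#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// First persistent homology of the Vietoris-Rips filtration of an integer
// distance matrix, over GF(2). The filtration is built to max_scale
// (default: the matrix diameter, at which the complex is a full clique and
// H1 vanishes, so all bars are finite). Simplices are ordered by
// (filtration value, dimension, lexicographic vertex tuple).
//
// Standard column reduction restricted to the triangle/edge boundary: a
// triangle column that reduces to a non-zero chain pairs with its lowest
// edge; the reduced chain itself is a representative cycle alive at the
// bar's birth scale.

struct Edge {
  int value;
  int a, b; // a < b, 0-based
};

struct Tri {
  int value;
  int a, b, c; // a < b < c
};

static void sym_diff(std::vector<int> &x, const std::vector<int> &y) {
  std::vector<int> out;
  out.reserve(x.size() + y.size());
  std::set_symmetric_difference(x.begin(), x.end(), y.begin(), y.end(),
                                std::back_inserter(out));
  x.swap(out);
}

// [[Rcpp::export]]
List cpp_h1_persistence(IntegerMatrix D, int max_scale) {
  const int p = D.nrow();
  if (D.ncol() != p) stop("distance matrix must be square");
  int diam = 0;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      if (D(i, j) != D(j, i) || D(i, j) < 0)
        stop("distance matrix must be symmetric and nonnegative");
      if (D(i, j) > diam) diam = D(i, j);
    }
  if (max_scale < 0) max_scale = diam;

  std::vector<Edge> edges;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j)
      if (D(i, j) <= max_scale) edges.push_back({D(i, j), i, j});
  std::sort(edges.begin(), edges.end(), [](const Edge &x, const Edge &y) {
    if (x.value != y.value) return x.value < y.value;
    if (x.a != y.a) return x.a < y.a;
    return x.b < y.b;
  });
  const int ne = (int)edges.size();
  // rank lookup for an edge (a,b)
  std::vector<std::vector<int>> erank(p, std::vector<int>(p, -1));
  for (int e = 0; e < ne; ++e) erank[edges[e].a][edges[e].b] = e;

  std::vector<Tri> tris;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      if (D(i, j) > max_scale) continue;
      for (int k = j + 1; k < p; ++k) {
        int v = std::max(D(i, j), std::max(D(i, k), D(j, k)));
        if (v <= max_scale) tris.push_back({v, i, j, k});
      }
    }
  std::sort(tris.begin(), tris.end(), [](const Tri &x, const Tri &y) {
    if (x.value != y.value) return x.value < y.value;
    if (x.a != y.a) return x.a < y.a;
    if (x.b != y.b) return x.b < y.b;
    return x.c < y.c;
  });

  std::vector<int> pivot(ne, -1);            // edge rank -> reduced column id
  std::vector<std::vector<int>> cols;        // stored reduced columns
  std::vector<int> births, deaths;
  std::vector<std::vector<int>> reps;

  for (const Tri &t : tris) {
    std::vector<int> col = {erank[t.a][t.b], erank[t.a][t.c], erank[t.b][t.c]};
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      int low = col.back();
      if (pivot[low] < 0) break;
      sym_diff(col, cols[pivot[low]]);
    }
    if (col.empty()) continue; // negative triangle pair handled earlier
    int low = col.back();
    pivot[low] = (int)cols.size();
    cols.push_back(col);
    int birth = edges[low].value;
    if (birth < t.value) {
      births.push_back(birth);
      deaths.push_back(t.value);
      reps.push_back(col);
    }
  }

  List replist(reps.size());
  for (size_t r = 0; r < reps.size(); ++r) {
    IntegerMatrix em((int)reps[r].size(), 2);
    for (size_t e = 0; e < reps[r].size(); ++e) {
      em(e, 0) = edges[reps[r][e]].a + 1; // 1-based for R
      em(e, 1) = edges[reps[r][e]].b + 1;
    }
    replist[r] = em;
  }
  return List::create(_["birth"] = wrap(births),
                      _["death"] = wrap(deaths),
                      _["representative"] = replist);
}
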