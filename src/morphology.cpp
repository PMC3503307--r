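#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path compression.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

//' Connected-component labeling of a binary raster.
//'
//' Two-pass union-find labeling. Labels are contiguous positive integers
//' assigned in column-major scan order of each component's first pixel;
//' background (FALSE) pixels get label 0.
//'
//' @param mask logical matrix
//' @param connectivity 4 or 8
//' @noRd
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 4) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0); // dummy so labels start at 1

  // first pass: column-major scan, look "up" (r-1,c) and "left" (r,c-1)
  // and, for 8-connectivity, the two diagonals in the previous column.
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      int neigh[4] = {0, 0, 0, 0};
      int nn = 0;
      if (r > 0 && mask(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (c > 0 && mask(r, c - 1)) neigh[nn++] = lab(r, c - 1);
      if (connectivity == 8 && c > 0) {
        if (r > 0 && mask(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
        if (r + 1 < nr && mask(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
      }
      for (int k = 0; k < nn; ++k)
        if (best == 0 || neigh[k] < best) best = neigh[k];
      if (best == 0) {
        int newlab = (int)parent.size();
        parent.push_back(newlab);
        lab(r, c) = newlab;
      } else {
        lab(r, c) = best;
        for (int k = 0; k < nn; ++k) uf_union(parent, best, neigh[k]);
      }
    }
  }

  // resolve roots to contiguous labels in order of first appearance
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (remap[root] == 0) remap[root] = ++next;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}

//' Binary erosion by an arbitrary structuring element.
//'
//' The SE is given as an n x 2 integer matrix of (row, col) offsets from the
//' anchor. Pixels outside the image count as FALSE, so objects shrink at the
//' image border (standard object-centric convention).
//' @noRd
// [[Rcpp::export(name = ".binary_erode")]]
LogicalMatrix binary_erode(LogicalMatrix mask, IntegerMatrix offsets) {
  const int nr = mask.nrow(), nc = mask.ncol(), no = offsets.nrow();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) { out(r, c) = false; continue; }
      bool keep = true;
      for (int k = 0; k < no; ++k) {
        int rr = r + offsets(k, 0), cc = c + offsets(k, 1);
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || !mask(rr, cc)) {
          keep = false;
          break;
        }
      }
      out(r, c) = keep;
    }
  }
  return out;
}

//' Per-label pixel count and centroid (1-based row/col means).
//' Returns a list(area, centroid_row, centroid_col) indexed by label 1..K.
//' @noRd
// [[Rcpp::export(name = ".region_stats")]]
List region_stats(IntegerMatrix lab, int n_labels) {
  std::vector<double> area(n_labels, 0.0), sr(n_labels, 0.0), sc(n_labels, 0.0);
  const int nr = lab.nrow(), nc = lab.ncol();
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l > 0) {
        area[l - 1] += 1.0;
        sr[l - 1] += r + 1;
        sc[l - 1] += c + 1;
      }
    }
  NumericVector a(n_labels), cr(n_labels), cc(n_labels);
  for (int i = 0; i < n_labels; ++i) {
    a[i] = area[i];
    cr[i] = area[i] > 0 ? sr[i] / area[i] : NA_REAL;
    cc[i] = area[i] > 0 ? sc[i] / area[i] : NA_REAL;
  }
  return List::create(_["area_px"] = a, _["centroid_row"] = cr,
                      _["centroid_col"] = cc);
}

//' Row raster-scan intercept lengths: maximal runs of positive pixels
//' bounded on BOTH sides by a non-positive pixel in the same row (runs
//' touching the image border are discarded).
//' @noRd
// [[Rcpp::export(name = ".row_intercepts")]]
IntegerVector row_intercepts(IntegerMatrix lab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  std::vector<int> lens;
  for (int r = 0; r < nr; ++r) {
    int run = 0;
    bool bounded_left = false;
    for (int c = 0; c < nc; ++c) {
      if (lab(r, c) > 0) {
        ++run;
      } else {
        if (run > 0 && bounded_left) lens.push_back(run);
        run = 0;
        bounded_left = true;
      }
    }
    // run reaching the right border is unbounded: dropped
  }
  return wrap(lens);
}
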