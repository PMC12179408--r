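#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling by iterative flood fill.
// 2D: 8-connectivity (ImageJ "Analyze Particles" convention).
// 3D: 26-connectivity (ImageJ "3D Objects Counter" convention).
// Labels are assigned in raster-scan order of first encounter, so they are
// deterministic and consecutive 1..n.

// [[Rcpp::export(name = ".cc_label_2d")]]
IntegerMatrix cc_label_2d(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              stack.push_back(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(const LogicalVector& mask, int nr, int nc, int nz,
                          int connectivity) {
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  IntegerVector lab(mask.size());
  std::vector<int> stack;
  int next = 0;
  const int slice = nr * nc;
  for (int z = 0; z < nz; ++z) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        int idx0 = i + j * nr + z * slice;
        if (!mask[idx0] || lab[idx0]) continue;
        ++next;
        stack.push_back(idx0);
        lab[idx0] = next;
        while (!stack.empty()) {
          int idx = stack.back(); stack.pop_back();
          int cz = idx / slice, rem = idx % slice;
          int cj = rem / nr, ci = rem % nr;
          for (int dz = -1; dz <= 1; ++dz) {
            for (int dj = -1; dj <= 1; ++dj) {
              for (int di = -1; di <= 1; ++di) {
                if (!di && !dj && !dz) continue;
                if (connectivity == 6 &&
                    std::abs(di) + std::abs(dj) + std::abs(dz) != 1) continue;
                int ni = ci + di, nj = cj + dj, nz2 = cz + dz;
                if (ni < 0 || ni >= nr || nj < 0 || nj >= nc ||
                    nz2 < 0 || nz2 >= nz) continue;
                int nidx = ni + nj * nr + nz2 * slice;
                if (mask[nidx] && !lab[nidx]) {
                  lab[nidx] = next;
                  stack.push_back(nidx);
                }
              }
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(nr, nc, nz);
  lab.attr("n") = next;
  return lab;
}
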