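#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Neighbour offset tables for 6- and 26-connectivity.
static int n6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};

static void neighbours26(std::vector<std::array<int,3> >& off) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        if (dx || dy || dz) off.push_back({dx, dy, dz});
}

// Connected-component labels of a binary mask (0 = background).
// connectivity must be 6 or 26.
// [[Rcpp::export(name = ".cppLabelComponents")]]
IntegerVector cppLabelComponents(LogicalVector mask, IntegerVector dim,
                                 int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<std::array<int,3> > off;
  if (connectivity == 6) {
    for (int i = 0; i < 6; ++i) off.push_back({n6[i][0], n6[i][1], n6[i][2]});
  } else if (connectivity == 26) {
    neighbours26(off);
  } else {
    stop("connectivity must be 6 or 26");
  }
  IntegerVector lab(n);
  const int* m = LOGICAL(mask);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / ((size_t)nx * ny);
      for (size_t t = 0; t < off.size(); ++t) {
        int i = ci + off[t][0], j = cj + off[t][1], k = ck + off[t][2];
        if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
        size_t q = i + (size_t)nx * (j + (size_t)ny * k);
        if (m[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Fill enclosed cavities: any background voxel not 6-connected to the volume
// border becomes foreground. Foreground is never removed.
// [[Rcpp::export(name = ".cppFillHoles")]]
LogicalVector cppFillHoles(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const int* m = LOGICAL(mask);
  std::vector<char> outside(n, 0);
  std::vector<size_t> stack;
  // seed with all background border voxels
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        size_t q = i + (size_t)nx * (j + (size_t)ny * k);
        if (!m[q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
      }
  while (!stack.empty()) {
    size_t cur = stack.back(); stack.pop_back();
    int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / ((size_t)nx * ny);
    for (int t = 0; t < 6; ++t) {
      int i = ci + n6[t][0], j = cj + n6[t][1], k = ck + n6[t][2];
      if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
      size_t q = i + (size_t)nx * (j + (size_t)ny * k);
      if (!m[q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
    }
  }
  LogicalVector out(n);
  for (size_t q = 0; q < n; ++q) out[q] = m[q] || !outside[q];
  out.attr("dim") = dim;
  return out;
}

// Binary dilation / erosion with an arbitrary structuring element given as a
// matrix of integer voxel offsets (rows = (di, dj, dk)). Voxels outside the
// grid count as background.
// [[Rcpp::export(name = ".cppDilate")]]
LogicalVector cppDilate(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const int* m = LOGICAL(mask);
  LogicalVector out(n);
  int no = offsets.nrow();
  size_t q = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++q) {
        bool hit = false;
        for (int t = 0; t < no && !hit; ++t) {
          int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          if (m[ii + (size_t)nx * (jj + (size_t)ny * kk)]) hit = true;
        }
        out[q] = hit;
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export(name = ".cppErode")]]
LogicalVector cppErode(LogicalVector mask, IntegerVector dim,
                       IntegerMatrix offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const int* m = LOGICAL(mask);
  LogicalVector out(n);
  int no = offsets.nrow();
  size_t q = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++q) {
        bool all = true;
        for (int t = 0; t < no && all; ++t) {
          int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) {
            all = false;
          } else if (!m[ii + (size_t)nx * (jj + (size_t)ny * kk)]) {
            all = false;
          }
        }
        out[q] = all;
      }
  out.attr("dim") = dim;
  return out;
}
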