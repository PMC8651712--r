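// Core raster-hydrology kernels: priority-flood depression filling,
// D8 steepest-descent routing, flow accumulation, basin labelling.
// Neighbor scan order is fixed (E, SE, S, SW, W, NW, N, NE) so runs are
// bit-reproducible; direction codes 1..8 follow that order, 0 marks an
// outlet (flow leaves the grid), NA marks nodata/undrained cells.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int DR[8] = { 0, 1, 1, 1, 0, -1, -1, -1 };
static const int DC[8] = { 1, 1, 0, -1, -1, -1, 0, 1 };

struct Cell {
  double z;
  long long seq;
  int r, c;
};

struct CellCmp {
  // min-heap on elevation, FIFO among equal elevations (flats are
  // conquered breadth-first from their spill point)
  bool operator()(const Cell& a, const Cell& b) const {
    if (a.z != b.z) return a.z > b.z;
    return a.seq > b.seq;
  }
};

// Priority-flood fill seeded from all non-nodata boundary cells.
// Returns the filled surface, a flood-parent direction per cell
// (0 = boundary seed) and the drained mask. Cells enclosed by nodata are
// never reached and keep their input elevation with drained = FALSE.
// [[Rcpp::export(name = ".fillDepressionsC")]]
List fillDepressionsC(NumericMatrix dem) {
  const int nr = dem.nrow(), nc = dem.ncol();
  NumericMatrix filled(nr, nc);
  IntegerMatrix parent(nr, nc);
  LogicalMatrix drained(nr, nc);
  std::priority_queue<Cell, std::vector<Cell>, CellCmp> pq;
  long long seq = 0;

  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      filled(r, c) = dem(r, c);
      parent(r, c) = NA_INTEGER;
      drained(r, c) = false;
    }

  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      bool edge = (r == 0 || r == nr - 1 || c == 0 || c == nc - 1);
      if (edge && !NumericMatrix::is_na(dem(r, c))) {
        drained(r, c) = true;
        parent(r, c) = 0;
        pq.push(Cell{ dem(r, c), seq++, r, c });
      }
    }
  if (pq.empty()) stop("no non-nodata cell on the grid boundary");

  while (!pq.empty()) {
    Cell cur = pq.top();
    pq.pop();
    for (int k = 0; k < 8; ++k) {
      int rr = cur.r + DR[k], cc = cur.c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (drained(rr, cc) || NumericMatrix::is_na(dem(rr, cc))) continue;
      double z = dem(rr, cc);
      double spill = filled(cur.r, cur.c);
      filled(rr, cc) = (z > spill) ? z : spill;
      // direction from (rr,cc) back to cur: the opposite offset
      int opp = (k + 4) % 8;
      parent(rr, cc) = opp + 1;
      drained(rr, cc) = true;
      pq.push(Cell{ filled(rr, cc), seq++, rr, cc });
    }
  }
  return List::create(_["filled"] = filled, _["parent"] = parent,
                      _["drained"] = drained);
}

// D8 directions on a filled surface. Steepest strict descent wins (drop
// over center-to-center distance, diagonals cellSize*sqrt(2)); equal
// slopes break to the earliest neighbor in scan order. Flat cells fall
// back to their flood-parent direction; boundary cells with no lower
// drained neighbor are outlets (code 0).
// [[Rcpp::export(name = ".d8DirectionsC")]]
IntegerMatrix d8DirectionsC(NumericMatrix filled, IntegerMatrix parent,
                            LogicalMatrix drained, double cellSize) {
  const int nr = filled.nrow(), nc = filled.ncol();
  const double diag = cellSize * std::sqrt(2.0);
  IntegerMatrix dir(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      dir(r, c) = NA_INTEGER;
      if (!drained(r, c)) continue;
      double best = 0.0;
      int bestK = -1;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (!drained(rr, cc)) continue;
        double drop = filled(r, c) - filled(rr, cc);
        if (drop <= 0) continue;
        double s = drop / ((k % 2 == 1) ? diag : cellSize);
        if (s > best) { best = s; bestK = k; }
      }
      if (bestK >= 0) {
        dir(r, c) = bestK + 1;
      } else {
        int p = parent(r, c);
        if (p == NA_INTEGER)
          stop("internal: drained cell without flood parent");
        if (p == 0) {
          bool edge = (r == 0 || r == nr - 1 || c == 0 || c == nc - 1);
          if (!edge) stop("internal: unfilled pit encountered off-boundary");
          dir(r, c) = 0;
        } else {
          dir(r, c) = p;
        }
      }
    }
  return dir;
}

// Flow accumulation (cells draining through each cell, inclusive) by
// topological propagation; stops with an error if the direction field
// contains a cycle.
// [[Rcpp::export(name = ".flowAccumulationC")]]
IntegerMatrix flowAccumulationC(IntegerMatrix dir) {
  const int nr = dir.nrow(), nc = dir.ncol();
  const int n = nr * nc;
  std::vector<int> ds(n, -2);  // -2 nodata, -1 outlet, else downstream index
  std::vector<int> indeg(n, 0);
  IntegerMatrix acc(nr, nc);
  int nDrained = 0;

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      acc(r, c) = NA_INTEGER;
      int d = dir(r, c);
      if (d == NA_INTEGER) continue;
      ++nDrained;
      if (d == 0) { ds[i] = -1; continue; }
      int rr = r + DR[d - 1], cc = c + DC[d - 1];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc)
        stop("direction points off-grid; use code 0 for outlets");
      ds[i] = rr + cc * nr;
    }
  for (int i = 0; i < n; ++i)
    if (ds[i] >= 0) ++indeg[ds[i]];

  std::queue<int> q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      if (ds[i] != -2) {
        acc(r, c) = 1;
        if (indeg[i] == 0) q.push(i);
      }
    }
  int processed = 0;
  while (!q.empty()) {
    int i = q.front();
    q.pop();
    ++processed;
    int j = ds[i];
    if (j >= 0) {
      acc[j] += acc[i];
      if (--indeg[j] == 0) q.push(j);
    }
  }
  if (processed != nDrained) stop("cycle detected in flow directions");
  return acc;
}

// Basin labels: each drained cell gets the 1-based linear index (column-
// major, matching R) of the outlet cell its flow path terminates at.
// [[Rcpp::export(name = ".basinsC")]]
IntegerMatrix basinsC(IntegerMatrix dir) {
  const int nr = dir.nrow(), nc = dir.ncol();
  const int n = nr * nc;
  std::vector<int> ds(n, -2);
  IntegerMatrix basin(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      basin(r, c) = NA_INTEGER;
      int d = dir(r, c);
      if (d == NA_INTEGER) continue;
      if (d == 0) { ds[i] = -1; continue; }
      ds[i] = (r + DR[d - 1]) + (c + DC[d - 1]) * nr;
    }
  std::vector<int> stack;
  for (int i0 = 0; i0 < n; ++i0) {
    if (ds[i0] == -2 || basin[i0] != NA_INTEGER) continue;
    stack.clear();
    int i = i0;
    while (true) {
      if (basin[i] != NA_INTEGER) break;
      stack.push_back(i);
      if (ds[i] == -1) { basin[i] = i + 1; break; }
      i = ds[i];
      if ((int)stack.size() > n) stop("cycle detected in flow directions");
    }
    int lab = basin[i];
    for (size_t k = 0; k < stack.size(); ++k) basin[stack[k]] = lab;
  }
  return basin;
}

// Lower envelope of cones: for every grid cell, the minimum over planted
// channel vertices of (vertex elevation + hillslope * distance), plus the
// index of the vertex attaining it. Used by the landscape generator for
// valley carving and for its geometry-based ground-truth bookkeeping.
// [[Rcpp::export(name = ".minConeC")]]
List minConeC(int nrow, int ncol, NumericVector pr, NumericVector pc,
              NumericVector pz, double hillslope, double cellSize) {
  const int np = pr.size();
  if (np == 0) stop("no channel vertices");
  NumericMatrix z(nrow, ncol);
  IntegerMatrix idx(nrow, ncol);
  for (int c = 0; c < ncol; ++c)
    for (int r = 0; r < nrow; ++r) {
      double best = R_PosInf;
      int bestI = 0;
      for (int i = 0; i < np; ++i) {
        double dr = (r + 1) - pr[i], dc = (c + 1) - pc[i];
        double d = std::sqrt(dr * dr + dc * dc) * cellSize;
        double v = pz[i] + hillslope * d;
        if (v < best) { best = v; bestI = i + 1; }
      }
      z(r, c) = best;
      idx(r, c) = bestI;
    }
  return List::create(_["z"] = z, _["nearest"] = idx);
}
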