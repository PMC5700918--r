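#include <Rcpp.h>
using namespace Rcpp;

// Lattice core for the individual-based model.
//
// Grids are IntegerMatrix: larvae in {0,1}, adults in {0..K}.
// All randomness flows through R's RNG (RNGScope via Rcpp attributes), so
// set.seed() on the R side makes every trajectory reproducible.

// Uniform integer on [0, n-1] drawn from R's stream.
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  if (k == n) k = n - 1; // guard against unif_rand() == 1.0
  return k;
}

// Fisher-Yates shuffle of an index vector using R's RNG.
static void shuffle(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = runif_int(i + 1);
    std::swap(v[i], v[j]);
  }
}

// Pick a uniform cell in the clipped Chebyshev ball of radius r around
// (i, j), excluding the origin cell. Returns false when the ball is empty
// (r == 0 or a 1x1 lattice).
static bool draw_neighbour(int i, int j, int r, int nrow, int ncol,
                           int& oi, int& oj) {
  if (r <= 0) return false;
  int r0 = std::max(0, i - r), r1 = std::min(nrow - 1, i + r);
  int c0 = std::max(0, j - r), c1 = std::min(ncol - 1, j + r);
  int span_c = c1 - c0 + 1;
  int ncand = (r1 - r0 + 1) * span_c - 1;
  if (ncand <= 0) return false;
  int origin = (i - r0) * span_c + (j - c0);
  int k = runif_int(ncand);
  if (k >= origin) ++k;
  oi = r0 + k / span_c;
  oj = c0 + k % span_c;
  return true;
}

// One larval dispersal sweep. Occupied cells are visited in random order;
// each larva draws one candidate cell within the Chebyshev ball whose
// radius depends on the crop of its current cell (radius_bt on Bt cells,
// radius_nonbt on non-Bt cells) and moves iff the destination is empty at
// that moment. Occupancy stays 0/1 and the larva count is conserved.
// [[Rcpp::export(name = ".larval_dispersal_step_cpp")]]
IntegerMatrix larval_dispersal_step_cpp(IntegerMatrix larvae,
                                        IntegerMatrix crop_bt,
                                        int radius_bt, int radius_nonbt) {
  IntegerMatrix g = clone(larvae);
  int nrow = g.nrow(), ncol = g.ncol();
  std::vector<int> occ;
  occ.reserve(256);
  for (int idx = 0; idx < nrow * ncol; ++idx)
    if (g[idx] == 1) occ.push_back(idx);
  shuffle(occ);
  for (size_t u = 0; u < occ.size(); ++u) {
    int idx = occ[u];
    int i = idx % nrow, j = idx / nrow;
    int r = crop_bt(i, j) == 1 ? radius_bt : radius_nonbt;
    int oi, oj;
    if (!draw_neighbour(i, j, r, nrow, ncol, oi, oj)) continue;
    if (g(oi, oj) == 0) {
      g(i, j) = 0;
      g(oi, oj) = 1;
    }
  }
  return g;
}

// One adult dispersal sweep. Individual females are enumerated (a cell with
// count c contributes c individuals), visited in random order; each draws
// one candidate cell within Chebyshev radius `radius` and moves iff the
// destination is below the carrying capacity K. Total count is conserved.
// [[Rcpp::export(name = ".adult_dispersal_step_cpp")]]
IntegerMatrix adult_dispersal_step_cpp(IntegerMatrix adults, int radius,
                                       int carrying_capacity) {
  IntegerMatrix g = clone(adults);
  int nrow = g.nrow(), ncol = g.ncol();
  std::vector<int> ind;
  ind.reserve(256);
  for (int idx = 0; idx < nrow * ncol; ++idx)
    for (int c = 0; c < g[idx]; ++c) ind.push_back(idx);
  shuffle(ind);
  for (size_t u = 0; u < ind.size(); ++u) {
    int idx = ind[u];
    int i = idx % nrow, j = idx / nrow;
    if (g(i, j) == 0) continue; // defensive; counts are decremented on move
    int oi, oj;
    if (!draw_neighbour(i, j, radius, nrow, ncol, oi, oj)) continue;
    if (g(oi, oj) < carrying_capacity) {
      g(i, j) -= 1;
      g(oi, oj) += 1;
    }
  }
  return g;
}

// One demographic transition sweep, events in a fixed order:
//   1. immature mortality: each larva dies w.p. mu_immature;
//   2. metamorphosis: each surviving larva metamorphoses w.p. p_meta; the
//      immature cell empties and one female is added to the same cell if
//      the adult count is below K (the female is lost otherwise);
//   3. adult mortality: each female dies independently w.p. mu_adult;
//   4. oviposition: in each cell whose immature slot is empty, each
//      resident female in turn oviposits w.p. p_ovi; the first success
//      fills the slot (at most one egg per cell per step).
// Returns list(larvae, adults).
// [[Rcpp::export(name = ".transition_step_cpp")]]
List transition_step_cpp(IntegerMatrix larvae, IntegerMatrix adults,
                         double mu_immature, double p_meta,
                         double mu_adult, double p_ovi,
                         int carrying_capacity) {
  IntegerMatrix L = clone(larvae);
  IntegerMatrix A = clone(adults);
  int n = L.nrow() * L.ncol();
  // immature mortality then metamorphosis
  for (int idx = 0; idx < n; ++idx) {
    if (L[idx] != 1) continue;
    if (unif_rand() < mu_immature) {
      L[idx] = 0;
    } else if (unif_rand() < p_meta) {
      L[idx] = 0;
      if (A[idx] < carrying_capacity) A[idx] += 1;
    }
  }
  // adult mortality (binomial thinning per cell)
  for (int idx = 0; idx < n; ++idx) {
    int c = A[idx];
    if (c == 0) continue;
    int surv = 0;
    for (int k = 0; k < c; ++k)
      if (unif_rand() >= mu_adult) ++surv;
    A[idx] = surv;
  }
  // oviposition into the female's own cell
  for (int idx = 0; idx < n; ++idx) {
    if (L[idx] == 1 || A[idx] == 0) continue;
    for (int k = 0; k < A[idx]; ++k) {
      if (unif_rand() < p_ovi) {
        L[idx] = 1;
        break;
      }
    }
  }
  return List::create(_["larvae"] = L, _["adults"] = A);
}
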