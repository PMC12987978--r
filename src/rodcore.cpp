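// Core geometry and grand-canonical Monte Carlo engine for hard rods with
// three allowed orientations (0, 60, 120 degrees) on a periodic square box.
//
// All lengths are in units of the rod width; energies in kB*T.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

static const double COS3[3] = {1.0, 0.5, -0.5};
static const double SIN3[3] = {0.0, 0.8660254037844386, 0.8660254037844386};

// Separating-axis test for two rectangles (open interiors): overlap iff the
// projected center displacement is strictly inside the summed half-extents on
// every candidate axis.  Exact contact (equality on some axis) is not overlap.
static bool sat_overlap(double dx, double dy, int ka, int kb,
                        double len, double wid) {
  const double hl = 0.5 * len, hw = 0.5 * wid;
  const double axes[4][2] = {
    {COS3[ka], SIN3[ka]}, {-SIN3[ka], COS3[ka]},
    {COS3[kb], SIN3[kb]}, {-SIN3[kb], COS3[kb]}};
  const double ua[2] = {COS3[ka], SIN3[ka]}, va[2] = {-SIN3[ka], COS3[ka]};
  const double ub[2] = {COS3[kb], SIN3[kb]}, vb[2] = {-SIN3[kb], COS3[kb]};
  for (int i = 0; i < 4; ++i) {
    const double ax = axes[i][0], ay = axes[i][1];
    double ra = hl * std::fabs(ax * ua[0] + ay * ua[1]) +
                hw * std::fabs(ax * va[0] + ay * va[1]);
    double rb = hl * std::fabs(ax * ub[0] + ay * ub[1]) +
                hw * std::fabs(ax * vb[0] + ay * vb[1]);
    if (std::fabs(ax * dx + ay * dy) >= ra + rb) return false;
  }
  return true;
}

// Overlap under periodic boundary conditions.  When the box is at least twice
// the overlap cutoff the minimum image suffices; otherwise all 9 images of the
// displacement are tested (small test boxes).
static bool pair_overlap_pbc(double ax, double ay, int ka,
                             double bx, double by, int kb,
                             double L, double len, double wid) {
  double dx = bx - ax, dy = by - ay;
  dx -= L * std::round(dx / L);
  dy -= L * std::round(dy / L);
  const double cutoff = std::sqrt(len * len + wid * wid);
  if (L >= 2.0 * cutoff) {
    if (dx * dx + dy * dy >= cutoff * cutoff) return false;
    return sat_overlap(dx, dy, ka, kb, len, wid);
  }
  for (int sx = -1; sx <= 1; ++sx)
    for (int sy = -1; sy <= 1; ++sy)
      if (sat_overlap(dx + sx * L, dy + sy * L, ka, kb, len, wid)) return true;
  return false;
}

// [[Rcpp::export]]
bool cpp_rods_overlap(double ax, double ay, int ka,
                      double bx, double by, int kb,
                      double box_side, double len, double wid) {
  return pair_overlap_pbc(ax, ay, ka, bx, by, kb, box_side, len, wid);
}

// Exhaustive scan of a rod matrix (columns x, y, k) against one candidate.
// [[Rcpp::export]]
bool cpp_any_overlap(NumericMatrix rods, double cx, double cy, int ck,
                     double box_side, double len, double wid,
                     int skip = -1) {
  const int n = rods.nrow();
  for (int i = 0; i < n; ++i) {
    if (i == skip) continue;
    if (pair_overlap_pbc(cx, cy, ck, rods(i, 0), rods(i, 1),
                         (int)rods(i, 2), box_side, len, wid))
      return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// GCMC engine

class RodEngine {
public:
  double L, len, wid, cutoff, A;
  double beta, mu, base_energy, mobility;
  double bias[3];
  int exchanges_per_step;
  bool hard_core;
  int move_mode;  // 0 = bounded displacement, 1 = free relocation w.p. mobility
  std::mt19937_64 rng;
  std::vector<double> x, y;
  std::vector<int> k;
  // uniform cell grid; exact because cell size >= overlap cutoff
  int ncell;
  double cell;
  std::vector<std::vector<int>> cells;
  std::vector<int> cell_of;
  long long step_count = 0;
  long long acc_trans = 0, acc_dep = 0, acc_evap = 0;
  long long att_trans = 0, att_dep = 0, att_evap = 0;

  RodEngine(double L_, double len_, double wid_, double beta_, double mu_,
            double base_energy_, NumericVector bias_, double mobility_,
            int exchanges_, bool hard_core_, int move_mode_, uint64_t seed)
      : L(L_), len(len_), wid(wid_), beta(beta_), mu(mu_),
        base_energy(base_energy_), mobility(mobility_),
        exchanges_per_step(exchanges_), hard_core(hard_core_),
        move_mode(move_mode_), rng(seed) {
    A = L * L;
    for (int i = 0; i < 3; ++i) bias[i] = bias_[i];
    cutoff = std::sqrt(len * len + wid * wid);
    ncell = (int)std::floor(L / std::max(cutoff, 1.0));
    if (ncell < 4) ncell = 1;  // degenerate grid: exhaustive scan
    cell = L / ncell;
    cells.assign((size_t)ncell * ncell, {});
  }

  double runif() {  // [0, 1) from the top 53 bits
    return (rng() >> 11) * (1.0 / 9007199254740992.0);
  }

  double wrap1(double v) const {
    v = std::fmod(v, L);
    if (v < 0) v += L;
    return v;
  }

  int cell_index(double px, double py) const {
    int cx = (int)(px / cell), cy = (int)(py / cell);
    if (cx >= ncell) cx = ncell - 1;
    if (cy >= ncell) cy = ncell - 1;
    return cy * ncell + cx;
  }

  double energy_of(int ki) const { return bias[ki] * base_energy; }

  bool overlaps_any(double px, double py, int pk, int skip) const {
    if (ncell == 1) {
      for (size_t i = 0; i < x.size(); ++i) {
        if ((int)i == skip) continue;
        if (pair_overlap_pbc(px, py, pk, x[i], y[i], k[i], L, len, wid))
          return true;
      }
      return false;
    }
    const int cx = std::min((int)(px / cell), ncell - 1);
    const int cy = std::min((int)(py / cell), ncell - 1);
    const double c2 = cutoff * cutoff;
    for (int ox = -1; ox <= 1; ++ox) {
      for (int oy = -1; oy <= 1; ++oy) {
        const int gx = (cx + ox + ncell) % ncell;
        const int gy = (cy + oy + ncell) % ncell;
        for (int i : cells[(size_t)gy * ncell + gx]) {
          if (i == skip) continue;
          double dx = x[i] - px, dy = y[i] - py;
          dx -= L * std::round(dx / L);
          dy -= L * std::round(dy / L);
          if (dx * dx + dy * dy >= c2) continue;
          if (sat_overlap(dx, dy, pk, k[i], len, wid)) return true;
        }
      }
    }
    return false;
  }

  void grid_insert(int idx) {
    int ci = cell_index(x[idx], y[idx]);
    cell_of[idx] = ci;
    cells[ci].push_back(idx);
  }

  void grid_remove(int idx) {
    std::vector<int>& v = cells[cell_of[idx]];
    for (size_t j = 0; j < v.size(); ++j) {
      if (v[j] == idx) { v[j] = v.back(); v.pop_back(); return; }
    }
  }

  void add_rod(double px, double py, int pk) {
    x.push_back(px); y.push_back(py); k.push_back(pk);
    cell_of.push_back(0);
    grid_insert((int)x.size() - 1);
  }

  void remove_rod(int idx) {
    grid_remove(idx);
    int last = (int)x.size() - 1;
    if (idx != last) {  // move the last rod into the vacated slot
      grid_remove(last);
      x[idx] = x[last]; y[idx] = y[last]; k[idx] = k[last];
      grid_insert(idx);
    }
    x.pop_back(); y.pop_back(); k.pop_back(); cell_of.pop_back();
  }

  void move_rod(int idx, double px, double py) {
    grid_remove(idx);
    x[idx] = px; y[idx] = py;
    grid_insert(idx);
  }

  void translation_phase() {
    const int n0 = (int)x.size();  // only rods existing at step start
    for (int i = 0; i < n0; ++i) {
      ++att_trans;
      double px, py;
      if (move_mode == 1) {
        if (runif() >= mobility) { ++acc_trans; continue; }  // identity
        px = runif() * L;
        py = runif() * L;
      } else {
        const double dx = (2.0 * runif() - 1.0) * mobility * L;
        const double dy = (2.0 * runif() - 1.0) * mobility * L;
        px = wrap1(x[i] + dx);
        py = wrap1(y[i] + dy);
      }
      if (hard_core && overlaps_any(px, py, k[i], i)) continue;
      move_rod(i, px, py);
      ++acc_trans;
    }
  }

  void exchange_attempt() {
    const int n = (int)x.size();
    if (runif() < 0.5) {  // deposition
      ++att_dep;
      const double px = runif() * L;
      const double py = runif() * L;
      int pk = (int)(runif() * 3.0);
      if (pk > 2) pk = 2;
      if (hard_core && overlaps_any(px, py, pk, -1)) return;
      const double thr = A * std::exp(beta * (mu - energy_of(pk))) / (n + 1);
      if (runif() <= thr) { add_rod(px, py, pk); ++acc_dep; }
    } else {  // evaporation
      ++att_evap;
      if (n == 0) return;
      int idx = (int)(runif() * n);
      if (idx >= n) idx = n - 1;
      const double thr = n / (A * std::exp(beta * (mu - energy_of(k[idx]))));
      if (runif() <= thr) { remove_rod(idx); ++acc_evap; }
    }
  }

  void run(int n_steps) {
    for (int s = 0; s < n_steps; ++s) {
      translation_phase();
      for (int e = 0; e < exchanges_per_step; ++e) exchange_attempt();
      ++step_count;
    }
  }
};

// [[Rcpp::export]]
SEXP cpp_engine_create(double box_side, double len, double wid, double beta,
                       double mu, double base_energy, NumericVector bias,
                       double mobility, int exchanges_per_step, bool hard_core,
                       int move_mode, double seed) {
  XPtr<RodEngine> ptr(new RodEngine(box_side, len, wid, beta, mu, base_energy,
                                    bias, mobility, exchanges_per_step,
                                    hard_core, move_mode, (uint64_t)seed),
                      true);
  return ptr;
}

// [[Rcpp::export]]
void cpp_engine_run(SEXP eng, int n_steps) {
  XPtr<RodEngine> p(eng);
  p->run(n_steps);
}

// [[Rcpp::export]]
void cpp_engine_insert(SEXP eng, NumericMatrix rods) {
  XPtr<RodEngine> p(eng);
  for (int i = 0; i < rods.nrow(); ++i) {
    double px = p->wrap1(rods(i, 0)), py = p->wrap1(rods(i, 1));
    int pk = (int)rods(i, 2);
    if (p->hard_core && p->overlaps_any(px, py, pk, -1))
      stop("cannot insert rod %d: hard-core overlap", i + 1);
    p->add_rod(px, py, pk);
  }
}

// [[Rcpp::export]]
List cpp_engine_state(SEXP eng) {
  XPtr<RodEngine> p(eng);
  const int n = (int)p->x.size();
  NumericVector xs(n), ys(n);
  IntegerVector ks(n);
  for (int i = 0; i < n; ++i) { xs[i] = p->x[i]; ys[i] = p->y[i]; ks[i] = p->k[i]; }
  return List::create(
      _["x"] = xs, _["y"] = ys, _["k"] = ks, _["n_rods"] = n,
      _["step"] = (double)p->step_count,
      _["acc_trans"] = (double)p->acc_trans,
      _["acc_dep"] = (double)p->acc_dep,
      _["acc_evap"] = (double)p->acc_evap,
      _["att_trans"] = (double)p->att_trans,
      _["att_dep"] = (double)p->att_dep,
      _["att_evap"] = (double)p->att_evap);
}

// Grid-accelerated overlap query against an engine's current configuration.
// [[Rcpp::export]]
bool cpp_engine_query_overlap(SEXP eng, double px, double py, int pk) {
  XPtr<RodEngine> p(eng);
  return p->overlaps_any(p->wrap1(px), p->wrap1(py), pk, -1);
}

// Hard-core audit: index of first overlapping pair, or 0 if none (1-based).
// [[Rcpp::export]]
IntegerVector cpp_first_overlap_pair(NumericMatrix rods, double box_side,
                                     double len, double wid) {
  const int n = rods.nrow();
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (pair_overlap_pbc(rods(i, 0), rods(i, 1), (int)rods(i, 2),
                           rods(j, 0), rods(j, 1), (int)rods(j, 2),
                           box_side, len, wid))
        return IntegerVector::create(i + 1, j + 1);
  return IntegerVector::create(0, 0);
}
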