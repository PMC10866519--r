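// Core Cellular Potts engine: lattice state, Hamiltonian deltas, edge-list
// Monte Carlo sampling, filopodial-tension term and polarization dynamics.
// All heavy per-attempt work lives here; R drives runs in MCS-sized chunks.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
#include <array>
#include <queue>

using namespace Rcpp;

// Moore neighborhood; opposite(k) == 7 - k by construction.
static const int OFFX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int OFFY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int N_NB = 8;

struct CPMState {
  int W = 0, H = 0;              // allocated lattice incl. 1-site frame
  std::vector<int> spin;         // W*H, column of y-major rows: p = y*W + x
  // per-cell bookkeeping, ids 1..ncell (0 = medium)
  int ncell = 0;
  int ntypes = 1;                // cell types 1..ntypes (0 = medium)
  std::vector<int> type;         // length ncell+1, type[0] = 0
  std::vector<int> area;
  std::vector<char> alive;
  std::vector<char> ever;        // has the cell ever held lattice sites?
  std::vector<double> sx, sy, sxx, syy, sxy;  // coordinate moments
  std::vector<double> cons;                   // cached constraint energy per cell
  std::vector<double> comx, comy;             // cached centers of mass
  // parameters
  double T = 50, l1 = 5, l2 = 5, AT = 100, LT = 10;
  std::vector<double> J;         // (ntypes+1)^2 row-major
  // edge list (paper's paired arrays)
  std::vector<int> edgelist;     // slot index -> edge number or -1
  std::vector<int> edgeindices;  // edge number -> slot index, -1 beyond nE
  int nE = 0;
  // filopodial tension
  bool filo_on = false;
  double lambdaF = 0, theta_max_deg = 45, r_max = 2, wmem = 0.99;
  int n_max = 3, t_interval = 20;
  int pulling_variant = 0;       // 0 none/all within mask rules below
  int repol_mode = 0;            // 0 vicsek, 1 belmonte (location-based)
  std::vector<double> pol;       // per-cell polarization angle [0, 2pi)
  struct Link { int u, v; double R; };
  std::vector<Link> links;                     // (src, dst, current length)
  std::vector<std::vector<int>> incident;      // per-cell link indices
  // sampling
  int sampler = 0;               // 0 edge list, 1 conventional site-pair
  std::mt19937_64 rng_main, rng_filo;
  long long mcs = 0;
  long long attempts = 0, accepted = 0;
};

static inline bool on_frame(const CPMState& S, int x, int y) {
  return x <= 0 || y <= 0 || x >= S.W - 1 || y >= S.H - 1;
}

static inline double runif01(std::mt19937_64& g) {
  return (g() >> 11) * (1.0 / 9007199254740992.0);
}

static inline int rint_below(std::mt19937_64& g, int n) {
  return (int)(g() % (uint64_t)n);
}

static inline double Jget(const CPMState& S, int ta, int tb) {
  return S.J[ta * (S.ntypes + 1) + tb];
}

// major-axis length from coordinate moments: 4 * sqrt(lambda_max(cov))
static double length_from_moments(int n, double sx, double sy, double sxx,
                                  double syy, double sxy) {
  if (n <= 0) return 0.0;
  double mx = sx / n, my = sy / n;
  double cxx = sxx / n - mx * mx;
  double cyy = syy / n - my * my;
  double cxy = sxy / n - mx * my;
  double tr2 = 0.5 * (cxx + cyy);
  double det = std::sqrt(std::max(0.25 * (cxx - cyy) * (cxx - cyy) + cxy * cxy, 0.0));
  double lmax = tr2 + det;
  return 4.0 * std::sqrt(std::max(lmax, 0.0));
}

// ---------------------------------------------------------------- edge list

static inline void edge_add(CPMState& S, int slot) {
  S.edgelist[slot] = S.nE;
  S.edgeindices[S.nE] = slot;
  S.nE++;
}

static inline void edge_remove(CPMState& S, int slot) {
  int k = S.edgelist[slot];
  int last = S.nE - 1;
  int jslot = S.edgeindices[last];
  // edge at the last index replaces the removed one; prefix stays dense
  S.edgeindices[k] = jslot;
  S.edgelist[jslot] = k;
  S.edgeindices[last] = -1;
  S.edgelist[slot] = -1;
  S.nE--;
}

static void build_edges(CPMState& S) {
  std::fill(S.edgelist.begin(), S.edgelist.end(), -1);
  std::fill(S.edgeindices.begin(), S.edgeindices.end(), -1);
  S.nE = 0;
  for (int y = 0; y < S.H; ++y)
    for (int x = 0; x < S.W; ++x) {
      if (on_frame(S, x, y)) continue;
      int p = y * S.W + x;
      for (int k = 0; k < N_NB; ++k) {
        int ux = x + OFFX[k], uy = y + OFFY[k];
        if (on_frame(S, ux, uy)) continue;
        if (S.spin[p] != S.spin[uy * S.W + ux]) edge_add(S, p * N_NB + k);
      }
    }
}

static void edges_around_site(CPMState& S, int x, int y) {
  int p = y * S.W + x;
  for (int k = 0; k < N_NB; ++k) {
    int ux = x + OFFX[k], uy = y + OFFY[k];
    if (on_frame(S, ux, uy)) continue;
    int u = uy * S.W + ux;
    bool want = S.spin[p] != S.spin[u];
    int i1 = p * N_NB + k;
    int i2 = u * N_NB + (7 - k);
    if (want) {
      if (S.edgelist[i1] < 0) edge_add(S, i1);
      if (S.edgelist[i2] < 0) edge_add(S, i2);
    } else {
      if (S.edgelist[i1] >= 0) edge_remove(S, i1);
      if (S.edgelist[i2] >= 0) edge_remove(S, i2);
    }
  }
}

// ------------------------------------------------------------- energy terms

// area + length constraint terms of one cell at (n sites, given moments)
static inline double cell_constraint(const CPMState& S, int n, double sx,
                                     double sy, double sxx, double syy,
                                     double sxy) {
  double L = length_from_moments(n, sx, sy, sxx, syy, sxy);
  double da = n - S.AT, dl = L - S.LT;
  return S.l1 * da * da + S.l2 * dl * dl;
}

static inline void refresh_cell_cache(CPMState& S, int c) {
  S.cons[c] = cell_constraint(S, S.area[c], S.sx[c], S.sy[c], S.sxx[c],
                              S.syy[c], S.sxy[c]);
  if (S.area[c] > 0) {
    S.comx[c] = S.sx[c] / S.area[c];
    S.comy[c] = S.sy[c] / S.area[c];
  } else {
    S.comx[c] = S.comy[c] = 0.0;
  }
}

// filopodial-tension contribution of a proposed copy (Eq. of motion term):
// lambda_F * sum over links touching the two affected cells of (R_after - R_before)
static double filo_delta(const CPMState& S, int s_old, int s_new, int tx, int ty) {
  if (!S.filo_on || S.lambdaF == 0.0 || S.links.empty()) return 0.0;
  bool a_moves = s_old > 0, b_moves = s_new > 0;
  if (!a_moves && !b_moves) return 0.0;
  double ax0 = 0, ay0 = 0, ax1 = 0, ay1 = 0, bx0 = 0, by0 = 0, bx1 = 0, by1 = 0;
  bool a_dies = false;
  if (a_moves) {
    int n = S.area[s_old];
    ax0 = S.comx[s_old]; ay0 = S.comy[s_old];
    if (n <= 1) a_dies = true;
    else { ax1 = (S.sx[s_old] - tx) / (n - 1); ay1 = (S.sy[s_old] - ty) / (n - 1); }
  }
  if (b_moves) {
    int n = S.area[s_new];
    bx0 = S.comx[s_new]; by0 = S.comy[s_new];
    bx1 = (S.sx[s_new] + tx) / (n + 1); by1 = (S.sy[s_new] + ty) / (n + 1);
  }
  double dd = 0.0;
  auto endpoint = [&](int c, bool after, double& ex, double& ey) -> bool {
    if (c == s_old && a_moves) {
      if (after) { if (a_dies) return false; ex = ax1; ey = ay1; }
      else { ex = ax0; ey = ay0; }
    } else if (c == s_new && b_moves) {
      if (after) { ex = bx1; ey = by1; } else { ex = bx0; ey = by0; }
    } else {
      if (S.area[c] <= 0) return false;
      ex = S.comx[c]; ey = S.comy[c];
    }
    return true;
  };
  auto link_term = [&](int li) {
    int u = S.links[li].u, v = S.links[li].v;
    double ux1, uy1, vx1, vy1;
    // links to a cell that would die are retired with the cell: no term
    if (!endpoint(u, true, ux1, uy1) || !endpoint(v, true, vx1, vy1)) return;
    double dxa = ux1 - vx1, dya = uy1 - vy1;
    dd += std::sqrt(dxa * dxa + dya * dya) - S.links[li].R;  // R cached = R_before
  };
  if (a_moves)
    for (int li : S.incident[s_old]) link_term(li);
  if (b_moves)
    for (int li : S.incident[s_new]) {
      int u = S.links[li].u, v = S.links[li].v;
      if (a_moves && (u == s_old || v == s_old)) continue;  // already counted
      link_term(li);
    }
  return S.lambdaF * dd;
}

// full energy change of copying spin(source at slot k of target) onto target
static double delta_h(const CPMState& S, int tx, int ty, int k) {
  int p = ty * S.W + tx;
  int sxn = tx + OFFX[k], syn = ty + OFFY[k];
  int s_old = S.spin[p];
  int s_new = S.spin[syn * S.W + sxn];
  double dH = 0.0;
  int t_new = S.type[s_new], t_old = S.type[s_old];
  for (int q = 0; q < N_NB; ++q) {
    int ux = tx + OFFX[q], uy = ty + OFFY[q];
    if (on_frame(S, ux, uy)) continue;
    int su = S.spin[uy * S.W + ux];
    int tu = S.type[su];
    if (su != s_new) dH += Jget(S, t_new, tu);
    if (su != s_old) dH -= Jget(S, t_old, tu);
  }
  if (s_old > 0) {
    int n = S.area[s_old];
    dH -= S.cons[s_old];
    dH += cell_constraint(S, n - 1, S.sx[s_old] - tx, S.sy[s_old] - ty,
                          S.sxx[s_old] - (double)tx * tx,
                          S.syy[s_old] - (double)ty * ty,
                          S.sxy[s_old] - (double)tx * ty);
  }
  if (s_new > 0) {
    int n = S.area[s_new];
    dH -= S.cons[s_new];
    dH += cell_constraint(S, n + 1, S.sx[s_new] + tx, S.sy[s_new] + ty,
                          S.sxx[s_new] + (double)tx * tx,
                          S.syy[s_new] + (double)ty * ty,
                          S.sxy[s_new] + (double)tx * ty);
  }
  dH += filo_delta(S, s_old, s_new, tx, ty);
  return dH;
}

static void retire_cell(CPMState& S, int c) {
  S.alive[c] = 0;
  if (S.links.empty()) return;
  // drop all filopodia touching the retired cell; rebuild incident lists
  std::vector<CPMState::Link> kept;
  kept.reserve(S.links.size());
  for (auto& l : S.links)
    if (l.u != c && l.v != c) kept.push_back(l);
  if (kept.size() != S.links.size()) {
    S.links.swap(kept);
    for (auto& v : S.incident) v.clear();
    for (int i = 0; i < (int)S.links.size(); ++i) {
      S.incident[S.links[i].u].push_back(i);
      S.incident[S.links[i].v].push_back(i);
    }
  }
}

static void apply_copy(CPMState& S, int tx, int ty, int k) {
  int p = ty * S.W + tx;
  int s_old = S.spin[p];
  int s_new = S.spin[(ty + OFFY[k]) * S.W + (tx + OFFX[k])];
  S.spin[p] = s_new;
  if (s_old > 0) {
    S.area[s_old]--;
    S.sx[s_old] -= tx; S.sy[s_old] -= ty;
    S.sxx[s_old] -= (double)tx * tx;
    S.syy[s_old] -= (double)ty * ty;
    S.sxy[s_old] -= (double)tx * ty;
    refresh_cell_cache(S, s_old);
    if (S.area[s_old] == 0) retire_cell(S, s_old);
  }
  if (s_new > 0) {
    S.area[s_new]++;
    S.sx[s_new] += tx; S.sy[s_new] += ty;
    S.sxx[s_new] += (double)tx * tx;
    S.syy[s_new] += (double)ty * ty;
    S.sxy[s_new] += (double)tx * ty;
    refresh_cell_cache(S, s_new);
  }
  if (!S.links.empty()) {
    auto upd = [&](int c) {
      for (int li : S.incident[c]) {
        auto& l = S.links[li];
        double dx = S.comx[l.u] - S.comx[l.v], dy = S.comy[l.u] - S.comy[l.v];
        l.R = std::sqrt(dx * dx + dy * dy);
      }
    };
    if (s_old > 0 && S.alive[s_old]) upd(s_old);
    if (s_new > 0) upd(s_new);
  }
  edges_around_site(S, tx, ty);
}

// --------------------------------------------------------------- filopodia

static inline bool mask_allows(const CPMState& S, int ts, int tt) {
  switch (S.pulling_variant) {
    case 0: return true;                 // one-type / all-all
    case 1: return ts == tt;             // same type
    case 2: return true;                 // all-all (explicit)
    case 3: return ts == 2;              // yellow-all
    case 4: return ts == 2 && tt == 2;   // yellow-yellow
  }
  return false;
}

static void refresh_filopodia(CPMState& S) {
  S.links.clear();
  for (auto& v : S.incident) v.clear();
  double rmax = S.r_max * S.LT;
  double cmin = std::cos(S.theta_max_deg * M_PI / 180.0);
  std::vector<int> cand;
  for (int s = 1; s <= S.ncell; ++s) {
    if (!S.alive[s] || S.area[s] == 0) continue;
    double cx = S.sx[s] / S.area[s], cy = S.sy[s] / S.area[s];
    double px = std::cos(S.pol[s]), py = std::sin(S.pol[s]);
    cand.clear();
    for (int t = 1; t <= S.ncell; ++t) {
      if (t == s || !S.alive[t] || S.area[t] == 0) continue;
      if (!mask_allows(S, S.type[s], S.type[t])) continue;
      double dx = S.sx[t] / S.area[t] - cx, dy = S.sy[t] / S.area[t] - cy;
      double r = std::hypot(dx, dy);
      if (r <= 0 || r > rmax) continue;
      if (std::fabs(dx * px + dy * py) / r < cmin) continue;  // double cone
      cand.push_back(t);
    }
    int take = std::min((int)cand.size(), S.n_max);
    // uniform sample without replacement (partial Fisher-Yates)
    for (int i = 0; i < take; ++i) {
      int j = i + rint_below(S.rng_filo, (int)cand.size() - i);
      std::swap(cand[i], cand[j]);
      int li = (int)S.links.size();
      int t = cand[i];
      double dx = S.sx[t] / S.area[t] - cx, dy = S.sy[t] / S.area[t] - cy;
      S.links.push_back({s, t, std::sqrt(dx * dx + dy * dy)});
      S.incident[s].push_back(li);
      S.incident[t].push_back(li);
    }
  }
  // synchronous polarization update from the new link set
  std::vector<double> newpol(S.pol);
  for (int s = 1; s <= S.ncell; ++s) {
    if (!S.alive[s]) continue;
    double vx = 0, vy = 0;
    int nlink = 0;
    for (int li : S.incident[s]) {
      if (S.links[li].u != s) continue;  // own filopodia only
      int t = S.links[li].v;
      if (S.repol_mode == 0) {
        vx += std::cos(S.pol[t]);
        vy += std::sin(S.pol[t]);
      } else {
        vx += S.sx[t] / S.area[t] - S.sx[s] / S.area[s];
        vy += S.sy[t] / S.area[t] - S.sy[s] / S.area[s];
      }
      nlink++;
    }
    if (nlink == 0) continue;
    double norm = std::hypot(vx, vy);
    if (norm < 1e-12) continue;  // antipodal tie: keep previous direction
    double pavg = std::atan2(vy, vx);
    double zx = S.wmem * std::cos(S.pol[s]) + (1 - S.wmem) * std::cos(pavg);
    double zy = S.wmem * std::sin(S.pol[s]) + (1 - S.wmem) * std::sin(pavg);
    if (std::hypot(zx, zy) < 1e-12) continue;
    double pn = std::atan2(zy, zx);
    if (pn < 0) pn += 2 * M_PI;
    newpol[s] = pn;
  }
  S.pol.swap(newpol);
}

// ------------------------------------------------------------ Monte Carlo

static void one_attempt_edge(CPMState& S) {
  int slot = S.edgeindices[rint_below(S.rng_main, S.nE)];
  int p = slot / N_NB, k = slot % N_NB;
  int tx = p % S.W, ty = p / S.W;
  double dH = delta_h(S, tx, ty, k);
  S.attempts++;
  if (dH <= 0 || runif01(S.rng_main) < std::exp(-dH / S.T)) {
    apply_copy(S, tx, ty, k);
    S.accepted++;
  }
}

static void one_attempt_conventional(CPMState& S) {
  S.attempts++;
  int p = rint_below(S.rng_main, S.W * S.H);
  int k = rint_below(S.rng_main, N_NB);
  int tx = p % S.W, ty = p / S.W;
  if (on_frame(S, tx, ty)) return;
  int ux = tx + OFFX[k], uy = ty + OFFY[k];
  if (on_frame(S, ux, uy)) return;
  if (S.spin[p] == S.spin[uy * S.W + ux]) return;
  double dH = delta_h(S, tx, ty, k);
  if (dH <= 0 || runif01(S.rng_main) < std::exp(-dH / S.T)) {
    apply_copy(S, tx, ty, k);
    S.accepted++;
  }
}

static void run_mcs(CPMState& S, int n) {
  for (int m = 0; m < n; ++m) {
    if (S.sampler == 0) {
      long long done = 0;
      while (S.nE > 0 && done < (S.nE + N_NB - 1) / N_NB) {  // |E| re-read live
        one_attempt_edge(S);
        done++;
      }
    } else {
      long long tot = (long long)S.W * S.H;
      for (long long a = 0; a < tot; ++a) one_attempt_conventional(S);
    }
    S.mcs++;
    if (S.filo_on && S.t_interval > 0 && S.mcs % S.t_interval == 0)
      refresh_filopodia(S);
  }
}

// ------------------------------------------------------------------ R API

typedef XPtr<CPMState> cpm_ptr;

// [[Rcpp::export]]
SEXP cpm_create_(int width, int height, IntegerVector cell_types, int n_types,
                 NumericMatrix Jmat, double temperature, double lambda_area,
                 double lambda_length, double target_area, double target_length,
                 bool filo_on, double lambda_F, double theta_max, double r_max,
                 int n_max, int t_interval, double w_mem, int pulling_variant,
                 int repol_mode, int sampler, double seed_main, double seed_filo) {
  CPMState* S = new CPMState();
  S->W = width; S->H = height;
  S->spin.assign((size_t)width * height, 0);
  S->ncell = cell_types.size();
  S->ntypes = n_types;
  S->type.assign(S->ncell + 1, 0);
  for (int i = 0; i < S->ncell; ++i) {
    if (cell_types[i] < 1 || cell_types[i] > n_types)
      stop("cell type out of range 1..n_types");
    S->type[i + 1] = cell_types[i];
  }
  if (Jmat.nrow() != n_types + 1 || Jmat.ncol() != n_types + 1)
    stop("J must be a (n_types+1) x (n_types+1) matrix including the medium");
  S->J.assign((size_t)(n_types + 1) * (n_types + 1), 0.0);
  for (int a = 0; a <= n_types; ++a)
    for (int b = 0; b <= n_types; ++b) {
      if (std::fabs(Jmat(a, b) - Jmat(b, a)) > 1e-9) stop("J must be symmetric");
      S->J[a * (n_types + 1) + b] = Jmat(a, b);
    }
  S->T = temperature; S->l1 = lambda_area; S->l2 = lambda_length;
  S->AT = target_area; S->LT = target_length;
  S->filo_on = filo_on; S->lambdaF = lambda_F; S->theta_max_deg = theta_max;
  S->r_max = r_max; S->n_max = n_max; S->t_interval = t_interval;
  S->wmem = w_mem; S->pulling_variant = pulling_variant;
  S->repol_mode = repol_mode; S->sampler = sampler;
  S->area.assign(S->ncell + 1, 0);
  S->alive.assign(S->ncell + 1, 1);
  S->alive[0] = 0;
  S->ever.assign(S->ncell + 1, 0);
  S->sx.assign(S->ncell + 1, 0); S->sy.assign(S->ncell + 1, 0);
  S->sxx.assign(S->ncell + 1, 0); S->syy.assign(S->ncell + 1, 0);
  S->sxy.assign(S->ncell + 1, 0);
  S->cons.assign(S->ncell + 1, 0); S->comx.assign(S->ncell + 1, 0);
  S->comy.assign(S->ncell + 1, 0);
  S->edgelist.assign((size_t)width * height * N_NB, -1);
  S->edgeindices.assign((size_t)width * height * N_NB, -1);
  S->rng_main.seed((uint64_t)seed_main);
  S->rng_filo.seed((uint64_t)seed_filo);
  S->incident.assign(S->ncell + 1, {});
  // polarization: uniformly random in [0, 2pi)
  S->pol.assign(S->ncell + 1, 0.0);
  for (int c = 1; c <= S->ncell; ++c)
    S->pol[c] = 2 * M_PI * runif01(S->rng_filo);
  return cpm_ptr(S, true);
}

// [[Rcpp::export]]
void cpm_set_spins_(SEXP xp, IntegerMatrix spins) {
  cpm_ptr S(xp);
  if (spins.nrow() != S->W || spins.ncol() != S->H)
    stop("spin matrix must be width x height");
  std::fill(S->area.begin(), S->area.end(), 0);
  std::fill(S->sx.begin(), S->sx.end(), 0.0);
  std::fill(S->sy.begin(), S->sy.end(), 0.0);
  std::fill(S->sxx.begin(), S->sxx.end(), 0.0);
  std::fill(S->syy.begin(), S->syy.end(), 0.0);
  std::fill(S->sxy.begin(), S->sxy.end(), 0.0);
  for (int y = 0; y < S->H; ++y)
    for (int x = 0; x < S->W; ++x) {
      int s = spins(x, y);
      if (s < 0 || s > S->ncell) stop("spin value outside registered cells");
      if (s > 0 && on_frame(*S, x, y)) stop("cells may not occupy the lattice frame");
      S->spin[y * S->W + x] = s;
      if (s > 0) {
        S->area[s]++;
        S->sx[s] += x; S->sy[s] += y;
        S->sxx[s] += (double)x * x; S->syy[s] += (double)y * y;
        S->sxy[s] += (double)x * y;
      }
    }
  S->links.clear();
  for (auto& v : S->incident) v.clear();
  for (int c = 1; c <= S->ncell; ++c) {
    S->alive[c] = S->area[c] > 0 ? 1 : 0;
    if (S->alive[c]) S->ever[c] = 1;
    refresh_cell_cache(*S, c);
  }
  build_edges(*S);
}

// [[Rcpp::export]]
IntegerMatrix cpm_spins_(SEXP xp) {
  cpm_ptr S(xp);
  IntegerMatrix m(S->W, S->H);
  for (int y = 0; y < S->H; ++y)
    for (int x = 0; x < S->W; ++x) m(x, y) = S->spin[y * S->W + x];
  return m;
}

// [[Rcpp::export]]
List cpm_cells_(SEXP xp) {
  cpm_ptr S(xp);
  int n = S->ncell;
  IntegerVector id(n), type(n), area(n);
  LogicalVector alive(n);
  NumericVector cx(n), cy(n), len(n), pol(n);
  for (int c = 1; c <= n; ++c) {
    id[c - 1] = c;
    type[c - 1] = S->type[c];
    area[c - 1] = S->area[c];
    alive[c - 1] = S->alive[c] != 0;
    if (S->area[c] > 0) {
      cx[c - 1] = S->sx[c] / S->area[c] + 1;  // 1-based R coordinates
      cy[c - 1] = S->sy[c] / S->area[c] + 1;
    } else { cx[c - 1] = NA_REAL; cy[c - 1] = NA_REAL; }
    len[c - 1] = length_from_moments(S->area[c], S->sx[c], S->sy[c], S->sxx[c],
                                     S->syy[c], S->sxy[c]);
    pol[c - 1] = S->pol[c];
  }
  return DataFrame::create(_["id"] = id, _["type"] = type, _["alive"] = alive,
                           _["area"] = area, _["x"] = cx, _["y"] = cy,
                           _["length"] = len, _["polarization"] = pol);
}

// [[Rcpp::export]]
List cpm_edges_(SEXP xp) {
  cpm_ptr S(xp);
  return List::create(_["edgelist"] = IntegerVector(S->edgelist.begin(), S->edgelist.end()),
                      _["edgeindices"] = IntegerVector(S->edgeindices.begin(), S->edgeindices.end()),
                      _["n_edges"] = S->nE);
}

// [[Rcpp::export]]
int cpm_n_edges_(SEXP xp) { return cpm_ptr(xp)->nE; }

// [[Rcpp::export]]
List cpm_run_(SEXP xp, int mcs) {
  cpm_ptr S(xp);
  long long a0 = S->attempts, c0 = S->accepted;
  run_mcs(*S, mcs);
  return List::create(_["mcs"] = (double)S->mcs,
                      _["attempts"] = (double)(S->attempts - a0),
                      _["accepted"] = (double)(S->accepted - c0));
}

// [[Rcpp::export]]
void cpm_burnin_(SEXP xp, int mcs) {
  cpm_ptr S(xp);
  double l2 = S->l2;
  bool filo = S->filo_on;
  S->l2 = 0.0;        // grow with area/adhesion terms only
  S->filo_on = false;
  for (int c = 1; c <= S->ncell; ++c) refresh_cell_cache(*S, c);
  long long m0 = S->mcs;
  run_mcs(*S, mcs);
  S->l2 = l2;
  S->filo_on = filo;
  for (int c = 1; c <= S->ncell; ++c) refresh_cell_cache(*S, c);
  S->mcs = m0;        // burn-in does not advance simulation time
}

// [[Rcpp::export]]
double cpm_mcs_(SEXP xp) { return (double)cpm_ptr(xp)->mcs; }

// [[Rcpp::export]]
double cpm_propose_(SEXP xp, int x, int y, int k) {
  cpm_ptr S(xp);
  int tx = x - 1, ty = y - 1, kk = k - 1;
  if (kk < 0 || kk >= N_NB) stop("neighbor slot must be in 1..8");
  if (on_frame(*S, tx, ty)) stop("target on lattice frame");
  int ux = tx + OFFX[kk], uy = ty + OFFY[kk];
  if (on_frame(*S, ux, uy)) stop("source on lattice frame");
  if (S->spin[ty * S->W + tx] == S->spin[uy * S->W + ux])
    stop("equal spins: not a boundary pair");
  return delta_h(*S, tx, ty, kk);
}

// [[Rcpp::export]]
void cpm_apply_(SEXP xp, int x, int y, int k) {
  cpm_ptr S(xp);
  apply_copy(*S, x - 1, y - 1, k - 1);
}

// [[Rcpp::export]]
IntegerVector cpm_sample_edge_(SEXP xp) {
  cpm_ptr S(xp);
  if (S->nE == 0) stop("no edges: simulation frozen");
  int slot = S->edgeindices[rint_below(S->rng_main, S->nE)];
  int p = slot / N_NB, k = slot % N_NB;
  return IntegerVector::create(_["x"] = p % S->W + 1, _["y"] = p / S->W + 1,
                               _["nb"] = k + 1, _["slot"] = slot);
}

// [[Rcpp::export]]
double cpm_hamiltonian_(SEXP xp) {
  cpm_ptr S(xp);
  double H = 0.0;
  // adhesion over unordered adjacent pairs; count (t, u) with u in the 4
  // "forward" neighbor slots so each pair appears once
  static const int FWD[4] = {4, 5, 6, 7};  // E, SW, S, SE
  for (int y = 1; y < S->H - 1; ++y)
    for (int x = 1; x < S->W - 1; ++x) {
      int sp = S->spin[y * S->W + x];
      for (int f = 0; f < 4; ++f) {
        int k = FWD[f];
        int ux = x + OFFX[k], uy = y + OFFY[k];
        if (on_frame(*S, ux, uy)) continue;
        int su = S->spin[uy * S->W + ux];
        if (su != sp) H += Jget(*S, S->type[sp], S->type[su]);
      }
    }
  for (int c = 1; c <= S->ncell; ++c)
    if (S->ever[c])
      H += cell_constraint(*S, S->area[c], S->sx[c], S->sy[c], S->sxx[c],
                           S->syy[c], S->sxy[c]);
  return H;
}

// [[Rcpp::export]]
List cpm_check_(SEXP xp) {
  cpm_ptr S(xp);
  // rebuild edge set from spins and compare as a set of slots
  CPMState ref;
  ref.W = S->W; ref.H = S->H; ref.spin = S->spin;
  ref.edgelist.assign(S->edgelist.size(), -1);
  ref.edgeindices.assign(S->edgeindices.size(), -1);
  build_edges(ref);
  bool ok = ref.nE == S->nE;
  int bad_bijection = 0;
  for (size_t i = 0; ok && i < S->edgelist.size(); ++i)
    if ((S->edgelist[i] >= 0) != (ref.edgelist[i] >= 0)) ok = false;
  for (int e = 0; e < S->nE; ++e) {
    int slot = S->edgeindices[e];
    if (slot < 0 || S->edgelist[slot] != e) bad_bijection++;
  }
  for (size_t e = S->nE; e < S->edgeindices.size(); ++e)
    if (S->edgeindices[e] != -1) bad_bijection++;
  // bookkeeping: recompute areas/moments from spins
  double dev = 0.0;
  std::vector<double> a(S->ncell + 1, 0), gx(S->ncell + 1, 0), gy(S->ncell + 1, 0),
      gxx(S->ncell + 1, 0), gyy(S->ncell + 1, 0), gxy(S->ncell + 1, 0);
  for (int y = 0; y < S->H; ++y)
    for (int x = 0; x < S->W; ++x) {
      int s = S->spin[y * S->W + x];
      if (s > 0) {
        a[s]++; gx[s] += x; gy[s] += y;
        gxx[s] += (double)x * x; gyy[s] += (double)y * y; gxy[s] += (double)x * y;
      }
    }
  for (int c = 1; c <= S->ncell; ++c) {
    dev = std::max(dev, std::fabs(a[c] - S->area[c]));
    dev = std::max(dev, std::fabs(gx[c] - S->sx[c]));
    dev = std::max(dev, std::fabs(gy[c] - S->sy[c]));
    dev = std::max(dev, std::fabs(gxx[c] - S->sxx[c]));
    dev = std::max(dev, std::fabs(gyy[c] - S->syy[c]));
    dev = std::max(dev, std::fabs(gxy[c] - S->sxy[c]));
  }
  return List::create(_["edges_ok"] = ok, _["bijection_errors"] = bad_bijection,
                      _["bookkeeping_dev"] = dev);
}

// [[Rcpp::export]]
IntegerMatrix cpm_filopodia_(SEXP xp) {
  cpm_ptr S(xp);
  IntegerMatrix m(S->links.size(), 2);
  for (int i = 0; i < (int)S->links.size(); ++i) {
    m(i, 0) = S->links[i].u;
    m(i, 1) = S->links[i].v;
  }
  colnames(m) = CharacterVector::create("source", "target");
  return m;
}

// [[Rcpp::export]]
void cpm_refresh_filopodia_(SEXP xp) { refresh_filopodia(*cpm_ptr(xp)); }

// [[Rcpp::export]]
NumericVector cpm_get_polarization_(SEXP xp) {
  cpm_ptr S(xp);
  return NumericVector(S->pol.begin() + 1, S->pol.end());
}

// [[Rcpp::export]]
void cpm_set_polarization_(SEXP xp, NumericVector pol) {
  cpm_ptr S(xp);
  if (pol.size() != S->ncell) stop("need one angle per cell");
  for (int c = 1; c <= S->ncell; ++c)
    S->pol[c] = std::fmod(std::fmod(pol[c - 1], 2 * M_PI) + 2 * M_PI, 2 * M_PI);
}

// [[Rcpp::export]]
void cpm_set_temperature_(SEXP xp, double T) {
  if (T <= 0) stop("temperature must be positive");
  cpm_ptr(xp)->T = T;
}

// ---------------------------------------------- 2D Kolmogorov-Smirnov core

static double ff_max_diff(const std::vector<double>& ax, const std::vector<double>& ay,
                          const std::vector<double>& bx, const std::vector<double>& by,
                          const std::vector<double>& ox, const std::vector<double>& oy) {
  double dmax = 0.0;
  size_t na = ax.size(), nb = bx.size();
  for (size_t i = 0; i < ox.size(); ++i) {
    double x0 = ox[i], y0 = oy[i];
    int a1 = 0, a2 = 0, a3 = 0, a4 = 0, b1 = 0, b2 = 0, b3 = 0, b4 = 0;
    for (size_t j = 0; j < na; ++j) {
      if (ax[j] > x0) { if (ay[j] > y0) a1++; else if (ay[j] < y0) a4++; }
      else if (ax[j] < x0) { if (ay[j] > y0) a2++; else if (ay[j] < y0) a3++; }
    }
    for (size_t j = 0; j < nb; ++j) {
      if (bx[j] > x0) { if (by[j] > y0) b1++; else if (by[j] < y0) b4++; }
      else if (bx[j] < x0) { if (by[j] > y0) b2++; else if (by[j] < y0) b3++; }
    }
    double d1 = std::fabs((double)a1 / na - (double)b1 / nb);
    double d2 = std::fabs((double)a2 / na - (double)b2 / nb);
    double d3 = std::fabs((double)a3 / na - (double)b3 / nb);
    double d4 = std::fabs((double)a4 / na - (double)b4 / nb);
    dmax = std::max(dmax, std::max(std::max(d1, d2), std::max(d3, d4)));
  }
  return dmax;
}

// [[Rcpp::export]]
double ks2d_stat_(NumericMatrix a, NumericMatrix b) {
  std::vector<double> ax(a.nrow()), ay(a.nrow()), bx(b.nrow()), by(b.nrow());
  for (int i = 0; i < a.nrow(); ++i) { ax[i] = a(i, 0); ay[i] = a(i, 1); }
  for (int i = 0; i < b.nrow(); ++i) { bx[i] = b(i, 0); by[i] = b(i, 1); }
  double d1 = ff_max_diff(ax, ay, bx, by, ax, ay);
  double d2 = ff_max_diff(ax, ay, bx, by, bx, by);
  return 0.5 * (d1 + d2);
}

// [[Rcpp::export]]
NumericVector ks2d_perm_(NumericMatrix a, NumericMatrix b, int n_perm, double seed) {
  int na = a.nrow(), nb = b.nrow(), n = na + nb;
  std::vector<double> px(n), py(n);
  for (int i = 0; i < na; ++i) { px[i] = a(i, 0); py[i] = a(i, 1); }
  for (int i = 0; i < nb; ++i) { px[na + i] = b(i, 0); py[na + i] = b(i, 1); }
  std::mt19937_64 g((uint64_t)seed);
  std::vector<int> idx(n);
  NumericVector out(n_perm);
  std::vector<double> ax(na), ay(na), bx(nb), by(nb);
  for (int r = 0; r < n_perm; ++r) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = n - 1; i > 0; --i) std::swap(idx[i], idx[rint_below(g, i + 1)]);
    for (int i = 0; i < na; ++i) { ax[i] = px[idx[i]]; ay[i] = py[idx[i]]; }
    for (int i = 0; i < nb; ++i) { bx[i] = px[idx[na + i]]; by[i] = py[idx[na + i]]; }
    double d1 = ff_max_diff(ax, ay, bx, by, ax, ay);
    double d2 = ff_max_diff(ax, ay, bx, by, bx, by);
    out[r] = 0.5 * (d1 + d2);
  }
  return out;
}

// ------------------------------------------- marker-based watershed (Meyer)

// priority-flood watershed of an elevation map from labeled seeds;
// 4-connected flooding, ties broken by insertion order
// [[Rcpp::export]]
IntegerMatrix watershed_markers_(NumericMatrix elevation, IntegerMatrix seeds) {
  int W = elevation.nrow(), H = elevation.ncol();
  if (seeds.nrow() != W || seeds.ncol() != H)
    stop("seeds must match the elevation map");
  IntegerMatrix lab(W, H);
  struct Node { double e; long long order; int x, y; };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.e != b.e) return a.e > b.e;
      return a.order > b.order;
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> q;
  long long ord = 0;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      lab(x, y) = seeds(x, y);
      if (seeds(x, y) > 0) q.push({elevation(x, y), ord++, x, y});
    }
  const int dx4[4] = {1, -1, 0, 0}, dy4[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    Node n = q.top(); q.pop();
    int l = lab(n.x, n.y);
    for (int k = 0; k < 4; ++k) {
      int ux = n.x + dx4[k], uy = n.y + dy4[k];
      if (ux < 0 || uy < 0 || ux >= W || uy >= H) continue;
      if (lab(ux, uy) == 0) {
        lab(ux, uy) = l;
        q.push({elevation(ux, uy), ord++, ux, uy});
      }
    }
  }
  return lab;
}
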