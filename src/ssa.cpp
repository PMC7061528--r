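#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
#include <algorithm>

using namespace Rcpp;

// Binding-site-resolved Gillespie engine.
//
// Reaction set for S species and R regulatory sites:
//   synthesis  per gene j:   g0[j] * prod_{bound sites on j} lambda
//   degradation per gene j:  k[j] * n[j]          (free copies only)
//   binding    per free site r:  scale[r]*h[r] * C(n_src, m) falling-factorial
//                                law (m=1: n; m=2: n(n-1)/2; m=4: n..(n-3)/6)
//   unbinding  per bound site r: f[r]
// Binding sequesters m copies of the source species; unbinding releases them.
// Waiting times are exponential in the total propensity (exact SSA).

static inline double bind_law(double h, int m, double n) {
  if (n < m) return 0.0;
  switch (m) {
  case 1: return h * n;
  case 2: return h * n * (n - 1.0) / 2.0;
  case 4: return h * n * (n - 1.0) * (n - 2.0) * (n - 3.0) / 6.0;
  default: stop("multimer order must be 1, 2 or 4");
  }
  return 0.0; // unreachable
}

struct Model {
  int S, R;
  std::vector<double> g0, k;          // per species
  std::vector<int> src, tgt, m;       // per site
  std::vector<double> h, f, lam;      // per site (h already strength-scaled)
  // adjacency: sites sourced by species; sites targeting species
  std::vector< std::vector<int> > sites_by_src, sites_by_tgt;
};

static Model unpack_model(const List& mod) {
  Model M;
  NumericVector g0 = mod["g0"], k = mod["k"];
  IntegerVector src = mod["src"], tgt = mod["tgt"], mm = mod["m"];
  NumericVector h = mod["h"], f = mod["f"], lam = mod["lam"];
  M.S = g0.size(); M.R = src.size();
  M.g0.assign(g0.begin(), g0.end());
  M.k.assign(k.begin(), k.end());
  M.h.assign(h.begin(), h.end());
  M.f.assign(f.begin(), f.end());
  M.lam.assign(lam.begin(), lam.end());
  M.src.resize(M.R); M.tgt.resize(M.R); M.m.resize(M.R);
  M.sites_by_src.resize(M.S); M.sites_by_tgt.resize(M.S);
  for (int r = 0; r < M.R; ++r) {
    M.src[r] = src[r]; M.tgt[r] = tgt[r]; M.m[r] = mm[r];
    if (M.src[r] < 0 || M.src[r] >= M.S || M.tgt[r] < 0 || M.tgt[r] >= M.S)
      stop("site source/target index out of range");
    M.sites_by_src[M.src[r]].push_back(r);
    M.sites_by_tgt[M.tgt[r]].push_back(r);
  }
  return M;
}

// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(List mod,
                 IntegerVector n0,
                 IntegerVector bound0,
                 double t_max,
                 double burn_in,
                 double record_every,
                 IntegerVector hist_axes,   // length 3, 0-based species, or length 0
                 double hist_bin,
                 int hist_nbin,
                 LogicalVector target_mask, // voxel mask (nbin^3) or length 0
                 double max_events) {
  Model M = unpack_model(mod);
  if ((int)n0.size() != M.S) stop("n0 length mismatch");
  if ((int)bound0.size() != M.R) stop("bound0 length mismatch");

  std::vector<double> n(M.S);
  std::vector<int> bound(M.R);
  for (int j = 0; j < M.S; ++j) n[j] = n0[j];
  for (int r = 0; r < M.R; ++r) bound[r] = bound0[r];

  const bool do_hist = hist_axes.size() == 3;
  std::vector<double> hist;
  int ax0 = 0, ax1 = 0, ax2 = 0;
  if (do_hist) {
    ax0 = hist_axes[0]; ax1 = hist_axes[1]; ax2 = hist_axes[2];
    hist.assign((size_t)hist_nbin * hist_nbin * hist_nbin, 0.0);
  }
  const bool do_target = target_mask.size() > 0;
  if (do_target && !do_hist) stop("first-passage mode needs histogram axes");

  const bool do_rec = R_finite(record_every) && record_every > 0;
  std::vector<double> rec_t;
  std::vector<double> rec_n; // row-major S columns
  double next_rec = 0.0;

  // synthesis propensity of gene j given current occupancy
  std::vector<double> syn(M.S), deg(M.S), pbind(M.R), punb(M.R);
  auto syn_rate = [&](int j) {
    double g = M.g0[j];
    for (int r : M.sites_by_tgt[j]) if (bound[r]) g *= M.lam[r];
    return g;
  };
  double total = 0.0;
  auto refresh = [&]() {
    for (int j = 0; j < M.S; ++j) { syn[j] = syn_rate(j); deg[j] = M.k[j] * n[j]; }
    for (int r = 0; r < M.R; ++r) {
      pbind[r] = bound[r] ? 0.0 : bind_law(M.h[r], M.m[r], n[M.src[r]]);
      punb[r] = bound[r] ? M.f[r] : 0.0;
    }
    total = 0.0;
    for (int j = 0; j < M.S; ++j) total += syn[j] + deg[j];
    for (int r = 0; r < M.R; ++r) total += pbind[r] + punb[r];
  };
  refresh();
  // incremental update of a propensity slot, keeping `total` in sync
  auto setp = [&](double& slot, double v) { total += v - slot; slot = v; };

  double t = 0.0, events = 0.0, fp_time = NA_REAL;
  bool absorbed = false;
  const bool hist_live = do_hist && !do_target;

  auto flush_records = [&](double upto) {
    // record the state held on [t, upto); state changes happen at `upto`
    while (next_rec < upto && next_rec <= t_max) {
      rec_t.push_back(next_rec);
      for (int j = 0; j < M.S; ++j) rec_n.push_back(n[j]);
      next_rec += record_every;
    }
  };

  GetRNGstate();
  while (t < t_max && events < max_events) {
    // guard against float drift of the running total
    if (((long long)events & 0xFFFFF) == 0xFFFFF) refresh();
    if (total <= 0.0) {
      absorbed = true;
      if (hist_live) { // absorbing state holds until t_max
        double w = t_max - std::max(t, burn_in);
        if (w > 0.0) {
          int i0 = (int)(n[ax0] / hist_bin), i1 = (int)(n[ax1] / hist_bin),
              i2 = (int)(n[ax2] / hist_bin);
          if (i0 >= hist_nbin) i0 = hist_nbin - 1;
          if (i1 >= hist_nbin) i1 = hist_nbin - 1;
          if (i2 >= hist_nbin) i2 = hist_nbin - 1;
          hist[(size_t)i0 + (size_t)hist_nbin * (i1 + (size_t)hist_nbin * i2)] += w;
        }
      }
      break;
    }

    double dt = -std::log(unif_rand()) / total;
    double t_new = t + dt;
    if (t_new > t_max) dt = t_max - t, t_new = t_max;

    if (hist_live) {
      // time-weighted occupancy of the pre-jump state, excluding burn-in
      double w = std::min(t_new, t_max) - std::max(t, burn_in);
      if (w > 0.0) {
        int i0 = (int)(n[ax0] / hist_bin), i1 = (int)(n[ax1] / hist_bin),
            i2 = (int)(n[ax2] / hist_bin);
        if (i0 >= hist_nbin) i0 = hist_nbin - 1;
        if (i1 >= hist_nbin) i1 = hist_nbin - 1;
        if (i2 >= hist_nbin) i2 = hist_nbin - 1;
        hist[(size_t)i0 + (size_t)hist_nbin * (i1 + (size_t)hist_nbin * i2)] += w;
      }
    }
    if (do_rec) flush_records(t_new);
    if (t_new >= t_max) { t = t_max; break; }
    t = t_new;

    // pick reaction
    double u = unif_rand() * total, acc = 0.0;
    int kind = -1, idx = -1;
    for (int j = 0; j < M.S && kind < 0; ++j) {
      acc += syn[j]; if (u < acc) { kind = 0; idx = j; break; }
      acc += deg[j]; if (u < acc) { kind = 1; idx = j; break; }
    }
    if (kind < 0) for (int r = 0; r < M.R; ++r) {
      acc += pbind[r]; if (u < acc) { kind = 2; idx = r; break; }
      acc += punb[r]; if (u < acc) { kind = 3; idx = r; break; }
    }
    if (kind < 0) { refresh(); continue; } // running-total drift: re-sync

    if (kind == 0) {            // synthesis
      n[idx] += 1.0;
      setp(deg[idx], M.k[idx] * n[idx]);
      for (int r : M.sites_by_src[idx])
        if (!bound[r]) setp(pbind[r], bind_law(M.h[r], M.m[r], n[idx]));
    } else if (kind == 1) {     // degradation
      n[idx] -= 1.0;
      setp(deg[idx], M.k[idx] * n[idx]);
      for (int r : M.sites_by_src[idx])
        if (!bound[r]) setp(pbind[r], bind_law(M.h[r], M.m[r], n[idx]));
    } else if (kind == 2) {     // binding: sequester m copies, set flag
      int s = M.src[idx];
      n[s] -= M.m[idx];
      bound[idx] = 1;
      setp(pbind[idx], 0.0); setp(punb[idx], M.f[idx]);
      setp(deg[s], M.k[s] * n[s]);
      setp(syn[M.tgt[idx]], syn_rate(M.tgt[idx]));
      for (int r : M.sites_by_src[s])
        if (!bound[r]) setp(pbind[r], bind_law(M.h[r], M.m[r], n[s]));
    } else {                    // unbinding
      int s = M.src[idx];
      n[s] += M.m[idx];
      bound[idx] = 0;
      setp(punb[idx], 0.0);
      setp(pbind[idx], bind_law(M.h[idx], M.m[idx], n[s]));
      setp(deg[s], M.k[s] * n[s]);
      setp(syn[M.tgt[idx]], syn_rate(M.tgt[idx]));
      for (int r : M.sites_by_src[s])
        if (!bound[r] && r != idx) setp(pbind[r], bind_law(M.h[r], M.m[r], n[s]));
    }
    events += 1.0;

    if (do_target) {
      int i0 = (int)(n[ax0] / hist_bin), i1 = (int)(n[ax1] / hist_bin),
          i2 = (int)(n[ax2] / hist_bin);
      if (i0 < hist_nbin && i1 < hist_nbin && i2 < hist_nbin) {
        size_t v = (size_t)i0 + (size_t)hist_nbin * (i1 + (size_t)hist_nbin * i2);
        if (target_mask[v]) { fp_time = t; break; }
      }
    }
  }
  PutRNGstate();
  // state is constant from the last event to t_max; emit trailing records
  if (do_rec && !do_target && (t >= t_max || absorbed))
    flush_records(t_max + record_every);

  List out;
  out["time"] = t;
  out["events"] = events;
  out["absorbed"] = absorbed;
  out["fp_time"] = fp_time;
  out["n_final"] = NumericVector(n.begin(), n.end());
  out["bound_final"] = IntegerVector(bound.begin(), bound.end());
  if (do_rec) {
    int nr = rec_t.size();
    NumericMatrix rec(nr, M.S + 1);
    for (int i = 0; i < nr; ++i) {
      rec(i, 0) = rec_t[i];
      for (int j = 0; j < M.S; ++j) rec(i, j + 1) = rec_n[(size_t)i * M.S + j];
    }
    out["records"] = rec;
  } else {
    out["records"] = R_NilValue;
  }
  if (do_hist && !do_target) {
    NumericVector hv(hist.begin(), hist.end());
    hv.attr("dim") = IntegerVector::create(hist_nbin, hist_nbin, hist_nbin);
    out["occupancy"] = hv;
  } else {
    out["occupancy"] = R_NilValue;
  }
  return out;
}

// Steepest-descent watershed on a 2D/3D potential array.
// Voxels with non-finite U are off-support. Returns 1-based labels (NA off
// support) and the linear indices (1-based) of the basin minima.
// [[Rcpp::export(name = ".watershed_cpp")]]
List watershed_cpp(NumericVector U, IntegerVector dims) {
  const int nd = dims.size();
  size_t n = 1;
  std::vector<int> d(nd), mult(nd);
  for (int k = 0; k < nd; ++k) { d[k] = dims[k]; mult[k] = (int)n; n *= dims[k]; }
  if ((size_t)U.size() != n) stop("U length does not match dims");

  std::vector<size_t> sup;
  sup.reserve(n);
  for (size_t i = 0; i < n; ++i) if (R_finite(U[i])) sup.push_back(i);
  std::sort(sup.begin(), sup.end(),
            [&](size_t a, size_t b) { return U[a] < U[b] || (U[a] == U[b] && a < b); });

  IntegerVector lab(n, NA_INTEGER);
  std::vector<int> minima;
  std::vector<int> coord(nd);
  for (size_t s = 0; s < sup.size(); ++s) {
    size_t i = sup[s];
    size_t rem = i;
    for (int k = 0; k < nd; ++k) { coord[k] = rem % d[k]; rem /= d[k]; }
    int best = NA_INTEGER;
    double bestU = R_PosInf;
    for (int k = 0; k < nd; ++k) {
      for (int step = -1; step <= 1; step += 2) {
        int c = coord[k] + step;
        if (c < 0 || c >= d[k]) continue;
        size_t j = i + (size_t)((long long)step * mult[k]);
        if (lab[j] == NA_INTEGER) continue;
        if (U[j] <= U[i] && U[j] < bestU) { best = lab[j]; bestU = U[j]; }
      }
    }
    if (best == NA_INTEGER) {
      minima.push_back((int)i + 1);
      lab[i] = (int)minima.size();
    } else {
      lab[i] = best;
    }
  }
  return List::create(_["labels"] = lab,
                      _["minima"] = IntegerVector(minima.begin(), minima.end()));
}

// Minimax saddle levels between marked minima on a 2D/3D potential array.
// Ascending union-find sweep over the support (finite U) with 2d-connectivity:
// the recorded level for a pair is the lowest U at which their components
// merge, i.e. the minimax over grid paths of the maximal U en route.
// `minima` are 1-based linear voxel indices. Returns nb x nb saddle-U matrix
// (Inf where disconnected) and 1-based saddle voxel indices (NA likewise).
// [[Rcpp::export(name = ".minimax_saddles_cpp")]]
List minimax_saddles_cpp(NumericVector U, IntegerVector dims, IntegerVector minima) {
  const int nd = dims.size();
  size_t n = 1;
  std::vector<long long> d(nd), mult(nd);
  for (int k = 0; k < nd; ++k) { d[k] = dims[k]; mult[k] = (long long)n; n *= dims[k]; }
  if ((size_t)U.size() != n) stop("U length does not match dims");
  const int nb = minima.size();

  std::vector<int> key(n, -1);
  for (int b = 0; b < nb; ++b) key[minima[b] - 1] = b;

  std::vector<size_t> sup;
  sup.reserve(n);
  for (size_t i = 0; i < n; ++i) if (R_finite(U[i])) sup.push_back(i);
  std::sort(sup.begin(), sup.end(),
            [&](size_t a, size_t b) { return U[a] < U[b] || (U[a] == U[b] && a < b); });

  std::vector<size_t> parent(n);
  for (size_t i = 0; i < n; ++i) parent[i] = i;
  std::function<size_t(size_t)> find = [&](size_t i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  // minima carried by each root
  std::vector< std::vector<int> > carries(n);
  std::vector<char> processed(n, 0);

  NumericMatrix sadU(nb, nb);
  IntegerMatrix sadV(nb, nb);
  std::fill(sadU.begin(), sadU.end(), R_PosInf);
  std::fill(sadV.begin(), sadV.end(), NA_INTEGER);
  long long pendingPairs = (long long)nb * (nb - 1) / 2;

  std::vector<int> coord(nd);
  for (size_t s = 0; s < sup.size() && pendingPairs > 0; ++s) {
    size_t i = sup[s];
    size_t rem = i;
    for (int k = 0; k < nd; ++k) { coord[k] = rem % d[k]; rem /= d[k]; }
    if (key[i] >= 0) carries[i].push_back(key[i]);
    processed[i] = 1;
    for (int k = 0; k < nd; ++k) {
      for (int step = -1; step <= 1; step += 2) {
        long long c = coord[k] + step;
        if (c < 0 || c >= d[k]) continue;
        size_t j = (size_t)((long long)i + step * mult[k]);
        if (!processed[j]) continue;
        size_t ri = find(i), rj = find(j);
        if (ri == rj) continue;
        std::vector<int>& ci = carries[ri];
        std::vector<int>& cj = carries[rj];
        if (!ci.empty() && !cj.empty()) {
          for (int a : ci) for (int b : cj) {
            if (!R_finite(sadU(a, b))) {
              sadU(a, b) = sadU(b, a) = U[i];
              sadV(a, b) = sadV(b, a) = (int)i + 1;
              --pendingPairs;
            }
          }
        }
        parent[rj] = ri;
        if (!cj.empty()) {
          ci.insert(ci.end(), cj.begin(), cj.end());
          cj.clear();
        }
      }
    }
  }
  return List::create(_["U_saddle"] = sadU, _["voxel"] = sadV);
}
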