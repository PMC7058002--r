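// Core numerical kernels: Gaussian-basis orbital evaluation, CI wavefunction
// values, linear-assignment permutation folding, and the Metropolis walker
// loop (sequential single-electron updates with Sherman-Morrison /
// determinant-lemma ratio evaluation).  All randomness comes from R's RNG,
// so runs are reproducible via set.seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

namespace {

// Unpacked wavefunction data (one R list -> POD struct, built once per call)
struct WF {
  arma::imat lmn;     // nao x 3 cartesian powers
  mat cen;            // nao x 3 centres (bohr)
  arma::ivec nprim;   // primitives per AO
  mat exps, coefs;    // nao x maxprim (normalisation folded into coefs)
  mat C;              // nao x nmo MO coefficients
  arma::imat occA;    // nterm x na, 0-based MO columns, ascending
  arma::imat occB;    // nterm x nb
  vec coef;           // CI coefficients
  int na, nb, nao, nmo, nterm;
};

WF unpack_wf(const List& w) {
  WF f;
  f.lmn = as<arma::imat>(w["lmn"]);
  f.cen = as<mat>(w["cen"]);
  f.nprim = as<arma::ivec>(w["nprim"]);
  f.exps = as<mat>(w["exps"]);
  f.coefs = as<mat>(w["coefs"]);
  f.C = as<mat>(w["C"]);
  f.occA = as<arma::imat>(w["occA"]);
  f.occB = as<arma::imat>(w["occB"]);
  f.coef = as<vec>(w["coef"]);
  f.na = f.occA.n_cols;
  f.nb = f.occB.n_cols;
  f.nao = f.lmn.n_rows;
  f.nmo = f.C.n_cols;
  f.nterm = f.coef.n_elem;
  return f;
}

// AO values at one point
void ao_eval_point(const WF& f, const double* p, double* out) {
  for (int m = 0; m < f.nao; ++m) {
    const double dx = p[0] - f.cen(m, 0);
    const double dy = p[1] - f.cen(m, 1);
    const double dz = p[2] - f.cen(m, 2);
    const double r2 = dx * dx + dy * dy + dz * dz;
    double rad = 0.0;
    for (int q = 0; q < f.nprim(m); ++q) {
      const double e = f.exps(m, q) * r2;
      if (e < 40.0) rad += f.coefs(m, q) * std::exp(-e);
    }
    if (rad == 0.0) { out[m] = 0.0; continue; }
    double poly = 1.0;
    for (int t = 0; t < f.lmn(m, 0); ++t) poly *= dx;
    for (int t = 0; t < f.lmn(m, 1); ++t) poly *= dy;
    for (int t = 0; t < f.lmn(m, 2); ++t) poly *= dz;
    out[m] = poly * rad;
  }
}

// AO values at a set of points: out(npt, nao)
void ao_eval_into(const WF& f, const mat& pts, mat& out) {
  std::vector<double> row(f.nao);
  for (arma::uword p = 0; p < pts.n_rows; ++p) {
    double xyz[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    ao_eval_point(f, xyz, row.data());
    for (int m = 0; m < f.nao; ++m) out(p, m) = row[m];
  }
}

// Psi at one configuration by direct determinant evaluation (reference
// route; the sampler uses incremental ratios and is cross-checked against
// this in the test suite).
double psi_of_config(const WF& f, const mat& pts, mat& ao_ws, mat& mo_ws) {
  const int N = f.na + f.nb;
  ao_eval_into(f, pts, ao_ws);
  mo_ws = ao_ws * f.C;  // N x nmo
  double tot = 0.0;
  mat Ma(f.na, f.na), Mb(f.nb, f.nb);
  for (int t = 0; t < f.nterm; ++t) {
    for (int j = 0; j < f.na; ++j)
      for (int i = 0; i < f.na; ++i)
        Ma(i, j) = mo_ws(i, f.occA(t, j));
    for (int j = 0; j < f.nb; ++j)
      for (int i = 0; i < f.nb; ++i)
        Mb(i, j) = mo_ws(f.na + i, f.occB(t, j));
    double da = (f.na > 0) ? arma::det(Ma) : 1.0;
    double db = (f.nb > 0) ? arma::det(Mb) : 1.0;
    tot += f.coef(t) * da * db;
  }
  (void)N;
  return tot;
}

// Jonker-Volgenant style shortest-augmenting-path linear assignment.
struct LapWS {
  std::vector<double> u, v, minv;
  std::vector<int> p, way;
  std::vector<char> used;
  void resize(int n) {
    u.assign(n + 1, 0.0); v.assign(n + 1, 0.0); minv.assign(n + 1, 0.0);
    p.assign(n + 1, 0); way.assign(n + 1, 0); used.assign(n + 1, 0);
  }
};

// Returns row assigned to each column (0-based) in ws.p; writes min cost.
void lap_solve(const mat& cost, double& total, std::vector<int>& rowofcol,
               LapWS& ws) {
  const int n = cost.n_rows;
  ws.resize(n);
  std::vector<double>& u = ws.u;
  std::vector<double>& v = ws.v;
  std::vector<double>& minv = ws.minv;
  std::vector<int>& p = ws.p;
  std::vector<int>& way = ws.way;
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), arma::datum::inf);
    std::fill(ws.used.begin(), ws.used.end(), 0);
    do {
      ws.used[j0] = 1;
      const int i0 = p[j0];
      int j1 = 0;
      double delta = arma::datum::inf;
      for (int j = 1; j <= n; ++j) {
        if (ws.used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (ws.used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { const int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  rowofcol.resize(n);
  total = 0.0;
  for (int j = 1; j <= n; ++j) {
    rowofcol[j - 1] = p[j] - 1;
    total += cost(p[j] - 1, j - 1);
  }
}

int perm_parity(const std::vector<int>& perm) {
  const int n = perm.size();
  std::vector<char> seen(n, 0);
  int par = 0;
  for (int i = 0; i < n; ++i) {
    if (seen[i]) continue;
    int len = 0, j = i;
    while (!seen[j]) { seen[j] = 1; j = perm[j]; ++len; }
    par += (len - 1);
  }
  return (par % 2 == 0) ? 1 : -1;
}

// squared-distance cost between an electron block and a site block
void block_cost(const mat& pts, const mat& site, int from, int nel,
                mat& cost) {
  for (int i = 0; i < nel; ++i)
    for (int j = 0; j < nel; ++j) {
      const double dx = pts(from + i, 0) - site(from + j, 0);
      const double dy = pts(from + i, 1) - site(from + j, 1);
      const double dz = pts(from + i, 2) - site(from + j, 2);
      cost(i, j) = dx * dx + dy * dy + dz * dz;
    }
}

struct Fold {
  std::vector<int> pa, pb;  // site slot j <- electron pa[j] (0-based)
  double sqdist;
  int parity;
};

struct FoldWS {
  mat ca, cb;
  LapWS lap;
  void init(int na, int nb) {
    ca.set_size(std::max(na, 1), std::max(na, 1));
    cb.set_size(std::max(nb, 1), std::max(nb, 1));
  }
};

Fold fold_to_site(const mat& pts, const mat& site, int na, int nb,
                  FoldWS& ws) {
  Fold f;
  double ca = 0.0, cb = 0.0;
  if (na > 0) {
    block_cost(pts, site, 0, na, ws.ca);
    lap_solve(ws.ca, ca, f.pa, ws.lap);
  }
  if (nb > 0) {
    block_cost(pts, site, na, nb, ws.cb);
    lap_solve(ws.cb, cb, f.pb, ws.lap);
  }
  f.sqdist = ca + cb;
  f.parity = (na > 0 ? perm_parity(f.pa) : 1) *
             (nb > 0 ? perm_parity(f.pb) : 1);
  return f;
}

mat config_as_mat(const vec& x, int N) {
  mat pts(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) pts(i, k) = x(3 * i + k);
  return pts;
}

// ---- incremental per-walker wavefunction state (multi-determinant VMC) --

// per-spin, per-configuration difference from the reference determinant
struct SpinDiffs {
  int n;                       // electrons of this spin
  std::vector<int> refocc;     // reference occupied MO columns (ascending)
  std::vector<int> k;          // excitation rank per term
  std::vector<std::vector<int> > pos;  // replaced positions in refocc
  std::vector<std::vector<int> > ins;  // new MO columns
  std::vector<double> sgn;     // parity to sort the replaced column list
};

SpinDiffs make_diffs(const arma::imat& occ) {
  SpinDiffs d;
  const int nterm = occ.n_rows;
  d.n = occ.n_cols;
  d.refocc.resize(d.n);
  for (int j = 0; j < d.n; ++j) d.refocc[j] = occ(0, j);
  d.k.resize(nterm);
  d.pos.resize(nterm);
  d.ins.resize(nterm);
  d.sgn.resize(nterm);
  for (int t = 0; t < nterm; ++t) {
    std::vector<int> tocc(d.n);
    for (int j = 0; j < d.n; ++j) tocc[j] = occ(t, j);
    std::vector<int> out_pos, in_col;
    for (int j = 0; j < d.n; ++j) {
      if (!std::binary_search(tocc.begin(), tocc.end(), d.refocc[j]))
        out_pos.push_back(j);
    }
    for (int j = 0; j < d.n; ++j) {
      if (!std::binary_search(d.refocc.begin(), d.refocc.end(), tocc[j]))
        in_col.push_back(tocc[j]);
    }
    d.k[t] = out_pos.size();
    d.pos[t] = out_pos;
    d.ins[t] = in_col;
    // sign: parity to sort the position-ordered column list ascending
    std::vector<int> L(d.refocc);
    for (size_t c = 0; c < out_pos.size(); ++c) L[out_pos[c]] = in_col[c];
    int inv = 0;
    for (size_t a = 0; a < L.size(); ++a)
      for (size_t b = a + 1; b < L.size(); ++b)
        if (L[a] > L[b]) ++inv;
    d.sgn[t] = (inv % 2 == 0) ? 1.0 : -1.0;
  }
  return d;
}

double small_det(const mat& B, int k) {
  if (k == 0) return 1.0;
  if (k == 1) return B(0, 0);
  if (k == 2) return B(0, 0) * B(1, 1) - B(0, 1) * B(1, 0);
  if (k == 3)
    return B(0, 0) * (B(1, 1) * B(2, 2) - B(1, 2) * B(2, 1))
         - B(0, 1) * (B(1, 0) * B(2, 2) - B(1, 2) * B(2, 0))
         + B(0, 2) * (B(1, 0) * B(2, 1) - B(1, 1) * B(2, 0));
  return arma::det(B.submat(0, 0, k - 1, k - 1));
}

struct WalkerState {
  mat pts;       // N x 3
  mat M;         // N x nmo MO values
  mat AinvA, AinvB;          // per-spin inverse of reference matrix
  vec rhoA, rhoB;            // per-term det ratios (incl. sort sign)
  double S;                  // sum_t c_t rhoA_t rhoB_t
  int psi_sign;              // current sign of Psi (flips only on odd folds)
  bool degenerate;           // reference determinant singular
};

struct Kernel {
  const WF* f;
  SpinDiffs da, db;
  int N, kmax;
  mat Bws;        // kmax x kmax scratch
  mat Ainv_new;   // scratch inverse
  std::vector<double> ao_row, mo_row;

  void init(const WF& wf) {
    f = &wf;
    da = make_diffs(wf.occA);
    db = make_diffs(wf.occB);
    N = wf.na + wf.nb;
    kmax = 1;
    for (int t = 0; t < wf.nterm; ++t) {
      kmax = std::max(kmax, da.k[t]);
      kmax = std::max(kmax, db.k[t]);
    }
    Bws.set_size(kmax, kmax);
    Ainv_new.set_size(std::max(wf.na, wf.nb), std::max(wf.na, wf.nb));
    ao_row.resize(wf.nao);
    mo_row.resize(wf.nmo);
  }

  // rho for all terms of one spin from Ainv and M (direct route)
  void rho_direct(const SpinDiffs& d, const mat& Ainv, const mat& M,
                  int row0, vec& rho) {
    const int nterm = f->nterm;
    rho.set_size(nterm);
    for (int t = 0; t < nterm; ++t) {
      const int k = d.k[t];
      for (int r = 0; r < k; ++r)
        for (int c = 0; c < k; ++c) {
          double s = 0.0;
          for (int j = 0; j < d.n; ++j)
            s += Ainv(d.pos[t][r], j) * M(row0 + j, d.ins[t][c]);
          Bws(r, c) = s;
        }
      rho(t) = d.sgn[t] * small_det(Bws, k);
    }
  }

  // full (re)build of walker state from positions; returns false if the
  // reference determinant is singular
  bool refresh(WalkerState& st) {
    mat ao(N, f->nao);
    ao_eval_into(*f, st.pts, ao);
    st.M = ao * f->C;
    return rebuild_from_M(st);
  }

  // cheap rebuild after an electron relabelling: MO values move with the
  // electrons, so only the rows of M are permuted (no AO re-evaluation)
  bool refold(WalkerState& st, const std::vector<int>& pa,
              const std::vector<int>& pb) {
    mat Mold = st.M;
    for (size_t j = 0; j < pa.size(); ++j) st.M.row(j) = Mold.row(pa[j]);
    for (size_t j = 0; j < pb.size(); ++j)
      st.M.row(f->na + j) = Mold.row(f->na + pb[j]);
    return rebuild_from_M(st);
  }

  bool rebuild_from_M(WalkerState& st) {
    bool ok = true;
    if (f->na > 0) {
      mat A(f->na, f->na);
      for (int i = 0; i < f->na; ++i)
        for (int j = 0; j < f->na; ++j)
          A(i, j) = st.M(i, da.refocc[j]);
      ok = ok && arma::inv(st.AinvA, A);
    }
    if (f->nb > 0) {
      mat A(f->nb, f->nb);
      for (int i = 0; i < f->nb; ++i)
        for (int j = 0; j < f->nb; ++j)
          A(i, j) = st.M(f->na + i, db.refocc[j]);
      ok = ok && arma::inv(st.AinvB, A);
    }
    st.degenerate = !ok;
    if (!ok) return false;
    if (f->na > 0) rho_direct(da, st.AinvA, st.M, 0, st.rhoA);
    else st.rhoA = vec(f->nterm, arma::fill::ones);
    if (f->nb > 0) rho_direct(db, st.AinvB, st.M, f->na, st.rhoB);
    else st.rhoB = vec(f->nterm, arma::fill::ones);
    st.S = 0.0;
    for (int t = 0; t < f->nterm; ++t)
      st.S += f->coef(t) * st.rhoA(t) * st.rhoB(t);
    return true;
  }

  // attempt a single-electron Metropolis trial; returns true if accepted
  bool try_move(WalkerState& st, int e, const double* newp, double uacc,
                long& n_signrej) {
    const bool is_alpha = e < f->na;
    const SpinDiffs& d = is_alpha ? da : db;
    mat& Ainv = is_alpha ? st.AinvA : st.AinvB;
    vec& rho = is_alpha ? st.rhoA : st.rhoB;
    const vec& rho_other = is_alpha ? st.rhoB : st.rhoA;
    const int row0 = is_alpha ? 0 : f->na;
    const int i = e - row0;  // local row
    const int n = d.n;

    ao_eval_point(*f, newp, ao_row.data());
    // mo_row = ao_row * C
    for (int m = 0; m < f->nmo; ++m) mo_row[m] = 0.0;
    for (int a = 0; a < f->nao; ++a) {
      const double v = ao_row[a];
      if (v == 0.0) continue;
      const double* Crow = f->C.colptr(0) + a;  // stride nao
      for (int m = 0; m < f->nmo; ++m)
        mo_row[m] += v * Crow[(size_t)m * f->nao];
    }
    // delta over reference occupied columns; w = delta^T Ainv; r = 1 + w_i
    double r = 1.0;
    std::vector<double> dlt(n), w(n, 0.0);
    for (int j = 0; j < n; ++j)
      dlt[j] = mo_row[d.refocc[j]] - st.M(e, d.refocc[j]);
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int l = 0; l < n; ++l) s += dlt[l] * Ainv(l, j);
      w[j] = s;
    }
    r += w[i];
    if (!std::isfinite(r) || std::abs(r) < 1e-14) { ++n_signrej; return false; }
    // updated inverse into scratch
    for (int l = 0; l < n; ++l) {
      const double q = Ainv(l, i) / r;
      for (int j = 0; j < n; ++j)
        Ainv_new(l, j) = Ainv(l, j) - q * w[j];
    }
    // new rho for this spin (M row e replaced by mo_row)
    double Snew = 0.0;
    std::vector<double> rho_new(f->nterm);
    for (int t = 0; t < f->nterm; ++t) {
      const int k = d.k[t];
      for (int rr = 0; rr < k; ++rr)
        for (int c = 0; c < k; ++c) {
          double s = 0.0;
          const int col = d.ins[t][c];
          for (int j = 0; j < n; ++j) {
            const double mv = (j == i) ? mo_row[col] : st.M(row0 + j, col);
            s += Ainv_new(d.pos[t][rr], j) * mv;
          }
          Bws(rr, c) = s;
        }
      rho_new[t] = d.sgn[t] * small_det(Bws, k);
      Snew += f->coef(t) * rho_new[t] * rho_other(t);
    }
    const double ratio = r * (Snew / st.S);
    if (!(ratio > 0.0)) { ++n_signrej; return false; }
    if (ratio < 1.0 && uacc >= ratio * ratio) return false;
    // accept
    st.pts(e, 0) = newp[0]; st.pts(e, 1) = newp[1]; st.pts(e, 2) = newp[2];
    for (int m = 0; m < f->nmo; ++m) st.M(e, m) = mo_row[m];
    Ainv = Ainv_new.submat(0, 0, n - 1, n - 1);
    for (int t = 0; t < f->nterm; ++t) rho(t) = rho_new[t];
    st.S = Snew;
    return true;
  }
};

}  // namespace

// [[Rcpp::export(name = ".ao_values_cpp")]]
arma::mat ao_values_cpp(const List& wf, const arma::mat& pts) {
  WF f = unpack_wf(wf);
  mat out(pts.n_rows, f.nao);
  ao_eval_into(f, pts, out);
  return out;
}

// [[Rcpp::export(name = ".psi_batch_cpp")]]
arma::vec psi_batch_cpp(const List& wf, const arma::mat& X) {
  // X: m x 3N configurations, rows independent; direct determinant route
  WF f = unpack_wf(wf);
  const int N = f.na + f.nb;
  if ((int)X.n_cols != 3 * N) stop("configuration length != 3*(na+nb)");
  vec out(X.n_rows);
  mat ao_ws(N, f.nao), mo_ws(N, f.nmo);
  for (arma::uword r = 0; r < X.n_rows; ++r) {
    mat pts = config_as_mat(X.row(r).t(), N);
    out(r) = psi_of_config(f, pts, ao_ws, mo_ws);
  }
  return out;
}

// [[Rcpp::export(name = ".lap_cpp")]]
List lap_cpp(const arma::mat& cost) {
  if (cost.n_rows != cost.n_cols) stop("cost matrix must be square");
  double total;
  std::vector<int> a;
  LapWS ws;
  lap_solve(cost, total, a, ws);
  IntegerVector rowofcol(a.size());
  for (size_t i = 0; i < a.size(); ++i) rowofcol[i] = a[i] + 1;
  return List::create(_["row_of_col"] = rowofcol, _["cost"] = total);
}

// [[Rcpp::export(name = ".best_fold_cpp")]]
List best_fold_cpp(const arma::vec& x, const arma::vec& site, int na, int nb) {
  const int N = na + nb;
  if ((int)x.n_elem != 3 * N || x.n_elem != site.n_elem)
    stop("dimension mismatch between configuration and site");
  mat pts = config_as_mat(x, N);
  mat st = config_as_mat(site, N);
  FoldWS ws;
  ws.init(na, nb);
  Fold f = fold_to_site(pts, st, na, nb, ws);
  vec folded(3 * N);
  for (int j = 0; j < na; ++j)
    for (int k = 0; k < 3; ++k) folded(3 * j + k) = pts(f.pa[j], k);
  for (int j = 0; j < nb; ++j)
    for (int k = 0; k < 3; ++k)
      folded(3 * (na + j) + k) = pts(na + f.pb[j], k);
  IntegerVector pa(na), pb(nb);
  for (int j = 0; j < na; ++j) pa[j] = f.pa[j] + 1;
  for (int j = 0; j < nb; ++j) pb[j] = f.pb[j] + 1;
  return List::create(_["folded"] = folded, _["alpha_perm"] = pa,
                      _["beta_perm"] = pb, _["parity"] = f.parity,
                      _["sq_distance"] = f.sqdist);
}

// [[Rcpp::export(name = ".nearest_site_cpp")]]
List nearest_site_cpp(const arma::vec& x, const arma::mat& sites,
                      int na, int nb) {
  const int N = na + nb;
  if ((int)x.n_elem != 3 * N) stop("dimension mismatch");
  mat pts = config_as_mat(x, N);
  FoldWS ws;
  ws.init(na, nb);
  int best = -1;
  double bestd = arma::datum::inf;
  for (arma::uword s = 0; s < sites.n_rows; ++s) {
    mat st = config_as_mat(sites.row(s).t(), N);
    Fold f = fold_to_site(pts, st, na, nb, ws);
    if (f.sqdist < bestd - 1e-12) { bestd = f.sqdist; best = s; }
  }
  return List::create(_["index"] = best + 1, _["sq_distance"] = bestd);
}

// [[Rcpp::export(name = ".classify_batch_cpp")]]
IntegerVector classify_batch_cpp(const arma::mat& X, const arma::mat& sites,
                                 int na, int nb) {
  const int N = na + nb;
  if ((int)X.n_cols != 3 * N) stop("dimension mismatch");
  std::vector<mat> site_pts;
  for (arma::uword s = 0; s < sites.n_rows; ++s)
    site_pts.push_back(config_as_mat(sites.row(s).t(), N));
  FoldWS ws;
  ws.init(na, nb);
  IntegerVector out(X.n_rows);
  for (arma::uword r = 0; r < X.n_rows; ++r) {
    mat pts = config_as_mat(X.row(r).t(), N);
    int best = -1;
    double bestd = arma::datum::inf;
    for (size_t s = 0; s < site_pts.size(); ++s) {
      Fold f = fold_to_site(pts, site_pts[s], na, nb, ws);
      if (f.sqdist < bestd - 1e-12) { bestd = f.sqdist; best = s; }
    }
    out[r] = best + 1;
  }
  return out;
}

// The Metropolis walker loop: one step = one sweep of sequential
// single-electron Gaussian trials (variance step_sd^2 per dimension of the
// moved electron), Metropolis-accepted on |Psi|^2 with node-crossing
// (sign-change) rejection.
//   pos: W x 3N walker positions (alpha block then beta block)
//   sites: nsite x 3N reference sites for on-the-fly classification
//          (0 rows to disable)
//   fold_site: 1-based index of the site walkers are folded back to after
//          each step (0 to disable folding)
//   burn_frac: fraction of initial steps excluded from the centroid
//   scheme: 0 = sweep (every electron tried once per step), 1 = single
//          (one uniformly chosen electron tried per step)
// [[Rcpp::export(name = ".run_walk_cpp")]]
List run_walk_cpp(const arma::mat& pos0, const List& wf, int n_steps,
                  double step_sd, const arma::mat& sites, int fold_site,
                  double burn_frac, int scheme) {
  WF f = unpack_wf(wf);
  const int W = pos0.n_rows;
  const int N = f.na + f.nb;
  const int D = 3 * N;
  if ((int)pos0.n_cols != D) stop("walker dimension != 3*(na+nb)");
  const int nsite = sites.n_rows;
  const int refresh_every = 100;

  Kernel kern;
  kern.init(f);
  std::vector<WalkerState> st(W);
  std::vector<mat> site_pts;
  for (int s = 0; s < nsite; ++s)
    site_pts.push_back(config_as_mat(sites.row(s).t(), N));
  FoldWS fws;
  fws.init(f.na, f.nb);

  mat ao_ws(N, f.nao), mo_ws(N, f.nmo);
  for (int w = 0; w < W; ++w) {
    st[w].pts = config_as_mat(pos0.row(w).t(), N);
    const double p0 = psi_of_config(f, st[w].pts, ao_ws, mo_ws);
    if (p0 == 0.0)
      stop("walker %d starts on a node (psi = 0); choose another start",
           w + 1);
    if (!kern.refresh(st[w]))
      stop("reference determinant singular at the start configuration");
    st[w].psi_sign = (p0 > 0) ? 1 : -1;
  }

  arma::imat counts(std::max(n_steps, 1), std::max(nsite, 1),
                    arma::fill::zeros);
  vec centroid(D, arma::fill::zeros);
  long n_centroid = 0, n_acc = 0, n_signrej = 0, n_fold = 0, n_oddfold = 0;
  long n_trials = 0;
  const int burn = (int)std::floor(burn_frac * n_steps);
  RNGScope scope;

  for (int k = 0; k < n_steps; ++k) {
    for (int w = 0; w < W; ++w) {
      WalkerState& s = st[w];
      const int ntry = (scheme == 1) ? 1 : N;
      for (int tr = 0; tr < ntry; ++tr) {
        const int e = (scheme == 1)
            ? std::min(N - 1, (int)(unif_rand() * N)) : tr;
        double np[3];
        np[0] = s.pts(e, 0) + step_sd * norm_rand();
        np[1] = s.pts(e, 1) + step_sd * norm_rand();
        np[2] = s.pts(e, 2) + step_sd * norm_rand();
        const double uacc = unif_rand();
        ++n_trials;
        if (kern.try_move(s, e, np, uacc, n_signrej)) ++n_acc;
      }
      if ((k + 1) % refresh_every == 0 && !kern.refresh(s))
        stop("reference determinant became singular during the walk");
      if (fold_site >= 1) {
        Fold fd = fold_to_site(s.pts, site_pts[fold_site - 1], f.na, f.nb,
                               fws);
        bool ident = true;
        for (int j = 0; j < f.na && ident; ++j) ident = (fd.pa[j] == j);
        for (int j = 0; j < f.nb && ident; ++j) ident = (fd.pb[j] == j);
        if (!ident) {
          ++n_fold;
          if (fd.parity < 0) ++n_oddfold;
          mat cur = s.pts;
          for (int j = 0; j < f.na; ++j)
            for (int t = 0; t < 3; ++t) s.pts(j, t) = cur(fd.pa[j], t);
          for (int j = 0; j < f.nb; ++j)
            for (int t = 0; t < 3; ++t)
              s.pts(f.na + j, t) = cur(f.na + fd.pb[j], t);
          s.psi_sign *= fd.parity;
          if (!kern.refold(s, fd.pa, fd.pb))
            stop("reference determinant became singular after folding");
        }
      }
      if (nsite > 0) {
        int best = -1;
        double bestd = arma::datum::inf;
        for (int si = 0; si < nsite; ++si) {
          Fold fd = fold_to_site(s.pts, site_pts[si], f.na, f.nb, fws);
          if (fd.sqdist < bestd - 1e-12) { bestd = fd.sqdist; best = si; }
        }
        counts(k, best) += 1;
      }
      if (k >= burn) {
        for (int e = 0; e < N; ++e)
          for (int t = 0; t < 3; ++t) centroid(3 * e + t) += s.pts(e, t);
        ++n_centroid;
      }
    }
    if (k % 32 == 0) Rcpp::checkUserInterrupt();
  }
  if (n_centroid > 0) centroid /= (double)n_centroid;

  mat pos_out(W, D);
  vec psi_out(W);
  for (int w = 0; w < W; ++w) {
    for (int e = 0; e < N; ++e)
      for (int t = 0; t < 3; ++t) pos_out(w, 3 * e + t) = st[w].pts(e, t);
    psi_out(w) = psi_of_config(f, st[w].pts, ao_ws, mo_ws);
  }
  return List::create(
      _["positions"] = pos_out, _["psi"] = psi_out,
      _["counts"] = (nsite > 0 && n_steps > 0) ? wrap(counts) : R_NilValue,
      _["centroid"] = centroid, _["n_centroid"] = (double)n_centroid,
      _["acceptance"] = n_trials > 0 ? (double)n_acc / n_trials : NA_REAL,
      _["n_sign_reject"] = (double)n_signrej,
      _["n_fold"] = (double)n_fold, _["n_odd_fold"] = (double)n_oddfold);
}
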