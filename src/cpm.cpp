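#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Lattice conventions: spin matrices are indexed (row, col) = (y, x) with the
// origin at the top-left site; sites outside the grid are medium (spin 0).
// Perimeters are counted as ordered discordant site pairs within a Euclidean
// ball of radius `radius` and rescaled by 1/xi at the R level or where noted.

static inline double sq(double x) { return x * x; }

struct Offsets {
  std::vector<int> dy, dx;
  int n;
  Offsets(double radius) {
    int R = (int)std::floor(radius + 1e-9);
    for (int a = -R; a <= R; ++a)
      for (int b = -R; b <= R; ++b) {
        if (a == 0 && b == 0) continue;
        if (a * a + b * b <= radius * radius + 1e-9) {
          dy.push_back(a);
          dx.push_back(b);
        }
      }
    n = (int)dy.size();
  }
};

// Moore neighborhood, clockwise ring order starting at top-left; consecutive
// entries are 4-adjacent, which the local connectivity test relies on.
static const int RING_DY[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
static const int RING_DX[8] = {-1, 0, 1, 1, 1, 0, -1, -1};

struct Engine {
  IntegerMatrix spin;
  int H, W, nc;
  NumericVector a, p, la, lp;
  IntegerVector type;
  NumericMatrix J;
  double xi;
  Offsets off;
  std::vector<double> A, D;  // per cell id 0..nc (index 0 = medium, unused)
  std::vector<double> M;     // (nc+1)^2 ordered discordant pair counts
  std::vector<int> stamp;    // flood-fill scratch
  int gen;
  std::vector<int> cen_spin;  // neighbor-census scratch
  std::vector<double> cen_cnt;

  Engine(IntegerMatrix spin_, NumericVector a_, NumericVector p_,
         NumericVector la_, NumericVector lp_, IntegerVector type_,
         NumericMatrix J_, double radius, double xi_)
      : spin(spin_), H(spin_.nrow()), W(spin_.ncol()), nc(a_.size()), a(a_),
        p(p_), la(la_), lp(lp_), type(type_), J(J_), xi(xi_), off(radius),
        A(nc + 1, 0.0), D(nc + 1, 0.0), M((nc + 1) * (nc + 1), 0.0),
        stamp(H * W, 0), gen(0), cen_spin(off.n + 1), cen_cnt(off.n + 1) {
    recount();
  }

  inline int sp(int r, int c) const {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return spin(r, c);
  }
  inline double &Mat(int i, int j) { return M[i * (nc + 1) + j]; }

  void recount() {
    std::fill(A.begin(), A.end(), 0.0);
    std::fill(D.begin(), D.end(), 0.0);
    std::fill(M.begin(), M.end(), 0.0);
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        int s = spin(r, c);
        if (s > 0) A[s] += 1;
        for (int k = 0; k < off.n; ++k) {
          int s2 = sp(r + off.dy[k], c + off.dx[k]);
          if (s2 != s) {
            Mat(s, s2) += 1;
            D[s] += 1;
          }
        }
      }
  }

  // Contact-energy contribution of changing the ordered+mirrored pair count
  // of {i, j} by dm raw pairs.  scope = 0: total Hamiltonian; scope = cell id:
  // only that cell's per-cell share (half of each cell-cell interface).
  inline double jterm(int i, int j, double dm, int scope) const {
    if (i == j) return 0.0;
    double Jv;
    if (i == 0 || j == 0) {
      int cell = (i == 0) ? j : i;
      Jv = J(0, type[cell - 1]);
    } else {
      Jv = J(type[i - 1], type[j - 1]);
    }
    double x = dm / xi;
    if (scope == 0) return Jv * x;
    if (i != scope && j != scope) return 0.0;
    if (i == 0 || j == 0) return Jv * x;
    return 0.5 * Jv * x;
  }

  // Energy change of copying spin `snew` onto site (r, c).
  double deltaH(int r, int c, int snew, int scope) {
    int sold = spin(r, c);
    double dH = 0.0;
    if (sold > 0 && (scope == 0 || scope == sold))
      dH += la[sold - 1] *
            (sq(A[sold] - 1 - a[sold - 1]) - sq(A[sold] - a[sold - 1]));
    if (snew > 0 && (scope == 0 || scope == snew))
      dH += la[snew - 1] *
            (sq(A[snew] + 1 - a[snew - 1]) - sq(A[snew] - a[snew - 1]));

    // neighbor spin census
    int *spins = cen_spin.data();
    double *cnt = cen_cnt.data();
    int k = 0, n_old = 0, n_new = 0;
    for (int m = 0; m < off.n; ++m) {
      int cc = sp(r + off.dy[m], c + off.dx[m]);
      if (cc == sold) ++n_old;
      if (cc == snew) ++n_new;
      int f = -1;
      for (int t = 0; t < k; ++t)
        if (spins[t] == cc) { f = t; break; }
      if (f < 0) {
        spins[k] = cc;
        cnt[k] = 1;
        ++k;
      } else {
        cnt[f] += 1;
      }
    }

    if (sold > 0 && (scope == 0 || scope == sold)) {
      double Dn = D[sold] + 2.0 * n_old - off.n;
      dH += lp[sold - 1] * (sq(Dn / xi - p[sold - 1]) -
                            sq(D[sold] / xi - p[sold - 1]));
    }
    if (snew > 0 && (scope == 0 || scope == snew)) {
      double Dn = D[snew] + off.n - 2.0 * n_new;
      dH += lp[snew - 1] * (sq(Dn / xi - p[snew - 1]) -
                            sq(D[snew] / xi - p[snew - 1]));
    }
    for (int t = 0; t < k; ++t) {
      dH += jterm(sold, spins[t], -cnt[t], scope);
      dH += jterm(snew, spins[t], +cnt[t], scope);
    }
    return dH;
  }

  void apply(int r, int c, int snew) {
    int sold = spin(r, c);
    if (sold > 0) A[sold] -= 1;
    if (snew > 0) A[snew] += 1;
    for (int m = 0; m < off.n; ++m) {
      int cc = sp(r + off.dy[m], c + off.dx[m]);
      if (cc != sold) {
        Mat(sold, cc) -= 1;
        Mat(cc, sold) -= 1;
        D[sold] -= 1;
        D[cc] -= 1;
      }
      if (cc != snew) {
        Mat(snew, cc) += 1;
        Mat(cc, snew) += 1;
        D[snew] += 1;
        D[cc] += 1;
      }
    }
    spin(r, c) = snew;
  }

  // Would removing site (r, c) from its cell keep the remainder 4-connected?
  // Fast local ring test first (sufficient when the cell's Moore neighbors of
  // the site form one 4-connected arc), exact flood fill as fallback.
  bool conn_ok(int r, int c) {
    int id = spin(r, c);
    if (id <= 0) return true;
    if (A[id] <= 1) return true;  // vacuously connected (cell vanishes)
    bool m[8];
    for (int k = 0; k < 8; ++k)
      m[k] = (sp(r + RING_DY[k], c + RING_DX[k]) == id);
    int blocks = 0;
    for (int k = 0; k < 8; ++k)
      if (m[k] && !m[(k + 7) % 8]) ++blocks;
    if (blocks <= 1) return true;
    // flood fill over the cell excluding (r, c)
    ++gen;
    stamp[r * W + c] = gen;  // mark removed site visited so BFS avoids it
    int start_r = -1, start_c = -1;
    for (int k = 1; k < 8; k += 2) {  // 4-neighbors sit at odd ring indices
      int rr = r + RING_DY[k], ccol = c + RING_DX[k];
      if (sp(rr, ccol) == id) { start_r = rr; start_c = ccol; break; }
    }
    if (start_r < 0) return false;
    std::vector<int> queue;
    queue.push_back(start_r * W + start_c);
    stamp[start_r * W + start_c] = gen;
    size_t head = 0;
    double reached = 1;
    while (head < queue.size()) {
      int pos = queue[head++];
      int rr = pos / W, cc2 = pos % W;
      for (int k = 1; k < 8; k += 2) {
        int r2 = rr + RING_DY[k], c2 = cc2 + RING_DX[k];
        if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
        int pos2 = r2 * W + c2;
        if (stamp[pos2] == gen) continue;
        if (spin(r2, c2) == id) {
          stamp[pos2] = gen;
          queue.push_back(pos2);
          reached += 1;
        }
      }
    }
    return reached == A[id] - 1;
  }

  double hamiltonian_total() const {
    double Hsum = 0.0;
    for (int i = 1; i <= nc; ++i) {
      Hsum += la[i - 1] * sq(A[i] - a[i - 1]);
      Hsum += lp[i - 1] * sq(D[i] / xi - p[i - 1]);
      Hsum += J(0, type[i - 1]) * M[i * (nc + 1) + 0] / xi;
      for (int j = 1; j <= nc; ++j)
        if (j != i)
          Hsum += 0.5 * J(type[i - 1], type[j - 1]) * M[i * (nc + 1) + j] / xi;
    }
    return Hsum;
  }
};

// Redistribute the chemical mass held at (r, c) — about to leave cell `id` —
// onto same-cell sites within `radius`, proportionally to their current
// content (uniformly if the neighborhood holds none), doubling the radius
// until a recipient exists.  The source site is zeroed.
static void redistribute_site(NumericMatrix &q, const IntegerMatrix &spin,
                              int r, int c, int id, double radius) {
  int H = spin.nrow(), W = spin.ncol();
  double mass = q(r, c);
  q(r, c) = 0.0;
  if (mass == 0.0) return;
  double rad = radius;
  double maxdim = (double)std::max(H, W);
  for (;;) {
    int R = (int)std::floor(rad + 1e-9);
    int r0 = std::max(0, r - R), r1 = std::min(H - 1, r + R);
    int c0 = std::max(0, c - R), c1 = std::min(W - 1, c + R);
    double tot = 0.0;
    int nsite = 0;
    for (int rr = r0; rr <= r1; ++rr)
      for (int cc = c0; cc <= c1; ++cc) {
        if (rr == r && cc == c) continue;
        double d2 = sq(rr - r) + sq(cc - c);
        if (d2 > rad * rad + 1e-9) continue;
        if (spin(rr, cc) == id) {
          tot += q(rr, cc);
          ++nsite;
        }
      }
    if (nsite > 0) {
      for (int rr = r0; rr <= r1; ++rr)
        for (int cc = c0; cc <= c1; ++cc) {
          if (rr == r && cc == c) continue;
          double d2 = sq(rr - r) + sq(cc - c);
          if (d2 > rad * rad + 1e-9) continue;
          if (spin(rr, cc) == id) {
            if (tot > 0.0)
              q(rr, cc) += mass * q(rr, cc) / tot;
            else
              q(rr, cc) += mass / nsite;
          }
        }
      return;
    }
    if (rad > 2.0 * maxdim) return;  // cell vanished; drop mass (unreachable for connected cells)
    rad *= 2.0;
  }
}

// [[Rcpp::export]]
List cpp_state_counts(IntegerMatrix spin, double radius, NumericVector a,
                      NumericVector p, NumericVector la, NumericVector lp,
                      IntegerVector type, NumericMatrix J, double xi) {
  Engine e(clone(spin), a, p, la, lp, type, J, radius, xi);
  int nc = e.nc;
  NumericVector A(nc), D(nc);
  NumericMatrix M(nc + 1, nc + 1);
  for (int i = 1; i <= nc; ++i) {
    A[i - 1] = e.A[i];
    D[i - 1] = e.D[i];
  }
  for (int i = 0; i <= nc; ++i)
    for (int j = 0; j <= nc; ++j) M(i, j) = e.M[i * (nc + 1) + j];
  return List::create(_["area"] = A, _["discordant"] = D, _["pairs"] = M,
                      _["hamiltonian"] = e.hamiltonian_total());
}

// [[Rcpp::export]]
double cpp_delta_h(IntegerMatrix spin, double radius, NumericVector a,
                   NumericVector p, NumericVector la, NumericVector lp,
                   IntegerVector type, NumericMatrix J, double xi, int row,
                   int col, int snew, int scope) {
  Engine e(clone(spin), a, p, la, lp, type, J, radius, xi);
  return e.deltaH(row - 1, col - 1, snew, scope);
}

// [[Rcpp::export]]
bool cpp_connectivity_preserved(IntegerMatrix spin, int row, int col) {
  // standalone exact test (ring fast path + flood fill), 1-based site
  int nc = 0;
  for (int i = 0; i < spin.size(); ++i) nc = std::max(nc, spin[i]);
  NumericVector z(nc);
  IntegerVector ty2(nc, 1);
  NumericMatrix J2(2, 2);
  Engine e(clone(spin), z, z, z, z, ty2, J2, 1.0, 1.0);
  return e.conn_ok(row - 1, col - 1);
}

// [[Rcpp::export]]
IntegerMatrix cpp_site_discordant(IntegerMatrix spin, double radius) {
  int H = spin.nrow(), W = spin.ncol();
  Offsets off(radius);
  IntegerMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int s = spin(r, c);
      int cnt = 0;
      for (int k = 0; k < off.n; ++k) {
        int rr = r + off.dy[k], cc = c + off.dx[k];
        int s2 = (rr < 0 || rr >= H || cc < 0 || cc >= W) ? 0 : spin(rr, cc);
        if (s2 != s) ++cnt;
      }
      out(r, c) = cnt;
    }
  return out;
}

// [[Rcpp::export]]
List cpp_run_mcs(IntegerMatrix spin, int n_mcs, NumericVector a,
                 NumericVector p, NumericVector la, NumericVector lp,
                 IntegerVector type, NumericMatrix J, double radius, double xi,
                 double temp, double h0, bool coupled, NumericMatrix u,
                 NumericMatrix v, double beta, double r_active,
                 double r_inactive) {
  IntegerMatrix sp2 = clone(spin);
  NumericMatrix u2 = coupled ? clone(u) : NumericMatrix(1, 1);
  NumericMatrix v2 = coupled ? clone(v) : NumericMatrix(1, 1);
  Engine e(sp2, a, p, la, lp, type, J, radius, xi);
  int H = e.H, W = e.W;
  long attempts = 0, accepted = 0;
  double dh_sum = 0.0, dhu_sum = 0.0;
  RNGScope scope_;
  for (int step = 0; step < n_mcs; ++step) {
    int N = H * W;
    for (int it = 0; it < N; ++it) {
      ++attempts;
      int sr = (int)(unif_rand() * H);
      int scol = (int)(unif_rand() * W);
      if (sr >= H) sr = H - 1;
      if (scol >= W) scol = W - 1;
      int k = (int)(unif_rand() * 8);
      if (k >= 8) k = 7;
      int tr = sr + RING_DY[k], tc = scol + RING_DX[k];
      if (tr < 0 || tr >= H || tc < 0 || tc >= W) continue;
      int snew = sp2(sr, scol);
      int sold = sp2(tr, tc);
      if (snew == sold) continue;
      if (sold > 0 && !e.conn_ok(tr, tc)) continue;
      // a gained site must touch its new cell through a 4-neighbor, or the
      // gaining cell would no longer be 4-connected
      if (snew > 0) {
        bool touch4 = false;
        for (int k4 = 1; k4 < 8 && !touch4; k4 += 2)
          if (e.sp(tr + RING_DY[k4], tc + RING_DX[k4]) == snew) touch4 = true;
        if (!touch4) continue;
      }
      double dH = e.deltaH(tr, tc, snew, 0);
      double dHu = 0.0;
      if (coupled) {
        if (snew > 0) dHu += beta * u2(sr, scol);  // protrusion of gaining cell
        if (sold > 0) dHu -= beta * u2(tr, tc);    // retraction of losing cell
      }
      double x = dH + dHu + h0;
      bool acc;
      if (x <= 0.0)
        acc = true;
      else if (temp > 0.0)
        acc = (unif_rand() < std::exp(-x / temp));
      else
        acc = false;
      if (!acc) continue;
      if (coupled && sold > 0) {
        redistribute_site(u2, sp2, tr, tc, sold, r_active);
        redistribute_site(v2, sp2, tr, tc, sold, r_inactive);
      }
      e.apply(tr, tc, snew);
      ++accepted;
      dh_sum += dH;
      dhu_sum += dHu;
    }
  }
  return List::create(_["spin"] = sp2, _["u"] = u2, _["v"] = v2,
                      _["attempts"] = (double)attempts,
                      _["accepted"] = (double)accepted, _["dh_sum"] = dh_sum,
                      _["dhu_sum"] = dhu_sum,
                      _["hamiltonian"] = e.hamiltonian_total());
}

// Boundary forces for one cell (id > 0) or all cells (id = 0).
// Components follow the centered-difference rule: at a boundary site the
// +axis and -axis variant configurations advance the cell's boundary one
// site in each direction (protrusion / retraction spin copies); the force
// is minus the difference of the cell's own Hamiltonian share over 2h.
// [[Rcpp::export]]
List cpp_boundary_forces(IntegerMatrix spin, double radius, NumericVector a,
                         NumericVector p, NumericVector la, NumericVector lp,
                         IntegerVector type, NumericMatrix J, double xi,
                         double h, int id) {
  Engine e(clone(spin), a, p, la, lp, type, J, radius, xi);
  int H = e.H, W = e.W;
  std::vector<int> xs, ys, ids, wts;
  std::vector<double> fxs, fys;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int i = e.spin(r, c);
      if (i <= 0) continue;
      if (id > 0 && i != id) continue;
      bool boundary = false;
      for (int k = 0; k < 8 && !boundary; ++k)
        if (e.sp(r + RING_DY[k], c + RING_DX[k]) != i) boundary = true;
      if (!boundary) continue;
      int wt = 0;  // local perimeter contribution (raw discordant pairs)
      for (int k = 0; k < e.off.n; ++k)
        if (e.sp(r + e.off.dy[k], c + e.off.dx[k]) != i) ++wt;

      double fx = 0.0, fy = 0.0;
      // x component
      int lsp = e.sp(r, c - 1), rsp = e.sp(r, c + 1);
      if (lsp == i && rsp != i) {
        // right-hand boundary: +x protrudes into (r, c+1), -x retracts (r, c)
        if (c + 1 < W) {
          double plus = e.deltaH(r, c + 1, i, i);
          double minus = e.deltaH(r, c, rsp, i);
          fx = -(plus - minus) / (2.0 * h);
        }
      } else if (rsp == i && lsp != i) {
        // left-hand boundary: +x retracts (r, c), -x protrudes into (r, c-1)
        if (c - 1 >= 0) {
          double plus = e.deltaH(r, c, lsp, i);
          double minus = e.deltaH(r, c - 1, i, i);
          fx = -(plus - minus) / (2.0 * h);
        }
      }
      // y component (y increases downward)
      int usp = e.sp(r - 1, c), dsp = e.sp(r + 1, c);
      if (usp == i && dsp != i) {
        // bottom boundary: +y protrudes into (r+1, c), -y retracts (r, c)
        if (r + 1 < H) {
          double plus = e.deltaH(r + 1, c, i, i);
          double minus = e.deltaH(r, c, dsp, i);
          fy = -(plus - minus) / (2.0 * h);
        }
      } else if (dsp == i && usp != i) {
        if (r - 1 >= 0) {
          double plus = e.deltaH(r, c, usp, i);
          double minus = e.deltaH(r - 1, c, i, i);
          fy = -(plus - minus) / (2.0 * h);
        }
      }
      xs.push_back(c + 1);
      ys.push_back(r + 1);
      ids.push_back(i);
      wts.push_back(wt);
      fxs.push_back(fx);
      fys.push_back(fy);
    }
  return List::create(_["x"] = xs, _["y"] = ys, _["cell_id"] = ids,
                      _["fx"] = fxs, _["fy"] = fys, _["weight"] = wts);
}

// Explicit Euler steps of the wave-pinning reaction-diffusion system on cell
// interiors; diffusion acts between 4-neighbor sites of the same cell
// (zero-flux at every cell boundary), in conservative flux form.
// [[Rcpp::export]]
List cpp_rd_steps(NumericMatrix u, NumericMatrix v, IntegerMatrix spin,
                  double Du, double Dv, double k0, double gamma_fb, double K,
                  double eta, double dt, double h, int nsteps) {
  int H = spin.nrow(), W = spin.ncol();
  NumericMatrix u0 = clone(u), v0 = clone(v);
  NumericMatrix u1(H, W), v1(H, W);
  double ih2 = 1.0 / (h * h);
  for (int s = 0; s < nsteps; ++s) {
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        int id = spin(r, c);
        if (id <= 0) {
          u1(r, c) = 0.0;
          v1(r, c) = 0.0;
          continue;
        }
        double lu = 0.0, lv = 0.0;
        static const int dy4[4] = {-1, 1, 0, 0};
        static const int dx4[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int rr = r + dy4[k], cc = c + dx4[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (spin(rr, cc) != id) continue;
          lu += u0(rr, cc) - u0(r, c);
          lv += v0(rr, cc) - v0(r, c);
        }
        double uu = u0(r, c), vv = v0(r, c);
        double f = vv * (k0 + gamma_fb * uu * uu / (K * K + uu * uu)) - eta * uu;
        u1(r, c) = uu + dt * (Du * ih2 * lu + f);
        v1(r, c) = vv + dt * (Dv * ih2 * lv - f);
      }
    std::swap(u0, u1);
    std::swap(v0, v1);
  }
  return List::create(_["u"] = u0, _["v"] = v0);
}

// [[Rcpp::export]]
NumericMatrix cpp_redistribute(NumericMatrix q, IntegerMatrix spin, int row,
                               int col, int id, double radius) {
  NumericMatrix q2 = clone(q);
  redistribute_site(q2, spin, row - 1, col - 1, id, radius);
  return q2;
}
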