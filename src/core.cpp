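#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <deque>
using namespace Rcpp;

// Grid cells are addressed in R's column-major order: idx = col * nrow + row
// (0-based here; R wrappers convert). Row 0 is the top raster row.

static inline int cidx(int row, int col, int nrow) { return col * nrow + row; }

// Sum of x over the foraging disk (center-to-center distance <= radius_cells),
// clipped at the grid boundary. Exact row-segment algorithm: per row offset dr
// the disk spans columns [-w, w] with w = floor(sqrt(r^2 - dr^2)); each
// segment sum comes from per-row prefix sums, so results carry no kernel
// truncation error and presence (result > 0) is exact for nonnegative input.
static void disk_sum_into(const double* x, int nrow, int ncol,
                          double radius_cells, double* out) {
  int R = (int)std::floor(radius_cells);
  double r2 = radius_cells * radius_cells;
  std::vector<int> w(2 * R + 1);
  for (int dr = -R; dr <= R; ++dr) {
    double rem = r2 - (double)dr * dr;
    w[dr + R] = rem >= 0 ? (int)std::floor(std::sqrt(rem)) : -1;
  }
  // prefix sums per grid row: P[row][c+1] = sum of x over columns 0..c
  std::vector<double> P((size_t)nrow * (ncol + 1), 0.0);
  for (int row = 0; row < nrow; ++row) {
    double acc = 0.0;
    double* Pr = &P[(size_t)row * (ncol + 1)];
    Pr[0] = 0.0;
    for (int col = 0; col < ncol; ++col) {
      acc += x[cidx(row, col, nrow)];
      Pr[col + 1] = acc;
    }
  }
  for (int col = 0; col < ncol; ++col) {
    for (int row = 0; row < nrow; ++row) {
      double s = 0.0;
      for (int dr = -R; dr <= R; ++dr) {
        int rr = row + dr;
        if (rr < 0 || rr >= nrow) continue;
        int ww = w[dr + R];
        if (ww < 0) continue;
        int lo = col - ww; if (lo < 0) lo = 0;
        int hi = col + ww; if (hi >= ncol) hi = ncol - 1;
        const double* Pr = &P[(size_t)rr * (ncol + 1)];
        s += Pr[hi + 1] - Pr[lo];
      }
      out[cidx(row, col, nrow)] = s;
    }
  }
}

// Number of in-bounds cells in the foraging disk of each cell.
static void disk_count_into(int nrow, int ncol, double radius_cells, double* out) {
  int R = (int)std::floor(radius_cells);
  double r2 = radius_cells * radius_cells;
  std::vector<int> w(2 * R + 1);
  for (int dr = -R; dr <= R; ++dr) {
    double rem = r2 - (double)dr * dr;
    w[dr + R] = rem >= 0 ? (int)std::floor(std::sqrt(rem)) : -1;
  }
  for (int col = 0; col < ncol; ++col) {
    for (int row = 0; row < nrow; ++row) {
      double n = 0.0;
      for (int dr = -R; dr <= R; ++dr) {
        int rr = row + dr;
        if (rr < 0 || rr >= nrow) continue;
        int ww = w[dr + R];
        if (ww < 0) continue;
        int lo = col - ww; if (lo < 0) lo = 0;
        int hi = col + ww; if (hi >= ncol) hi = ncol - 1;
        n += hi - lo + 1;
      }
      out[cidx(row, col, nrow)] = n;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_disk_sum(NumericVector x, int nrow, int ncol, double radius_cells) {
  NumericVector out(x.size());
  disk_sum_into(x.begin(), nrow, ncol, radius_cells, out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_disk_count(int nrow, int ncol, double radius_cells) {
  NumericVector out(nrow * ncol);
  disk_count_into(nrow, ncol, radius_cells, out.begin());
  return out;
}

// 4-connected components of equal-valued cells; labels 1..K in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label4(IntegerVector grid, int nrow, int ncol) {
  int ncell = nrow * ncol;
  IntegerVector lab(ncell, 0);
  int next = 0;
  std::deque<int> q;
  for (int start = 0; start < ncell; ++start) {
    if (lab[start] != 0) continue;
    int val = grid[start];
    lab[start] = ++next;
    q.clear();
    q.push_back(start);
    while (!q.empty()) {
      int cur = q.front(); q.pop_front();
      int row = cur % nrow, col = cur / nrow;
      const int nr[4] = {row - 1, row + 1, row, row};
      const int nc[4] = {col, col, col - 1, col + 1};
      for (int k = 0; k < 4; ++k) {
        if (nr[k] < 0 || nr[k] >= nrow || nc[k] < 0 || nc[k] >= ncol) continue;
        int nb = cidx(nr[k], nc[k], nrow);
        if (lab[nb] == 0 && grid[nb] == val) {
          lab[nb] = next;
          q.push_back(nb);
        }
      }
    }
  }
  return lab;
}

// Bitmask of habitat classes present within the foraging disk of each cell,
// per radius. Bits 0..5 = land-use codes (ABZ cells excluded from their
// arable bit), bit 6 = ABZ pseudo-class.
// [[Rcpp::export]]
IntegerMatrix cpp_presence_masks(IntegerVector landuse, LogicalVector abz,
                                 int nrow, int ncol, NumericVector radii_cells) {
  int ncell = nrow * ncol, nr = radii_cells.size();
  IntegerMatrix out(ncell, nr);
  std::vector<double> ind(ncell), acc(ncell);
  for (int j = 0; j < nr; ++j) {
    for (int cls = 0; cls <= 6; ++cls) {
      for (int i = 0; i < ncell; ++i) {
        bool in;
        if (cls == 6) in = abz[i];
        else in = (landuse[i] == cls) && !abz[i];
        ind[i] = in ? 1.0 : 0.0;
      }
      disk_sum_into(ind.data(), nrow, ncol, radii_cells[j], acc.data());
      for (int i = 0; i < ncell; ++i)
        if (acc[i] > 0) out(i, j) |= (1 << cls);
    }
  }
  return out;
}

// Shared occupancy/uptake machinery for the yearly growth step and for
// diagnostics (feeding-intensity maps, per-population mean uptake).
//
// For functional type j at a cell:
//   F_j      foraging abundance: sum of nesting populations of j whose
//            foraging disk covers the cell (disk sum of the nesting grid)
//   C_total  sum of competition factors c_i over types present in the cell
//            (F_i > 0; nesters are included since the focal cell lies in
//            its own disk)
//   beta_j   sum over nonconspecific types i with overlapping flying period
//            of (1 + (c_j - c_i)/C_total) * F_i, clamped at >= 0; the
//            C_total ratio is dropped when C_total = 0
//   uptake_j ((beta_j + F_j)/N_total) * suitability (printed form), or
//            (N_total/(beta_j + F_j)) * suitability (inverted form), with
//            N_total the overlapping-period foraging total; degenerate
//            ratios (0 denominator) are taken as 1
// period codes: 0 = first half of year, 1 = second half, 2 = both.
// [[Rcpp::export]]
List cpp_growth_core(NumericMatrix N, IntegerVector landuse, LogicalVector abz,
                     int nrow, int ncol,
                     NumericVector r, NumericVector cc,
                     NumericMatrix forage_suit, NumericMatrix nest_suit,
                     NumericVector trans_res, NumericVector trans_nest,
                     NumericVector b, IntegerVector period,
                     NumericVector radius_cells,
                     double weather, double k_max, double ext_thresh,
                     bool inverted, bool do_growth) {
  int ncell = nrow * ncol, S = N.ncol();
  NumericMatrix F(ncell, S), U(ncell, S), M(ncell, S);
  // foraging abundances
  for (int s = 0; s < S; ++s)
    disk_sum_into(&N(0, s), nrow, ncol, radius_cells[s], &F(0, s));
  // presence-based total competition factor per cell
  NumericVector Ctot(ncell);
  for (int s = 0; s < S; ++s) {
    double c_s = cc[s];
    for (int i = 0; i < ncell; ++i)
      if (F(i, s) > 0) Ctot[i] += c_s;
  }
  // flying-period group sums of foraging abundance (and c-weighted):
  // group 0 = overlaps "first" (periods 0,2); 1 = overlaps "second" (1,2);
  // 2 = all types
  std::vector<std::vector<double>> SF(3, std::vector<double>(ncell, 0.0));
  std::vector<std::vector<double>> ScF(3, std::vector<double>(ncell, 0.0));
  std::vector<std::vector<double>> SN(3, std::vector<double>(ncell, 0.0));
  std::vector<std::vector<double>> ScN(3, std::vector<double>(ncell, 0.0));
  for (int s = 0; s < S; ++s) {
    int p = period[s];
    double c_s = cc[s];
    for (int g = 0; g < 3; ++g) {
      bool member = (g == 2) || (p == 2) || (p == g);
      if (!member) continue;
      double* sf = SF[g].data(); double* scf = ScF[g].data();
      double* sn = SN[g].data(); double* scn = ScN[g].data();
      for (int i = 0; i < ncell; ++i) {
        double f = F(i, s), n = N(i, s);
        sf[i] += f; scf[i] += c_s * f;
        sn[i] += n; scn[i] += c_s * n;
      }
    }
  }
  // per-cell competition-dependent resource uptake
  for (int s = 0; s < S; ++s) {
    int g = period[s];
    double c_s = cc[s], tr = trans_res[s];
    const double* sf = SF[g].data(); const double* scf = ScF[g].data();
    for (int i = 0; i < ncell; ++i) {
      double Fj = F(i, s);
      double Ntot = sf[i];
      double Foth = Ntot - Fj;
      double beta = Foth;
      if (Ctot[i] > 0) beta += (c_s * Foth - (scf[i] - c_s * Fj)) / Ctot[i];
      if (beta < 0) beta = 0;
      double ratio;
      if (inverted) ratio = (beta + Fj) > 0 ? Ntot / (beta + Fj) : 1.0;
      else ratio = Ntot > 0 ? (beta + Fj) / Ntot : 1.0;
      double suit = forage_suit(s, landuse[i]) + (abz[i] ? tr : 0.0);
      U(i, s) = ratio * suit;
    }
  }
  // mean uptake over the foraging disk (in-bounds cells only)
  {
    std::vector<double> cnt(ncell);
    double last_rad = -1.0;
    // radii repeat (three foraging classes); recompute counts on change only
    std::vector<int> order(S);
    for (int s = 0; s < S; ++s) order[s] = s;
    std::sort(order.begin(), order.end(), [&](int a, int bIdx) {
      return radius_cells[a] < radius_cells[bIdx];
    });
    for (int oi = 0; oi < S; ++oi) {
      int s = order[oi];
      if (radius_cells[s] != last_rad) {
        disk_count_into(nrow, ncol, radius_cells[s], cnt.data());
        last_rad = radius_cells[s];
      }
      disk_sum_into(&U(0, s), nrow, ncol, radius_cells[s], &M(0, s));
      for (int i = 0; i < ncell; ++i) M(i, s) /= cnt[i];
    }
  }
  List out = List::create(_["F"] = F, _["uptake"] = U, _["mean_uptake"] = M,
                          _["C_total"] = Ctot);
  if (!do_growth) return out;
  // Maynard Smith-Slatkin growth with nesting-site competition in the
  // density term; synchronous update from the pre-step state
  NumericMatrix Nn(ncell, S);
  for (int s = 0; s < S; ++s) {
    int g = period[s];
    double c_s = cc[s], R_s = r[s], b_s = b[s], tn = trans_nest[s];
    const double* sn = SN[g].data(); const double* scn = ScN[g].data();
    for (int i = 0; i < ncell; ++i) {
      double n = N(i, s);
      if (n <= 0) { Nn(i, s) = 0.0; continue; }
      double K = k_max * (nest_suit(s, landuse[i]) + (abz[i] ? tn : 0.0));
      if (K <= 0) { Nn(i, s) = 0.0; continue; }
      double Noth = sn[i] - n;
      double beta = Noth;
      if (Ctot[i] > 0) beta += (c_s * Noth - (scn[i] - c_s * n)) / Ctot[i];
      if (beta < 0) beta = 0;
      double dens = std::pow((n + beta) / K, b_s);
      double nn = n * R_s * weather * M(i, s) / (1.0 + (R_s - 1.0) * dens);
      Nn(i, s) = nn < ext_thresh ? 0.0 : nn;
    }
  }
  out["N_next"] = Nn;
  return out;
}

// Density-dependent emigration followed by individual semidirected
// settlement search. All randomness uses R's RNG so set.seed() at the R
// level makes the step bit-reproducible.
// [[Rcpp::export]]
NumericMatrix cpp_dispersal_step(NumericMatrix N, NumericMatrix K,
                                 IntegerVector landuse, LogicalVector abz,
                                 int nrow, int ncol, double cell_size,
                                 NumericVector disp_mean, NumericVector disp_sd,
                                 NumericVector mu, NumericVector omega,
                                 int tries,
                                 IntegerMatrix presence, IntegerVector radius_col,
                                 NumericMatrix nest_suit, NumericVector trans_nest) {
  RNGScope scope;
  int ncell = nrow * ncol, S = N.ncol();
  NumericMatrix Nn = clone(N);
  // emigrant counts: f = min(1, mu*(N/K)^omega); K = 0 -> full emigration;
  // count = round-half-up(f*N) capped at floor(N)
  std::vector<int> e_cell, e_ft;
  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < ncell; ++i) {
      double n = Nn(i, s);
      if (n <= 0) continue;
      double Kv = K(i, s);
      double f = Kv > 0 ? std::min(1.0, mu[s] * std::pow(n / Kv, omega[s])) : 1.0;
      int cnt = (int)std::floor(f * n + 0.5);
      int cap = (int)std::floor(n);
      if (cnt > cap) cnt = cap;
      if (cnt <= 0) continue;
      Nn(i, s) = n - cnt;
      for (int k = 0; k < cnt; ++k) { e_cell.push_back(i); e_ft.push_back(s); }
    }
  }
  int M = (int)e_cell.size();
  // seeded random processing order over individuals (Fisher-Yates)
  for (int i = M - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(e_cell[i], e_cell[j]);
    std::swap(e_ft[i], e_ft[j]);
  }
  // class suitability ranking per type: 7 classes (6 land uses + ABZ as its
  // own class with suitability nest_suit[arable] + trans_effect_nest),
  // ordered by descending suitability, ties broken by ascending class code.
  // rank_cache packs, per (ft, presence mask), the rank of each class into
  // 4-bit fields plus the number of ranked classes.
  std::vector<std::vector<double>> suit7(S, std::vector<double>(7));
  std::vector<std::vector<int>> order7(S, std::vector<int>(7));
  for (int s = 0; s < S; ++s) {
    for (int c = 0; c < 6; ++c) suit7[s][c] = nest_suit(s, c);
    suit7[s][6] = nest_suit(s, 1) + trans_nest[s];
    for (int c = 0; c < 7; ++c) order7[s][c] = c;
    std::sort(order7[s].begin(), order7[s].end(), [&](int a, int bI) {
      if (suit7[s][a] != suit7[s][bI]) return suit7[s][a] > suit7[s][bI];
      return a < bI;
    });
  }
  std::vector<int> rank_cache((size_t)S * 128, -1);
  const double TWO_PI = 2.0 * M_PI;
  for (int e = 0; e < M; ++e) {
    int origin = e_cell[e], s = e_ft[e];
    int mask = presence(origin, radius_col[s]);
    int& packed = rank_cache[(size_t)s * 128 + mask];
    if (packed < 0) {
      int p = 0, nr_ = 0;
      int ranks[7];
      for (int c = 0; c < 7; ++c) ranks[c] = 0;  // 0 = unranked
      for (int oi = 0; oi < 7; ++oi) {
        int c = order7[s][oi];
        if (mask & (1 << c)) ranks[c] = ++nr_;
      }
      for (int c = 0; c < 7; ++c) p |= ranks[c] << (4 * c);
      p |= nr_ << 28;
      packed = p;
    }
    int n_ranks = (packed >> 28) & 0xF;
    double dm = disp_mean[s], ds = disp_sd[s];
    int orow = origin % nrow, ocol = origin / nrow;
    for (int k = 1; k <= tries; ++k) {
      double d;
      do { d = R::rnorm(dm, ds); } while (d <= 0);
      double theta = unif_rand() * TWO_PI;
      int drow = (int)std::lround(d * std::sin(theta) / cell_size);
      int dcol = (int)std::lround(d * std::cos(theta) / cell_size);
      int trow = orow + drow, tcol = ocol + dcol;
      if (trow < 0 || trow >= nrow || tcol < 0 || tcol >= ncol)
        continue;  // left the landscape: attempt consumed
      int tgt = cidx(trow, tcol, nrow);
      int tclass = abz[tgt] ? 6 : landuse[tgt];
      int trank = (packed >> (4 * tclass)) & 0xF;
      if (trank == 0) continue;  // class unseen in the foraging range
      int allowed = (int)std::ceil((double)k * n_ranks / tries);
      if (trank > allowed) continue;
      if (Nn(tgt, s) < K(tgt, s)) {  // capacity check, mid-step state
        Nn(tgt, s) += 1.0;
        break;
      }
    }
  }
  return Nn;
}
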