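// Compiled round loop for the swidden labour-exchange model.
//
// This is a performance port of the pure-R reference engine
// (run_round / run_simulation(engine = "r")). Both engines consume
// R's RNG stream in the same canonical order -- per round:
//   revision draws (per agent) -> N^2 helping draws (column-major)
//   -> one key per forested cell for clearing -> one draw per
//   eligible empty cell for regeneration (column-major) -> shock
//   draws (only when shocks are enabled) --
// and all floating-point expressions match the R formulations
// (long-double accumulation where R's sum()/mean() use it), so the
// two engines produce identical runs for identical seeds. The test
// suite asserts this equivalence.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Neighborhood {
  // flat neighbour lists: nbr[idx * 8 + k], k < nnbr[idx]
  std::vector<int> nbr;
  std::vector<int> nnbr;
};

Neighborhood build_neighborhood(int L, int n_neigh, bool torus) {
  Neighborhood nb;
  const int L2 = L * L;
  nb.nbr.assign((size_t)L2 * 8, -1);
  nb.nnbr.assign(L2, 0);
  int dr8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int dc8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int dr4[4] = {-1, 1, 0, 0};
  int dc4[4] = {0, 0, -1, 1};
  const int *dr = (n_neigh == 8) ? dr8 : dr4;
  const int *dc = (n_neigh == 8) ? dc8 : dc4;
  for (int col = 0; col < L; ++col) {
    for (int row = 0; row < L; ++row) {
      int idx = col * L + row;
      int cnt = 0;
      for (int k = 0; k < n_neigh; ++k) {
        int r = row + dr[k], c = col + dc[k];
        if (torus) {
          r = (r + L) % L;
          c = (c + L) % L;
        } else if (r < 0 || r >= L || c < 0 || c >= L) {
          continue;
        }
        nb.nbr[(size_t)idx * 8 + cnt] = c * L + r;
        ++cnt;
      }
      nb.nnbr[idx] = cnt;
    }
  }
  return nb;
}

// Myopic best response: enumerate x in 0..cap, expected-helper belief
// Ntilde(x) = sum_{j != i} [(1-mu_j) hist(i,j) + mu_j 1{x <= y_j}].
int myopic_best(int i, int cap, const NumericVector &y,
                const NumericVector &mu, const NumericMatrix &hist,
                int N, int h, double c) {
  if (cap <= 0) return 0;
  long double racc = 0.0L;
  for (int j = 0; j < N; ++j) {
    if (j == i) continue;
    racc += (1.0 - mu[j]) * hist(i, j);
  }
  double recip = (double)racc;
  double best_g = R_NegInf;
  int best_x = 0;
  for (int x = 0; x <= cap; ++x) {
    long double sacc = 0.0L;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      if (y[j] >= x) sacc += mu[j];
    }
    double Nt = recip + (double)sacc;
    double mh = h * (1.0 + Nt);
    double m = std::min((double)x, mh);
    double g = m - c * m / mh;
    if (g > best_g) {
      best_g = g;
      best_x = x;
    }
  }
  return best_x;
}

// Remove k uniformly chosen forest cells: one uniform key per forest
// cell in ascending cell order, k smallest keys win (same scheme and
// draw order as the R engine). Returns number removed.
int remove_forest_cells(IntegerVector &states, IntegerVector &lag,
                        int k, int l) {
  if (k <= 0) return 0;
  std::vector<std::pair<double, int> > keyed;
  const int L2 = states.size();
  for (int idx = 0; idx < L2; ++idx) {
    if (states[idx] == 1) keyed.push_back(std::make_pair(0.0, idx));
  }
  for (size_t m = 0; m < keyed.size(); ++m) keyed[m].first = unif_rand();
  if ((size_t)k > keyed.size())
    stop("internal error: clearing demand exceeds forest");
  std::partial_sort(keyed.begin(), keyed.begin() + k, keyed.end());
  for (int m = 0; m < k; ++m) {
    int idx = keyed[m].second;
    states[idx] = 0;
    if (l > 0) lag[idx] = l;
  }
  return k;
}

}  // namespace

// [[Rcpp::export]]
List sim_engine_cpp(IntegerMatrix states0, IntegerMatrix lag0,
                    IntegerVector x0, NumericVector y0, NumericVector mu,
                    NumericMatrix hist0,
                    int N, int L, int T,
                    double p0, double p1, double pmax_, double F_,
                    int h, double c0, double c, double alpha, double lambda,
                    double nu0, double nu1, double nu2, double innov_sd,
                    int l, double p_sh, double f_sh, int shock_start,
                    int n_neigh, bool torus, bool record_agents) {
  const int L2 = L * L;
  IntegerVector states(L2), lag(L2);
  for (int i = 0; i < L2; ++i) {
    states[i] = states0[i];
    lag[i] = lag0[i];
  }
  IntegerVector x = clone(x0);
  NumericVector y = clone(y0);
  NumericMatrix hist = clone(hist0);
  Neighborhood nb = build_neighborhood(L, n_neigh, torus);

  NumericVector pi_prev(N, 0.0);
  IntegerVector newx(N), nplus(N), xa(N);
  NumericVector newy(N);
  NumericVector pi_cur(N), share(N), w(N);
  IntegerMatrix D(N, N);
  std::vector<int> flips;
  flips.reserve(L2);

  NumericVector r_x_mean(T), r_xa_mean(T), r_y_mean(T), r_nplus_mean(T),
      r_pi_mean(T);
  IntegerVector r_dfp(T), r_shock(T), r_harvest(T), r_shock_loss(T),
      r_forest(T);
  IntegerMatrix agents_x_rec, agents_nplus_rec;
  if (record_agents) {
    agents_x_rec = IntegerMatrix(N, T);
    agents_nplus_rec = IntegerMatrix(N, T);
  }

  int forest_count = 0;
  for (int i = 0; i < L2; ++i) forest_count += states[i];
  const int ymax = h * N;

  for (int t = 1; t <= T; ++t) {
    const int fc0 = forest_count;
    const int cap = fc0 / N;

    // (1) simultaneous strategy revision against previous-round state
    for (int i = 0; i < N; ++i) {
      newx[i] = x[i];
      newy[i] = y[i];
    }
    for (int i = 0; i < N; ++i) {
      double u = unif_rand();
      if (u < nu0) newx[i] = myopic_best(i, cap, y, mu, hist, N, h, c);
      if (t > 1) {
        double ub = unif_rand();
        if (ub < nu1) {
          // logit imitation over previous-round payoffs (self included)
          double mx = pi_prev[0];
          for (int j = 1; j < N; ++j) mx = std::max(mx, (double)pi_prev[j]);
          long double tot = 0.0L;
          for (int j = 0; j < N; ++j) {
            w[j] = std::exp(lambda * (pi_prev[j] - mx));
            tot += w[j];
          }
          double sw = (double)tot;
          double u2 = unif_rand();
          long double acc = 0.0L;
          int tgt = N - 1;
          for (int j = 0; j < N; ++j) {
            acc += (double)(w[j] / sw);
            if (u2 < (double)acc) {
              tgt = j;
              break;
            }
          }
          newy[i] = y[tgt];
        } else if (ub < nu1 + nu2) {
          // local mutation: Gaussian step, clamped to [0, h*N]
          double yy = y[i] + norm_rand() * innov_sd;
          if (yy < 0.0) yy = 0.0;
          if (yy > ymax) yy = ymax;
          newy[i] = yy;
        }
      }
    }
    for (int i = 0; i < N; ++i) {
      x[i] = newx[i];
      y[i] = newy[i];
    }

    // (2) helping decisions: N^2 Bernoulli draws, column-major
    for (int j = 0; j < N; ++j) {
      for (int i = 0; i < N; ++i) {
        double u = unif_rand();
        if (i == j) {
          D(i, j) = 0;
        } else {
          double q = (1.0 - mu[i]) * hist(j, i) +
                     mu[i] * ((x[j] <= y[i]) ? 1.0 : 0.0);
          D(i, j) = (u < q) ? 1 : 0;
        }
      }
    }
    for (int j = 0; j < N; ++j) {
      int s = 0;
      for (int i = 0; i < N; ++i) s += D(i, j);
      nplus[j] = s;
    }

    // (3) harvests under the triple cap
    int harvest_total = 0;
    for (int i = 0; i < N; ++i) {
      int v = std::min(x[i], h * (1 + nplus[i]));
      v = std::min(v, cap);
      xa[i] = v;
      harvest_total += v;
    }

    // (4) clear harvested cells
    remove_forest_cells(states, lag, harvest_total, l);
    forest_count -= harvest_total;

    // (5) costs and payoffs
    for (int j = 0; j < N; ++j)
      share[j] = c * xa[j] / (h * (1.0 + nplus[j]));
    for (int i = 0; i < N; ++i) {
      long double acc = 0.0L;
      for (int j = 0; j < N; ++j)
        acc += D(i, j) * (c0 + share[j]);
      double Ci = (double)acc + ((xa[i] > 0) ? share[i] : 0.0);
      pi_cur[i] = xa[i] - Ci;
    }

    // (6) history update
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i)
        hist(i, j) = (1.0 - alpha) * hist(i, j) + alpha * D(i, j);

    // (7) synchronous regeneration (pre-update neighbour densities)
    flips.clear();
    for (int idx = 0; idx < L2; ++idx) {
      if (states[idx] == 0 && lag[idx] == 0) {
        int cnt = 0;
        const int nn = nb.nnbr[idx];
        const int *ptr = &nb.nbr[(size_t)idx * 8];
        for (int k = 0; k < nn; ++k) cnt += states[ptr[k]];
        double fk = (double)cnt / nn;
        double p = (fk <= F_) ? ((pmax_ - p0) * fk / F_ + p0)
                              : ((pmax_ - p1 * F_ - (pmax_ - p1) * fk) /
                                 (1.0 - F_));
        double u = unif_rand();
        if (u < p) flips.push_back(idx);
      }
    }
    int dfp = (int)flips.size();
    for (int k = 0; k < dfp; ++k) states[flips[k]] = 1;
    forest_count += dfp;
    for (int idx = 0; idx < L2; ++idx)
      if (lag[idx] > 0) --lag[idx];

    // (8) external shock (draws consumed only when enabled)
    int shock_occurred = 0, shock_loss = 0;
    if (p_sh > 0.0 && t >= shock_start) {
      double u = unif_rand();
      if (u < p_sh) {
        shock_occurred = 1;
        int k_sh = (int)std::nearbyint(f_sh * L2);
        if (forest_count < k_sh) {
          for (int idx = 0; idx < L2; ++idx) {
            if (states[idx] == 1) {
              states[idx] = 0;
              if (l > 0) lag[idx] = l;
              ++shock_loss;
            }
          }
        } else {
          remove_forest_cells(states, lag, k_sh, l);
          shock_loss = k_sh;
        }
        forest_count -= shock_loss;
      }
    }

    // (9) record the round
    long double sx = 0.0L, sxa = 0.0L, sy = 0.0L, snp = 0.0L, spi = 0.0L;
    for (int i = 0; i < N; ++i) {
      sx += x[i];
      sxa += xa[i];
      sy += y[i];
      snp += nplus[i];
      spi += pi_cur[i];
    }
    const int ti = t - 1;
    r_x_mean[ti] = (double)(sx / N);
    r_xa_mean[ti] = (double)(sxa / N);
    r_y_mean[ti] = (double)(sy / N);
    r_nplus_mean[ti] = (double)(snp / N);
    r_pi_mean[ti] = (double)(spi / N);
    r_dfp[ti] = dfp;
    r_shock[ti] = shock_occurred;
    r_harvest[ti] = harvest_total;
    r_shock_loss[ti] = shock_loss;
    r_forest[ti] = forest_count;
    if (record_agents) {
      for (int i = 0; i < N; ++i) {
        agents_x_rec(i, ti) = x[i];
        agents_nplus_rec(i, ti) = nplus[i];
      }
    }
    for (int i = 0; i < N; ++i) pi_prev[i] = pi_cur[i];
  }

  List out = List::create(
      _["x_mean"] = r_x_mean, _["xa_mean"] = r_xa_mean,
      _["y_mean"] = r_y_mean, _["nplus_mean"] = r_nplus_mean,
      _["pi_mean"] = r_pi_mean, _["delta_f_plus"] = r_dfp,
      _["shock"] = r_shock, _["harvest_total"] = r_harvest,
      _["shock_loss"] = r_shock_loss, _["forest_cells"] = r_forest);
  if (record_agents) {
    out["agents_x"] = agents_x_rec;
    out["agents_nplus"] = agents_nplus_rec;
  }
  return out;
}
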