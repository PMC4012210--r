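#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact stochastic simulation of the bivalent-ligand / dimeric-TCR
// cross-linking network for one realization, with per-complex dwell
// tracking.  Species: x1 free dimeric clusters, x2 free ligands, x3 singly
// bound complexes, x4 doubly occupied dimers (optional channel), x5
// cross-linked complexes.  Channels and propensities:
//   binding       x1 + x2 -> x3   4 * k_plus * x1 * x2
//   unbinding     x3 -> x1 + x2   k_off * x3
//   cross-link    x3 -> x5        k2 * x3
//   reverse       x5 -> x3        2 * k_minus2 * x5
//   2nd binding   x3 + x2 -> x4   k_plus * x3 * x2        (optional)
//   2nd unbind    x4 -> x3 + x2   2 * k_off * x4          (optional)
// A cross-link episode whose age reaches tau counts once toward the
// response; the complex itself stays in the kinetics (no internalization).
// The first-passage time T is the instant the n_events-th episode's age
// reaches tau.  On a reverse cross-link one episode is removed uniformly
// at random (all episodes carry i.i.d. exponential clocks, so the removed
// one is uniform among those present).
//
// [[Rcpp::export]]
List ssa_mtsi_realization(double k_plus, double k_off, double k2,
                          double k_minus2, double n_dimers, double n_ligand,
                          bool allow_double, int n_events, double tau,
                          double horizon,
                          bool record_trajectory = false,
                          bool record_episodes = false,
                          int max_steps = 100000000) {
  long long x1 = (long long)(n_dimers + 0.5),
            x2 = (long long)(n_ligand + 0.5), x3 = 0, x4 = 0, x5 = 0;
  double t = 0.0;
  std::vector<double> ftime;    // formation times, insertion (= time) order
  std::vector<char> counted;
  size_t first_uncounted = 0;
  int completed = 0;
  double T = NA_REAL;
  bool censored = false, responded = false;

  std::vector<double> traj;     // rows: time, x1, x2, x3, x4, x5, completed
  std::vector<double> episode_lengths;
  RNGScope rngScope;

  if (n_events == 0) {
    return List::create(_["T"] = 0.0, _["censored"] = false,
                        _["n_steps"] = 0,
                        _["trajectory"] = R_NilValue,
                        _["episode_lengths"] = R_NilValue);
  }

  if (record_trajectory) {
    double row[7] = {t, (double)x1, (double)x2, (double)x3, (double)x4,
                     (double)x5, (double)completed};
    traj.insert(traj.end(), row, row + 7);
  }

  int step = 0;
  while (step < max_steps) {
    ++step;
    double a_bind   = 4.0 * k_plus * (double)x1 * (double)x2;
    double a_unbind = k_off * (double)x3;
    double a_cross  = k2 * (double)x3;
    double a_rev    = 2.0 * k_minus2 * (double)x5;
    double a_bind2  = allow_double ? k_plus * (double)x3 * (double)x2 : 0.0;
    double a_unb2   = allow_double ? 2.0 * k_off * (double)x4 : 0.0;
    double a_total  = a_bind + a_unbind + a_cross + a_rev + a_bind2 + a_unb2;

    // next pending dwell-completion among uncounted episodes (they are in
    // formation order, so the first uncounted matures first)
    double next_mat = R_PosInf;
    while (first_uncounted < ftime.size() && counted[first_uncounted])
      ++first_uncounted;
    if (first_uncounted < ftime.size())
      next_mat = ftime[first_uncounted] + tau;

    double t_next;
    if (a_total > 0.0) {
      t_next = t + exp_rand() / a_total;
    } else if (R_FINITE(next_mat)) {
      t_next = next_mat;          // absorbing kinetics, pending maturities
    } else {
      censored = true;            // truly absorbing: nothing can happen
      break;
    }

    // process dwell completions occurring before the next reaction
    while (R_FINITE(next_mat) && next_mat <= t_next && next_mat <= horizon) {
      counted[first_uncounted] = 1;
      ++completed;
      if (completed >= n_events) { T = next_mat; responded = true; break; }
      ++first_uncounted;
      while (first_uncounted < ftime.size() && counted[first_uncounted])
        ++first_uncounted;
      next_mat = (first_uncounted < ftime.size())
                   ? ftime[first_uncounted] + tau : R_PosInf;
    }
    if (responded) break;
    if (t_next > horizon) { censored = true; break; }
    t = t_next;
    if (a_total <= 0.0) continue;  // only maturities were pending

    double u = unif_rand() * a_total;
    if (u < a_bind) {
      --x1; --x2; ++x3;
    } else if (u < a_bind + a_unbind) {
      ++x1; ++x2; --x3;
    } else if (u < a_bind + a_unbind + a_cross) {
      --x3; ++x5;
      ftime.push_back(t);
      counted.push_back(0);
    } else if (u < a_bind + a_unbind + a_cross + a_rev) {
      ++x3; --x5;
      size_t j = (size_t)(unif_rand() * ftime.size());
      if (j >= ftime.size()) j = ftime.size() - 1;
      if (record_episodes) episode_lengths.push_back(t - ftime[j]);
      ftime.erase(ftime.begin() + j);
      counted.erase(counted.begin() + j);
      if (j < first_uncounted) --first_uncounted;
    } else if (u < a_bind + a_unbind + a_cross + a_rev + a_bind2) {
      --x3; --x2; ++x4;
    } else {
      ++x3; ++x2; --x4;
    }

    if (record_trajectory) {
      double row[7] = {t, (double)x1, (double)x2, (double)x3, (double)x4,
                       (double)x5, (double)completed};
      traj.insert(traj.end(), row, row + 7);
    }
  }
  if (!responded && !censored) censored = true;  // max_steps guard

  SEXP traj_out = R_NilValue;
  if (record_trajectory) {
    int nrow = traj.size() / 7;
    NumericMatrix m(nrow, 7);
    for (int i = 0; i < nrow; ++i)
      for (int j = 0; j < 7; ++j) m(i, j) = traj[7 * i + j];
    colnames(m) = CharacterVector::create("time", "x1", "x2", "x3", "x4",
                                          "x5", "completed");
    traj_out = m;
  }
  SEXP ep_out = R_NilValue;
  if (record_episodes) ep_out = wrap(episode_lengths);

  return List::create(_["T"] = T, _["censored"] = censored,
                      _["n_steps"] = step,
                      _["trajectory"] = traj_out,
                      _["episode_lengths"] = ep_out);
}
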