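#include <Rcpp.h>
using namespace Rcpp;

// Daily update loop of the female-only cage model, compiled for the inner
// loops of the ABC sampler.  Uses R's RNG throughout so runs are reproducible
// from set.seed() on the R side.  The update order per day matches step_day():
// survival+aging, emergence at the new day, then (on oviposition days) the
// weekly harvest and its emergence scheduling.
// [[Rcpp::export]]
List cpp_sim_weeks(NumericVector aw0, NumericVector at0,
                   NumericVector mu_wt, NumericVector mu_tg,
                   NumericVector phi_wt, NumericVector phi_tg,
                   int cohort_size, int min_ov_age, int juv_base,
                   int ivl, int n_days, double egg_weight_tg,
                   double pupal_mortality) {
  const int m = aw0.size();
  std::vector<double> aw(aw0.begin(), aw0.end());
  std::vector<double> at(at0.begin(), at0.end());
  const int horizon = n_days + juv_base + 5;
  std::vector<double> em_wt(horizon + 1, 0.0), em_tg(horizon + 1, 0.0);

  const int n_harvest = n_days / ivl;
  IntegerVector n_tg_out(n_harvest), n_wt_out(n_harvest);
  int k = 0;

  double pw[3] = {phi_wt[0], phi_wt[1], phi_wt[2]};
  double pt[3] = {phi_tg[0], phi_tg[1], phi_tg[2]};

  for (int d = 1; d <= n_days; ++d) {
    // deaths and aging: age i survivors move to age i + 1; the oldest class
    // has hazard 1 and is simply dropped
    for (int i = m - 1; i >= 1; --i) {
      aw[i] = aw[i - 1] > 0 ? R::rbinom(aw[i - 1], 1.0 - mu_wt[i - 1]) : 0.0;
      at[i] = at[i - 1] > 0 ? R::rbinom(at[i - 1], 1.0 - mu_tg[i - 1]) : 0.0;
    }
    aw[0] = em_wt[d];
    at[0] = em_tg[d];

    if (d % ivl == 0) {
      double el_w = 0.0, el_t = 0.0;
      for (int i = min_ov_age; i < m; ++i) { el_w += aw[i]; el_t += at[i]; }
      int n_tg = 0, n_wt = 0;
      if (el_w + el_t > 0) {
        double w_t = egg_weight_tg * el_t;
        double p = 0.5 * w_t / (w_t + el_w);
        n_tg = (int) R::rbinom((double) cohort_size, p);
        n_wt = cohort_size - n_tg;
        // deterministic female share: half the harvest per genotype
        double f_tg = R::fround(n_tg / 2.0, 0.0);
        double f_wt = R::fround((n_tg + n_wt) / 2.0, 0.0) - f_tg;
        if (pupal_mortality > 0) {
          f_tg = R::rbinom(f_tg, 1.0 - pupal_mortality);
          f_wt = R::rbinom(f_wt, 1.0 - pupal_mortality);
        }
        int dw[3] = {0, 0, 0}, dt[3] = {0, 0, 0};
        rmultinom((int) f_wt, pw, 3, dw);
        rmultinom((int) f_tg, pt, 3, dt);
        for (int j = 0; j < 3; ++j) {
          em_wt[d + juv_base + 1 + j] += dw[j];
          em_tg[d + juv_base + 1 + j] += dt[j];
        }
      }
      n_tg_out[k] = n_tg;
      n_wt_out[k] = n_wt;
      ++k;
    }
  }

  double tg_alive = 0.0;
  for (int i = 0; i < m; ++i) tg_alive += at[i];
  for (int d = n_days + 1; d <= horizon; ++d) tg_alive += em_tg[d];

  return List::create(_["n_tg"] = n_tg_out, _["n_wt"] = n_wt_out,
                      _["tg_alive_end"] = tg_alive);
}
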