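// Event-driven (Gillespie) simulation of branched actin network growth
// under a force clamp. Events: nucleate a new filament, elongate an
// uncapped filament by one subunit, cap an uncapped filament. Propensities
// are recomputed after every event; the external stress is shared equally
// over uncapped filaments and an internal tethering force adds to the
// per-filament load. Uses R's RNG so set.seed() governs reproducibility.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List ssa_run_cpp(double duration, double sample_dt,
                 double k_nuc_max, double npf_density, double area,
                 double k_on0, double k_cap0, double k_be,
                 double delta_actin, double delta_cap, double f_tether,
                 double kBT, double subunit_rise_nm,
                 double molarity_to_density,
                 double polymer_conc0, double polymer_exponent, double e_ref,
                 NumericVector sched_time, NumericVector sched_stress,
                 IntegerVector init_subunits, double max_events,
                 double k_abort, double abort_window_subunits) {
  RNGScope scope;
  std::vector<long long> sub(init_subunits.begin(), init_subunits.end());
  double t = 0.0, h = 0.0;
  long long total_sub = 0;
  for (size_t i = 0; i < sub.size(); ++i) total_sub += sub[i];
  long long n_nuc = 0, n_cap = 0, n_el = 0, n_abort = 0;
  long long paused = 0;
  bool was_paused = false;
  bool truncated = false;
  double rise_um = subunit_rise_nm * 1e-3;

  int n_samp = (int)std::floor(duration / sample_dt + 1e-9) + 1;
  NumericVector s_time(n_samp), s_E(n_samp), s_height(n_samp), s_phi(n_samp),
      s_stress(n_samp), s_sin(n_samp), s_poly(n_samp), s_nuc(n_samp),
      s_cap(n_samp), s_el(n_samp);
  int samp_i = 0;
  double next_sample_t = 0.0;

  std::vector<double> cap_time;
  std::vector<double> cap_len;

  int sched_i = 0;
  const int n_sched = sched_time.size();
  double events = 0;

  for (;;) {
    while (sched_i + 1 < n_sched && t >= sched_time[sched_i + 1] - 1e-12)
      sched_i++;
    double stress = sched_stress[sched_i];

    int n = (int)sub.size();
    double E = n / area;
    double phi = (E * k_be) / (1.0 + E * k_be);
    double sin_th = 1.0, f_eff = f_tether;
    if (n > 0) {
      double CA = polymer_conc0;
      if (polymer_exponent != 0.0)
        CA = polymer_conc0 * std::pow(E / e_ref, polymer_exponent);
      double Lv = CA * molarity_to_density * rise_um; // um filament per um^3
      sin_th = E / Lv;
      if (sin_th > 1.0) sin_th = 1.0;
      if (sin_th < 1e-6) sin_th = 1e-6;
      f_eff = stress * area / n + f_tether;
      was_paused = false;
    } else if (stress > 0) {
      // no uncapped filament carries the load: the boundary holds the
      // stress and load coupling is paused for this episode
      if (!was_paused) { paused++; was_paused = true; }
    }
    double B_el = std::exp(-f_eff * delta_actin * sin_th / kBT);
    double B_cap = std::exp(-f_eff * delta_cap * sin_th / kBT);
    double a_nuc = k_nuc_max * npf_density * area * (1.0 - phi);
    double a_el = n * k_on0 * B_el;
    double a_cap = n * k_cap0 * B_cap;
    // optional early failure of young (surface-proximal) branches;
    // deliberately force-independent
    int n_young = 0;
    if (k_abort > 0) {
      for (int i = 0; i < n; ++i)
        if (sub[i] < abort_window_subunits) n_young++;
    }
    double a_ab = k_abort * n_young;
    double a0 = a_nuc + a_el + a_cap + a_ab;

    double t_next_sched =
        (sched_i + 1 < n_sched) ? sched_time[sched_i + 1] : R_PosInf;
    double dt = (a0 > 0) ? R::rexp(1.0 / a0) : R_PosInf;
    double t_ev = t + dt;
    double t_flush = std::min(std::min(t_ev, t_next_sched), duration);

    while (samp_i < n_samp && next_sample_t <= t_flush + 1e-12) {
      s_time[samp_i] = next_sample_t;
      s_E[samp_i] = E;
      s_height[samp_i] = h;
      s_phi[samp_i] = phi;
      s_stress[samp_i] = stress;
      s_sin[samp_i] = sin_th;
      s_poly[samp_i] = (double)total_sub;
      s_nuc[samp_i] = (double)n_nuc;
      s_cap[samp_i] = (double)n_cap;
      s_el[samp_i] = (double)n_el;
      samp_i++;
      next_sample_t += sample_dt;
    }

    if (t_ev >= duration && t_next_sched >= duration) break;
    if (t_next_sched < t_ev) { // rates change at the setpoint switch;
      t = t_next_sched;        // the exponential clock is memoryless
      continue;
    }

    t = t_ev;
    events += 1;
    if (events > max_events) { truncated = true; break; }
    double u = R::unif_rand() * a0;
    if (u < a_nuc) {
      sub.push_back(1); // a nucleus counts as one subunit
      total_sub++;
      n_nuc++;
    } else if (u < a_nuc + a_el) {
      int idx = (int)(R::unif_rand() * n);
      if (idx >= n) idx = n - 1;
      sub[idx]++;
      total_sub++;
      n_el++;
      // the growth surface advances at the per-filament elongation speed
      h += rise_um * sin_th / n;
    } else if (u < a_nuc + a_el + a_cap) {
      int idx = (int)(R::unif_rand() * n);
      if (idx >= n) idx = n - 1;
      cap_time.push_back(t);
      cap_len.push_back((double)sub[idx]);
      sub[idx] = sub.back();
      sub.pop_back();
      n_cap++;
    } else {
      // abortive failure: remove a uniformly chosen young filament
      int pick = (int)(R::unif_rand() * n_young);
      if (pick >= n_young) pick = n_young - 1;
      int seen = 0;
      for (int i = 0; i < n; ++i) {
        if (sub[i] < abort_window_subunits) {
          if (seen == pick) {
            sub[i] = sub.back();
            sub.pop_back();
            break;
          }
          seen++;
        }
      }
      n_abort++;
    }
  }

  return List::create(
      _["time_s"] = s_time, _["free_ends"] = s_E, _["height_um"] = s_height,
      _["wh2_occupancy"] = s_phi, _["stress_pa"] = s_stress,
      _["sin_theta"] = s_sin, _["polymer_subunits"] = s_poly,
      _["nucleation_events"] = s_nuc, _["capping_events"] = s_cap,
      _["elongation_events"] = s_el, _["cap_time"] = wrap(cap_time),
      _["cap_len"] = wrap(cap_len), _["n_nucleated"] = (double)n_nuc,
      _["n_capped"] = (double)n_cap, _["n_elongated"] = (double)n_el,
      _["total_subunits"] = (double)total_sub,
      _["n_aborted"] = (double)n_abort,
      _["paused_episodes"] = (double)paused, _["truncated"] = truncated);
}
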