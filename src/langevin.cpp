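#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear link force vs stretch and its local slope.  Below
// the table the link is slack (zero force, it cannot push); above it
// the last slope is extrapolated.
static inline void link_force(double s, const double* sg, const double* fg,
                              int n, double* F, double* slope) {
  if (s <= sg[0]) { *F = 0.0; *slope = 0.0; return; }
  if (s >= sg[n - 1]) {
    double sl = (fg[n - 1] - fg[n - 2]) / (sg[n - 1] - sg[n - 2]);
    *F = fg[n - 1] + sl * (s - sg[n - 1]);
    *slope = sl;
    return;
  }
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (sg[mid] <= s) lo = mid; else hi = mid;
  }
  double sl = (fg[hi] - fg[lo]) / (sg[hi] - sg[lo]);
  *F = fg[lo] + sl * (s - sg[lo]);
  *slope = sl;
}

// Overdamped bead in a trap, pulled through the tabulated link by a
// microtubule tip:
//   gamma dx/dt = -c_trap x + F_link(tip - x) + sqrt(2 kbt gamma) xi(t)
// Each substep advances the locally linearised dynamics with the exact
// Ornstein-Uhlenbeck (exponential Euler-Maruyama) update, which is
// unconditionally stable and leaves the stationary variance unbiased;
// the only approximation is freezing the link slope across one substep.
//
// Tip state machine:
//   mode 0 = shrinking (tip velocity +v_shrink, force builds up)
//   mode 1 = stalled   (tip velocity 0; entered when the filtered link
//                       force reaches stall_force)
//   mode 2 = growing   (tip velocity -v_grow; entered at rescue_time)
//   mode 3 = detached  (no link force; at detach_time or filtered
//                       force >= detach_force)
// Force-dependent transitions act on an exponential moving average of
// the link force with time constant trigger_tau, since the
// instantaneous force carries the full thermal fluctuation (~1 pN).
// Unset triggers are passed as NA.  One output sample per `substeps`
// integration steps, decimated (boxcar_m = 1) or boxcar-averaged over
// the last boxcar_m substeps.
// [[Rcpp::export]]
List sim_langevin_cpp(int n_out, int substeps, double dt, double gamma,
                      double ctrap, double kbt, double x0, double tip0,
                      NumericVector s_tab, NumericVector f_tab,
                      bool attached0, double v_shrink, double v_grow,
                      double stall_force, double rescue_time,
                      double catastrophe_time, double detach_time,
                      double detach_force, double trigger_tau,
                      int boxcar_m, double noise_sd) {
  const int ntab = s_tab.size();
  const double* sg = ntab ? &s_tab[0] : 0;
  const double* fg = ntab ? &f_tab[0] : 0;
  NumericVector x_out(n_out), tip_out(n_out), f_out(n_out);
  IntegerVector mode_out(n_out);
  double t_stall = NA_REAL, t_rescue = NA_REAL, t_cat = NA_REAL,
    t_detach = NA_REAL;
  double x = x0, tip = tip0, t = 0.0;
  int mode = attached0 ? 0 : 3;
  const bool has_stall = R_finite(stall_force);
  const bool has_rescue = R_finite(rescue_time);
  const bool has_cat = R_finite(catastrophe_time);
  const bool has_dtime = R_finite(detach_time);
  const bool has_dforce = R_finite(detach_force);
  const double ema_a = dt / (trigger_tau + dt);
  double F = 0.0, slope = 0.0;
  if (mode != 3) link_force(tip - x, sg, fg, ntab, &F, &slope);
  double f_ema = F;

  for (int i = 0; i < n_out; ++i) {
    double acc = 0.0;
    int n_acc = 0;
    for (int j = 0; j < substeps; ++j) {
      F = 0.0; slope = 0.0;
      if (mode != 3) {
        link_force(tip - x, sg, fg, ntab, &F, &slope);
        f_ema += ema_a * (F - f_ema);
        if (has_dtime && t >= detach_time) {
          mode = 3; t_detach = t; F = 0.0; slope = 0.0;
        } else if (has_dforce && f_ema >= detach_force) {
          mode = 3; t_detach = t; F = 0.0; slope = 0.0;
        } else {
          if (mode == 0 && has_stall && f_ema >= stall_force) {
            mode = 1;
            if (!R_finite(t_stall)) t_stall = t;
          }
          if ((mode == 0 || mode == 1) && has_rescue &&
              !R_finite(t_rescue) && t >= rescue_time) {
            mode = 2; t_rescue = t;   // one-shot
          }
          if (mode == 2 && has_cat && !R_finite(t_cat) &&
              t >= catastrophe_time) {
            mode = 0; t_cat = t;      // one-shot
          }
          if (mode == 0) tip += v_shrink * dt;
          else if (mode == 2) tip -= v_grow * dt;
        }
      }
      // exact OU update of the locally linearised dynamics
      double c_loc = ctrap + slope;
      double xeq = x + (-ctrap * x + F) / c_loc;
      double e1 = std::exp(-c_loc * dt / gamma);
      x = xeq + (x - xeq) * e1 +
        std::sqrt(kbt / c_loc * (1.0 - e1 * e1)) * norm_rand();
      t += dt;
      if (j >= substeps - boxcar_m) { acc += x; ++n_acc; }
    }
    double xm = acc / n_acc;
    if (noise_sd > 0.0) xm += noise_sd * norm_rand();
    x_out[i] = xm;
    tip_out[i] = tip;
    mode_out[i] = mode;
    if (mode == 3) {
      f_out[i] = 0.0;
    } else {
      link_force(tip - x, sg, fg, ntab, &F, &slope);
      f_out[i] = F;
    }
  }
  return List::create(_["x"] = x_out, _["tip"] = tip_out,
                      _["mode"] = mode_out, _["link_force"] = f_out,
                      _["t_stall"] = t_stall, _["t_rescue"] = t_rescue,
                      _["t_catastrophe"] = t_cat, _["t_detach"] = t_detach);
}
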