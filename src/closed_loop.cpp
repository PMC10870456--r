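#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-loop fixed-step RK4 integration of the single inverted pendulum
// under blended feedforward / feedback / intrinsic ankle torque.
//
// State is (theta, theta_dot) in radians; controller gains are per degree
// (the conversion lives here, at the plant/controller boundary).
// Reference trajectory arrays are sampled on a half-step grid so the RK4
// stages at t, t + dt/2 and t + dt read exact analytic values
// (index 2*i, 2*i + 1, 2*i + 2 for step i).

struct Model {
  double J, m, L, g;
  double ka_deg, ba_deg;          // intrinsic stiffness/damping, N.m per deg(/s)
  double kp_deg, ki_deg, kff;     // feedback gains per deg(/s); kff dimensionless
  double onset, t_r, t_apa;       // seconds (onset is absolute trial time)
  bool printed_blend;             // true: Eq. as printed (alpha weights FF)
  bool linearized;                // sin(theta) ~ theta in the plant
  const double *thr, *thrd, *thrdd; // reference on half-step grid, rad
};

static const double RAD2DEG = 57.29577951308232;

struct Torques {
  double fb, ff, ais, alpha, total;
};

static inline Torques torques_at(const Model &md, double t, double th,
                                 double thd, int j) {
  Torques o;
  const double thr = md.thr[j], thrd = md.thrd[j], thrdd = md.thrdd[j];
  o.fb = md.kp_deg * (thr - th) * RAD2DEG + md.ki_deg * (thrd - thd) * RAD2DEG;
  o.ff = md.kff * (md.J * thrdd - md.m * md.g * md.L * thr);
  o.ais = -(md.ka_deg * th * RAD2DEG + md.ba_deg * thd * RAD2DEG);
  const double tt = t - md.onset;
  double a = (tt - md.t_r) / md.t_apa;
  if (a < 0.0) a = 0.0;
  if (a > 1.0) a = 1.0;
  o.alpha = a;
  if (tt > md.t_r && tt < md.t_r + md.t_apa) {
    const double w_ff = md.printed_blend ? a : 1.0 - a;
    o.total = w_ff * o.ff + (1.0 - w_ff) * o.fb + o.ais;
  } else {
    // before APA onset: feedback regulation about the (still) upright
    // reference; after APA end: pure feedback (second branch of the blend)
    o.total = o.fb + o.ais;
  }
  return o;
}

static inline double accel(const Model &md, double th, double tau) {
  const double grav = md.m * md.g * md.L * (md.linearized ? th : std::sin(th));
  return (grav + tau) / md.J;
}

// [[Rcpp::export]]
List simulate_closed_loop_cpp(NumericVector theta_ref, NumericVector dtheta_ref,
                              NumericVector ddtheta_ref, double dt, int n_steps,
                              double J, double m, double L, double g,
                              double ka_deg, double ba_deg, double kp_deg,
                              double ki_deg, double kff, double onset,
                              double t_r, double t_apa, bool printed_blend,
                              bool linearized, double theta0, double dtheta0,
                              double diverge_rad) {
  if (theta_ref.size() != 2 * n_steps + 1 ||
      dtheta_ref.size() != 2 * n_steps + 1 ||
      ddtheta_ref.size() != 2 * n_steps + 1)
    stop("reference arrays must be sampled on the half-step grid (2*n_steps + 1)");

  Model md;
  md.J = J; md.m = m; md.L = L; md.g = g;
  md.ka_deg = ka_deg; md.ba_deg = ba_deg;
  md.kp_deg = kp_deg; md.ki_deg = ki_deg; md.kff = kff;
  md.onset = onset; md.t_r = t_r; md.t_apa = t_apa;
  md.printed_blend = printed_blend; md.linearized = linearized;
  md.thr = REAL(theta_ref); md.thrd = REAL(dtheta_ref); md.thrdd = REAL(ddtheta_ref);

  const int n_out = n_steps + 1;
  NumericVector th_out(n_out, NA_REAL), thd_out(n_out, NA_REAL),
      thdd_out(n_out, NA_REAL), cop_out(n_out, NA_REAL),
      fb_out(n_out, NA_REAL), ff_out(n_out, NA_REAL), ais_out(n_out, NA_REAL),
      alpha_out(n_out, NA_REAL), tau_out(n_out, NA_REAL);

  double th = theta0, thd = dtheta0;
  bool diverged = false;
  int n_valid = 0;
  const double cop_coef = J / (m * g);

  for (int i = 0; i <= n_steps; ++i) {
    const double t = i * dt;
    Torques tq = torques_at(md, t, th, thd, 2 * i);
    const double acc = accel(md, th, tq.total);
    th_out[i] = th; thd_out[i] = thd; thdd_out[i] = acc;
    cop_out[i] = L * th - cop_coef * acc; // linearized COP/ZMP relation, metres
    fb_out[i] = tq.fb; ff_out[i] = tq.ff; ais_out[i] = tq.ais;
    alpha_out[i] = tq.alpha; tau_out[i] = tq.total;
    n_valid = i + 1;
    if (!std::isfinite(th) || !std::isfinite(thd) || std::fabs(th) > diverge_rad) {
      diverged = true;
      break;
    }
    if (i == n_steps) break;

    // RK4 step
    const double h = dt;
    const double k1th = thd;
    const double k1thd = acc;
    double th2 = th + 0.5 * h * k1th, thd2 = thd + 0.5 * h * k1thd;
    Torques q2 = torques_at(md, t + 0.5 * h, th2, thd2, 2 * i + 1);
    const double k2th = thd2, k2thd = accel(md, th2, q2.total);
    double th3 = th + 0.5 * h * k2th, thd3 = thd + 0.5 * h * k2thd;
    Torques q3 = torques_at(md, t + 0.5 * h, th3, thd3, 2 * i + 1);
    const double k3th = thd3, k3thd = accel(md, th3, q3.total);
    double th4 = th + h * k3th, thd4 = thd + h * k3thd;
    Torques q4 = torques_at(md, t + h, th4, thd4, 2 * i + 2);
    const double k4th = thd4, k4thd = accel(md, th4, q4.total);

    th += h / 6.0 * (k1th + 2.0 * k2th + 2.0 * k3th + k4th);
    thd += h / 6.0 * (k1thd + 2.0 * k2thd + 2.0 * k3thd + k4thd);
  }

  return List::create(
      _["theta"] = th_out, _["theta_dot"] = thd_out, _["theta_ddot"] = thdd_out,
      _["cop_m"] = cop_out, _["tau_fb"] = fb_out, _["tau_ff"] = ff_out,
      _["tau_ais"] = ais_out, _["alpha"] = alpha_out, _["tau_total"] = tau_out,
      _["diverged"] = diverged, _["n_valid"] = n_valid);
}
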