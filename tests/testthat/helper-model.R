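# shared fixtures: group-mean anthropometry and a mid-range lean plan

healthy_anthro <- function() derive_anthropometry(1.756, 77.28)
pd_anthro <- function() derive_anthropometry(1.645, 68.5)

healthy_t1_params <- function(theta_f = 1.879) {
  planning_params(t_r = 0.35, t_f = 2.0, t_b = 1.51, t_APA = 0.46,
                  theta_f = theta_f)
}

pd_t1_params <- function(theta_f = 1.879) {
  planning_params(t_r = 0.9, t_f = 2.50, t_b = 2.34, t_APA = 0.36,
                  theta_f = theta_f)
}

# synthetic piecewise-linear trial with analytically known segmentation:
# 5 s baseline at 0; APA dip to -1 cm at t = 6 returning to 0 at 6.5;
# linear rise to 4 cm at 8; linear fall to 0 at 10; undershoot to -0.2 cm
# at 10.5; rebound to -0.1 at 11; flat to 12. All knots lie on the 80 Hz
# grid.
trapezoid_trial <- function(target_id = 1, fs = 80) {
  t <- seq(0, 12, by = 1 / fs)
  knots_t <- c(0, 5.5, 6, 6.5, 8, 10, 10.5, 11, 12)
  knots_v <- c(0, 0, -1, 0, 4, 0, -0.2, -0.1, -0.1)
  s <- approx(knots_t, knots_v, xout = t)$y
  sign_ap <- if (target_id == 8) -1 else 1
  cop_trial(time = t, cop_ap = sign_ap * s, cop_ml = rep(0, length(t)),
            target_onset = 5, target_id = target_id, sampling_hz = fs)
}
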