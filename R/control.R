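#' Postural control gains
#'
#' Gains of the two control paths: a proportional-plus-velocity feedback
#' law (`K_P` in N m/deg on the angle error, `K_I` in N m/(deg/s) on the
#' rate error, fixed at 5 by convention) and a feedforward inverse-model
#' path with dimensionless gain `K_FF`.
#'
#' @param K_P proportional feedback gain, N m per degree (> 0).
#' @param K_FF feedforward gain, dimensionless (>= 0).
#' @param K_I velocity-error feedback gain, N m per (deg/s) (>= 0,
#'   default 5).
#' @return An object of class `control_gains`.
#' @export
control_gains <- function(K_P, K_FF, K_I = 5) {
  check_number(K_P, "K_P", 0, closed_lower = FALSE)
  check_number(K_FF, "K_FF", 0)
  check_number(K_I, "K_I", 0)
  structure(list(K_P = K_P, K_I = K_I, K_FF = K_FF),
            class = "control_gains")
}

#' Feedback (PI) torque
#'
#' \code{tau_FB = K_P (theta_ref - theta) + K_I (theta_ref_dot - theta_dot)}
#' with angles in degrees.
#'
#' @param gains a [control_gains] object.
#' @param theta_ref,theta_ref_dot reference angle (deg) and rate (deg/s).
#' @param state a [body_state].
#' @return torque in N m.
#' @export
feedback_torque <- function(gains, theta_ref, theta_ref_dot, state) {
  gains$K_P * (theta_ref - state$theta) +
    gains$K_I * (theta_ref_dot - state$theta_dot)
}

#' Feedforward inverse-model torque
#'
#' Time-domain realization of the inverse pendulum model
#' \code{K_FF (J_B s^2 - m g L_COM)} applied to the reference trajectory:
#' \code{tau_FF = K_FF (J_B * theta_ref_ddot - m g L_COM * theta_ref)} with
#' the reference and its second derivative taken analytically from the
#' planner (angles converted to radians internally).
#'
#' @param K_FF feedforward gain (dimensionless).
#' @param anthro an [anthropometry][derive_anthropometry] object.
#' @param theta_ref reference angle, degrees.
#' @param theta_ref_ddot analytic reference acceleration, deg/s^2.
#' @return torque in N m.
#' @export
feedforward_torque <- function(K_FF, anthro, theta_ref, theta_ref_ddot) {
  K_FF * (anthro$J_B * theta_ref_ddot * .deg2rad -
            anthro$mass * anthro$g * anthro$L_COM * theta_ref * .deg2rad)
}

#' Blend feedforward and feedback torques over the APA window
#'
#' Within the APA window (`t_r < t < t_r + t_APA`) the control command is a
#' time-weighted mixture governed by `alpha = (t - t_r)/t_APA` (clipped to
#' \[0, 1\]); outside the window it is pure feedback. Two weightings are
#' provided because the printed blending rule and its narrative description
#' disagree:
#' \itemize{
#'   \item `"printed"` (default): `tau = alpha * tau_FF +
#'     (1 - alpha) * tau_FB + tau_AIS` -- feedback at APA onset, feedforward
#'     at APA end;
#'   \item `"narrative"`: the weights are swapped, giving the
#'     feedforward-to-feedback hand-over the prose describes.
#' }
#'
#' @param t time from target onset, seconds.
#' @param params a [planning_params] object (supplies `t_r`, `t_APA`).
#' @param tau_FF,tau_FB,tau_AIS component torques, N m.
#' @param blend `"printed"` or `"narrative"`.
#' @return A list of class `control_command` with fields `tau_FB`,
#'   `tau_FF`, `tau_AIS`, `alpha` and `tau_total`.
#' @export
blend_torque <- function(t, params, tau_FF, tau_FB, tau_AIS,
                         blend = c("printed", "narrative")) {
  blend <- match.arg(blend)
  if (params$t_APA <= 0) {
    ls_abort("t_APA must be positive", "leansim_error_validation",
             field = "t_APA")
  }
  alpha <- min(max((t - params$t_r) / params$t_APA, 0), 1)
  in_window <- t > params$t_r && t < params$t_r + params$t_APA
  if (in_window) {
    w_ff <- if (blend == "printed") alpha else 1 - alpha
    tau_total <- w_ff * tau_FF + (1 - w_ff) * tau_FB + tau_AIS
  } else {
    tau_total <- tau_FB + tau_AIS
  }
  structure(list(tau_FB = tau_FB, tau_FF = tau_FF, tau_AIS = tau_AIS,
                 alpha = alpha, tau_total = tau_total),
            class = "control_command")
}

#' Closed-loop static stability check
#'
#' Static stability of the feedback loop requires the total restoring
#' stiffness to exceed the gravitational toppling stiffness:
#' `(K_P + K_A)` expressed per radian must be greater than `m g L_COM`.
#' @noRd
check_static_stability <- function(gains, plant, anthro) {
  mgl <- anthro$mass * anthro$g * anthro$L_COM
  k_tot <- (gains$K_P + plant$K_A) * .rad2deg
  if (k_tot <= mgl) {
    ls_abort(sprintf(
      "closed loop statically unstable: (K_P + K_A) = %.1f N m/rad <= m g L_COM = %.1f N m/rad (K_P = %.2f N m/deg, K_FF = %.2f)",
      k_tot, mgl, gains$K_P, gains$K_FF),
      "leansim_error_unstable_gains", K_P = gains$K_P, K_FF = gains$K_FF)
  }
  invisible(TRUE)
}
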