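#' Temporal and angular parameters of the planned lean
#'
#' Container for the CNS motor plan of one lean: reaction time `t_r`,
#' reaching time `t_f`, return time `t_b`, APA duration `t_APA`, initial
#' and target lean angles (degrees), the polynomial coefficients of the
#' bell-shaped reference profile, and an optional hold at the target.
#'
#' With the default coefficients `A1 = 15, A2 = 6, A3 = 10` the reference
#' polynomial is the minimum-jerk profile: it starts at `theta_0` and ends
#' at `theta_f` with zero velocity and acceleration at both ends.
#'
#' @param t_r reaction time, s (> 0): delay between target onset and the
#'   start of the planned movement.
#' @param t_f reaching time, s (> 0): duration of the lean to the target.
#' @param t_b return time, s (> 0): duration of the return to upright.
#' @param t_APA APA duration, s; must satisfy `0 < t_APA <= t_f`. Length of
#'   the feedforward-to-feedback blending window.
#' @param theta_0 initial lean angle, degrees (default 0: upright baseline).
#' @param theta_f target lean angle, degrees.
#' @param A1,A2,A3 trajectory shape coefficients.
#' @param hold pause at the target before the return, s (>= 0).
#' @return An object of class `planning_params`.
#' @export
planning_params <- function(t_r, t_f, t_b, t_APA, theta_f, theta_0 = 0,
                            A1 = 15, A2 = 6, A3 = 10, hold = 0) {
  check_number(t_r, "t_r", 0, closed_lower = FALSE)
  check_number(t_f, "t_f", 0, closed_lower = FALSE)
  check_number(t_b, "t_b", 0, closed_lower = FALSE)
  check_number(t_APA, "t_APA", 0, t_f, closed_lower = FALSE)
  check_number(theta_0, "theta_0", -90, 90)
  check_number(theta_f, "theta_f", -90, 90)
  check_number(hold, "hold", 0)
  structure(list(t_r = t_r, t_f = t_f, t_b = t_b, t_APA = t_APA,
                 theta_0 = theta_0, theta_f = theta_f,
                 A1 = A1, A2 = A2, A3 = A3, hold = hold),
            class = "planning_params")
}

# polynomial bracket and its derivatives in normalized time tau
.plan_poly <- function(tau, A1, A2, A3) {
  list(
    p = A1 * tau^4 - A2 * tau^5 - A3 * tau^3,
    dp = 4 * A1 * tau^3 - 5 * A2 * tau^4 - 3 * A3 * tau^2,
    ddp = 12 * A1 * tau^2 - 20 * A2 * tau^3 - 6 * A3 * tau
  )
}

#' Reference lean-angle trajectory and its analytic derivatives
#'
#' Evaluates the planned reference angle at times `t` measured from target
#' onset. The plan is piecewise: constant `theta_0` during planning
#' (`t <= t_r`); during reaching the polynomial profile
#' \deqn{\theta_{ref} = \theta_0 + (\theta_0 - \theta_f)
#'   (A_1 \tau^4 - A_2 \tau^5 - A_3 \tau^3), \quad
#'   \tau = (t - t_r)/t_f;}
#' an optional hold at `theta_f`; a mirrored profile from `theta_f` back to
#' `theta_0` over `t_b`; and `theta_0` afterwards. First and second
#' derivatives are analytic, never numeric.
#'
#' @param params a [planning_params] object.
#' @param t time(s) from target onset, seconds (vectorized, `t >= 0`).
#' @return A data.frame with columns `t`, `theta_ref` (deg),
#'   `theta_ref_dot` (deg/s), `theta_ref_ddot` (deg/s^2).
#' @export
plan_reference <- function(params, t) {
  p <- params
  th <- rep(p$theta_0, length(t))
  thd <- numeric(length(t))
  thdd <- numeric(length(t))

  reach_end <- p$t_r + p$t_f
  hold_end <- reach_end + p$hold
  ret_end <- hold_end + p$t_b

  i <- t > p$t_r & t <= reach_end
  if (any(i)) {
    tau <- (t[i] - p$t_r) / p$t_f
    pl <- .plan_poly(tau, p$A1, p$A2, p$A3)
    amp <- p$theta_0 - p$theta_f
    th[i] <- p$theta_0 + amp * pl$p
    thd[i] <- amp * pl$dp / p$t_f
    thdd[i] <- amp * pl$ddp / p$t_f^2
  }
  i <- t > reach_end & t <= hold_end
  th[i] <- p$theta_f
  i <- t > hold_end & t <= ret_end
  if (any(i)) {
    sig <- (t[i] - hold_end) / p$t_b
    pl <- .plan_poly(sig, p$A1, p$A2, p$A3)
    amp <- p$theta_f - p$theta_0
    th[i] <- p$theta_f + amp * pl$p
    thd[i] <- amp * pl$dp / p$t_b
    thdd[i] <- amp * pl$ddp / p$t_b^2
  }
  # t > ret_end stays at theta_0 with zero derivatives (initialized values),
  # but the default coefficients make the profile land there exactly; for
  # non-default coefficients the endpoint value is whatever the polynomial
  # gives, so recompute explicitly:
  i <- t > ret_end
  if (any(i)) {
    pl <- .plan_poly(1, p$A1, p$A2, p$A3)
    th[i] <- p$theta_f + (p$theta_f - p$theta_0) * pl$p
    thd[i] <- 0
    thdd[i] <- 0
  }
  data.frame(t = t, theta_ref = th, theta_ref_dot = thd,
             theta_ref_ddot = thdd)
}

# signed theoretical limit-of-stability angles per target, degrees.
# AP: positive forward; targets 6-8 lean backward. ML: positive rightward;
# mirrored pairs (2,3), (4,5), (6,7) share AP and have opposite ML.
.target_angles <- data.frame(
  target_id = 1:8,
  ap_limit_angle = c(6.25, 4.5, 4.5, 1.7, 1.7, -4.4, -4.4, -4.4),
  ml_limit_angle = c(0, 6, -6, 8, -8, 6, -6, 0)
)

#' Limit-of-stability target layout
#'
#' Places the eight lean targets at a fraction (default 30%) of the
#' subject's theoretical limit of stability:
#' \code{d = scale_fraction * H_CoM * tan(theta_limit)}, applied
#' independently in the anterior-posterior and medio-lateral directions.
#' The limit angles are the protocol's standard table (AP: 6.25 deg target
#' 1; 4.5 deg targets 2-3; 1.7 deg targets 4-5; 4.4 deg backward targets
#' 6-8; ML: 0 deg targets 1 and 8; 6 deg targets 2, 3, 6, 7; 8 deg targets
#' 4-5), with forward/right positive.
#'
#' @param H_CoM ankle-to-COM height of the subject, metres (> 0).
#' @param scale_fraction fraction of the theoretical limit (default 0.3).
#' @return An object of class `target_layout`: a data.frame with columns
#'   `target_id`, `ap_limit_angle`, `ml_limit_angle` (deg, signed),
#'   `ap_distance`, `ml_distance` (m, signed), plus attributes `H_CoM` and
#'   `scale_fraction`.
#' @export
target_layout <- function(H_CoM, scale_fraction = 0.3) {
  check_number(H_CoM, "H_CoM", 0, closed_lower = FALSE)
  check_number(scale_fraction, "scale_fraction", 0)
  out <- .target_angles
  out$ap_distance <- scale_fraction * H_CoM * tan(out$ap_limit_angle * .deg2rad)
  out$ml_distance <- scale_fraction * H_CoM * tan(out$ml_limit_angle * .deg2rad)
  attr(out, "H_CoM") <- H_CoM
  attr(out, "scale_fraction") <- scale_fraction
  class(out) <- c("target_layout", "data.frame")
  out
}

#' Target lean angle from a planar target distance
#'
#' Inverse of the static COP-lean relation: a target at Euclidean distance
#' `d` on the floor requires a lean angle `atan(d / H_CoM)` (degrees).
#'
#' @param d target distance from the central point, metres (>= 0).
#' @param H_CoM ankle-to-COM height, metres (> 0).
#' @return lean angle in degrees.
#' @export
theta_target_from_distance <- function(d, H_CoM) {
  check_number(H_CoM, "H_CoM", 0, closed_lower = FALSE)
  atan(d / H_CoM) * .rad2deg
}

#' Unit direction vector and planar distance of a layout target
#' @noRd
target_direction <- function(layout, target_id) {
  row <- layout[layout$target_id == target_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    ls_abort(sprintf("target_id %s not present in layout", target_id),
             "leansim_error_validation")
  }
  d <- c(row$ap_distance, row$ml_distance)
  len <- sqrt(sum(d^2))
  if (len <= 0) {
    ls_abort(sprintf("target %s has zero distance: direction undefined",
                     target_id), "leansim_error_validation")
  }
  list(unit = d / len, distance = len)
}
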