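#' Derive subject anthropometry for the single-pendulum body model
#'
#' The body is modelled as a single inverted pendulum rotating about the
#' ankle. From standing height and mass this derives the ankle-to-COM
#' height \code{L_COM} and the moment of inertia about the ankle
#' \code{J_B}, the quantities the controller and the target geometry use.
#'
#' The derivation is a documented anthropometric convention, exposed so it
#' can be overridden: \code{L_COM = c_L * height} (default
#' \code{c_L = 0.5527}, the classic proportion of COM height to stature)
#' and a point-mass inertia \code{J_B = mass * L_COM^2} unless an explicit
#' \code{J_B} is supplied.
#'
#' @param height standing height in metres; must lie in (1.2, 2.2).
#' @param mass body mass in kg; must lie in (30, 150).
#' @param c_L ratio of ankle-to-COM height to standing height.
#' @param J_B moment of inertia about the ankle in kg m^2, or `NULL` for the
#'   point-mass default.
#' @return An object of class `anthropometry`: a list with fields `mass`,
#'   `height`, `L_COM`, `J_B` and `g` (fixed at 9.81 m/s^2).
#' @examples
#' derive_anthropometry(1.756, 77.28)
#' @export
derive_anthropometry <- function(height, mass, c_L = 0.5527, J_B = NULL) {
  check_number(height, "height", 1.2, 2.2, closed_lower = FALSE,
               closed_upper = FALSE)
  check_number(mass, "mass", 30, 150, closed_lower = FALSE,
               closed_upper = FALSE)
  check_number(c_L, "c_L", 0, 1, closed_lower = FALSE)
  L <- c_L * height
  if (is.null(J_B)) J_B <- mass * L^2 else check_number(J_B, "J_B", 0,
                                                        closed_lower = FALSE)
  out <- list(mass = mass, height = height, L_COM = L, J_B = J_B, g = 9.81)
  class(out) <- "anthropometry"
  out
}

#' @export
print.anthropometry <- function(x, ...) {
  cat(sprintf(
    "<anthropometry> mass %.1f kg, height %.3f m, L_COM %.4f m, J_B %.2f kg m^2\n",
    x$mass, x$height, x$L_COM, x$J_B))
  invisible(x)
}

#' Intrinsic ankle stiffness and damping parameters
#'
#' Passive (non-neural) ankle mechanics: torque
#' \code{tau_AIS = -(K_A * theta + B_A * theta_dot)} with `theta` in degrees.
#' Passive stiffness alone must be sub-critical (`K_A` expressed per radian
#' below `m g L_COM`), so that upright stance is unstable without active
#' control; this is enforced when an anthropometry is supplied.
#'
#' Defaults scale with the gravitational toppling stiffness:
#' \code{K_A = 0.15 m g L_COM} and \code{B_A = 0.05 m g L_COM} per radian
#' (converted to per-degree units). These are stated assumptions: the
#' literature places passive ankle stiffness well below the critical value,
#' but no single number is canonical.
#'
#' @param anthro an [anthropometry][derive_anthropometry] object used for the
#'   scaled defaults and the sub-criticality check; may be `NULL` when both
#'   gains are given explicitly.
#' @param K_A intrinsic stiffness, N m per degree.
#' @param B_A intrinsic damping, N m per (degree/second).
#' @param linearized logical; use `sin(theta) ~ theta` in the plant.
#' @return An object of class `plant_params` with fields `K_A`, `B_A`,
#'   `linearized`.
#' @export
plant_params <- function(anthro = NULL, K_A = NULL, B_A = NULL,
                         linearized = FALSE) {
  if (is.null(K_A) || is.null(B_A)) {
    if (is.null(anthro)) {
      ls_abort("supply `anthro` or both `K_A` and `B_A`",
               "leansim_error_validation")
    }
    mgl <- anthro$mass * anthro$g * anthro$L_COM
    if (is.null(K_A)) K_A <- 0.15 * mgl * .deg2rad
    if (is.null(B_A)) B_A <- 0.05 * mgl * .deg2rad
  }
  check_number(K_A, "K_A", 0)
  check_number(B_A, "B_A", 0)
  if (!is.null(anthro)) {
    mgl <- anthro$mass * anthro$g * anthro$L_COM
    if (K_A * .rad2deg >= mgl) {
      ls_abort(sprintf(
        "intrinsic stiffness K_A (%.1f N m/rad) must stay below m g L_COM (%.1f N m/rad): passive stance is sub-critically stiff",
        K_A * .rad2deg, mgl), "leansim_error_validation", field = "K_A")
    }
  }
  structure(list(K_A = K_A, B_A = B_A, linearized = isTRUE(linearized)),
            class = "plant_params")
}

#' Body state of the pendulum
#'
#' @param theta lean angle from vertical along the task direction, degrees
#'   (positive toward the target); must satisfy |theta| < 90.
#' @param theta_dot angular velocity, degrees per second.
#' @param t time, seconds.
#' @return An object of class `body_state`.
#' @export
body_state <- function(theta = 0, theta_dot = 0, t = 0) {
  check_number(theta, "theta", -90, 90, closed_lower = FALSE,
               closed_upper = FALSE)
  check_number(theta_dot, "theta_dot")
  check_number(t, "t")
  structure(list(theta = theta, theta_dot = theta_dot, t = t),
            class = "body_state")
}

#' Intrinsic (passive) ankle torque
#'
#' \code{tau_AIS = -(K_A * theta + B_A * theta_dot)}: the passive mechanics
#' oppose both displacement and velocity.
#'
#' @param state a [body_state] (angles in degrees).
#' @param plant a [plant_params] object.
#' @return torque in N m.
#' @export
intrinsic_torque <- function(state, plant) {
  -(plant$K_A * state$theta + plant$B_A * state$theta_dot)
}

#' Advance the pendulum one fixed RK4 step under a constant applied torque
#'
#' Integrates \code{J_B * theta_ddot = m g L_COM sin(theta) + tau_total}
#' (with \code{sin(theta)} replaced by \code{theta} when the plant is
#' linearized) by one classical fourth-order Runge-Kutta step. `tau_total`
#' is held constant over the step; closed-loop simulation, where the torque
#' varies within the step, is done by [simulate_trial()].
#'
#' @param state a [body_state]; angles in degrees.
#' @param tau_total applied torque in N m (on top of gravity).
#' @param anthro an [anthropometry][derive_anthropometry] object.
#' @param dt step size in seconds, in (0, 0.01].
#' @param plant a [plant_params] object; only `linearized` is used here
#'   (intrinsic torque, when wanted, belongs in `tau_total`).
#' @return the advanced [body_state] at `t + dt`.
#' @export
pendulum_step <- function(state, tau_total, anthro, dt,
                          plant = plant_params(anthro)) {
  check_number(dt, "dt", 0, 0.01, closed_lower = FALSE)
  if (!is.finite(tau_total)) {
    ls_abort("`tau_total` must be finite", "leansim_error_numeric")
  }
  th <- state$theta * .deg2rad
  thd <- state$theta_dot * .deg2rad
  mgl <- anthro$mass * anthro$g * anthro$L_COM
  f <- function(th, thd) {
    grav <- if (plant$linearized) mgl * th else mgl * sin(th)
    c(thd, (grav + tau_total) / anthro$J_B)
  }
  y <- c(th, thd)
  k1 <- f(y[1], y[2])
  k2 <- f(y[1] + dt / 2 * k1[1], y[2] + dt / 2 * k1[2])
  k3 <- f(y[1] + dt / 2 * k2[1], y[2] + dt / 2 * k2[2])
  k4 <- f(y[1] + dt * k3[1], y[2] + dt * k3[2])
  y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  body_state(y[1] * .rad2deg, y[2] * .rad2deg, state$t + dt)
}

#' COP displacement from body motion (linearized COP/ZMP relation)
#'
#' For a single inverted pendulum the centre of pressure is displaced from
#' the ankle by \code{COP = L_COM * theta - (J_B / (m g)) * theta_ddot}
#' (angles in radians; output in cm). In static conditions this reduces to
#' the ground projection of the COM; a body acceleration toward the target
#' pushes the COP the opposite way, which is the mechanical origin of the
#' anticipatory postural adjustment.
#'
#' @param theta lean angle, degrees.
#' @param theta_ddot angular acceleration, degrees per second squared.
#' @param anthro an [anthropometry][derive_anthropometry] object.
#' @return COP displacement in cm (positive toward the lean direction).
#' @export
cop_from_motion <- function(theta, theta_ddot, anthro) {
  100 * (anthro$L_COM * theta * .deg2rad -
           anthro$J_B / (anthro$mass * anthro$g) * theta_ddot * .deg2rad)
}
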