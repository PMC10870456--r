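#' Simulation configuration
#'
#' @param prep_s quiet-stance preparation before target onset, s
#'   (default 5, the protocol's baseline window).
#' @param tail_s quiet tail after the planned return, s; long enough for the
#'   COP to settle so the returning phase can be segmented.
#' @param dt integrator step, s; must divide the output sampling period
#'   exactly (default 1/800 s, ten integration steps per 80 Hz sample).
#' @param sampling_hz output sampling rate of the emitted COP, Hz.
#' @param blend `"printed"` or `"narrative"` APA blending (see
#'   [blend_torque()]).
#' @param noise_sd_cm SD of additive white measurement noise on the emitted
#'   COP channels, cm (0 disables; requires `seed` when positive).
#' @param seed integer seed for the measurement noise.
#' @param initial_theta,initial_theta_dot initial body state, deg and deg/s
#'   (defaults 0: calibrated upright stance).
#' @param diverge_deg lean angle treated as simulation divergence, degrees.
#' @param keep_states keep the full-rate internal states (body angle,
#'   torque components) in the trial metadata; used for model diagnostics.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(prep_s = 5, tail_s = 3, dt = 1 / 800,
                       sampling_hz = 80, blend = c("printed", "narrative"),
                       noise_sd_cm = 0, seed = NULL,
                       initial_theta = 0, initial_theta_dot = 0,
                       diverge_deg = 45, keep_states = FALSE) {
  blend <- match.arg(blend)
  check_number(prep_s, "prep_s", 0)
  check_number(tail_s, "tail_s", 0)
  check_number(dt, "dt", 0, 0.01, closed_lower = FALSE)
  check_number(sampling_hz, "sampling_hz", 0, closed_lower = FALSE)
  check_number(noise_sd_cm, "noise_sd_cm", 0)
  step_ratio <- 1 / (dt * sampling_hz)
  if (abs(step_ratio - round(step_ratio)) > 1e-9) {
    ls_abort("`dt` must divide the sampling period 1/sampling_hz exactly",
             "leansim_error_validation", field = "dt")
  }
  if (noise_sd_cm > 0 && is.null(seed)) {
    ls_abort("measurement noise requires an explicit `seed`",
             "leansim_error_validation", field = "seed")
  }
  structure(list(prep_s = prep_s, tail_s = tail_s, dt = dt,
                 sampling_hz = sampling_hz, blend = blend,
                 noise_sd_cm = noise_sd_cm, seed = seed,
                 initial_theta = initial_theta,
                 initial_theta_dot = initial_theta_dot,
                 diverge_deg = diverge_deg,
                 keep_states = isTRUE(keep_states)),
            class = "sim_config")
}

# Build the trial timeline and the analytic reference sampled on the
# half-step grid the RK4 stages need. Reused across gain evaluations
# during identification, where the plan is fixed.
.build_timeline <- function(params, config) {
  fs <- config$sampling_hz
  dur <- config$prep_s + params$t_r + params$t_f + params$hold +
    params$t_b + config$tail_s
  n_samp <- ceiling(dur * fs)
  total_s <- n_samp / fs
  n_steps <- as.integer(round(total_s / config$dt))
  t_half <- seq(0, by = config$dt / 2, length.out = 2L * n_steps + 1L)
  ref <- plan_reference(params, t_half - config$prep_s)
  list(n_steps = n_steps, n_samp = n_samp, total_s = total_s,
       onset = config$prep_s, ref = ref,
       decim = as.integer(round(1 / (config$dt * fs))))
}

.run_closed_loop <- function(timeline, anthro, plant, gains, params, config) {
  check_static_stability(gains, plant, anthro)
  raw <- simulate_closed_loop_cpp(
    timeline$ref$theta_ref * .deg2rad,
    timeline$ref$theta_ref_dot * .deg2rad,
    timeline$ref$theta_ref_ddot * .deg2rad,
    config$dt, timeline$n_steps,
    anthro$J_B, anthro$mass, anthro$L_COM, anthro$g,
    plant$K_A, plant$B_A, gains$K_P, gains$K_I, gains$K_FF,
    timeline$onset, params$t_r, params$t_APA,
    config$blend == "printed", plant$linearized,
    config$initial_theta * .deg2rad, config$initial_theta_dot * .deg2rad,
    config$diverge_deg * .deg2rad)
  if (isTRUE(raw$diverged)) {
    ls_abort(sprintf(
      "simulation diverged (|theta| > %g deg) at t = %.3f s with K_P = %.3f, K_FF = %.3f",
      config$diverge_deg, (raw$n_valid - 1) * config$dt,
      gains$K_P, gains$K_FF),
      "leansim_error_diverged", K_P = gains$K_P, K_FF = gains$K_FF)
  }
  raw
}

#' Simulate one voluntary-lean COP trial
#'
#' Runs the closed loop of motor planning and postural control: the
#' reference trajectory from [plan_reference()] drives the feedback and
#' feedforward controllers, whose blended torque ([blend_torque()]) moves
#' the inverted-pendulum plant; the emitted COP is the linearized COP/ZMP
#' output of [cop_from_motion()], sampled at `sampling_hz` along the
#' task direction.
#'
#' The trial starts with `prep_s` seconds of quiet stance (the baseline the
#' segmentation uses), has its target-onset event at the end of the
#' preparation, and ends `tail_s` seconds after the planned return. With
#' measurement noise disabled the output is fully deterministic; with noise
#' enabled it is deterministic given the seed.
#'
#' @param anthro an [anthropometry][derive_anthropometry] object.
#' @param plant a [plant_params] object.
#' @param params a [planning_params] object.
#' @param gains a [control_gains] object; must satisfy the closed-loop
#'   static-stability condition.
#' @param config a [sim_config].
#' @param direction unit vector (AP, ML) toward the target; the simulated
#'   1-DOF lean is mapped to the two planar COP channels through it.
#' @param target_id optional target label carried in the trial.
#' @return A `cop_trial` object: list with `time` (s), `cop_ap`, `cop_ml`
#'   (cm), `target_onset` (s), `target_id`, `sampling_hz` and `metadata`
#'   (anthropometry, gains, plan, config, and optionally the internal
#'   states).
#' @export
simulate_trial <- function(anthro, plant, params, gains,
                           config = sim_config(), direction = c(1, 0),
                           target_id = 1L) {
  if (length(direction) != 2L || !all(is.finite(direction))) {
    ls_abort("`direction` must be a finite (AP, ML) vector",
             "leansim_error_validation", field = "direction")
  }
  len <- sqrt(sum(direction^2))
  if (len <= 0) {
    ls_abort("`direction` must be non-zero", "leansim_error_validation",
             field = "direction")
  }
  direction <- direction / len

  timeline <- .build_timeline(params, config)
  raw <- .run_closed_loop(timeline, anthro, plant, gains, params, config)

  keep <- seq(1L, timeline$n_steps + 1L, by = timeline$decim)
  time <- (keep - 1L) * config$dt
  cop_cm <- raw$cop_m[keep] * 100
  cop_ap <- cop_cm * direction[1]
  cop_ml <- cop_cm * direction[2]
  if (config$noise_sd_cm > 0) {
    noise <- with_seed(config$seed,
                       rnorm(2L * length(keep), sd = config$noise_sd_cm))
    cop_ap <- cop_ap + noise[seq_along(keep)]
    cop_ml <- cop_ml + noise[length(keep) + seq_along(keep)]
  }

  metadata <- list(anthropometry = unclass(anthro),
                   plant = unclass(plant),
                   gains = unclass(gains),
                   planning = unclass(params),
                   direction = direction,
                   noise_sd_cm = config$noise_sd_cm,
                   seed = config$seed,
                   blend = config$blend)
  if (config$keep_states) {
    metadata$states <- data.frame(
      t = seq(0, by = config$dt, length.out = timeline$n_steps + 1L),
      theta = raw$theta * .rad2deg, theta_dot = raw$theta_dot * .rad2deg,
      theta_ddot = raw$theta_ddot * .rad2deg, cop_cm = raw$cop_m * 100,
      tau_fb = raw$tau_fb, tau_ff = raw$tau_ff, tau_ais = raw$tau_ais,
      alpha = raw$alpha, tau_total = raw$tau_total)
  }

  cop_trial(time = time, cop_ap = cop_ap, cop_ml = cop_ml,
            target_onset = timeline$onset, target_id = target_id,
            sampling_hz = config$sampling_hz, metadata = metadata)
}

#' Construct (and validate) a COP trial object
#'
#' A uniformly sampled planar COP recording with a target-onset event.
#' Validates the uniform grid and the minimum 5 s baseline.
#'
#' @param time sample times, s (uniform grid starting at 0).
#' @param cop_ap,cop_ml COP displacement channels, cm.
#' @param target_onset target-onset event time, s (>= 5 s of baseline).
#' @param target_id target label (1-8).
#' @param sampling_hz sampling rate, Hz.
#' @param metadata free-form list.
#' @return An object of class `cop_trial`.
#' @export
cop_trial <- function(time, cop_ap, cop_ml, target_onset, target_id,
                      sampling_hz = 80, metadata = list()) {
  n <- length(time)
  if (length(cop_ap) != n || length(cop_ml) != n) {
    ls_abort("time and COP channels must have equal length",
             "leansim_error_format")
  }
  if (anyNA(time) || anyNA(cop_ap) || anyNA(cop_ml)) {
    ls_abort("missing samples are not allowed", "leansim_error_format")
  }
  step <- 1 / sampling_hz
  dev <- abs(diff(time) - step)
  if (any(dev > 1e-6)) {
    ls_abort(sprintf("non-uniform time grid at index %d",
                     which(dev > 1e-6)[1] + 1L),
             "leansim_error_format", index = which(dev > 1e-6)[1] + 1L)
  }
  if (target_onset < 5) {
    ls_abort("target_onset must allow >= 5 s of quiet-stance baseline",
             "leansim_error_format", field = "target_onset")
  }
  structure(list(time = time, cop_ap = cop_ap, cop_ml = cop_ml,
                 target_onset = target_onset, target_id = target_id,
                 sampling_hz = sampling_hz, metadata = metadata),
            class = "cop_trial")
}

#' @export
print.cop_trial <- function(x, ...) {
  cat(sprintf(
    "<cop_trial> target %s, %d samples at %g Hz (%.2f s), onset %.2f s\n",
    x$target_id, length(x$time), x$sampling_hz,
    x$time[length(x$time)], x$target_onset))
  invisible(x)
}
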