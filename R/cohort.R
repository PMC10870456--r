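#' Specification of a synthetic study cohort
#'
#' Describes the statistical structure of a two-group voluntary-lean study:
#' group sizes, demographic distributions, per-direction means of the
#' temporal parameters and control gains, between-subject spread, and the
#' rank-correlation structure linking gains to clinical scores.
#'
#' Between-subject spreads are not published for the normative tables, so
#' they are configured as a coefficient of variation (default 15% of the
#' group-direction mean) and must be treated as assumptions. Gain-clinical
#' correlations are induced by a shared latent severity factor (Gaussian
#' copula): clinical scores load on the factor with weight 0.8, and the
#' gains of the configured directions load with `strength / 0.8`, so the
#' product recovers the configured correlation.
#'
#' @param n_pd,n_healthy subjects per group (>= 2).
#' @param cv between-subject coefficient of variation of all planning and
#'   gain parameters (>= 0).
#' @param correlation list with `strength` (absolute gain-score
#'   correlation, |rho| <= 1) and the direction sets `kp_updrs_targets`
#'   (K_P loads positively on severity there), `kp_frt_targets` and
#'   `kff_updrs_targets` (K_FF loads negatively). Defaults: strength 0.6,
#'   K_P-UPDRS in the backward directions 6-8, K_P-FRT (negative) in the
#'   forward directions 1-3, K_FF in directions 1, 5, 7.
#' @param param_means per-direction group means, as from
#'   [group_parameter_defaults()].
#' @param demographics as from [group_demographic_defaults()]; SDs may be
#'   set to zero for degenerate cohorts.
#' @param seed default seed used by [generate_cohort()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pd = 24, n_healthy = 24, cv = 0.15,
                        correlation = list(strength = 0.6,
                                           kp_updrs_targets = 6:8,
                                           kp_frt_targets = 1:3,
                                           kff_updrs_targets = c(1, 5, 7)),
                        param_means = group_parameter_defaults(),
                        demographics = group_demographic_defaults(),
                        seed = NULL) {
  if (n_pd < 2 || n_healthy < 2) {
    ls_abort("need at least 2 subjects per group", "leansim_error_spec")
  }
  check_number(cv, "cv", 0)
  check_number(correlation$strength, "correlation$strength", 0, 1)
  structure(list(n_pd = n_pd, n_healthy = n_healthy, cv = cv,
                 correlation = correlation, param_means = param_means,
                 demographics = demographics, seed = seed),
            class = "cohort_spec")
}

# identification bounds double as physiologic truncation bounds for draws
.param_bounds <- list(
  t_r = c(0.05, 5), t_apa = c(0.05, 2), t_f = c(0.2, 8), t_b = c(0.2, 8),
  apa_size = c(0, 10), lean_max = c(0.1, 20),
  k_p = c(5, 300), k_ff = c(0, 30)
)

#' Generate a synthetic cohort of subjects
#'
#' Draws subjects for both groups from truncated normal distributions
#' around the configured group/direction means. Clinical scores (patient
#' group only) and the gains of the configured directions share a latent
#' severity factor, inducing the configured rank correlations. Deterministic
#' given the seed.
#'
#' @param spec a [cohort_spec].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return A list of `subject_record` objects (class `lean_cohort`), each
#'   with `id`, `group`, `age`, `anthropometry`, `clinical` (UPDRS/FRT or
#'   `NA`), and `params`, a per-direction data.frame of true planning
#'   parameters and gains.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  load_w <- 0.8  # clinical-score loading on the latent severity factor
  gain_w <- spec$correlation$strength / load_w
  if (gain_w > 1) {
    ls_abort("correlation strength above 0.8 is not representable by the copula",
             "leansim_error_spec")
  }
  with_seed(seed, {
    subjects <- list()
    sid <- 0L
    for (group in c("pd", "healthy")) {
      n <- if (group == "pd") spec$n_pd else spec$n_healthy
      dem <- spec$demographics[[group]]
      means <- spec$param_means[spec$param_means$group == group, ,
                                drop = FALSE]
      for (i in seq_len(n)) {
        sid <- sid + 1L
        height <- rtrunc_norm(1, dem$height_cm[1] / 100,
                              dem$height_cm[2] / 100, 1.21, 2.19)
        mass <- rtrunc_norm(1, dem$mass[1], dem$mass[2], 31, 149)
        age <- rtrunc_norm(1, dem$age[1], dem$age[2], 18, 95)
        anthro <- derive_anthropometry(height, mass)

        xi <- rnorm(1)  # latent severity
        clinical <- list(updrs = NA_real_, frt = NA_real_)
        if (!is.null(dem$updrs)) {
          clinical$updrs <- rtrunc_norm(
            1, dem$updrs[1] + dem$updrs[2] * load_w * xi,
            dem$updrs[2] * sqrt(1 - load_w^2), 0, 108)
          clinical$frt <- rtrunc_norm(
            1, dem$frt[1] - dem$frt[2] * load_w * xi,
            dem$frt[2] * sqrt(1 - load_w^2), 1, 80)
        }

        draw <- function(mu, par, target) {
          lam <- 0
          if (par == "k_p" &&
              (target %in% spec$correlation$kp_updrs_targets ||
               target %in% spec$correlation$kp_frt_targets)) {
            lam <- gain_w
          }
          if (par == "k_ff" &&
              target %in% spec$correlation$kff_updrs_targets) {
            lam <- -gain_w
          }
          z <- lam * xi + sqrt(1 - lam^2) * rnorm(1)
          b <- .param_bounds[[par]]
          min(max(mu * (1 + spec$cv * z), b[1]), b[2])
        }
        pars <- do.call(rbind, lapply(seq_len(nrow(means)), function(r) {
          m <- means[r, ]
          row <- data.frame(target_id = m$target_id)
          for (par in c("t_r", "t_apa", "t_f", "t_b", "k_p", "k_ff")) {
            row[[par]] <- draw(m[[par]], par, m$target_id)
          }
          # APA window cannot outlast the reach
          row$t_apa <- min(row$t_apa, 0.9 * row$t_f)
          row
        }))

        subjects[[sid]] <- structure(
          list(id = sprintf("S%03d", sid), group = group, age = age,
               anthropometry = anthro, clinical = clinical,
               severity = xi, params = pars),
          class = "subject_record")
      }
    }
    structure(subjects, class = "lean_cohort", spec = spec, seed = seed)
  })
}

#' @export
print.lean_cohort <- function(x, ...) {
  groups <- table(vapply(x, `[[`, character(1), "group"))
  cat(sprintf("<lean_cohort> %d subjects (%s)\n", length(x),
              paste(sprintf("%s: %d", names(groups), groups),
                    collapse = ", ")))
  invisible(x)
}

#' Long table of per-subject, per-direction parameters
#'
#' Flattens a cohort into the table the statistics stage consumes: one row
#' per subject and direction with the true planning parameters, gains and
#' clinical scores.
#'
#' @param cohort a `lean_cohort` from [generate_cohort()].
#' @return A data.frame with columns `subject`, `group`, `target_id`,
#'   `t_r`, `t_apa`, `t_f`, `t_b`, `k_p`, `k_ff`, `updrs`, `frt`.
#' @export
cohort_parameter_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    cbind(data.frame(subject = s$id, group = s$group), s$params,
          data.frame(updrs = s$clinical$updrs, frt = s$clinical$frt))
  }))
}

#' Simulate the full set of trials for one synthetic subject
#'
#' Forward-simulates every requested target direction and repetition with
#' the subject's true parameters, optionally adding seeded white
#' measurement noise to the emitted COP.
#'
#' @param subject a `subject_record` from [generate_cohort()].
#' @param layout a [target_layout]; defaults to the subject's own
#'   (`L_COM`-scaled) layout.
#' @param noise list with `cop_sd_cm` (default 0) and `seed` (required when
#'   the SD is positive); per-trial sub-seeds are derived deterministically.
#' @param repetitions trials per direction (default 4, the protocol).
#' @param targets target ids to simulate (default all 8).
#' @param config base [sim_config]; noise settings are overridden per trial.
#' @return A list of [cop_trial] objects (length
#'   `length(targets) * repetitions`).
#' @export
generate_trials <- function(subject, layout = NULL,
                            noise = list(cop_sd_cm = 0, seed = NULL),
                            repetitions = 4, targets = 1:8,
                            config = sim_config()) {
  anthro <- subject$anthropometry
  if (is.null(layout)) layout <- target_layout(anthro$L_COM)
  plant <- plant_params(anthro)
  sd_cm <- if (is.null(noise$cop_sd_cm)) 0 else noise$cop_sd_cm
  if (sd_cm > 0 && is.null(noise$seed)) {
    ls_abort("measurement noise requires `noise$seed`",
             "leansim_error_validation", field = "seed")
  }
  trials <- list()
  k <- 0L
  for (tid in as.integer(targets)) {
    p <- subject$params[subject$params$target_id == tid, ]
    dir <- target_direction(layout, tid)
    params <- planning_params(t_r = p$t_r, t_f = p$t_f, t_b = p$t_b,
                              t_APA = p$t_apa,
                              theta_f = theta_target_from_distance(
                                dir$distance, anthro$L_COM))
    gains <- control_gains(K_P = p$k_p, K_FF = p$k_ff)
    for (rep in seq_len(repetitions)) {
      k <- k + 1L
      cfg <- config
      cfg$noise_sd_cm <- sd_cm
      cfg$seed <- if (sd_cm > 0) {
        (noise$seed + 997L * tid + rep) %% .Machine$integer.max
      } else NULL
      tr <- tryCatch(
        simulate_trial(anthro, plant, params, gains, cfg,
                       direction = dir$unit, target_id = tid),
        leansim_error_diverged = function(e) {
          ls_abort(sprintf("subject %s target %d: %s",
                           subject$id, tid, conditionMessage(e)),
                   "leansim_error_diverged")
        })
      tr$metadata$subject_id <- subject$id
      tr$metadata$group <- subject$group
      tr$metadata$repetition <- rep
      trials[[k]] <- tr
    }
  }
  trials
}
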