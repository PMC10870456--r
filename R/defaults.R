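# Published group-level means of the temporal parameters, COP features and
# control gains per lean direction, for Parkinson's disease (pd) and
# age-matched healthy (healthy) cohorts. These are the defaults the
# synthetic cohort generator draws around; within-group spreads are NOT
# published and are configured separately (see cohort_spec()).

.group_means <- local({
  tgt <- 1:8
  pd <- data.frame(
    group = "pd", target_id = tgt,
    t_r = c(0.9, 0.88, 0.93, 0.92, 1.05, 1.48, 1.38, 1.25),
    t_apa = c(0.36, 0.38, 0.36, 0.41, 0.33, 0.53, 0.45, 0.35),
    t_f = c(2.50, 2.83, 2.61, 2.05, 2.60, 3.07, 2.71, 2.84),
    t_b = c(2.34, 2.85, 2.95, 2.6, 2.67, 2.80, 2.76, 2.19),
    t_total = c(5.74, 6.57, 6.61, 5.59, 6.31, 7.35, 6.86, 5.95),
    apa_size = c(0.63, 0.52, 0.71, 0.67, 0.54, 0.51, 0.49, 0.38),
    lean_max = c(4.32, 4.49, 4.51, 4.69, 4.46, 4.11, 3.98, 2.60),
    k_p = c(61.73, 86.20, 81.27, 91.30, 99.32, 103.01, 105.93, 104.60),
    k_ff = c(4.16, 4.09, 5.18, 4.90, 4.12, 4.57, 4.56, 5.14)
  )
  h <- data.frame(
    group = "healthy", target_id = tgt,
    t_r = c(0.35, 0.35, 0.4, 0.41, 0.32, 0.3, 0.34, 0.53),
    t_apa = c(0.46, 0.48, 0.58, 0.52, 0.43, 0.60, 0.50, 0.49),
    t_f = c(2.00, 2.14, 1.91, 2.08, 1.90, 2.25, 2.60, 2.01),
    t_b = c(1.51, 1.46, 1.74, 1.51, 1.50, 1.48, 1.59, 1.49),
    t_total = c(3.88, 3.95, 4.06, 4.00, 3.73, 4.02, 4.53, 4.04),
    apa_size = c(1.58, 1.46, 1.42, 1.59, 1.59, 1.55, 1.42, 1.07),
    lean_max = c(5.00, 6.14, 6.46, 6.73, 6.68, 6.25, 6.34, 4.25),
    k_p = c(42.40, 33.08, 29.80, 33.90, 30.30, 29.22, 30.81, 51.20),
    k_ff = c(14.95, 14.88, 15.64, 14.80, 15.10, 15.34, 14.72, 17.8)
  )
  rbind(pd, h)
})

# demographic and clinical normative values: mean and SD per group
.group_demographics <- list(
  healthy = list(age = c(54.9, 7.4), height_cm = c(175.6, 8.8),
                 mass = c(77.28, 12.7)),
  pd = list(age = c(61.5, 9.6), height_cm = c(164.5, 8.4),
            mass = c(68.5, 11.5),
            updrs = c(26.14, 4.4), frt = c(31.5, 10.2))
)

#' Normative per-direction group parameters
#'
#' Group-mean values, per lean direction (targets 1-8), of the temporal
#' parameters (`t_r`, `t_apa`, `t_f`, `t_b`, `t_total`, seconds), the two
#' COP features (`apa_size`, `lean_max`, cm) and the control gains (`k_p`,
#' N m/deg; `k_ff`, dimensionless) for Parkinson's disease patients and
#' age-matched healthy adults. These are the defaults around which
#' [generate_cohort()] draws synthetic subjects.
#'
#' @param group optional filter, `"pd"` or `"healthy"`.
#' @return A data.frame with one row per group and target.
#' @export
group_parameter_defaults <- function(group = NULL) {
  out <- .group_means
  if (!is.null(group)) {
    group <- match.arg(group, c("pd", "healthy"))
    out <- out[out$group == group, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Normative demographics and clinical scores per group
#'
#' Mean and SD of age (years), height (cm) and mass (kg) per group, and,
#' for the patient group, the UPDRS and Functional Reach Test scores used
#' to correlate with the identified gains.
#'
#' @return A nested list (`healthy`, `pd`) of `c(mean, sd)` pairs.
#' @export
group_demographic_defaults <- function() .group_demographics
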