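test_that("cohort generation is deterministic per seed", {
  c1 <- generate_cohort(cohort_spec(n_pd = 4, n_healthy = 4), seed = 11)
  c2 <- generate_cohort(cohort_spec(n_pd = 4, n_healthy = 4), seed = 11)
  expect_identical(cohort_parameter_table(c1), cohort_parameter_table(c2))
  c3 <- generate_cohort(cohort_spec(n_pd = 4, n_healthy = 4), seed = 12)
  expect_false(identical(cohort_parameter_table(c1),
                         cohort_parameter_table(c3)))
})

test_that("degenerate zero-spread cohorts reproduce the group means", {
  dem <- group_demographic_defaults()
  for (g in names(dem)) for (k in names(dem[[g]])) dem[[g]][[k]][2] <- 0
  coh <- generate_cohort(cohort_spec(n_pd = 2, n_healthy = 2, cv = 0,
                                     demographics = dem), seed = 1)
  tab <- cohort_parameter_table(coh)
  means <- group_parameter_defaults()
  for (grp in c("pd", "healthy")) {
    got <- tab[tab$group == grp & tab$target_id == 1, ]
    want <- means[means$group == grp & means$target_id == 1, ]
    expect_equal(unique(got$k_p), want$k_p, tolerance = 1e-12)
    expect_equal(unique(got$k_ff), want$k_ff, tolerance = 1e-12)
    expect_equal(unique(got$t_r), want$t_r, tolerance = 1e-12)
  }
})

test_that("large cohorts concentrate on the configured means", {
  coh <- generate_cohort(cohort_spec(n_pd = 200, n_healthy = 2), seed = 42)
  tab <- cohort_parameter_table(coh)
  kp_t1 <- tab$k_p[tab$group == "pd" & tab$target_id == 1]
  expect_lt(abs(mean(kp_t1) - 61.73) / 61.73, 0.05)
  # truncation respects the identification bounds
  expect_true(all(tab$k_p >= 5 & tab$k_p <= 300))
  expect_true(all(tab$k_ff >= 0 & tab$k_ff <= 30))
  expect_true(all(tab$t_r > 0 & tab$t_apa < tab$t_f))
})

test_that("clinical scores correlate with gains as configured", {
  coh <- generate_cohort(cohort_spec(n_pd = 400, n_healthy = 2), seed = 9)
  tab <- cohort_parameter_table(coh)
  pd <- tab[tab$group == "pd", ]
  # backward direction: K_P loads positively on severity, as does UPDRS
  r_updrs <- cor(pd$k_p[pd$target_id == 7], pd$updrs[pd$target_id == 7],
                 method = "spearman")
  expect_gt(r_updrs, 0.4)
  # forward direction: FRT declines with severity, so K_P-FRT is negative
  r_frt <- cor(pd$k_p[pd$target_id == 1], pd$frt[pd$target_id == 1],
               method = "spearman")
  expect_lt(r_frt, -0.4)
  # unconfigured direction: no induced correlation
  r_null <- cor(pd$k_ff[pd$target_id == 3], pd$updrs[pd$target_id == 3],
                method = "spearman")
  expect_lt(abs(r_null), 0.15)
})

test_that("trial generation covers targets x repetitions deterministically", {
  coh <- generate_cohort(cohort_spec(n_pd = 2, n_healthy = 2), seed = 21)
  subj <- coh[[3]]  # a healthy subject
  trials <- generate_trials(subj, targets = c(1, 8), repetitions = 2)
  expect_length(trials, 4L)
  expect_equal(vapply(trials, `[[`, integer(1), "target_id"),
               c(1L, 1L, 8L, 8L))
  # noiseless repetitions are identical
  expect_identical(trials[[1]]$cop_ap, trials[[2]]$cop_ap)
  # backward target leans backward
  expect_lt(min(trials[[3]]$cop_ap), 0)

  noisy <- generate_trials(subj, noise = list(cop_sd_cm = 0.05, seed = 5),
                           targets = 1, repetitions = 2)
  expect_false(identical(noisy[[1]]$cop_ap, noisy[[2]]$cop_ap))
  again <- generate_trials(subj, noise = list(cop_sd_cm = 0.05, seed = 5),
                           targets = 1, repetitions = 2)
  expect_identical(noisy[[1]]$cop_ap, again[[1]]$cop_ap)
})

test_that("noiseless subject round-trips through segment and identify", {
  coh <- generate_cohort(cohort_spec(n_pd = 2, n_healthy = 2), seed = 33)
  subj <- coh[[4]]
  lay <- target_layout(subj$anthropometry$L_COM)
  trials <- generate_trials(subj, lay, targets = 1, repetitions = 1)
  seg <- segment_trial(trials[[1]], lay)
  truth <- subj$params[subj$params$target_id == 1, ]
  expect_lt(abs(seg$t_r - truth$t_r), 1 / 80 + 1e-9)
  dirv <- leansim:::target_direction(lay, 1)
  p <- planning_params(t_r = truth$t_r, t_f = truth$t_f, t_b = truth$t_b,
                       t_APA = truth$t_apa,
                       theta_f = theta_target_from_distance(
                         dirv$distance, subj$anthropometry$L_COM))
  fit <- identify_gains(feature_pair(seg$lean_max, seg$apa_size),
                        subj$anthropometry,
                        plant_params(subj$anthropometry), p)
  expect_lt(abs(fit$K_P - truth$k_p) / truth$k_p, 0.02)
  expect_lt(abs(fit$K_FF - truth$k_ff) / truth$k_ff, 0.02)
})
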