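test_that("closed-loop simulation is deterministic", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  p <- healthy_t1_params()
  g <- control_gains(42.40, 14.95)
  t1 <- simulate_trial(a, pl, p, g)
  t2 <- simulate_trial(a, pl, p, g)
  expect_identical(t1$cop_ap, t2$cop_ap)

  cfgn <- sim_config(noise_sd_cm = 0.05, seed = 7)
  n1 <- simulate_trial(a, pl, p, g, cfgn)
  n2 <- simulate_trial(a, pl, p, g, cfgn)
  expect_identical(n1$cop_ap, n2$cop_ap)
  n3 <- simulate_trial(a, pl, p, g, sim_config(noise_sd_cm = 0.05, seed = 8))
  expect_false(identical(n1$cop_ap, n3$cop_ap))
  # noise leaves the caller's RNG untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_trial(a, pl, p, g, cfgn)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("stored total torque equals the recomputed blend at every sample", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  p <- healthy_t1_params()
  tr <- simulate_trial(a, pl, p, control_gains(61.73, 4.16),
                       sim_config(keep_states = TRUE))
  st <- tr$metadata$states
  sub <- st[seq(1, nrow(st), by = 7), ]  # spot-check across the trial
  recomputed <- mapply(function(t, ff, fb, ais) {
    blend_torque(t - tr$target_onset, p, ff, fb, ais)$tau_total
  }, sub$t, sub$tau_ff, sub$tau_fb, sub$tau_ais)
  expect_true(all(abs(recomputed - sub$tau_total) < 1e-9))
})

test_that("preparation is quiet and the APA has the anticipatory sign", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  p <- healthy_t1_params()
  for (g in list(control_gains(42.40, 14.95), control_gains(61.73, 4.16))) {
    tr <- simulate_trial(a, pl, p, g)
    base <- tr$cop_ap[tr$time < tr$target_onset]
    expect_true(all(abs(base) < 1e-9))
    post <- tr$cop_ap[tr$time > tr$target_onset]
    # first departure from baseline is opposite the (positive) target
    first_move <- post[abs(post) > 1e-6][1]
    expect_lt(first_move, 0)
  }
})

test_that("unstable or diverging gain settings raise typed errors", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  p <- healthy_t1_params()
  expect_error(simulate_trial(a, pl, p, control_gains(5, 1)),
               class = "leansim_error_unstable_gains")
  expect_error(simulate_trial(a, pl, p, control_gains(12, 1000)),
               class = "leansim_error_diverged")
})

test_that("simulated reaction time is recovered within one sample", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  lay <- target_layout(a$L_COM)
  for (tr_true in c(0.35, 0.9)) {
    p <- planning_params(t_r = tr_true, t_f = 2.2, t_b = 1.6, t_APA = 0.45,
                        theta_f = 1.879)
    tr <- simulate_trial(a, pl, p, control_gains(60, 6))
    seg <- segment_trial(tr, lay)
    expect_lt(abs(seg$t_r - tr_true), 1 / 80 + 1e-9)
  }
})

test_that("held target reference converges with monotone accuracy in K_P", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  p <- planning_params(t_r = 0.35, t_f = 2, t_b = 1.5, t_APA = 0.46,
                      theta_f = 1.879, hold = 6)
  err <- vapply(c(20, 40, 80, 160, 300), function(kp) {
    tr <- simulate_trial(a, pl, p, control_gains(kp, 0),
                         sim_config(tail_s = 1, keep_states = TRUE))
    st <- tr$metadata$states
    i_end <- which.min(abs(st$t - (5 + 0.35 + 2 + 5.8)))
    # COP has converged onto the COM projection at steady state
    expect_lt(abs(st$cop_cm[i_end] -
                    100 * a$L_COM * st$theta[i_end] * pi / 180), 1e-3)
    abs(1.879 - st$theta[i_end])
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("trial container rejects malformed recordings", {
  t <- seq(0, 8, by = 1 / 80)
  x <- rep(0, length(t))
  expect_s3_class(cop_trial(t, x, x, 5, 1), "cop_trial")
  t_bad <- t; t_bad[100] <- t_bad[100] + 0.004
  err <- expect_error(cop_trial(t_bad, x, x, 5, 1),
                      class = "leansim_error_format")
  expect_match(conditionMessage(err), "index 100")
  expect_error(cop_trial(t, x, x, 3, 1), class = "leansim_error_format")
})
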