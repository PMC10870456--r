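test_that("feature surfaces are deterministic with missing unstable points", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  p <- healthy_t1_params()
  kp <- c(5, 40, 90, 200)
  kff <- c(0, 5, 12, 25)
  s1 <- feature_surface(a, pl, p, kp, kff)
  s2 <- feature_surface(a, pl, p, kp, kff)
  expect_identical(s1$apa_size, s2$apa_size)
  expect_identical(s1$lean_max, s2$lean_max)
  # K_P = 5 N m/deg is below the static stability threshold: missing row
  expect_true(all(is.na(s1$apa_size[1, ])))
  expect_true(all(!is.na(s1$apa_size[-1, ])))
  # APA size grows with the feedforward gain along every stable row
  for (i in 2:4) expect_true(all(diff(s1$apa_size[i, ]) > 0))
  # without feedforward the APA reduces to the small feedback-driven floor
  expect_true(all(s1$apa_size[-1, 1] < 0.5))
  expect_true(all(s1$apa_size[-1, 4] > 2))
})

test_that("all-unstable grids raise an empty-surface error", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  p <- healthy_t1_params()
  expect_error(feature_surface(a, pl, p, c(5, 8), c(0, 5)),
               class = "leansim_error_empty_surface")
})

test_that("identification inverts simulated features to the planted gains", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  lay <- target_layout(a$L_COM)
  p <- healthy_t1_params()
  for (g in list(c(42.40, 14.95), c(61.73, 4.16))) {
    tr <- simulate_trial(a, pl, p, control_gains(g[1], g[2]))
    seg <- segment_trial(tr, lay)
    fit <- identify_gains(feature_pair(seg$lean_max, seg$apa_size),
                          a, pl, p)
    expect_lt(abs(fit$K_P - g[1]) / g[1], 0.01)
    expect_lt(abs(fit$K_FF - g[2]) / g[2], 0.01)
    expect_true(fit$converged)
    # no regression against any multi-start initialization
    obj2_solution <- (fit$residual_lean / fit$scales[["lean"]])^2 +
      (fit$residual_apa / fit$scales[["apa"]])^2
    expect_lte(obj2_solution, min(fit$starts$objective) + 1e-9)
  }
})

test_that("feedback-only features identify a near-zero feedforward gain", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  lay <- target_layout(a$L_COM)
  p <- healthy_t1_params()
  tr <- simulate_trial(a, pl, p, control_gains(61.73, 0))
  seg <- segment_trial(tr, lay)
  fit <- identify_gains(feature_pair(seg$lean_max, seg$apa_size), a, pl, p)
  expect_lte(fit$K_FF, 0.1)
})

test_that("degenerate zero targets return a flagged boundary fit", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  p <- healthy_t1_params()
  fit <- identify_gains(feature_pair(0, 0), a, pl, p)
  expect_true(any(fit$bounds_hit))
  expect_false(fit$converged)
  expect_true(is.finite(fit$objective))
})

test_that("identification commutes with feature averaging", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  lay <- target_layout(a$L_COM)
  p <- healthy_t1_params()
  tr <- simulate_trial(a, pl, p, control_gains(55, 7))
  seg <- segment_trial(tr, lay)
  feats <- data.frame(target_id = 1, apa_size = seg$apa_size,
                      lean_max = seg$lean_max, flagged = FALSE)
  agg <- aggregate_subject(do.call(rbind, replicate(4, feats,
                                                    simplify = FALSE)))
  fit1 <- identify_gains(feature_pair(seg$lean_max, seg$apa_size), a, pl, p)
  fit4 <- identify_gains(feature_pair(agg$lean_max, agg$apa_size), a, pl, p)
  expect_equal(fit1$K_P, fit4$K_P)
  expect_equal(fit1$K_FF, fit4$K_FF)
})

test_that("planted gains are recovered across the physiologic range", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  lay <- target_layout(a$L_COM)
  p <- healthy_t1_params()
  set.seed(101)
  kp <- runif(5, 30, 105)
  kff <- runif(5, 4, 17)
  errs <- vapply(1:5, function(i) {
    tr <- simulate_trial(a, pl, p, control_gains(kp[i], kff[i]))
    seg <- segment_trial(tr, lay)
    fit <- identify_gains(feature_pair(seg$lean_max, seg$apa_size),
                          a, pl, p)
    max(abs(fit$K_P - kp[i]) / kp[i], abs(fit$K_FF - kff[i]) / kff[i])
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})
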