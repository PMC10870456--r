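test_that("projection reduces planar COP to the task axis", {
  lay <- target_layout(1)
  tr <- trapezoid_trial(target_id = 1)
  s <- project_onto_direction(tr, lay)
  expect_equal(s, tr$cop_ap - mean(tr$cop_ap[tr$time < 5]))

  # a COP sitting exactly on the target projects to the target distance
  t <- seq(0, 8, by = 1 / 80)
  row <- lay[lay$target_id == 4, ]
  on_target <- ifelse(t < 5, 0, 1)
  tr4 <- cop_trial(t, 100 * row$ap_distance * on_target,
                   100 * row$ml_distance * on_target, 5, 4)
  s4 <- project_onto_direction(tr4, lay)
  d <- 100 * sqrt(row$ap_distance^2 + row$ml_distance^2)
  expect_equal(max(s4), d, tolerance = 1e-12)

  expect_error(project_onto_direction(
    cop_trial(t, on_target, on_target, 5, 99), lay),
    class = "leansim_error_validation")
})

test_that("APA onset detection crosses 2 SD opposite the target, sustained", {
  fs <- 80
  t <- seq(0, 10, by = 1 / fs)
  set.seed(3)
  noise <- rnorm(length(t), sd = 0.02)
  ramp <- ifelse(t > 7, -(t - 7) * 2, 0)
  sig <- noise + ramp
  onset <- detect_apa_onset(sig, t, target_onset = 6)
  # analytic crossing: ramp passes 2 SD of the (noisy) baseline
  thr <- mean(sig[t < 6]) - 2 * sd(sig[t < 6])
  expect_gte(onset, 7)
  expect_lt(onset, 7.2)
  # scaling the whole signal leaves the onset unchanged
  expect_identical(detect_apa_onset(3.7 * sig, t, 6), onset)
  # pure baseline noise: no APA
  expect_error(detect_apa_onset(noise, t, 6),
               class = "leansim_error_no_apa")
})

test_that("trapezoid fixture yields its closed-form segmentation", {
  lay <- target_layout(1)
  seg <- segment_trial(trapezoid_trial(), lay)
  expect_equal(seg$t_r, 0.5125, tolerance = 1e-9)
  expect_equal(seg$apa_size, 1, tolerance = 1e-6)
  expect_equal(seg$t_APA, 6.5 - 5.5125, tolerance = 1e-9)
  expect_equal(seg$lean_max, 4, tolerance = 1e-6)
  expect_equal(seg$t_f, 8 - 5.5125, tolerance = 1e-9)
  expect_equal(seg$t_b, 2.5, tolerance = 1 / 80 + 1e-9)
  expect_equal(seg$t_total, seg$t_r + seg$t_f + seg$t_b)
})

test_that("segmentation is invariant to sign convention and offsets", {
  lay <- target_layout(1)
  ref <- segment_trial(trapezoid_trial(target_id = 1), lay)
  # backward target with mirrored signal: identical magnitudes
  flip <- segment_trial(trapezoid_trial(target_id = 8), lay)
  for (f in c("t_r", "t_APA", "t_f", "t_b", "apa_size", "lean_max")) {
    expect_equal(flip[[f]], ref[[f]], tolerance = 1e-12)
  }
  # constant offset on both channels changes nothing
  tr <- trapezoid_trial()
  tr$cop_ap <- tr$cop_ap + 3
  tr$cop_ml <- tr$cop_ml - 1.2
  off <- segment_trial(tr, lay)
  expect_equal(off$apa_size, ref$apa_size, tolerance = 1e-12)
  expect_equal(off$t_r, ref$t_r)
})

test_that("segmentation recovers planted simulations across a gain grid", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  lay <- target_layout(a$L_COM)
  p <- pd_t1_params()
  for (kp in c(45, 90)) {
    for (kff in c(3, 8)) {
      tr <- simulate_trial(a, pl, p, control_gains(kp, kff),
                           sim_config(keep_states = TRUE))
      seg <- segment_trial(tr, lay)
      expect_lt(abs(seg$t_r - p$t_r), 1 / 80 + 1e-9)
      # features agree with the simulator's internal full-rate state
      st <- tr$metadata$states
      lean_int <- max(st$cop_cm) - 0
      expect_lt(abs(seg$lean_max - lean_int) / lean_int, 0.01)
      # full-rate APA window: first negative excursion up to its return
      post <- which(st$t > tr$target_onset)
      i0 <- post[which(st$cop_cm[post] < 0)[1]]
      i1 <- i0 + which(st$cop_cm[seq(i0, nrow(st))] >= 0)[1] - 1L
      apa_int <- max(st$cop_cm[i0:i1]) - min(st$cop_cm[i0:i1])
      # the APA extremum is a cusp at the end-of-window torque step, so
      # the 80 Hz sample can sit up to ~2% short of the full-rate value
      expect_lt(abs(seg$apa_size - apa_int) / apa_int, 0.025)
      expect_equal(seg$t_total, seg$t_r + seg$t_f + seg$t_b)
    }
  }
})

test_that("baseline-only trials are flagged, not silently dropped", {
  t <- seq(0, 12, by = 1 / 80)
  set.seed(5)
  tr <- cop_trial(t, rnorm(length(t), sd = 0.02),
                  rnorm(length(t), sd = 0.02), 5, 1)
  expect_error(segment_trial(tr, target_layout(1)),
               class = "leansim_error_no_apa")
})

test_that("per-direction aggregation averages unflagged repetitions", {
  one <- data.frame(target_id = 1, apa_size = 1.2, lean_max = 4.5,
                    flagged = FALSE)
  four <- do.call(rbind, replicate(4, one, simplify = FALSE))
  agg <- aggregate_subject(four)
  expect_equal(agg$apa_size, 1.2)
  expect_equal(agg$n, 4L)

  mixed <- four
  mixed$apa_size <- c(1, 2, 3, 100)
  mixed$flagged <- c(FALSE, FALSE, FALSE, TRUE)
  agg2 <- aggregate_subject(mixed)
  expect_equal(agg2$apa_size, 2)
  expect_equal(agg2$n, 3L)
  expect_equal(agg2$n_flagged, 1L)

  allbad <- four
  allbad$flagged <- TRUE
  agg3 <- aggregate_subject(allbad)
  expect_true(agg3$missing)
  expect_true(is.na(agg3$apa_size))
})
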