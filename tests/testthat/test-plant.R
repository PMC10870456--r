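test_that("anthropometry derivation follows the documented conventions", {
  a <- healthy_anthro()
  expect_equal(a$L_COM, 0.5527 * 1.756, tolerance = 1e-12)
  expect_equal(a$J_B, 77.28 * (0.5527 * 1.756)^2, tolerance = 1e-12)
  expect_equal(a$g, 9.81)

  # point-mass inertia is linear in mass at fixed height
  light <- derive_anthropometry(1.756, 60)
  heavy <- derive_anthropometry(1.756, 120)
  expect_equal(heavy$J_B, 2 * light$J_B, tolerance = 1e-12)

  err <- expect_error(derive_anthropometry(0.5, 70),
                      class = "leansim_error_validation")
  expect_match(conditionMessage(err), "height")
  expect_error(derive_anthropometry(1.7, 20),
               class = "leansim_error_validation")
})

test_that("intrinsic ankle torque opposes displacement and velocity", {
  pl <- plant_params(K_A = 2, B_A = 0.5)
  expect_identical(intrinsic_torque(body_state(0, 0), pl), 0)
  expect_equal(intrinsic_torque(body_state(1, 0), pl), -2)
  for (th in c(-3, -0.2, 0.4, 2)) {
    expect_identical(sign(intrinsic_torque(body_state(th, 0), pl)),
                     -sign(th))
  }
})

test_that("plant params enforce sub-critical intrinsic stiffness", {
  a <- healthy_anthro()
  pl <- plant_params(a)
  mgl <- a$mass * a$g * a$L_COM
  expect_equal(pl$K_A * 180 / pi, 0.15 * mgl, tolerance = 1e-12)
  expect_lt(pl$K_A * 180 / pi, mgl)
  expect_error(plant_params(a, K_A = 1.1 * mgl * pi / 180, B_A = 0),
               class = "leansim_error_validation")
})

test_that("pendulum step preserves equilibria and torque balance", {
  a <- healthy_anthro()
  pl <- plant_params(a, K_A = 0, B_A = 0)
  s0 <- body_state(0, 0)
  s1 <- pendulum_step(s0, 0, a, 0.005, pl)
  expect_equal(s1$theta, 0)
  expect_equal(s1$theta_dot, 0)

  # exact gravity cancellation leaves a resting state untouched
  tau_bal <- -a$mass * a$g * a$L_COM * sin(2 * pi / 180)
  s2 <- pendulum_step(body_state(2, 0), tau_bal, a, 0.005, pl)
  expect_equal(s2$theta, 2, tolerance = 1e-12)
  expect_equal(s2$theta_dot, 0, tolerance = 1e-12)

  expect_error(pendulum_step(s0, NaN, a, 0.005, pl),
               class = "leansim_error_numeric")
  expect_error(pendulum_step(s0, 0, a, 0.02, pl),
               class = "leansim_error_validation")
})

test_that("unforced linear pendulum matches the cosh closed form", {
  a <- healthy_anthro()
  pl <- plant_params(a, K_A = 0, B_A = 0, linearized = TRUE)
  omega <- sqrt(a$mass * a$g * a$L_COM / a$J_B)
  dt <- 1 / 800
  s <- body_state(0.1, 0)
  for (i in seq_len(160)) s <- pendulum_step(s, 0, a, dt, pl)
  expect_equal(s$t, 0.2, tolerance = 1e-12)
  expect_lt(abs(s$theta - 0.1 * cosh(omega * 0.2)), 1e-6)
})

test_that("passive stance diverges from any nonzero angle", {
  a <- healthy_anthro()
  pl <- plant_params(a)  # sub-critical defaults
  for (th0 in c(0.5, -1)) {
    s <- body_state(th0, 0)
    traj <- numeric(200)
    for (i in 1:200) {  # 1 s at dt = 5 ms, intrinsic torque only
      s <- pendulum_step(s, intrinsic_torque(s, pl), a, 0.005, pl)
      traj[i] <- abs(s$theta)
    }
    expect_true(all(diff(c(abs(th0), traj)) > 0))
  }
})

test_that("halving the step changes the 2 s trajectory below 1e-6 deg", {
  # fixed (constant) torque profile on the unstable linear pendulum; the
  # trajectory is held exactly within each step, so RK4 order applies
  a <- healthy_anthro()
  pl <- plant_params(a, K_A = 0, B_A = 0, linearized = TRUE)
  run <- function(dt) {
    s <- body_state(0.3, 0)
    for (i in seq_len(round(2 / dt))) s <- pendulum_step(s, -1, a, dt, pl)
    s$theta
  }
  expect_lt(abs(run(0.002) - run(0.001)), 1e-6)
})

test_that("COP output reduces to the COM projection in statics", {
  a <- healthy_anthro()
  expect_equal(cop_from_motion(1, 0, a), 100 * a$L_COM * pi / 180,
               tolerance = 1e-12)
  expect_identical(cop_from_motion(0, 0, a), 0)
  # acceleration toward the target pushes the COP the opposite way
  expect_lt(cop_from_motion(0, 5, a), 0)
  for (th in c(-2, 0.3, 1.7)) {
    expect_equal(cop_from_motion(th, 0, a),
                 100 * a$L_COM * th * pi / 180, tolerance = 1e-12)
  }
})
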