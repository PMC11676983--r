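test_that("mass-action rate law matches hand evaluation and conserves pairs", {
  sys <- tmsdr_system(ka = 1e-3, kd = 1e-4)

  # empty system: nothing reacts
  expect_equal(unname(mass_action_rhs(reaction_state(0, 0, 0, 0), sys)),
               rep(0, 4))

  # detailed balance: ka = kd with all species at 1 nM
  bal <- tmsdr_system(ka = 2e-4, kd = 2e-4)
  expect_equal(unname(mass_action_rhs(reaction_state(1, 1, 1, 1), bal)),
               rep(0, 4))

  # hand evaluation: v = 1e-3 * 10 * 10 = 0.1 nM/s
  d <- mass_action_rhs(reaction_state(10, 10), sys)
  expect_equal(d[["x1"]], -0.1)
  expect_equal(unname(d), c(-0.1, -0.1, 0.1, 0.1))

  # instantaneous conservation of x1 + x3 and x2 + x3
  st <- reaction_state(3, 7, 2, 5)
  d2 <- mass_action_rhs(st, sys)
  expect_equal(d2[["x1"]] + d2[["x3"]], 0)
  expect_equal(d2[["x2"]] + d2[["x3"]], 0)

  expect_error(mass_action_rhs(c(x1 = -1, x2 = 1, x3 = 0, x4 = 0), sys),
               class = "tmsdr_config_error")
})

test_that("simulated trajectories conserve composition and relax to equilibrium", {
  init <- default_init()
  tt <- seq(0, 5400, by = 10)
  for (i in seq_len(nrow(reference_rate_constants()))) {
    r <- reference_rate_constants()[i, ]
    sys <- tmsdr_system(ka = r$ka, kd = r$kd)
    traj <- simulate_tmsdr(sys, init, tt)
    expect_lt(max(abs(traj$x1_nM + traj$x3_nM - 10)), 1e-6)
    expect_lt(max(abs(traj$x2_nM + traj$x3_nM - 10)), 1e-6)
    expect_lt(max(abs(traj$x4_nM - traj$x3_nM)), 1e-6)
    expect_true(all(traj$x1_nM > -1e-8))
  }

  # detailed balance at the end of a long run
  sys <- tmsdr_system(ka = 4.78e-5, kd = 4.60e-3)
  long <- simulate_tmsdr(sys, init, c(0, 10^(2:6)))
  fin <- as.numeric(long[nrow(long), -1L])
  expect_lt(abs(sys$ka * fin[1] * fin[2] - sys$kd * fin[3] * fin[4]), 1e-9)

  # irreversible limit goes to completion
  irr <- simulate_tmsdr(tmsdr_system(ka = 1e-3, kd = 0), init, c(0, 1e6))
  expect_lt(irr$x1_nM[2], 1e-3)

  # missing co-reactant: nothing happens
  still <- simulate_tmsdr(tmsdr_system(ka = 1e-3, kd = 1e-4),
                          reaction_state(10, 0, 0, 0), tt)
  expect_equal(still$x1_nM, rep(10, length(tt)))

  expect_error(simulate_tmsdr(sys, init, c(0, 10, 5)),
               class = "tmsdr_config_error")
  expect_error(simulate_tmsdr(sys, init, c(5, 10)),
               class = "tmsdr_config_error")
})

test_that("closed-form progress curve matches the textbook second-order law", {
  # irreversible, equal initials: x(t) = C^2 ka t / (1 + C ka t)
  ka <- 1e-3; C <- 10
  sys <- tmsdr_system(ka = ka, kd = 0)
  tt <- c(0, 10, 100, 1000, 1e5)
  expect_equal(closed_form_extent(sys, reaction_state(C, C), tt),
               C^2 * ka * tt / (1 + C * ka * tt), tolerance = 1e-12)
})

test_that("closed form and numeric integration agree for all rate regimes", {
  inits <- list(default_init(), reaction_state(12, 8, 3, 1))
  tt <- seq(0, 5400, by = 60)
  for (ka in c(1e-6, 1e-4, 1e-2)) {
    for (kd in c(1e-6, 1e-4, 1e-2)) {
      sys <- tmsdr_system(ka = ka, kd = kd)
      for (init in inits) {
        cf <- closed_form_extent(sys, init, tt)
        traj <- simulate_tmsdr(sys, init, tt)
        num <- init[["x1"]] - traj$x1_nM
        scale <- max(abs(cf), init[["x1"]] * 1e-3)
        expect_lt(max(abs(num - cf)) / scale, 1e-5,
                  label = sprintf("ka=%g kd=%g", ka, kd))
      }
    }
  }
})

test_that("equilibrium extent solves the mass-action balance", {
  init <- default_init()

  # symmetric rates: 50% substitution regardless of C
  for (C in c(1, 10, 100)) {
    sys <- tmsdr_system(ka = 3e-4, kd = 3e-4)
    expect_equal(equilibrium_extent(sys, reaction_state(C, C)), C / 2,
                 tolerance = 1e-10)
  }

  # equal-initials ratio is concentration-invariant and matches sqrt(K)/(1+sqrt(K))
  sys <- tmsdr_system(ka = 1.74e-4, kd = 8.51e-4)
  for (C in c(1, 10, 100)) {
    xeq <- equilibrium_extent(sys, reaction_state(C, C))
    expect_equal(xeq / C, equal_initials_eq_ratio(sys$ka, sys$kd),
                 tolerance = 1e-10)
  }

  # long-time ODE integration as an independent oracle (frozen: 0.92508 nM)
  sys1 <- tmsdr_system(ka = 4.78e-5, kd = 4.60e-3)
  xeq <- equilibrium_extent(sys1, init)
  traj <- simulate_tmsdr(sys1, init, c(0, 1e6))
  expect_equal(xeq, 10 - traj$x1_nM[2], tolerance = 1e-6)
  expect_equal(xeq / 10, 0.0925, tolerance = 1e-3)

  # detailed balance holds exactly at the returned state
  st <- init + c(-xeq, -xeq, xeq, xeq)
  expect_lt(abs(sys1$ka * st[1] * st[2] - sys1$kd * st[3] * st[4]), 1e-12)

  # irreversible case completes the limiting reactant
  expect_equal(equilibrium_extent(tmsdr_system(ka = 1e-3, kd = 0),
                                  reaction_state(4, 9)), 4)

  expect_error(equilibrium_extent(sys1, reaction_state(0, 0, 1, 1)),
               class = "tmsdr_config_error")
})

test_that("extent is nondecreasing in time when products start at zero", {
  set.seed(11)
  tt <- seq(0, 5400, by = 30)
  for (i in 1:20) {
    ka <- 10^runif(1, -6, -2)
    kd <- 10^runif(1, -6, -2)
    init <- reaction_state(runif(1, 1, 50), runif(1, 1, 50))
    x <- closed_form_extent(tmsdr_system(ka = ka, kd = kd), init, tt)
    expect_equal(x[1], 0)
    expect_true(all(diff(x) >= -1e-12))
  }
})

test_that("substitution ratio maps displacement onto [0, 1]", {
  expect_equal(substitution_ratio(0, 10), 0)
  expect_equal(substitution_ratio(10, 10), 1)
  expect_equal(substitution_ratio(c(0, 2.5, 10), 10), c(0, 0.25, 1))
  expect_error(substitution_ratio(5, -1), class = "tmsdr_config_error")
  expect_error(substitution_ratio(-3, 10), class = "tmsdr_config_error")

  sys <- tmsdr_system(ka = 1e-3, kd = 1e-4)
  traj <- simulate_tmsdr(sys, default_init(), seq(0, 1000, by = 10))
  r <- substitution_ratio(traj)
  expect_equal(r[1], 0)
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(r, (10 - traj$x1_nM) / 10, tolerance = 1e-12)
})
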