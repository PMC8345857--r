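test_that("the zero state is a fixed point of the integrator", {
  mod <- small_model()
  N <- length(mod$mesh$nodes)
  traj <- simulate(mod, ic = tau_state(rep(0, N), rep(0, N)),
                   opts = solver_options(t_end = 1e6, n_output = 10))
  expect_true(all(traj$n == 0) && all(traj$m == 0))
  ss <- run_to_steady_state(mod, ic = tau_state(rep(0, N), rep(0, N)),
                            opts = solver_options(t_end = 1e6, n_output = 10))
  expect_true(ss$converged)
})

test_that("total mass is conserved along a feedback-driven trajectory", {
  mod <- small_model(tau_preset("anterograde"))
  traj <- simulate(mod)
  mass <- (traj$n + traj$m) %*% mod$mesh$widths
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-6)
})

test_that("symmetric pure diffusion equilibrates both compartments equally", {
  mod <- symmetric_model(tau_params(delta = 0, epsilon = 0,
                                    beta = 0, gamma = 0))
  ss <- run_to_steady_state(mod, ic = axonal_uniform_ic(mod))
  expect_lt(abs(sd_bias(ss$state, mod)), 1e-3)
})

test_that("change rate implements the normalized L1 diagnostic", {
  mod <- small_model()
  N <- length(mod$mesh$nodes)
  c0 <- rep(0.2, N)
  dt <- 1000
  same <- fake_trajectory(mod, c(0, dt), rbind(c0, c0),
                          matrix(0, 2, N))
  expect_equal(unname(change_rate(same)), 0)

  halved <- fake_trajectory(mod, c(0, dt), rbind(c0, c0 / 2),
                            matrix(0, 2, N))
  expect_equal(unname(change_rate(halved)), 1 / dt, tolerance = 1e-12)

  # amplitude-free: rescaling both species leaves the rate unchanged
  scaled <- fake_trajectory(mod, c(0, dt), rbind(5 * c0, 5 * c0 / 2),
                            matrix(0, 2, N))
  expect_equal(change_rate(scaled), change_rate(halved), tolerance = 1e-12)

  empty <- fake_trajectory(mod, c(0, dt), matrix(0, 2, N), matrix(0, 2, N))
  expect_equal(unname(change_rate(empty)), 0)
  expect_error(change_rate(same, index = 1), ">= 2")
})

test_that("late-time change rates decay roughly exponentially", {
  mod <- small_model(tau_preset("unbiased"))
  traj <- simulate(mod)
  r <- change_rate(traj)
  tt <- as.numeric(names(r))
  late <- tt > 1e6 & r > 1e-14
  expect_gte(sum(late), 4)
  # log-rate vs time is close to linear with negative slope
  fit <- stats::lm(log(r[late]) ~ tt[late])
  expect_lt(stats::coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("steady state is reached and flagged from the default initial condition", {
  mod <- small_model(tau_preset("anterograde"))
  ss <- run_to_steady_state(mod)
  expect_true(ss$converged)
  expect_false(is.na(ss$t_steady))
  # months of model time, not instantaneous
  expect_gt(ss$t_steady, 1e6)

  short <- run_to_steady_state(mod, opts = solver_options(t_end = 1e5))
  expect_false(short$converged)
  expect_true(is.na(short$t_steady))
})

test_that("the steady state does not depend on how the mass was initialized", {
  mod <- small_model(tau_preset("anterograde"))
  opts <- solver_options()
  a <- run_to_steady_state(mod, ic = axonal_uniform_ic(mod), opts = opts)
  b <- run_to_steady_state(mod, ic = sd_seed_ic(mod, "pre"), opts = opts)
  expect_equal(total_mass(b$state, mod), total_mass(a$state, mod),
               tolerance = 1e-6)
  expect_lt(pairwise_error(a$trajectory, b$trajectory, time = opts$t_end),
            1e-3)
})

test_that("tightening the relative tolerance leaves the mass trace unchanged", {
  mod <- small_model(tau_preset("unbiased"))
  opts1 <- solver_options(t_end = 1e6, n_output = 15, rel_tol = 1e-8)
  opts2 <- solver_options(t_end = 1e6, n_output = 15, rel_tol = 1e-9)
  m1 <- (simulate(mod, opts = opts1)$n + simulate(mod, opts = opts1)$m) %*%
    mod$mesh$widths
  m2 <- (simulate(mod, opts = opts2)$n + simulate(mod, opts = opts2)$m) %*%
    mod$mesh$widths
  expect_lt(max(abs(m1 - m2)) / m1[1], 1e-8)
})

test_that("halving both mesh spacings moves the steady bias by under 2 percent", {
  for (preset in c("anterograde", "retrograde", "unbiased")) {
    p <- tau_preset(preset)
    coarse <- tau_model(p, layout = small_layout(),
                        coarse_h = 5, fine_h = 1)
    fine <- tau_model(p, layout = small_layout(),
                      coarse_h = 2.5, fine_h = 0.5)
    b1 <- sd_bias(run_to_steady_state(coarse)$state, coarse)
    b2 <- sd_bias(run_to_steady_state(fine)$state, fine)
    expect_lt(abs(b1 - b2) / max(abs(b2), 0.05), 0.02)
  }
})

test_that("compiled and reference right-hand sides give the same trajectory", {
  mod <- small_model(tau_preset("retrograde"))
  opts <- solver_options(t_end = 1e5, n_output = 8)
  a <- simulate(mod, opts = opts, use_compiled = TRUE)
  b <- simulate(mod, opts = opts, use_compiled = FALSE)
  expect_equal(a$n, b$n, tolerance = 1e-7)
  expect_equal(a$m, b$m, tolerance = 1e-7)
})

test_that("an ensemble simulation returns mass-matched random-start trajectories", {
  mod <- small_model(tau_preset("anterograde"))
  opts <- solver_options(t_end = 1e4, n_output = 5)
  ens <- simulate(mod, nsim = 3, seed = 10, opts = opts)
  expect_length(ens, 3)
  masses <- vapply(ens, function(tr) total_mass(state_at(tr, 1), mod),
                   numeric(1))
  expect_equal(masses, rep(100, 3), tolerance = 1e-6)
  expect_error(simulate(mod, nsim = 2, opts = opts), "seed")
})
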