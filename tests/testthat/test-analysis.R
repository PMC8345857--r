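test_that("somatodendritic means are width-weighted compartment averages", {
  mod <- small_model()
  N <- length(mod$mesh$nodes)

  mu0 <- sd_means(axonal_uniform_ic(mod), mod)
  expect_equal(unname(mu0), rep(0, 4))

  mu1 <- sd_means(sd_seed_ic(mod, "pre", dose = 0.5), mod)
  expect_equal(mu1[["pre_m"]], 0.5, tolerance = 1e-12)
  expect_equal(unname(mu1[c("pre_n", "post_n", "post_m")]), rep(0, 3))

  mu2 <- sd_means(tau_state(rep(0.3, N), rep(0, N)), mod)
  expect_equal(mu2[["pre_n"]], 0.3, tolerance = 1e-12)
  expect_equal(mu2[["post_n"]], 0.3, tolerance = 1e-12)
})

test_that("bias statistic covers the pure, balanced and undefined cases", {
  mod <- small_model()
  expect_equal(sd_bias(sd_seed_ic(mod, "post", dose = 1), mod), 1)
  expect_equal(sd_bias(sd_seed_ic(mod, "pre", dose = 1), mod), -1)

  N <- length(mod$mesh$nodes)
  uniform <- tau_state(rep(0.2, N), rep(0.1, N))
  expect_equal(sd_bias(uniform, mod), 0, tolerance = 1e-12)

  # pre total 0.3, post total 0.1 -> -0.5
  comp <- mod$mesh$compartment
  n <- numeric(N)
  m <- numeric(N)
  n[comp == "SD_pre"] <- 0.1
  m[comp == "SD_pre"] <- 0.2
  n[comp == "SD_post"] <- 0.1
  expect_equal(sd_bias(tau_state(n, m), mod), -0.5, tolerance = 1e-12)

  # no somatodendritic tau at all: undefined, not zero
  expect_true(is.na(sd_bias(axonal_uniform_ic(mod), mod)))
})

test_that("bias is antisymmetric under compartment exchange and scale-free", {
  mod <- symmetric_model(tau_params())
  N <- length(mod$mesh$nodes)
  set.seed(2)
  n <- runif(N)
  m <- runif(N)
  m[mod$mesh$compartment == "SC"] <- 0
  st <- tau_state(n, m)
  swapped <- tau_state(rev(n), rev(m))
  expect_equal(sd_bias(swapped, mod), -sd_bias(st, mod), tolerance = 1e-10)
  expect_equal(sd_bias(tau_state(3 * n, 3 * m), mod), sd_bias(st, mod),
               tolerance = 1e-12)
})

test_that("bias time series reports undefined early points and preset signs", {
  mod <- small_model(tau_preset("anterograde"))
  traj <- simulate(mod)
  bs <- bias_timeseries(traj)
  expect_s3_class(bs, "tau_bias_series")
  expect_identical(names(bs), c("time_s", "sd_pre_n_uM", "sd_pre_m_uM",
                                "sd_post_n_uM", "sd_post_m_uM", "bias"))
  expect_true(is.na(bs$bias[1]))          # axonal IC: no SD tau at t = 0
  expect_gt(bs$bias[nrow(bs)], 0)
  expect_true(all(abs(bs$bias[!is.na(bs$bias)]) <= 1))
})

test_that("total mass integrates the state and is constant along trajectories", {
  mod <- small_model()
  N <- length(mod$mesh$nodes)
  expect_equal(total_mass(tau_state(rep(0, N), rep(0, N)), mod), 0)
  expect_equal(total_mass(axonal_uniform_ic(mod, 0.2), mod), 100,
               tolerance = 1e-12)
  traj <- simulate(small_model(tau_preset("retrograde")))
  masses <- vapply(seq_along(traj$times), function(k)
    total_mass(state_at(traj, k), traj$model), numeric(1))
  expect_lt(max(abs(masses - masses[1])) / masses[1], 1e-6)
})

test_that("pairwise error is symmetric, bounded and exact in edge cases", {
  mod <- small_model()
  N <- length(mod$mesh$nodes)
  w <- mod$mesh$widths
  times <- c(0, 100)

  a <- fake_trajectory(mod, times, rbind(rep(0.1, N), rep(0.1, N)),
                       matrix(0, 2, N))
  expect_equal(unname(pairwise_error(a, a)), rep(0, 2))

  # equal-mass disjoint supports: error exactly 1
  half <- N %/% 2
  nb <- c(rep(0, half), rep(0.1, N - half))
  nb <- nb * sum(a$n[1, ] * w) / sum(nb * w)
  na <- c(rep(0.1, half), rep(0, N - half))
  na <- na * sum(a$n[1, ] * w) / sum(na * w)
  A <- fake_trajectory(mod, times, rbind(na, na), matrix(0, 2, N))
  B <- fake_trajectory(mod, times, rbind(nb, nb), matrix(0, 2, N))
  expect_equal(unname(pairwise_error(A, B)), rep(1, 2), tolerance = 1e-12)
  expect_equal(pairwise_error(A, B, time = 100),
               pairwise_error(B, A, time = 100))

  other <- tau_model(tau_params(), layout = build_layout(100, 40, 500, 20, 100))
  C <- fake_trajectory(other, times,
                       matrix(0.1, 2, length(other$mesh$nodes)),
                       matrix(0, 2, length(other$mesh$nodes)))
  expect_error(pairwise_error(A, C), "mesh")
})

test_that("flux profile is the reporting alias of the face fluxes", {
  mod <- small_model(tau_params(delta = 1))
  st <- random_ic(mod, seed = 21, target_mass = 100)
  expect_identical(flux_profile(st, mod), face_fluxes(st, mod))
  z <- tau_state(rep(0, length(mod$mesh$nodes)),
                 rep(0, length(mod$mesh$nodes)))
  expect_true(all(flux_profile(z, mod) == 0))
})
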