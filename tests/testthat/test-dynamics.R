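test_that("effective velocity follows the kinesin feedback law without clamping", {
  p0 <- tau_params()                               # v_a = v_r = 0.7
  expect_equal(effective_velocity(0, 0, p0), 0)
  expect_equal(effective_velocity(0.2, 0, tau_params(delta = 1)), 0.14)
  # (1 - epsilon m) < 0 is admitted: strongly negative net velocity
  expect_equal(effective_velocity(0, 2, tau_params(epsilon = 1)), -1.4)
})

test_that("interconversion rate is beta m - gamma n (n + m)", {
  expect_equal(interconversion_rate(0, 0, tau_params()), 0)
  expect_equal(interconversion_rate(0, 0.1, tau_params(beta = 1e-6, gamma = 0)),
               1e-7)
  expect_equal(interconversion_rate(0.2, 0, tau_params(beta = 0, gamma = 1e-5)),
               -4e-7)
})

test_that("face fluxes combine scaled diffusion and upwinded active transport", {
  mod <- small_model(tau_params(delta = 1, epsilon = 0.35))
  ic <- axonal_uniform_ic(mod, c0 = 0.2)
  fl <- face_fluxes(ic, mod)
  # uniform axonal n: no gradient inside the axon, pure active flux
  interior <- which(mod$masks$transport == 1)
  inner <- interior[10]                  # away from the compartment ends
  expect_equal(fl[inner], (1 - 0.92) * 0.14 * 0.2, tolerance = 1e-12)
  expect_gt(fl[inner], 0)                # anterograde
  # domain-end faces carry zero flux for any state
  expect_identical(fl[1], 0)
  expect_identical(fl[length(fl)], 0)

  # constant state with no net velocity and no feedback: all fluxes vanish
  mod0 <- small_model(tau_params(delta = 0, epsilon = 0))
  st <- tau_state(rep(0.1, length(mod0$mesh$nodes)),
                  rep(0, length(mod0$mesh$nodes)))
  expect_true(all(abs(face_fluxes(st, mod0)) < 1e-15))
})

test_that("time derivative: fixed point, uniform-state reaction, conservation", {
  mod <- small_model(tau_params(delta = 0, epsilon = 0, lam = 1))
  N <- length(mod$mesh$nodes)

  d0 <- time_derivative(tau_state(rep(0, N), rep(0, N)), mod)
  expect_true(all(d0$dn == 0) && all(d0$dm == 0))

  # spatially uniform soluble tau: flux divergence vanishes, only reaction
  cc <- 0.3
  d <- time_derivative(tau_state(rep(cc, N), rep(0, N)), mod)
  g <- mod$params$gamma * cc^2
  sc <- mod$mesh$compartment == "SC"
  expect_equal(d$dn[!sc], rep(-g, sum(!sc)), tolerance = 1e-12)
  expect_equal(d$dn[sc], rep(0, sum(sc)), tolerance = 1e-12)
  expect_equal(d$dm[!sc], rep(g, sum(!sc)), tolerance = 1e-12)
  expect_equal(d$dm[sc], rep(0, sum(sc)), tolerance = 1e-12)
})

test_that("discrete total mass derivative is zero for random admissible states", {
  mod <- small_model(tau_params(delta = 0.7, epsilon = 0.9))
  w <- mod$mesh$widths
  set.seed(42)
  for (k in 1:20) {
    st <- random_ic(mod, seed = k, target_mass = runif(1, 10, 500))
    d <- time_derivative(st, mod)
    scale <- sum((abs(d$dn) + abs(d$dm)) * w) + 1e-30
    expect_lt(abs(sum((d$dn + d$dm) * w)), 1e-12 * max(scale, 1))
    # interconversion contributes antisymmetrically at every node
    fl <- face_fluxes(st, mod)
    div <- diff(fl) / w
    expect_equal(d$dn + div, -d$dm, tolerance = 1e-12)
  }
})

test_that("flux divergence of the reported profile reproduces dn/dt minus the reaction", {
  mod <- small_model(tau_params())
  st <- random_ic(mod, seed = 11, target_mass = 100)
  d <- time_derivative(st, mod)
  fl <- flux_profile(st, mod)
  G <- mod$masks$interconversion * interconversion_rate(st$n, st$m, mod$params)
  expect_equal(-diff(fl) / mod$mesh$widths + G, d$dn, tolerance = 1e-12)
})

test_that("pure symmetric diffusion commutes with mirror reflection", {
  p <- tau_params(delta = 0, epsilon = 0, beta = 0, gamma = 0)
  mod <- symmetric_model(p)
  N <- length(mod$mesh$nodes)
  # the mesh itself must be mirror-symmetric
  expect_equal(mod$mesh$nodes, mod$layout$total_length - rev(mod$mesh$nodes),
               tolerance = 1e-9)
  set.seed(1)
  n <- runif(N)
  m <- runif(N)
  m[mod$mesh$compartment == "SC"] <- 0
  d <- time_derivative(tau_state(n, m), mod)
  dr <- time_derivative(tau_state(rev(n), rev(m)), mod)
  expect_equal(dr$dn, rev(d$dn), tolerance = 1e-10)
  expect_equal(dr$dm, rev(d$dm), tolerance = 1e-10)
})

test_that("right-hand side matches a dense loop evaluation of the equations", {
  lay <- build_layout(2, 1, 4, 1, 2)
  mod <- tau_model(tau_params(delta = 0.8, epsilon = 0.6, beta = 1e-6,
                              gamma = 1e-5, lam = 0.3),
                   layout = lay, coarse_h = 1, fine_h = 1, refine_width = 1)
  p <- mod$params
  nodes <- mod$mesh$nodes
  N <- length(nodes)
  set.seed(7)
  n <- runif(N)
  m <- runif(N)

  # independent dense evaluation, scalar loops, everything re-derived from
  # the layout: compartment of each node, effective diffusivities, harmonic
  # interface means, upwind advection, reaction masking
  bounds <- cumsum(c(2, 1, 4, 1))
  comp_of <- function(x) {
    if (x < bounds[1]) "SD_pre" else if (x < bounds[2]) "AIS"
    else if (x < bounds[3]) "AXON" else if (x < bounds[4]) "SC" else "SD_post"
  }
  Deff <- function(x) {
    cmp <- comp_of(x)
    if (cmp == "AXON") p$f * p$D_n
    else if (cmp %in% c("AIS", "SC")) p$lam * p$D_n
    else p$D_n
  }
  faces <- c(0, (nodes[-1] + nodes[-N]) / 2, sum(c(2, 1, 4, 1, 2)))
  flux <- numeric(N + 1)
  for (j in 2:N) {
    xl <- nodes[j - 1]; xr <- nodes[j]
    Dj <- 2 / (1 / Deff(xl) + 1 / Deff(xr))
    flux[j] <- -Dj * (n[j] - n[j - 1]) / (xr - xl)
    if (comp_of(xl) == "AXON" && comp_of(xr) == "AXON") {
      nb <- (n[j - 1] + n[j]) / 2
      mb <- (m[j - 1] + m[j]) / 2
      v <- p$v_a * (1 + p$delta * nb) * (1 - p$epsilon * mb) - p$v_r
      flux[j] <- flux[j] + (1 - p$f) * v * (if (v > 0) n[j - 1] else n[j])
    }
  }
  dn <- dm <- numeric(N)
  for (i in 1:N) {
    wi <- faces[i + 1] - faces[i]
    G <- if (comp_of(nodes[i]) == "SC") 0 else
      p$beta * m[i] - p$gamma * n[i] * (n[i] + m[i])
    dn[i] <- -(flux[i + 1] - flux[i]) / wi + G
    dm[i] <- -G
  }

  d <- time_derivative(tau_state(n, m), mod)
  expect_equal(d$dn, dn, tolerance = 1e-12)
  expect_equal(d$dm, dm, tolerance = 1e-12)
})

test_that("compiled right-hand side agrees with the R reference", {
  mod <- small_model(tau_params(delta = 0.9, epsilon = 0.8))
  N <- length(mod$mesh$nodes)
  mesh <- mod$mesh
  set.seed(5)
  for (k in 1:5) {
    n <- runif(N)
    m <- runif(N)
    ref <- tauspread:::rhs_r(n, m, mod)
    dy <- tauspread:::rhs_interleaved(
      as.vector(rbind(n, m)),
      mesh$nodes[-1] - mesh$nodes[-N], mesh$widths,
      mod$masks$D_face[2:N], mod$masks$transport[2:N],
      mod$masks$interconversion,
      mod$params$f, mod$params$v_a, mod$params$v_r,
      mod$params$delta, mod$params$epsilon,
      mod$params$beta, mod$params$gamma)
    expect_equal(dy[seq(1, 2 * N, 2)], ref$dn, tolerance = 1e-14)
    expect_equal(dy[seq(2, 2 * N, 2)], ref$dm, tolerance = 1e-14)
  }
})

test_that("invalid states are rejected", {
  mod <- small_model()
  N <- length(mod$mesh$nodes)
  expect_error(tau_state(rep(-0.1, N), rep(0, N)), "nonnegative")
  expect_error(tau_state(rep(NaN, N), rep(0, N)), "NA")
  st <- tau_state(rep(0.1, N - 1), rep(0, N - 1))
  expect_error(time_derivative(st, mod), "mismatched")
})
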