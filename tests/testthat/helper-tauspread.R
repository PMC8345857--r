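# shared fixtures: compact geometries and solver settings that keep runs fast
# while preserving every structural feature (all five compartments, barrier
# faces, refinement bands)

small_layout <- function() build_layout(sd_pre = 200, ais = 40, axon = 500,
                                        cleft = 20, sd_post = 200)

small_model <- function(params = tau_params(), ...) {
  tau_model(params, layout = small_layout(), ...)
}

# symmetric geometry for mirror-reflection properties
symmetric_model <- function(params) {
  tau_model(params, layout = build_layout(sd_pre = 200, ais = 40, axon = 500,
                                          cleft = 40, sd_post = 200))
}

default_opts <- function(...) solver_options(...)

# deterministic synthetic bias grid from a closed-form bias surface
synthetic_grid <- function(bias_fun,
                           delta = seq(0.125, 1, by = 0.125),
                           epsilon = seq(0, 0.6, length.out = 12)) {
  g <- expand.grid(epsilon = epsilon, delta = delta)[, c("delta", "epsilon")]
  g$bias <- bias_fun(g$delta, g$epsilon)
  g$converged <- TRUE
  class(g) <- c("tau_bias_grid", "data.frame")
  g
}

# bare trajectory container for analysis-function tests
fake_trajectory <- function(model, times, nmat, mmat) {
  structure(list(times = times, n = nmat, m = mmat, model = model,
                 opts = NULL, diagnostics = NULL),
            class = "tau_trajectory")
}
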