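#' Effective anterograde/retrograde transport velocity
#'
#' The tug-of-war between kinesin and dynein is summarised by an effective
#' velocity `v(n, m) = v_a (1 + delta n)(1 - epsilon m) - v_r`: soluble tau
#' enhances kinesin processivity (through `delta`) while insoluble tau
#' inhibits it (through `epsilon`); the retrograde velocity is unaffected.
#' The expression is evaluated literally — no clamping is applied, so a
#' sufficiently large insoluble concentration (`epsilon * m > 1`) produces
#' a strongly negative, net-retrograde velocity, which is physically
#' meaningful.
#'
#' @param n,m Soluble / insoluble tau concentrations (uM); vectorized.
#' @param params A `"tau_params"`.
#' @return Effective velocity in um/s (positive = anterograde).
#' @examples
#' effective_velocity(0.2, 0, tau_params(delta = 1))   # 0.14 um/s
#' @export
effective_velocity <- function(n, m, params) {
  params$v_a * (1 + params$delta * n) * (1 - params$epsilon * m) - params$v_r
}

#' Net interconversion rate between soluble and insoluble tau
#'
#' `Gamma(n, m) = beta m - gamma n (n + m)`: fragmentation releases soluble
#' tau from aggregates at rate `beta m`, while aggregation consumes soluble
#' tau through bimolecular encounters with either species at rate
#' `gamma n (n + m)`. Positive values convert insoluble to soluble tau.
#'
#' @inheritParams effective_velocity
#' @return Net rate of soluble tau production (uM/s); vectorized.
#' @export
interconversion_rate <- function(n, m, params) {
  params$beta * m - params$gamma * n * (n + m)
}

# core finite-volume right-hand side (R reference implementation).
# No input validation: callers validate. Returns list(dn, dm, flux) with
# flux over all faces (boundary faces identically zero).
rhs_r <- function(n, m, model) {
  p <- model$params
  mesh <- model$mesh
  masks <- model$masks
  N <- length(n)
  dx <- mesh$nodes[-1] - mesh$nodes[-N]
  i <- seq_len(N - 1L)
  # diffusive flux at interior faces, effective diffusivity per face
  flux <- -masks$D_face[i + 1L] * (n[i + 1L] - n[i]) / dx
  # active transport at axon-interior faces: face-averaged velocity,
  # first-order upwind for the advected concentration
  tm <- masks$transport[i + 1L]
  if (any(tm > 0)) {
    nbar <- (n[i] + n[i + 1L]) / 2
    mbar <- (m[i] + m[i + 1L]) / 2
    v <- effective_velocity(nbar, mbar, p)
    nup <- ifelse(v > 0, n[i], n[i + 1L])
    flux <- flux + tm * (1 - p$f) * v * nup
  }
  flux <- c(0, flux, 0)                      # zero-flux Neumann ends
  div <- (flux[-1] - flux[-(N + 1L)]) / mesh$widths
  G <- masks$interconversion * interconversion_rate(n, m, p)
  list(dn = -div + G, dm = -G, flux = flux)
}

#' Conservative face fluxes of soluble tau
#'
#' Evaluates the net flux of soluble tau at every cell face: the diffusive
#' component everywhere (with the compartment-dependent effective
#' diffusivity) plus the active-transport component `(1 - f) v(n, m) n` at
#' faces interior to the axon proper, with the advected concentration
#' upwinded by the sign of the face-averaged velocity. The two domain-end
#' faces carry identically zero flux (closed system).
#'
#' @param state A `"tau_state"` on the model's mesh.
#' @param model A `"tau_model"`.
#' @return Numeric vector of fluxes (uM um / s), one per face
#'   (`length(model$mesh$faces)`); positive values point towards the
#'   postsynaptic neuron.
#' @export
face_fluxes <- function(state, model) {
  check_state_on_mesh(state, model)
  rhs_r(state$n, state$m, model)$flux
}

#' Time derivative of the discretized model
#'
#' The method-of-lines right-hand side on the masked mesh: for each cell,
#' minus the finite-volume flux divergence (soluble tau only; insoluble tau
#' is immobile) plus the interconversion source, which is switched off in
#' the synaptic cleft. The discrete total mass derivative is exactly zero
#' for every admissible state: interior fluxes telescope, end fluxes
#' vanish, and interconversion cancels between the two species.
#'
#' @inheritParams face_fluxes
#' @return A list with components `dn` and `dm` (uM/s per node).
#' @export
time_derivative <- function(state, model) {
  check_state_on_mesh(state, model)
  if (anyNA(state$n) || anyNA(state$m))
    stop("state contains NA/NaN")
  if (any(state$n < 0) || any(state$m < 0))
    stop("negative concentration in state")
  out <- rhs_r(state$n, state$m, model)
  list(dn = out$dn, dm = out$dm)
}
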