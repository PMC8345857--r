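#' Solver options
#'
#' Controls for the stiff method-of-lines integration. Output times default
#' to 40 log-spaced points between 10 s and `t_end` (preceded by `t = 0`),
#' resolving the three characteristic phases of the dynamics (hours, days,
#' months).
#'
#' @param t_end Final integration time (s). The default `1e8` s leaves the
#'   slowest, fragmentation-limited relaxation mode several e-folds of
#'   decay beyond the months over which the distributions visibly
#'   equilibrate, so the change-rate diagnostic can actually fall below
#'   `steady_tol`; the stiff integrator makes the extra horizon nearly
#'   free.
#' @param output_times Strictly increasing times (s) at which states are
#'   stored; must start at 0 and end at `t_end`. `NULL` for the log-spaced
#'   default.
#' @param n_output Number of log-spaced output points when `output_times`
#'   is `NULL`.
#' @param rel_tol,abs_tol Relative / absolute integrator tolerances.
#' @param steady_tol Threshold (1/s) on the normalized change rate
#'   ([change_rate()]) below which the system is declared at steady state.
#' @param max_steps Maximum internal integrator steps per output interval.
#' @return An object of class `"tau_solver_options"`.
#' @export
solver_options <- function(t_end = 1e8, output_times = NULL, n_output = 40,
                           rel_tol = 1e-8, abs_tol = 1e-12,
                           steady_tol = 1e-9, max_steps = 1e5) {
  stopifnot(t_end > 0, rel_tol > 0, abs_tol > 0, steady_tol > 0)
  if (is.null(output_times)) {
    output_times <- c(0, 10^seq(1, log10(t_end), length.out = n_output))
  } else {
    output_times <- sort(unique(as.numeric(output_times)))
    if (output_times[1] != 0) output_times <- c(0, output_times)
  }
  if (any(diff(output_times) <= 0) || max(output_times) > t_end)
    stop("output_times must be strictly increasing within [0, t_end]")
  structure(list(t_end = t_end, output_times = output_times,
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 steady_tol = steady_tol, max_steps = max_steps),
            class = "tau_solver_options")
}

#' Simulate tau transport dynamics
#'
#' Integrates the masked reaction-diffusion-advection system with a stiff
#' implicit multistep method (`deSolve::lsode`, banded internally generated
#' Jacobian). The discretization conserves total tau mass exactly; a drift
#' larger than `1e-6` relative at any output time aborts with an error.
#'
#' With `nsim > 1` an ensemble of trajectories is returned, each started
#' from a mass-matched random initial profile ([random_ic()]) seeded from
#' `seed` — the experiment used to probe robustness of the steady state to
#' initialization.
#'
#' @param object A `"tau_model"`.
#' @param nsim Number of trajectories.
#' @param seed Integer seed for the random initial profiles (required when
#'   `nsim > 1`).
#' @param ic A `"tau_state"` initial condition; defaults to the uniform
#'   axonal soluble-tau profile [axonal_uniform_ic()] at 0.2 uM.
#' @param opts A `"tau_solver_options"`.
#' @param use_compiled Use the compiled right-hand side (default); set to
#'   `FALSE` to integrate with the pure-R reference implementation.
#' @param ... Unused.
#' @return A `"tau_trajectory"` (or a list of them when `nsim > 1`):
#'   components `times`, matrices `n` and `m` (time by node, uM), `model`,
#'   `opts`, and solver `diagnostics`.
#' @examples
#' \donttest{
#' mod <- tau_model(tau_preset("anterograde"))
#' traj <- simulate(mod, opts = solver_options(t_end = 1e5))
#' }
#' @importFrom stats simulate
#' @export
simulate.tau_model <- function(object, nsim = 1, seed = NULL, ic = NULL,
                               opts = solver_options(), use_compiled = TRUE,
                               ...) {
  stopifnot(inherits(opts, "tau_solver_options"))
  if (nsim > 1) {
    if (is.null(seed)) stop("seed is required for an ensemble (nsim > 1)")
    base_ic <- if (is.null(ic)) axonal_uniform_ic(object) else ic
    mass <- total_mass(base_ic, object)
    return(lapply(seq_len(nsim), function(k)
      simulate.tau_model(object, ic = random_ic(object, seed = seed + k - 1L,
                                                target_mass = mass),
                         opts = opts, use_compiled = use_compiled)))
  }
  if (is.null(ic)) ic <- axonal_uniform_ic(object)
  check_state_on_mesh(ic, object)

  mesh <- object$mesh
  p <- object$params
  N <- length(mesh$nodes)
  dx <- mesh$nodes[-1] - mesh$nodes[-N]
  Dface <- object$masks$D_face[2:N]
  tmask <- object$masks$transport[2:N]
  imask <- object$masks$interconversion
  w <- mesh$widths

  y0 <- as.vector(rbind(ic$n, ic$m))       # interleaved (n_i, m_i)
  deriv <- if (use_compiled) {
    function(t, y, parms)
      list(rhs_interleaved(y, dx, w, Dface, tmask, imask,
                           p$f, p$v_a, p$v_r, p$delta, p$epsilon,
                           p$beta, p$gamma))
  } else {
    function(t, y, parms) {
      out <- rhs_r(y[seq(1, 2 * N, 2)], y[seq(2, 2 * N, 2)], object)
      list(as.vector(rbind(out$dn, out$dm)))
    }
  }
  sol <- deSolve::lsode(y = y0, times = opts$output_times, func = deriv,
                        parms = NULL, rtol = opts$rel_tol,
                        atol = opts$abs_tol, jactype = "bandint",
                        bandup = 3, banddown = 3, maxsteps = opts$max_steps)
  diag <- attributes(sol)[c("istate", "rstate")]
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integrator failed; diagnostics: istate = ",
         attr(sol, "istate")[1])
  ymat <- unclass(sol)[, -1, drop = FALSE]
  if (anyNA(ymat)) stop("integration produced NaN state; aborted")
  nmat <- ymat[, seq(1, 2 * N, 2), drop = FALSE]
  mmat <- ymat[, seq(2, 2 * N, 2), drop = FALSE]

  traj <- structure(list(times = opts$output_times, n = nmat, m = mmat,
                         model = object, opts = opts, diagnostics = diag),
                    class = "tau_trajectory")
  mass <- mass_series(traj)
  if (mass[1] > 0 && max(abs(mass - mass[1])) / mass[1] > 1e-6)
    stop(sprintf(
      "mass conservation violated: max relative drift %.3g exceeds 1e-6",
      max(abs(mass - mass[1])) / mass[1]))
  traj
}

mass_series <- function(traj) {
  w <- traj$model$mesh$widths
  as.vector((traj$n + traj$m) %*% w)
}

#' Extract the state at one output time
#'
#' @param traj A `"tau_trajectory"`.
#' @param index Output-time index (1-based); defaults to the final time.
#' @param clamp Truncate tiny negative floating-point undershoots to zero
#'   (applied to reported states only, never inside the solver).
#' @return A `"tau_state"`.
#' @export
state_at <- function(traj, index = length(traj$times), clamp = TRUE) {
  stopifnot(inherits(traj, "tau_trajectory"))
  n <- traj$n[index, ]
  m <- traj$m[index, ]
  if (clamp) {
    n <- pmax(n, 0)
    m <- pmax(m, 0)
  }
  tau_state(n, m, time = traj$times[index])
}

#' Normalized rate of change of the tau distributions
#'
#' The steady-state diagnostic: for successive stored outputs,
#' `(||n_k - n_{k-1}||_1 + ||m_k - m_{k-1}||_1) /
#'  (||n_k||_1 + ||m_k||_1) / (t_k - t_{k-1})`,
#' with cell-width-weighted discrete L1 norms. The measure is scale-free in
#' amplitude; it is defined as 0 for an empty system. Note the rates depend
#' on the stored-output cadence, which is therefore part of any reported
#' result (the trajectory carries its output grid).
#'
#' @param traj A `"tau_trajectory"`.
#' @param index Optional single output index (>= 2); default all.
#' @return Rates in 1/s: one per requested index (vector named by time).
#' @export
change_rate <- function(traj, index = NULL) {
  stopifnot(inherits(traj, "tau_trajectory"))
  idx <- if (is.null(index)) seq_along(traj$times)[-1] else as.integer(index)
  if (any(idx < 2)) stop("index must be >= 2")
  w <- traj$model$mesh$widths
  out <- vapply(idx, function(k) {
    num <- sum(abs(traj$n[k, ] - traj$n[k - 1, ]) * w) +
      sum(abs(traj$m[k, ] - traj$m[k - 1, ]) * w)
    den <- sum(abs(traj$n[k, ]) * w) + sum(abs(traj$m[k, ]) * w)
    if (den == 0) return(0)
    num / den / (traj$times[k] - traj$times[k - 1])
  }, numeric(1))
  names(out) <- traj$times[idx]
  out
}

#' Integrate to steady state
#'
#' Runs the model to `opts$t_end` and flags convergence by the first output
#' time at which the normalized change rate ([change_rate()]) drops below
#' `opts$steady_tol`. An unconverged run is returned with an explicit flag,
#' never silently.
#'
#' @param model A `"tau_model"`.
#' @param ic Initial `"tau_state"`; default uniform axonal profile.
#' @param opts A `"tau_solver_options"`.
#' @param ... Passed on to [simulate.tau_model()].
#' @return A list: `state` (final `"tau_state"`), `trajectory`,
#'   `converged` (logical), `t_steady` (first time under tolerance, or NA).
#' @export
run_to_steady_state <- function(model, ic = NULL, opts = solver_options(),
                                ...) {
  traj <- simulate(model, ic = ic, opts = opts, ...)
  rates <- change_rate(traj)
  under <- which(rates < opts$steady_tol)
  converged <- length(under) > 0
  list(state = state_at(traj),
       trajectory = traj,
       converged = converged,
       t_steady = if (converged) as.numeric(names(rates)[under[1]]) else NA_real_)
}

#' @export
print.tau_trajectory <- function(x, ...) {
  cat(sprintf("tau_trajectory: %d output times in [0, %g] s, %d nodes\n",
              length(x$times), max(x$times), ncol(x$n)))
  m <- mass_series(x)
  cat(sprintf("  total mass %.6g uM um (max relative drift %.2g)\n",
              m[1], if (m[1] > 0) max(abs(m - m[1])) / m[1] else 0))
  invisible(x)
}

#' @export
as.data.frame.tau_trajectory <- function(x, ...) {
  mesh <- x$model$mesh
  Tn <- length(x$times)
  N <- length(mesh$nodes)
  data.frame(time_s = rep(x$times, each = N),
             x_um = rep(mesh$nodes, Tn),
             compartment = rep(mesh$compartment, Tn),
             n_uM = pmax(as.vector(t(x$n)), 0),
             m_uM = pmax(as.vector(t(x$m)), 0))
}

#' Plot concentration profiles of a trajectory
#'
#' Soluble (solid) and insoluble (dashed) tau profiles at a set of output
#' times, with compartment boundaries marked.
#'
#' @param x A `"tau_trajectory"`.
#' @param times Output times to draw (nearest stored times are used);
#'   defaults to five log-spread snapshots.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.tau_trajectory <- function(x, times = NULL, ...) {
  if (is.null(times)) {
    k <- unique(round(seq(1, length(x$times), length.out = 5)))
  } else {
    k <- vapply(times, function(t) which.min(abs(x$times - t)), integer(1))
  }
  cols <- grDevices::hcl.colors(length(k), "viridis")
  graphics::matplot(x$model$mesh$nodes, t(pmax(x$n[k, , drop = FALSE], 0)),
                    type = "l", lty = 1, col = cols,
                    xlab = "x (um)", ylab = "concentration (uM)", ...)
  graphics::matlines(x$model$mesh$nodes, t(pmax(x$m[k, , drop = FALSE], 0)),
                     lty = 2, col = cols)
  graphics::abline(v = x$model$layout$boundaries, col = "grey70", lty = 3)
  graphics::legend("topright", bty = "n", lty = c(1, 2),
                   legend = c("soluble n", "insoluble m"))
  invisible(x)
}
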