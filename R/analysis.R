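#' Mean somatodendritic concentrations
#'
#' Cell-width-weighted means of soluble and insoluble tau over each
#' somatodendritic compartment — the quantities the one-dimensional
#' reduction of the cell bodies is built to capture.
#'
#' @param state A `"tau_state"`.
#' @param model A `"tau_model"`.
#' @return Named numeric vector `c(pre_n, pre_m, post_n, post_m)` in uM.
#' @export
sd_means <- function(state, model) {
  check_state_on_mesh(state, model)
  w <- model$mesh$widths
  comp <- model$mesh$compartment
  wmean <- function(v, lab) {
    i <- comp == lab
    sum(v[i] * w[i]) / sum(w[i])
  }
  c(pre_n = wmean(state$n, "SD_pre"), pre_m = wmean(state$m, "SD_pre"),
    post_n = wmean(state$n, "SD_post"), post_m = wmean(state$m, "SD_post"))
}

#' Somatodendritic deposition bias
#'
#' The directional bias statistic
#' `B = ((n_post + m_post) - (n_pre + m_pre)) /
#'      (n_post + m_post + n_pre + m_pre)`
#' over the compartment-mean concentrations: `+1` is purely anterograde
#' (all somatodendritic tau postsynaptic), `-1` purely retrograde, `0`
#' equal deposition. When there is no somatodendritic tau at all the bias
#' is undefined and `NA` is returned — never 0, which would fake an
#' "unbiased" reading.
#'
#' @inheritParams sd_means
#' @return A single value in `[-1, 1]`, or `NA` if undefined.
#' @export
sd_bias <- function(state, model) {
  mu <- sd_means(state, model)
  pre <- mu[["pre_n"]] + mu[["pre_m"]]
  post <- mu[["post_n"]] + mu[["post_m"]]
  if (pre + post <= 0) return(NA_real_)
  (post - pre) / (post + pre)
}

#' Bias time series of a trajectory
#'
#' @param traj A `"tau_trajectory"`.
#' @return A data frame of class `"tau_bias_series"` with columns
#'   `time_s`, `sd_pre_n_uM`, `sd_pre_m_uM`, `sd_post_n_uM`,
#'   `sd_post_m_uM`, `bias` (`NA` where undefined).
#' @export
bias_timeseries <- function(traj) {
  stopifnot(inherits(traj, "tau_trajectory"))
  rows <- lapply(seq_along(traj$times), function(k) {
    st <- state_at(traj, k)
    mu <- sd_means(st, traj$model)
    data.frame(time_s = traj$times[k],
               sd_pre_n_uM = mu[["pre_n"]], sd_pre_m_uM = mu[["pre_m"]],
               sd_post_n_uM = mu[["post_n"]], sd_post_m_uM = mu[["post_m"]],
               bias = sd_bias(st, traj$model))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tau_bias_series", "data.frame")
  out
}

#' @export
plot.tau_bias_series <- function(x, ...) {
  graphics::plot(x$time_s, x$bias, type = "l", log = "x", col = "magenta",
                 xlab = "time (s)", ylab = "SD bias", ylim = c(-1, 1), ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Post-hoc net flux profile
#'
#' Reporting alias of [face_fluxes()]: the net soluble-tau flux evaluated
#' on a stored state, as used to visualise the direction of transport along
#' the axon.
#'
#' @inheritParams sd_means
#' @return Flux per face (uM um / s).
#' @export
flux_profile <- function(state, model) face_fluxes(state, model)

#' Total tau mass
#'
#' The cell-width-weighted integral of `n + m` over the domain. The model
#' is closed (zero-flux ends, symmetric interconversion), so this quantity
#' is conserved along every trajectory.
#'
#' @inheritParams sd_means
#' @return Mass in uM um.
#' @export
total_mass <- function(state, model) {
  check_state_on_mesh(state, model)
  sum((state$n + state$m) * model$mesh$widths)
}

#' Relative pairwise error between two trajectories
#'
#' `(||n_A - n_B||_1 + ||m_A - m_B||_1) /
#'  (||n_A||_1 + ||m_A||_1 + ||n_B||_1 + ||m_B||_1)`
#' with cell-width-weighted L1 norms: symmetric, bounded in `[0, 1]`, zero
#' iff the states coincide, and 1 for equal-mass states with disjoint
#' support. Used to quantify convergence of differently initialized runs
#' to a common steady state.
#'
#' @param trajA,trajB Two `"tau_trajectory"` objects on the same mesh and
#'   output grid.
#' @param time Optional single time (s; must be a stored output time) at
#'   which to evaluate; default all shared output times.
#' @return Named vector of errors (names = times), or a single value.
#' @export
pairwise_error <- function(trajA, trajB, time = NULL) {
  stopifnot(inherits(trajA, "tau_trajectory"), inherits(trajB, "tau_trajectory"))
  if (!isTRUE(all.equal(trajA$model$mesh$nodes, trajB$model$mesh$nodes)))
    stop("trajectories are on different meshes")
  if (!isTRUE(all.equal(trajA$times, trajB$times)))
    stop("trajectories have different output times")
  idx <- if (is.null(time)) seq_along(trajA$times) else {
    k <- match(time, trajA$times)
    if (is.na(k)) k <- which.min(abs(trajA$times - time))
    k
  }
  w <- trajA$model$mesh$widths
  out <- vapply(idx, function(k) {
    num <- sum(abs(trajA$n[k, ] - trajB$n[k, ]) * w) +
      sum(abs(trajA$m[k, ] - trajB$m[k, ]) * w)
    den <- sum(abs(trajA$n[k, ]) * w) + sum(abs(trajA$m[k, ]) * w) +
      sum(abs(trajB$n[k, ]) * w) + sum(abs(trajB$m[k, ]) * w)
    if (den == 0) 0 else num / den
  }, numeric(1))
  names(out) <- trajA$times[idx]
  if (length(out) == 1L) unname(out) else out
}
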