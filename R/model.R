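#' Assemble a tau transport model
#'
#' Bundles a compartment layout, an aligned finite-volume mesh, the spatial
#' process masks and the model parameters into a single model object that
#' all simulation and analysis functions consume.
#'
#' @param params A `"tau_params"` object; defaults to [tau_params()].
#' @param layout A `"tau_layout"` object; defaults to [build_layout()].
#' @param coarse_h,fine_h,refine_width Mesh spacing controls passed to
#'   [build_mesh()] (um).
#' @return An object of class `"tau_model"` with elements `layout`, `mesh`,
#'   `masks`, `params`.
#' @examples
#' mod <- tau_model(tau_preset("anterograde"))
#' mod
#' @export
tau_model <- function(params = tau_params(), layout = build_layout(),
                      coarse_h = 5, fine_h = 1, refine_width = 10) {
  stopifnot(inherits(params, "tau_params"), inherits(layout, "tau_layout"))
  mesh <- build_mesh(layout, coarse_h = coarse_h, fine_h = fine_h,
                     refine_width = refine_width)
  structure(list(layout = layout, mesh = mesh,
                 masks = build_masks(layout, mesh, params),
                 params = params),
            class = "tau_model")
}

#' Replace the parameters of a tau model
#'
#' Returns a model identical to `model` but with new parameters; the masks
#' are rebuilt because the barrier scale, diffusing fraction and diffusivity
#' enter the face-level effective diffusivities.
#'
#' @param model A `"tau_model"`.
#' @param params A `"tau_params"`.
#' @return A `"tau_model"`.
#' @export
set_params <- function(model, params) {
  stopifnot(inherits(model, "tau_model"), inherits(params, "tau_params"))
  model$params <- params
  model$masks <- build_masks(model$layout, model$mesh, params)
  model
}

#' @export
print.tau_model <- function(x, ...) {
  cat("Two-neuron tau transport model\n")
  print(x$layout)
  print(x$mesh)
  print(x$params)
  invisible(x)
}

#' @export
coef.tau_model <- function(object, ...) coef(object$params)

#' @export
summary.tau_model <- function(object, ...) {
  print(object)
  m <- object$masks
  cat(sprintf("Masks: %d transport faces, %d interconverting nodes, %d cleft nodes\n",
              sum(m$transport), sum(m$interconversion),
              sum(m$interconversion == 0)))
  invisible(object)
}

#' Spatial state of the model at one time
#'
#' A pair of concentration profiles on the mesh nodes: soluble tau `n` and
#' insoluble tau `m`, both in uM, plus the model time in seconds.
#'
#' @param n,m Numeric vectors of equal length (uM), elementwise nonnegative.
#' @param time Model time (s).
#' @return An object of class `"tau_state"`.
#' @export
tau_state <- function(n, m, time = 0) {
  if (length(n) != length(m))
    stop("n and m must have the same length")
  if (anyNA(n) || anyNA(m))
    stop("state contains NA/NaN")
  if (any(n < 0) || any(m < 0))
    stop("concentrations must be nonnegative")
  structure(list(n = as.numeric(n), m = as.numeric(m), time = time),
            class = "tau_state")
}

check_state_on_mesh <- function(state, model) {
  if (!inherits(state, "tau_state")) stop("expected a 'tau_state'")
  if (length(state$n) != length(model$mesh$nodes))
    stop("state and mesh have mismatched lengths")
  invisible(state)
}

#' @export
print.tau_state <- function(x, ...) {
  cat(sprintf("tau_state at t = %g s: %d nodes, max n = %.4g uM, max m = %.4g uM\n",
              x$time, length(x$n), max(x$n), max(x$m)))
  invisible(x)
}
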