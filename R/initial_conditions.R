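#' Uniform axonal soluble-tau initial condition
#'
#' The canonical initialization: a constant soluble tau concentration in
#' the axon proper (excluding the AIS) and zero elsewhere, with no
#' insoluble aggregates anywhere. This emulates pathology initiating in
#' the axon and subsequently spreading to the two, initially unaffected,
#' cell bodies.
#'
#' @param model A `"tau_model"`.
#' @param c0 Axonal soluble tau concentration (uM), default 0.2.
#' @return A `"tau_state"` at `time = 0`.
#' @examples
#' mod <- tau_model()
#' total_mass(axonal_uniform_ic(mod), mod)   # 0.2 uM x 500 um = 100
#' @export
axonal_uniform_ic <- function(model, c0 = 0.2) {
  stopifnot(inherits(model, "tau_model"), c0 >= 0)
  n <- ifelse(model$mesh$compartment == "AXON", c0, 0)
  tau_state(n, numeric(length(n)), time = 0)
}

#' Somatodendritic insoluble-tau seeding
#'
#' Initializes the system with a constant concentration of insoluble tau
#' in one somatodendritic compartment and nothing anywhere else, mimicking
#' microfluidically isolated seeding experiments. Because insoluble tau is
#' immobile, spread must proceed through fragmentation first.
#'
#' @param model A `"tau_model"`.
#' @param side `"pre"` or `"post"`.
#' @param dose Insoluble tau concentration in the seeded compartment (uM).
#'   The default (`NULL`) mass-matches the model's default
#'   [axonal_uniform_ic()]: `0.2 uM * axon length / compartment length`
#'   (e.g. 0.5 uM for a 500 um axon and 200 um compartment).
#' @return A `"tau_state"` at `time = 0`.
#' @export
sd_seed_ic <- function(model, side = c("pre", "post"), dose = NULL) {
  stopifnot(inherits(model, "tau_model"))
  if (!is.character(side) || !side[1] %in% c("pre", "post"))
    stop("side must be 'pre' or 'post'")
  lab <- if (side[1] == "pre") "SD_pre" else "SD_post"
  if (is.null(dose))
    dose <- 0.2 * model$layout$lengths[["AXON"]] /
      model$layout$lengths[[lab]]
  stopifnot(dose >= 0)
  m <- ifelse(model$mesh$compartment == lab, dose, 0)
  tau_state(numeric(length(m)), m, time = 0)
}

#' Mass-matched random initial condition
#'
#' Draws independent Uniform(0, 1) anchor values for each species at the
#' midpoint of each somatodendritic compartment and at ten equally spaced
#' points spanning the axon proper, interpolates linearly between anchors
#' across the full domain (held constant beyond the outermost anchors),
#' zeroes insoluble tau in the synaptic cleft, and rescales both profiles
#' by one common factor so the total tau mass matches `target_mass`.
#' A common factor (rather than per-species normalization) preserves the
#' drawn soluble/insoluble proportions; set `per_species = TRUE` to
#' normalize each species to half the target instead.
#'
#' @param model A `"tau_model"`.
#' @param seed Integer; the draw is fully reproducible from it and leaves
#'   the global RNG state untouched.
#' @param target_mass Total tau mass (uM um); the default (`NULL`) matches
#'   the model's default axonal initial condition (`0.2 uM * axon length`).
#' @param per_species Normalize n and m separately to `target_mass / 2`.
#' @return A `"tau_state"` at `time = 0`.
#' @export
random_ic <- function(model, seed, target_mass = NULL, per_species = FALSE) {
  stopifnot(inherits(model, "tau_model"))
  if (is.null(target_mass))
    target_mass <- 0.2 * model$layout$lengths[["AXON"]]
  stopifnot(target_mass > 0)
  layout <- model$layout
  starts <- c(0, layout$boundaries)
  mid <- function(lab) {
    i <- match(lab, layout$labels)
    starts[i] + layout$lengths[[i]] / 2
  }
  axon_i <- match("AXON", layout$labels)
  ax <- seq(starts[axon_i], starts[axon_i] + layout$lengths[[axon_i]],
            length.out = 10)
  anchor_x <- c(mid("SD_pre"), ax, mid("SD_post"))
  draws <- with_preserved_seed(seed, stats::runif(2 * length(anchor_x)))
  nv <- draws[seq_along(anchor_x)]
  mv <- draws[-seq_along(anchor_x)]
  nodes <- model$mesh$nodes
  n <- stats::approx(anchor_x, nv, xout = nodes, rule = 2)$y
  m <- stats::approx(anchor_x, mv, xout = nodes, rule = 2)$y
  m[model$mesh$compartment == "SC"] <- 0
  w <- model$mesh$widths
  if (per_species) {
    n <- n * (target_mass / 2) / sum(n * w)
    m <- m * (target_mass / 2) / sum(m * w)
  } else {
    s <- target_mass / sum((n + m) * w)
    n <- n * s
    m <- m * s
  }
  tau_state(n, m, time = 0)
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
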