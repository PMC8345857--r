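#' Compartment layout of the two-neuron system
#'
#' The model domain is a single spatial axis running through five segments
#' in fixed order: presynaptic somatodendritic compartment (SD_pre), axon
#' initial segment (AIS), axon proper (AXON), synaptic cleft (SC), and
#' postsynaptic somatodendritic compartment (SD_post).
#'
#' Defaults: 200 um somatodendritic segments and a 40 um AIS; the axon
#' proper (1000 um, a short but realistic axon) and the cleft segment
#' (20 um) are package defaults, the cleft being treated as an AIS-like
#' one-dimensional diffusion barrier rather than a nanometre-scale
#' physical gap. The axon length sets the path over which transport
#' feedback can build concentration gradients and therefore the strength
#' of the steady-state deposition bias; 1000 um reproduces the strong
#' regime biases at the calibrated baseline (see the methods vignette).
#'
#' @param sd_pre,ais,axon,cleft,sd_post Segment lengths in um; all must be
#'   strictly positive.
#' @return An object of class `"tau_layout"` with elements `labels`,
#'   `lengths` (named, um), `boundaries` (the 4 internal interface
#'   positions, um) and `total_length` (um).
#' @examples
#' build_layout()$boundaries   # 200 240 1240 1260
#' @export
build_layout <- function(sd_pre = 200, ais = 40, axon = 1000,
                         cleft = 20, sd_post = 200) {
  lengths <- c(SD_pre = sd_pre, AIS = ais, AXON = axon,
               SC = cleft, SD_post = sd_post)
  for (nm in names(lengths)) {
    v <- lengths[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("compartment '%s' must have a strictly positive length", nm))
  }
  cs <- cumsum(lengths)
  structure(list(labels = names(lengths),
                 lengths = lengths,
                 boundaries = unname(cs[1:4]),
                 total_length = unname(cs[5])),
            class = "tau_layout")
}

#' @export
print.tau_layout <- function(x, ...) {
  cat("Two-neuron compartment layout (", x$total_length, " um total)\n", sep = "")
  starts <- c(0, x$boundaries)
  for (i in seq_along(x$labels))
    cat(sprintf("  %-7s [%6.1f, %6.1f] um\n", x$labels[i],
                starts[i], starts[i] + x$lengths[i]))
  invisible(x)
}

# segment index (1..5) containing each position; positions exactly on an
# internal boundary are assigned to the segment to their right
layout_segment <- function(layout, x) {
  findInterval(x, c(0, layout$boundaries), rightmost.closed = FALSE) |>
    pmin(5L) |> pmax(1L)
}

#' Inhomogeneous spatial mesh aligned to a compartment layout
#'
#' Builds a vertex-centred finite-volume mesh on `[0, L_total]`: node
#' spacing at most `fine_h` within `refine_width` of every internal
#' compartment boundary and at most `coarse_h` elsewhere. Every internal
#' compartment boundary coincides exactly with a cell face (the midpoint of
#' two nodes placed `fine_h / 2` on either side), so no finite-volume cell
#' straddles two compartments and interface fluxes are single-valued.
#'
#' @param layout A `"tau_layout"` from [build_layout()].
#' @param coarse_h Coarse node spacing (um), used away from boundaries.
#' @param fine_h Fine node spacing (um), used inside refinement bands.
#' @param refine_width Half-width (um) of the refinement band centred on
#'   each internal boundary.
#' @return An object of class `"tau_mesh"`: `nodes` (positions, um),
#'   `faces` (cell interfaces including the two domain ends),
#'   `widths` (cell widths, um), `segment` (segment index 1..5 per node),
#'   `compartment` (segment label per node) and the spacing arguments.
#' @examples
#' m <- build_mesh(build_layout())
#' range(diff(m$nodes))
#' @export
build_mesh <- function(layout, coarse_h = 5, fine_h = 1, refine_width = 10) {
  stopifnot(inherits(layout, "tau_layout"))
  if (!(fine_h > 0 && fine_h <= coarse_h))
    stop("require 0 < fine_h <= coarse_h")
  if (fine_h > refine_width)
    stop("refinement band unresolvable: fine_h exceeds refine_width")

  starts <- c(0, layout$boundaries)
  ends <- c(layout$boundaries, layout$total_length)
  nodes <- numeric(0)
  for (i in 1:5) {
    left_int <- i > 1        # internal boundary at the left end?
    right_int <- i < 5
    x_l <- if (left_int) starts[i] + fine_h / 2 else starts[i]
    x_r <- if (right_int) ends[i] - fine_h / 2 else ends[i]
    if (x_l >= x_r) {        # degenerate narrow segment: single node
      nodes <- c(nodes, (starts[i] + ends[i]) / 2)
      next
    }
    fL_end <- if (left_int) min(starts[i] + refine_width, x_r) else x_l
    fR_start <- if (right_int) max(ends[i] - refine_width, x_l) else x_r
    if (fL_end >= fR_start) {          # refinement bands overlap: all fine
      seg_nodes <- zone_nodes(x_l, x_r, fine_h)
    } else {
      seg_nodes <- c(
        if (fL_end > x_l) zone_nodes(x_l, fL_end, fine_h) else x_l,
        zone_nodes(fL_end, fR_start, coarse_h)[-1],
        if (x_r > fR_start) zone_nodes(fR_start, x_r, fine_h)[-1])
    }
    nodes <- c(nodes, seg_nodes)
  }
  nodes <- sort(unique(nodes))
  faces <- c(0, (nodes[-1] + nodes[-length(nodes)]) / 2, layout$total_length)
  seg <- layout_segment(layout, nodes)
  structure(list(nodes = nodes,
                 faces = faces,
                 widths = diff(faces),
                 segment = seg,
                 compartment = layout$labels[seg],
                 coarse_h = coarse_h, fine_h = fine_h,
                 refine_width = refine_width),
            class = "tau_mesh")
}

# equispaced nodes from a to b with spacing <= h (endpoints included)
zone_nodes <- function(a, b, h) {
  n <- max(1L, ceiling((b - a) / h - 1e-9))
  seq(a, b, length.out = n + 1L)
}

#' @export
print.tau_mesh <- function(x, ...) {
  cat(sprintf("Finite-volume mesh: %d nodes on [0, %g] um\n",
              length(x$nodes), max(x$faces)))
  cat(sprintf("  spacing %g um (fine, within %g um of boundaries) / %g um (coarse)\n",
              x$fine_h, x$refine_width, x$coarse_h))
  invisible(x)
}

#' Spatial process masks on a mesh
#'
#' Encodes which processes operate where: active transport only at faces
#' interior to the axon proper, tau interconversion everywhere except the
#' synaptic cleft, and diffusion everywhere with a compartment-dependent
#' effective diffusivity (`f * D_n` in the axon, `D_n` in the
#' somatodendritic compartments, `lam * D_n` in the AIS and cleft). Faces
#' between cells of different compartments use the harmonic mean of the
#' adjacent effective diffusivities, the standard conservative treatment of
#' a discontinuous coefficient.
#'
#' @param layout A `"tau_layout"`.
#' @param mesh A `"tau_mesh"` built on `layout`.
#' @param params A `"tau_params"`.
#' @return An object of class `"tau_masks"`: `transport` (0/1 per face),
#'   `interconversion` (0/1 per node), `diff_scale` (effective face
#'   diffusivity divided by `D_n`, in `(0, 1]`) and `D_face` (effective
#'   face diffusivity, um^2/s). Vectors over faces have length
#'   `length(mesh$faces)`; entries for the two domain-end faces are 0 for
#'   `transport` and unused for diffusion (zero-flux ends).
#' @export
build_masks <- function(layout, mesh, params) {
  stopifnot(inherits(layout, "tau_layout"), inherits(mesh, "tau_mesh"),
            inherits(params, "tau_params"))
  # reject meshes not aligned to the layout: every internal boundary must
  # coincide with a face
  for (b in layout$boundaries)
    if (min(abs(mesh$faces - b)) > 1e-9)
      stop("mesh/layout mismatch: a cell straddles a compartment boundary")
  seg <- mesh$segment
  nfaces <- length(mesh$faces)
  # per-node effective diffusivity
  sd_scale <- if (params$scale_sd_diffusion) params$f else 1
  node_scale <- c(sd_scale, params$lam, params$f, params$lam, sd_scale)[seg]
  D_node <- params$D_n * node_scale
  # interior face j (2..nfaces-1) lies between nodes j-1 and j
  jl <- seq_len(nfaces - 2L)          # left node of each interior face
  jr <- jl + 1L
  D_face_int <- 2 / (1 / D_node[jl] + 1 / D_node[jr])
  axon_idx <- match("AXON", layout$labels)
  transport <- c(0, as.numeric(seg[jl] == axon_idx & seg[jr] == axon_idx), 0)
  D_face <- c(D_node[1], D_face_int, D_node[length(D_node)])
  interconv <- as.numeric(seg != match("SC", layout$labels))
  structure(list(transport = transport,
                 interconversion = interconv,
                 diff_scale = D_face / params$D_n,
                 D_face = D_face),
            class = "tau_masks")
}
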