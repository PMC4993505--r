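# Geometry descriptions for the two computational domains.

#' Two-membrane slab benchmark geometry
#'
#' A rectangle of length `L` (x direction) stacked, from the centre outwards,
#' as intracellular strip (|y| < d_intra/2), two membranes of width `d_mem`,
#' and two extracellular bands of thickness `d_out` each carrying the far-field
#' Dirichlet boundary.  The membrane potential is probed at two control points
#' `x_a` (intracellular face) and `x_b` (extracellular face) on a common
#' vertical through one membrane.
#'
#' The default dimensions place the upper membrane at y in [0.434, 0.534] um,
#' matching the control points (2, 0.434) and (2, 0.534).
#'
#' @param L membrane length, um.
#' @param d_intra distance between the two membranes (intracellular width), um.
#' @param d_mem membrane width, um.
#' @param d_out thickness of each extracellular band, um.  Chosen much larger
#'   than the Debye length so that the far-field Dirichlet condition on its
#'   outer boundary is harmless.
#' @param x_a,x_b control points (x, y) in um on either side of the upper
#'   membrane, on a common perpendicular to it.
#' @return object of class `slab_geometry`.
#' @export
#' @examples
#' g <- slab_geometry()
#' g$d_intra / 2   # intracellular half-width = y of the membrane face
slab_geometry <- function(L = 4, d_intra = 0.868, d_mem = 0.1, d_out = 0.4,
                          x_a = c(2, d_intra / 2),
                          x_b = c(2, d_intra / 2 + d_mem)) {
  if (!(L > 0 && d_intra > 0 && d_mem > 0 && d_out > 0))
    stop("slab geometry: all band widths must be > 0", call. = FALSE)
  y1 <- d_intra / 2; y2 <- y1 + d_mem; y3 <- y2 + d_out
  if (abs(x_a[1] - x_b[1]) > 1e-12)
    stop("control points must lie on a common perpendicular to the membrane",
         call. = FALSE)
  if (x_a[1] <= 0 || x_a[1] >= L)
    stop("control points must lie strictly inside 0 < x < L", call. = FALSE)
  if (abs(x_a[2]) > y1 + 1e-12)
    stop("x_a must lie in (the closure of) the intracellular strip",
         call. = FALSE)
  if (abs(x_b[2]) < y2 - 1e-12 || abs(x_b[2]) > y3 + 1e-12)
    stop("x_b must lie in (the closure of) the extracellular band",
         call. = FALSE)
  structure(list(L = L, d_intra = d_intra, d_mem = d_mem, d_out = d_out,
                 x_a = as.numeric(x_a), x_b = as.numeric(x_b),
                 y1 = y1, y2 = y2, y3 = y3),
            class = "slab_geometry")
}

#' Node-of-Ranvier longitudinal section geometry (2D)
#'
#' Longitudinal cut through an axon section of length `L`: intracellular strip
#' of half-width `d` (the axon radius), a membrane whose thickness steps from
#' `D_m` (myelinated) down to `D_n` (bare) over the central nodal span of
#' length `L_node`, and extracellular space outside, closed by an outer
#' Dirichlet boundary at distance `d_out` beyond the myelin.
#'
#' @param d axon radius (intracellular half-width), um.
#' @param D_n membrane thickness over the node, um.
#' @param D_m membrane thickness under the myelin, um.
#' @param L axon section length, um.
#' @param L_node length of the nodal span where channel currents apply, um.
#' @param d_out extracellular thickness beyond the myelin, um.
#' @return object of class `ranvier_geometry`.
#' @export
ranvier_geometry <- function(d = 0.434, D_n = 0.02, D_m = 0.406,
                             L = 4, L_node = 0.7, d_out = 0.4) {
  if (!(d > 0 && D_n > 0 && D_m > 0 && L > 0 && L_node > 0 && d_out > 0))
    stop("ranvier geometry: all dimensions must be > 0", call. = FALSE)
  if (D_n > D_m)
    stop("ranvier geometry: D_n must not exceed D_m", call. = FALSE)
  if (L_node >= L)
    stop("ranvier geometry: L_node must be < L", call. = FALSE)
  structure(list(d = d, D_n = D_n, D_m = D_m, L = L, L_node = L_node,
                 d_out = d_out),
            class = "ranvier_geometry")
}

#' Grading specification for tailored meshes
#'
#' Describes a geometric grading of node spacing away from the membrane:
#' first-layer size `h0` at the membrane face, growth ratio `r` per layer,
#' capped at `h_max` far from the membrane.
#'
#' @param h0 first-layer element size at the membrane, um.
#' @param r geometric growth ratio (> 1).
#' @param h_max size cap away from the membrane, um.
#' @return object of class `grading_spec`.
#' @export
grading_spec <- function(h0, r = 2, h_max = 0.05) {
  if (!(h0 > 0)) stop("grading: h0 must be > 0", call. = FALSE)
  if (!(r > 1)) stop("grading: r must be > 1", call. = FALSE)
  if (!(h_max >= h0)) stop("grading: h_max must be >= h0", call. = FALSE)
  structure(list(h0 = h0, r = r, h_max = h_max), class = "grading_spec")
}

# Geometric sequence of layer thicknesses h0, h0 r, ... (capped at hmax)
# covering a segment of length len; the tail is filled with near-hmax layers
# and only the final layer is trimmed to fit exactly.
graded_increments <- function(len, h0, r, hmax) {
  stopifnot(len > 0)
  inc <- numeric(0)
  h <- min(h0, len)
  acc <- 0
  while (acc + h < len - 1e-15 * len) {
    inc <- c(inc, h)
    acc <- acc + h
    h <- min(h * r, hmax)
  }
  inc <- c(inc, len - acc)
  inc
}

# Uniform subdivision of a segment with spacing <= h (at least n_min pieces).
uniform_increments <- function(len, h, n_min = 1L) {
  n <- max(n_min, ceiling(len / h - 1e-12))
  rep(len / n, n)
}
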