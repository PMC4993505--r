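# Triangulations with region labels and tagged boundary / interface edges.
#
# A `pnp_mesh` is a list with
#   nodes  : n x 2 matrix of coordinates (um)
#   tri    : m x 3 integer matrix, counterclockwise
#   region : length-m integer vector (REGION_INTRA/MEMBRANE/EXTRA)
#   bedges : B x 2 integer matrix of tagged edges (domain boundary and
#            electrolyte-membrane interfaces)
#   btag   : length-B integer vector of TAG_* codes
# Only vertices are stored; P2 midside nodes are derived from edges by the
# finite-element layer.

new_pnp_mesh <- function(nodes, tri, region, bedges, btag, check = TRUE) {
  m <- structure(list(
    nodes = matrix(as.numeric(nodes), ncol = 2),
    tri = matrix(as.integer(tri), ncol = 3),
    region = as.integer(region),
    bedges = matrix(as.integer(bedges), ncol = 2),
    btag = as.integer(btag)
  ), class = "pnp_mesh")
  if (check) mesh_check(m)
  m
}

#' @export
print.pnp_mesh <- function(x, ...) {
  cat(sprintf("<pnp_mesh> %d nodes, %d triangles (%s), %d tagged edges\n",
              nrow(x$nodes), nrow(x$tri),
              paste(sprintf("%s: %d", REGION_NAMES, tabulate(x$region, 3L)),
                    collapse = ", "),
              nrow(x$bedges)))
  invisible(x)
}

# Twice the signed area of each triangle (positive = counterclockwise).
tri_signed_area2 <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
}

#' Triangle areas of a mesh
#' @param mesh a `pnp_mesh`.
#' @return numeric vector of element areas (um^2).
#' @export
mesh_areas <- function(mesh) tri_signed_area2(mesh$nodes, mesh$tri) / 2

#' Total area per region
#' @param mesh a `pnp_mesh`.
#' @return named numeric vector (intra, membrane, extra).
#' @export
region_areas <- function(mesh) {
  a <- mesh_areas(mesh)
  out <- c(0, 0, 0)
  for (r in 1:3) out[r] <- sum(a[mesh$region == r])
  names(out) <- REGION_NAMES
  out
}

# Stable integer key for an undirected edge (valid for < 2^26 nodes).
edge_key <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  lo * 2^26 + hi
}

# Unique edges of the triangulation and the triangle->edge incidence.
# Returns list(edges = E x 2 (lo, hi), tri_edge = m x 3 edge index where
# local edge j is opposite local vertex j, edge_tri = E x 2 adjacent
# triangles (0 where absent)).
mesh_edges <- function(mesh) {
  tri <- mesh$tri
  m <- nrow(tri)
  ea <- c(tri[, 2], tri[, 3], tri[, 1])
  eb <- c(tri[, 3], tri[, 1], tri[, 2])
  key <- edge_key(ea, eb)
  uk <- unique(key)
  idx <- match(key, uk)
  first <- !duplicated(key)
  edges <- cbind(pmin(ea, eb)[first], pmax(ea, eb)[first])
  tri_edge <- matrix(idx, nrow = m, ncol = 3)
  tid <- rep(seq_len(m), 3L)
  o <- order(idx, tid)
  ei <- idx[o]; ti <- tid[o]
  dup <- duplicated(ei)
  if (any(duplicated(ei[dup])))
    stop("mesh: non-manifold edge (more than two incident triangles)",
         call. = FALSE)
  edge_tri <- matrix(0L, nrow = length(uk), ncol = 2)
  edge_tri[ei[!dup], 1] <- ti[!dup]
  edge_tri[ei[dup], 2] <- ti[dup]
  list(edges = edges, tri_edge = tri_edge, edge_tri = edge_tri)
}
mesh_edges_fast <- mesh_edges

#' Validate a mesh
#'
#' Checks strict positivity of all signed areas under counterclockwise
#' orientation, region labels, and that every domain-boundary edge carries
#' exactly one tag.  Stops with an informative error on violation.
#'
#' @param mesh a `pnp_mesh`.
#' @return invisibly `TRUE`.
#' @export
mesh_check <- function(mesh) {
  s2 <- tri_signed_area2(mesh$nodes, mesh$tri)
  if (any(s2 <= 0))
    stop(sprintf("mesh: %d triangle(s) with non-positive area", sum(s2 <= 0)),
         call. = FALSE)
  if (!all(mesh$region %in% 1:3))
    stop("mesh: region labels must be in {intra, membrane, extra}",
         call. = FALSE)
  if (length(mesh$region) != nrow(mesh$tri))
    stop("mesh: region labels must partition the triangles", call. = FALSE)
  ed <- mesh_edges_fast(mesh)
  onb <- ed$edge_tri[, 2] == 0L
  t1 <- ed$edge_tri[, 1]; t2 <- ed$edge_tri[, 2]
  iface <- !onb & mesh$region[t1] != mesh$region[pmax(t2, 1L)]
  need_tag <- which(onb | iface)
  have <- edge_key(mesh$bedges[, 1], mesh$bedges[, 2])
  if (anyDuplicated(have))
    stop("mesh: an edge carries more than one tag", call. = FALSE)
  need <- edge_key(ed$edges[need_tag, 1], ed$edges[need_tag, 2])
  if (!all(need %in% have))
    stop("mesh: missing tags on boundary or interface edges", call. = FALSE)
  if (!all(have %in% edge_key(ed$edges[, 1], ed$edges[, 2])))
    stop("mesh: tagged edge not present in the triangulation", call. = FALSE)
  if (!all(mesh$btag %in% 1:6)) stop("mesh: unknown tag code", call. = FALSE)
  # Gamma_inn edges must separate membrane from electrolyte
  inn <- mesh$btag %in% c(TAG_INN_INTRA, TAG_INN_EXTRA, TAG_INTERFACE)
  if (any(inn)) {
    k <- match(have[inn], edge_key(ed$edges[, 1], ed$edges[, 2]))
    ok <- ed$edge_tri[k, 2] != 0L
    if (any(ok)) {
      ra <- mesh$region[ed$edge_tri[k[ok], 1]]
      rb <- mesh$region[ed$edge_tri[k[ok], 2]]
      if (!all(xor(ra == REGION_MEMBRANE, rb == REGION_MEMBRANE)))
        stop("mesh: interface-tagged edge not on a membrane interface",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Total length of tagged edges
#' @param mesh a `pnp_mesh`.
#' @param tag tag name (`"ext"`, `"exl"`, `"exr"`, `"inn_intra"`,
#'   `"inn_extra"`, `"interface"`) or integer code.
#' @return total length in um.
#' @export
tag_length <- function(mesh, tag) {
  code <- if (is.character(tag)) match(tag, TAG_NAMES) else as.integer(tag)
  sel <- mesh$btag == code
  if (!any(sel)) return(0)
  p <- mesh$nodes[mesh$bedges[sel, 1], , drop = FALSE]
  q <- mesh$nodes[mesh$bedges[sel, 2], , drop = FALSE]
  sum(sqrt(rowSums((p - q)^2)))
}

# ---------------------------------------------------------------------------
# Tensor-product construction shared by the structured builders.
#
# xs, ys       : sorted grid lines
# region_fun   : function(cx, cy) -> region code, applied to quad centres
# perim_tag_fun: function(mx, my) -> tag code for perimeter edge midpoints
# inn_fun      : optional function(mx, my) -> TRUE where an interface edge is
#                a Gamma_inn edge (nodal membrane face)
tensor_mesh <- function(xs, ys, region_fun, perim_tag_fun, inn_fun = NULL) {
  nx <- length(xs); ny <- length(ys)
  stopifnot(nx >= 2, ny >= 2)
  nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  nid <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- nid(i, j); b <- nid(i + 1L, j); c <- nid(i + 1L, j + 1L); d <- nid(i, j + 1L)
  # alternate the quad diagonal in a union-jack pattern for symmetry:
  # diagonal a-c on even (i+j), diagonal b-d on odd
  flip <- (i + j) %% 2L == 0L
  tri <- rbind(
    cbind(a, b, ifelse(flip, c, d)),
    cbind(ifelse(flip, a, b), c, d)
  )
  qc_x <- (xs[i] + xs[i + 1L]) / 2
  qc_y <- (ys[j] + ys[j + 1L]) / 2
  region <- rep(mapply(region_fun, qc_x, qc_y), 2L)
  mesh <- new_pnp_mesh(nodes, tri, region,
                       bedges = matrix(integer(0), 0, 2), btag = integer(0),
                       check = FALSE)
  mesh <- retag_mesh(mesh, perim_tag_fun, inn_fun)
  mesh_check(mesh)
  mesh
}

# Recompute bedges/btag of a mesh from scratch: perimeter edges via
# perim_tag_fun, interface edges via region adjacency (+ inn_fun override).
retag_mesh <- function(mesh, perim_tag_fun, inn_fun = NULL) {
  ed <- mesh_edges_fast(mesh)
  onb <- ed$edge_tri[, 2] == 0L
  t2 <- pmax(ed$edge_tri[, 2], 1L)
  iface <- !onb & mesh$region[ed$edge_tri[, 1]] != mesh$region[t2]
  sel <- which(onb | iface)
  e <- ed$edges[sel, , drop = FALSE]
  mx <- (mesh$nodes[e[, 1], 1] + mesh$nodes[e[, 2], 1]) / 2
  my <- (mesh$nodes[e[, 1], 2] + mesh$nodes[e[, 2], 2]) / 2
  tag <- integer(length(sel))
  ib <- onb[sel]
  if (any(ib)) tag[ib] <- mapply(perim_tag_fun, mx[ib], my[ib])
  if (any(!ib)) {
    tag[!ib] <- TAG_INTERFACE
    if (!is.null(inn_fun)) {
      # decide intra vs extra side from the adjacent non-membrane region
      k <- sel[!ib]
      ra <- mesh$region[ed$edge_tri[k, 1]]
      rb <- mesh$region[ed$edge_tri[k, 2]]
      other <- ifelse(ra == REGION_MEMBRANE, rb, ra)
      isinn <- mapply(inn_fun, mx[!ib], my[!ib])
      tag[!ib][isinn & other == REGION_INTRA] <- TAG_INN_INTRA
      tag[!ib][isinn & other == REGION_EXTRA] <- TAG_INN_EXTRA
    }
  }
  mesh$bedges <- e
  mesh$btag <- as.integer(tag)
  mesh
}

# ---------------------------------------------------------------------------

# Snap grid lines within tol of a marker to the marker, then deduplicate.
snap_lines <- function(v, markers, tol = 1e-9) {
  for (t in markers) v[abs(v - t) < tol] <- t
  sort(unique(v))
}

# y grid lines of the slab: five bands (extra, membrane, intra, membrane,
# extra) with per-band increment generators.
slab_ylines <- function(geom, intra_inc, mem_inc, extra_inc) {
  y1 <- geom$y1; y2 <- geom$y2; y3 <- geom$y3
  up_extra <- y2 + cumsum(extra_inc)
  up_mem <- y1 + cumsum(mem_inc)
  half_intra <- cumsum(intra_inc)            # from face toward centre
  intra_up <- y1 - half_intra[half_intra < geom$d_intra / 2 - 1e-15]
  ys_up <- c(0, sort(intra_up), y1, up_mem, up_extra)
  ys <- snap_lines(c(-ys_up, ys_up), c(-y3, -y2, -y1, 0, y1, y2, y3))
  ys[length(ys)] <- y3; ys[1] <- -y3        # guard rounding
  ys
}

slab_perim_tag <- function(geom) {
  y1 <- geom$y1; y2 <- geom$y2; L <- geom$L
  function(mx, my) {
    if (abs(my) > y2) return(TAG_EXT)       # extracellular outer boundary
    if (mx < L / 2) TAG_EXL else TAG_EXR    # interior strip lateral ends
  }
}

#' Build a structured mesh of the slab benchmark
#'
#' Five horizontal bands (extra, membrane, intra, membrane, extra) on a
#' rectangle, meshed as a tensor grid with alternating diagonals.  The outer
#' boundary of each extracellular band (its outer edge and two lateral ends)
#' is tagged `ext` (Dirichlet); the lateral ends of the interior strip are
#' tagged `exl` / `exr` (no-flux); membrane interfaces are tagged
#' `interface`.  There are no `inn` edges: the benchmark has no transmembrane
#' flux.
#'
#' @param geom a [slab_geometry()].
#' @param target_h requested element size, um.
#' @return a `pnp_mesh`.
#' @export
#' @examples
#' m <- build_slab_mesh(slab_geometry(), target_h = 0.2)
#' region_areas(m)
build_slab_mesh <- function(geom, target_h) {
  stopifnot(inherits(geom, "slab_geometry"))
  if (!(target_h > 0)) stop("target_h must be > 0", call. = FALSE)
  xs <- cumsum(c(0, uniform_increments(geom$L, target_h, n_min = 1L)))
  intra_inc <- uniform_increments(geom$d_intra / 2, target_h)
  mem_inc <- uniform_increments(geom$d_mem, target_h)
  extra_inc <- uniform_increments(geom$d_out, target_h)
  ys <- slab_ylines(geom, intra_inc, mem_inc, extra_inc)
  y1 <- geom$y1; y2 <- geom$y2
  region_fun <- function(cx, cy) {
    ay <- abs(cy)
    if (ay < y1) REGION_INTRA else if (ay < y2) REGION_MEMBRANE
    else REGION_EXTRA
  }
  tensor_mesh(xs, ys, region_fun, slab_perim_tag(geom))
}

#' Build a tailored (geometrically graded) slab mesh
#'
#' Node spacing normal to each membrane follows `h0 * r^k` for layer k away
#' from the membrane face, capped at `h_max`, in both the intracellular and
#' extracellular electrolyte; the membrane interior gets `n_mem` uniform rows
#' (its potential is affine at equilibrium).  Horizontal spacing is uniform
#' with `nx` intervals.
#'
#' @param geom a [slab_geometry()].
#' @param spec a [grading_spec()].
#' @param nx number of horizontal intervals (default 16).
#' @param n_mem rows across each membrane band (default 2).
#' @return a `pnp_mesh`.
#' @export
build_tailored_mesh <- function(geom, spec, nx = 16L, n_mem = 2L) {
  stopifnot(inherits(geom, "slab_geometry"), inherits(spec, "grading_spec"))
  xs <- cumsum(c(0, uniform_increments(geom$L, geom$L / nx)))
  intra_inc <- graded_increments(geom$d_intra / 2, spec$h0, spec$r, spec$h_max)
  mem_inc <- uniform_increments(geom$d_mem, geom$d_mem / n_mem, n_min = n_mem)
  extra_inc <- graded_increments(geom$d_out, spec$h0, spec$r, spec$h_max)
  ys <- slab_ylines(geom, intra_inc, mem_inc, extra_inc)
  y1 <- geom$y1; y2 <- geom$y2
  region_fun <- function(cx, cy) {
    ay <- abs(cy)
    if (ay < y1) REGION_INTRA else if (ay < y2) REGION_MEMBRANE
    else REGION_EXTRA
  }
  tensor_mesh(xs, ys, region_fun, slab_perim_tag(geom))
}

#' Build a structured mesh of the 2D node-of-Ranvier section
#'
#' Intracellular strip |y| < d, membrane of thickness `D_n` over the central
#' nodal span and `D_m` elsewhere, extracellular space outside up to an outer
#' Dirichlet boundary.  The electrolyte-facing membrane edges of the nodal
#' span are tagged `inn_intra` (|y| = d) and `inn_extra` (|y| = d + D_n).
#'
#' @param geom a [ranvier_geometry()].
#' @param target_h requested element size, um.
#' @param grading optional [grading_spec()]; when given, the vertical spacing
#'   is geometrically graded towards the electrolyte-membrane faces.
#' @return a `pnp_mesh`.
#' @export
build_ranvier_mesh <- function(geom, target_h, grading = NULL) {
  stopifnot(inherits(geom, "ranvier_geometry"))
  if (!(target_h > 0)) stop("target_h must be > 0", call. = FALSE)
  d <- geom$d; Dn <- geom$D_n; Dm <- geom$D_m; L <- geom$L
  xl <- (L - geom$L_node) / 2; xr <- (L + geom$L_node) / 2
  y3 <- d + Dm + geom$d_out
  xs <- snap_lines(c(
    cumsum(c(0, uniform_increments(xl, target_h))),
    xl + cumsum(c(0, uniform_increments(xr - xl, target_h))),
    xr + cumsum(c(0, uniform_increments(L - xr, target_h)))
  ), c(0, xl, xr, L))
  grade <- function(len, from_face) {
    if (is.null(grading)) uniform_increments(len, target_h)
    else graded_increments(len, grading$h0, grading$r, grading$h_max)
  }
  intra_inc <- grade(d, TRUE)                        # from |y| = d inward
  memn_inc <- uniform_increments(Dn, if (is.null(grading)) target_h
                                 else max(grading$h0, Dn / 4), n_min = 2L)
  # between d + D_n and d + D_m: grade away from the nodal extracellular face
  mid_inc <- grade(Dm - Dn, TRUE)
  out_inc <- grade(geom$d_out, TRUE)
  ys_up <- c(0, d - cumsum(intra_inc)[cumsum(intra_inc) < d - 1e-15],
             d, d + cumsum(memn_inc), d + Dn + cumsum(mid_inc),
             d + Dm + cumsum(out_inc))
  ys <- snap_lines(c(-ys_up, ys_up),
                   c(0, d, d + Dn, d + Dm, y3, -d, -(d + Dn), -(d + Dm), -y3))
  region_fun <- function(cx, cy) {
    ay <- abs(cy)
    if (ay < d) return(REGION_INTRA)
    if (ay < d + Dn) return(REGION_MEMBRANE)
    if (ay < d + Dm) {
      if (cx > xl && cx < xr) REGION_EXTRA else REGION_MEMBRANE
    } else REGION_EXTRA
  }
  perim_tag <- function(mx, my) {
    if (abs(my) > d + Dn) return(TAG_EXT)
    if (mx < L / 2) TAG_EXL else TAG_EXR
  }
  inn_fun <- function(mx, my) {
    mx > xl - 1e-12 && mx < xr + 1e-12 &&
      (abs(abs(my) - d) < 1e-9 || abs(abs(my) - (d + Dn)) < 1e-9)
  }
  tensor_mesh(xs, ys, region_fun, perim_tag, inn_fun)
}

#' Distance from nodes to the nearest membrane interface
#'
#' For every mesh node (or the nodes of one region), the Euclidean distance
#' to the nearest edge tagged `interface`, `inn_intra` or `inn_extra`.
#'
#' @param mesh a `pnp_mesh`.
#' @param region optional region name (`"intra"`, `"membrane"`, `"extra"`) to
#'   restrict the node set to vertices of that region's triangles.
#' @return named list: `node` (indices), `dist` (um).
#' @export
node_membrane_distance <- function(mesh, region = NULL) {
  sel <- mesh$btag %in% c(TAG_INN_INTRA, TAG_INN_EXTRA, TAG_INTERFACE)
  if (!any(sel)) stop("mesh has no membrane interface edges", call. = FALSE)
  segs <- mesh$bedges[sel, , drop = FALSE]
  if (is.null(region)) {
    nodes_idx <- seq_len(nrow(mesh$nodes))
  } else {
    rc <- match(region, REGION_NAMES)
    nodes_idx <- sort(unique(as.vector(mesh$tri[mesh$region == rc, ])))
  }
  P <- mesh$nodes[nodes_idx, , drop = FALSE]
  dmin <- rep(Inf, nrow(P))
  A <- mesh$nodes[segs[, 1], , drop = FALSE]
  B <- mesh$nodes[segs[, 2], , drop = FALSE]
  for (s in seq_len(nrow(segs))) {
    ab <- B[s, ] - A[s, ]
    len2 <- sum(ab^2)
    t <- ((P[, 1] - A[s, 1]) * ab[1] + (P[, 2] - A[s, 2]) * ab[2]) / len2
    t <- pmin(1, pmax(0, t))
    dx <- A[s, 1] + t * ab[1] - P[, 1]
    dy <- A[s, 2] + t * ab[2] - P[, 2]
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
  }
  list(node = nodes_idx, dist = dmin)
}
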