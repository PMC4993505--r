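# P2 Lagrange finite elements on triangles: reference basis, quadrature,
# function spaces restricted to region subsets, and assembly of the blocks of
# the coupled Newton system.
#
# Local dof ordering on an element (v1, v2, v3 counterclockwise):
#   1..3 vertex dofs, 4 = midside of (v1,v2), 5 = (v2,v3), 6 = (v3,v1).
# Global dofs: vertex i -> i, edge e -> n_vertices + e.

# --- reference element -----------------------------------------------------

# P2 shape functions at reference coordinates (xi, eta); vertices at
# (0,0), (1,0), (0,1).
p2_shape <- function(xi, eta) {
  l1 <- 1 - xi - eta; l2 <- xi; l3 <- eta
  cbind(l1 * (2 * l1 - 1), l2 * (2 * l2 - 1), l3 * (2 * l3 - 1),
        4 * l1 * l2, 4 * l2 * l3, 4 * l3 * l1)
}

# derivatives wrt (xi, eta): list(dxi = nq x 6, deta = nq x 6)
p2_dshape <- function(xi, eta) {
  l1 <- 1 - xi - eta; l2 <- xi; l3 <- eta
  dxi <- cbind(1 - 4 * l1, 4 * l2 - 1, 0 * l3,
               4 * (l1 - l2), 4 * l3, -4 * l3)
  deta <- cbind(1 - 4 * l1, 0 * l2, 4 * l3 - 1,
                -4 * l2, 4 * l2, 4 * (l1 - l3))
  list(dxi = dxi, deta = deta)
}

# Reference-element second derivatives of the P2 basis (constant):
# rows = basis function, cols = (xi.xi, xi.eta, eta.eta)
P2_D2REF <- rbind(
  c(4, 4, 4), c(4, 0, 0), c(0, 0, 4),
  c(-8, -4, 0), c(0, 4, 0), c(0, -4, -8))

# Symmetric Gauss rules on the unit triangle; weights sum to 1/2 (its area).
# degree 5: 7 points; degree 7: 13 points (one negative centroid weight).
tri_quadrature <- function(degree = 5) {
  if (degree <= 5) {
    a1 <- 0.0597158717897698; b1 <- 0.4701420641051151
    a2 <- 0.7974269853530873; b2 <- 0.1012865073234563
    bc <- rbind(c(1, 1, 1) / 3,
                c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
                c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2))
    w <- c(0.225, rep(0.1323941527885062, 3), rep(0.1259391805448271, 3)) / 2
  } else {
    a1 <- 0.2603459660790466; a2 <- 0.0651301029022158
    b  <- 0.6384441885698096; g  <- 0.3128654960048739
    bc <- rbind(c(1, 1, 1) / 3,
                c(1 - 2 * a1, a1, a1), c(a1, 1 - 2 * a1, a1), c(a1, a1, 1 - 2 * a1),
                c(1 - 2 * a2, a2, a2), c(a2, 1 - 2 * a2, a2), c(a2, a2, 1 - 2 * a2),
                c(b, g, 1 - b - g), c(g, b, 1 - b - g), c(b, 1 - b - g, g),
                c(g, 1 - b - g, b), c(1 - b - g, b, g), c(1 - b - g, g, b))
    w <- c(-0.1495700444676740,
           rep(0.1756152574332031, 3), rep(0.0533472356088397, 3),
           rep(0.0771137608902570, 6)) / 2
  }
  list(xi = bc[, 2], eta = bc[, 3], w = w)
}

# Gauss-Legendre rule on [0,1] (3 points, degree 5).
edge_quadrature <- function() {
  s <- sqrt(3 / 5) / 2
  list(t = c(0.5 - s, 0.5, 0.5 + s), w = c(5, 8, 5) / 18)
}

# --- function spaces -------------------------------------------------------

#' P2 function space on a region subset of a mesh
#'
#' Builds the quadratic Lagrange space whose dofs sit at the vertices and
#' edge midpoints of the triangles in `regions`.  Dofs on edges tagged with
#' any of `dirichlet_tags` are marked as Dirichlet dofs.  Interface dofs
#' shared between a membrane triangle and an electrolyte triangle belong to
#' every space covering either side.
#'
#' @param mesh a `pnp_mesh`.
#' @param regions character vector of region names, or `"all"`.
#' @param dirichlet_tags character vector of edge tag names carrying
#'   essential boundary conditions (default `"ext"`).
#' @param struct optional precomputed [mesh_edges()] structure (shared
#'   between the spaces of one mesh).
#' @return an object of class `fe_space`.
#' @export
#' @examples
#' m <- build_slab_mesh(slab_geometry(), 0.25)
#' Vh <- fe_space(m, "all")
#' Ch <- fe_space(m, c("intra", "extra"))
#' c(Vh$ndof, Ch$ndof)
fe_space <- function(mesh, regions = "all", dirichlet_tags = "ext",
                     struct = NULL) {
  if (is.null(struct)) struct <- mesh_edges(mesh)
  n <- nrow(mesh$nodes)
  E <- nrow(struct$edges)
  if (identical(regions, "all")) {
    tsel <- seq_len(nrow(mesh$tri))
  } else {
    codes <- match(regions, REGION_NAMES)
    if (anyNA(codes)) stop("unknown region name", call. = FALSE)
    tsel <- which(mesh$region %in% codes)
  }
  if (length(tsel) == 0) stop("fe_space: empty region", call. = FALSE)
  tri <- mesh$tri[tsel, , drop = FALSE]
  te <- struct$tri_edge[tsel, , drop = FALSE]
  # global dofs per element in local order (see header)
  T6g <- cbind(tri, n + te[, 3], n + te[, 1], n + te[, 2])
  act <- sort(unique(as.vector(T6g)))
  g2l <- integer(n + E)
  g2l[act] <- seq_along(act)
  T6 <- matrix(g2l[T6g], ncol = 6)
  # dof coordinates
  mid <- (mesh$nodes[struct$edges[, 1], , drop = FALSE] +
            mesh$nodes[struct$edges[, 2], , drop = FALSE]) / 2
  allxy <- rbind(mesh$nodes, mid)
  xy <- allxy[act, , drop = FALSE]
  # Dirichlet dofs
  dtags <- match(dirichlet_tags, TAG_NAMES)
  dsel <- which(mesh$btag %in% dtags)
  dir_g <- integer(0)
  if (length(dsel)) {
    be <- mesh$bedges[dsel, , drop = FALSE]
    ekey <- edge_key(struct$edges[, 1], struct$edges[, 2])
    eidx <- match(edge_key(be[, 1], be[, 2]), ekey)
    dir_g <- unique(c(as.vector(be), n + eidx))
    dir_g <- dir_g[g2l[dir_g] > 0L]
  }
  structure(list(
    mesh = mesh, struct = struct, tris = tsel, T6 = T6, T6g = T6g,
    ndof = length(act), act = act, g2l = g2l, xy = xy,
    dirichlet = sort(g2l[dir_g]),
    nvert = n, nedge = E,
    cache = new.env(parent = emptyenv())
  ), class = "fe_space")
}

#' @export
print.fe_space <- function(x, ...) {
  cat(sprintf("<fe_space> P2, %d dofs on %d triangles (%d Dirichlet)\n",
              x$ndof, length(x$tris), length(x$dirichlet)))
  invisible(x)
}

# Per-element geometry + physical shape data for a quadrature rule.
# Returns list with detJ (m), N (nq x 6), gx, gy (m x nq x 6), and the
# inverse-transpose Jacobian entries.
space_geom <- function(space, degree = 5) {
  key <- paste0("geom", degree)
  if (!is.null(space$cache[[key]])) return(space$cache[[key]])
  mesh <- space$mesh
  tri <- mesh$tri[space$tris, , drop = FALSE]
  p1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tri[, 3], , drop = FALSE]
  x21 <- p2[, 1] - p1[, 1]; y21 <- p2[, 2] - p1[, 2]
  x31 <- p3[, 1] - p1[, 1]; y31 <- p3[, 2] - p1[, 2]
  detJ <- x21 * y31 - x31 * y21
  # inv(J)^T rows: d xi/dx = y31/det, d xi/dy = -x31/det,
  #               d eta/dx = -y21/det, d eta/dy = x21/det
  a11 <- y31 / detJ; a12 <- -x31 / detJ
  a21 <- -y21 / detJ; a22 <- x21 / detJ
  q <- tri_quadrature(degree)
  N <- p2_shape(q$xi, q$eta)
  d <- p2_dshape(q$xi, q$eta)
  m <- nrow(tri); nq <- length(q$w)
  gx <- array(0, c(m, nq, 6)); gy <- array(0, c(m, nq, 6))
  for (qi in seq_len(nq)) for (i in 1:6) {
    gx[, qi, i] <- d$dxi[qi, i] * a11 + d$deta[qi, i] * a21
    gy[, qi, i] <- d$dxi[qi, i] * a12 + d$deta[qi, i] * a22
  }
  # physical quadrature points
  qx <- matrix(0, m, nq); qy <- matrix(0, m, nq)
  for (qi in seq_len(nq)) {
    qx[, qi] <- p1[, 1] + q$xi[qi] * x21 + q$eta[qi] * x31
    qy[, qi] <- p1[, 2] + q$xi[qi] * y21 + q$eta[qi] * y31
  }
  g <- list(detJ = detJ, w = q$w, N = N, gx = gx, gy = gy,
            qx = qx, qy = qy,
            a11 = a11, a12 = a12, a21 = a21, a22 = a22)
  space$cache[[key]] <- g
  g
}

# expand a per-region named coefficient (or scalar, or per-element vector)
# into a per-covered-element vector
coef_per_element <- function(space, coefficient) {
  m <- length(space$tris)
  if (is.null(coefficient)) return(rep(1, m))
  if (length(coefficient) == m && is.null(names(coefficient)))
    return(as.numeric(coefficient))
  if (length(coefficient) == 1L && is.null(names(coefficient)))
    return(rep(as.numeric(coefficient), m))
  reg <- REGION_NAMES[space$mesh$region[space$tris]]
  if (!all(reg %in% names(coefficient)))
    stop("coefficient must name every covered region", call. = FALSE)
  as.numeric(coefficient[reg])
}

# --- assembly --------------------------------------------------------------

# build a sparse matrix from per-element 6x6 local contributions
# loc: function(i, j) -> numeric vector over covered elements
asm_pairs <- function(space_r, space_c, loc) {
  m <- nrow(space_r$T6)
  ii <- integer(36L * m); jj <- integer(36L * m); vv <- numeric(36L * m)
  k <- 0L
  for (i in 1:6) for (j in 1:6) {
    idx <- k + seq_len(m)
    ii[idx] <- space_r$T6[, i]
    jj[idx] <- space_c$T6[, j]
    vv[idx] <- loc(i, j)
    k <- k + m
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                       dims = c(space_r$ndof, space_c$ndof))
}

#' Assemble the P2 mass matrix
#'
#' \eqn{(M)_{ij} = \int \psi_i \psi_j \, dx} over the space's region (or a
#' named sub-region).  Symmetric positive definite on its region; the sum of
#' all entries equals the covered area.
#'
#' @param space an [fe_space()].
#' @param region optional region name to restrict the integration domain.
#' @return sparse symmetric matrix (`dgCMatrix`).
#' @export
assemble_mass <- function(space, region = NULL) {
  g <- space_geom(space)
  sel <- region_mask(space, region)
  N <- g$N; w <- g$w
  Mref <- crossprod(N * w, N)          # sum_q w_q N_i N_j
  detJ <- g$detJ * sel
  asm_pairs(space, space, function(i, j) detJ * Mref[i, j])
}

region_mask <- function(space, region) {
  if (is.null(region)) return(rep(1, length(space$tris)))
  rc <- match(region, REGION_NAMES)
  if (is.na(rc)) stop("unknown region name", call. = FALSE)
  msk <- as.numeric(space$mesh$region[space$tris] == rc)
  if (!any(msk > 0)) stop("assemble: empty region", call. = FALSE)
  msk
}

#' Assemble a stiffness (diffusion) matrix with piecewise-constant coefficient
#'
#' \eqn{(K)_{ij} = \int a \, \nabla\psi_i\cdot\nabla\psi_j \, dx} where `a`
#' is constant per region (e.g. the diffusion coefficient D_k, zero on the
#' membrane, or the scaled permittivity, discontinuous across interfaces).
#'
#' @param space an [fe_space()].
#' @param coefficient scalar, per-element vector, or named per-region vector
#'   (names `intra`, `membrane`, `extra`).  Must be non-negative.
#' @return sparse symmetric positive semidefinite matrix.
#' @export
assemble_stiffness <- function(space, coefficient = 1) {
  a <- coef_per_element(space, coefficient)
  if (any(a < 0)) stop("stiffness coefficient must be non-negative",
                       call. = FALSE)
  g <- space_geom(space)
  w <- g$w; nq <- length(w)
  fac <- a * g$detJ
  asm_pairs(space, space, function(i, j) {
    s <- 0
    for (qi in seq_len(nq))
      s <- s + w[qi] * (g$gx[, qi, i] * g$gx[, qi, j] +
                          g$gy[, qi, i] * g$gy[, qi, j])
    fac * s
  })
}

#' Assemble the Newton coupling blocks of the drift term
#'
#' For the current iterate (`c_field`, `V_field`) of one species, assembles
#' \deqn{(D_{cc})_{ij} = \int \tilde D \, \psi_j \, \nabla V_s\cdot\nabla\psi_i \, dx,\qquad
#'       (D_{cv})_{ij} = \int \tilde D \, c_s \, \nabla\varphi_j\cdot\nabla\psi_i \, dx,}
#' the derivatives of the nonlinear drift \eqn{\int \tilde D c \nabla V\cdot\nabla\psi}
#' with respect to the concentration and the potential coefficients.
#' `D_cc %*% c_s` is exactly the drift residual contribution.
#'
#' @param space_c concentration space (rows; electrolyte regions).
#' @param space_v potential space (columns of `Dcv`; global).
#' @param c_field,V_field current iterate as `discrete_field`s (or coefficient
#'   vectors in the respective spaces).
#' @param dtilde drift mobility, named per region or scalar (zero on any
#'   region not covered by `space_c`).
#' @return list with sparse matrices `Dcc` (Nc x Nc) and `Dcv` (Nc x Nv).
#' @export
assemble_coupling <- function(space_c, space_v, c_field, V_field, dtilde) {
  cc <- field_coef(c_field, space_c)
  vv <- field_coef(V_field, space_v)
  gc <- space_geom(space_c)
  dt <- coef_per_element(space_c, dtilde)
  m <- nrow(space_c$T6); nq <- length(gc$w)
  # both spaces must cover the c-space triangles; build V-side dof map there
  Tv <- map_tris(space_v, space_c$tris)
  # gradient of V and value of c at the c-space quadrature points
  gVx <- matrix(0, m, nq); gVy <- matrix(0, m, nq); cq <- matrix(0, m, nq)
  for (i in 1:6) {
    vi <- vv[Tv[, i]]
    ci <- cc[space_c$T6[, i]]
    for (qi in seq_len(nq)) {
      gVx[, qi] <- gVx[, qi] + vi * gc$gx[, qi, i]
      gVy[, qi] <- gVy[, qi] + vi * gc$gy[, qi, i]
      cq[, qi] <- cq[, qi] + ci * gc$N[qi, i]
    }
  }
  fac <- dt * gc$detJ
  Dcc <- asm_pairs(space_c, space_c, function(i, j) {
    s <- 0
    for (qi in seq_len(nq))
      s <- s + gc$w[qi] * gc$N[qi, j] *
        (gVx[, qi] * gc$gx[, qi, i] + gVy[, qi] * gc$gy[, qi, i])
    fac * s
  })
  # Dcv: rows in c-space, cols in v-space (on the shared triangles)
  ii <- integer(36L * m); jj <- integer(36L * m); vvv <- numeric(36L * m)
  k <- 0L
  for (i in 1:6) for (j in 1:6) {
    s <- 0
    for (qi in seq_len(nq))
      s <- s + gc$w[qi] * cq[, qi] *
        (gc$gx[, qi, j] * gc$gx[, qi, i] + gc$gy[, qi, j] * gc$gy[, qi, i])
    idx <- k + seq_len(m)
    ii[idx] <- space_c$T6[, i]; jj[idx] <- Tv[, j]; vvv[idx] <- fac * s
    k <- k + m
  }
  Dcv <- Matrix::sparseMatrix(i = ii, j = jj, x = vvv,
                              dims = c(space_c$ndof, space_v$ndof))
  list(Dcc = Dcc, Dcv = Dcv)
}

# local dof matrix of `space` restricted to a set of mesh triangles
map_tris <- function(space, tris) {
  pos <- match(tris, space$tris)
  if (anyNA(pos))
    stop("spaces are defined on mismatched regions", call. = FALSE)
  space$T6[pos, , drop = FALSE]
}

#' Assemble the charge (mixed mass) matrix of the Poisson source
#'
#' \eqn{S_{ij} = -F z \int \psi_i \varphi_j \, dx} over the concentration
#' space's region, with rows in the potential space and columns in the
#' concentration space.  In the package's internal units the Poisson equation
#' is Faraday-scaled, so `F = 1` by default (see [eps_scaled()]).
#'
#' @param space_c concentration space.
#' @param space_v potential space.
#' @param z valence of the species.
#' @param faraday scale constant (1 in internal units).
#' @return sparse Nv x Nc matrix.
#' @export
assemble_charge_matrix <- function(space_c, space_v, z, faraday = 1) {
  g <- space_geom(space_c)
  Mref <- crossprod(g$N * g$w, g$N)
  Tv <- map_tris(space_v, space_c$tris)
  m <- nrow(space_c$T6)
  ii <- integer(36L * m); jj <- integer(36L * m); vv <- numeric(36L * m)
  fac <- -faraday * z * g$detJ
  k <- 0L
  for (i in 1:6) for (j in 1:6) {
    idx <- k + seq_len(m)
    ii[idx] <- Tv[, i]; jj[idx] <- space_c$T6[, j]
    vv[idx] <- fac * Mref[i, j]
    k <- k + m
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                       dims = c(space_v$ndof, space_c$ndof))
}

#' Assemble a boundary load vector from a flux on tagged edges
#'
#' \eqn{(F)_j = -\int_\Gamma f \, \psi_j \, ds} over all edges carrying
#' `tag`, with a 3-point Gauss rule per edge.  `f` may be a constant, a
#' function `f(x, y)`, or a vector of per-edge constants.
#'
#' @param space an [fe_space()] containing the tagged edges' dofs.
#' @param tag edge tag name.
#' @param f flux value(s) (mM um ms-1 in internal units).
#' @return dense load vector of length `space$ndof`.
#' @export
assemble_boundary_load <- function(space, tag, f) {
  code <- match(tag, TAG_NAMES)
  sel <- which(space$mesh$btag == code)
  if (!length(sel))
    stop(sprintf("boundary tag '%s' absent from mesh", tag), call. = FALSE)
  be <- space$mesh$bedges[sel, , drop = FALSE]
  st <- space$struct
  ekey <- edge_key(st$edges[, 1], st$edges[, 2])
  eidx <- match(edge_key(be[, 1], be[, 2]), ekey)
  q <- edge_quadrature()
  out <- numeric(space$ndof)
  p1 <- space$mesh$nodes[be[, 1], , drop = FALSE]
  p2 <- space$mesh$nodes[be[, 2], , drop = FALSE]
  len <- sqrt(rowSums((p2 - p1)^2))
  fvec <- if (is.function(f)) NULL else rep_len(as.numeric(f), nrow(be))
  dofs <- cbind(space$g2l[be[, 1]], space$g2l[be[, 2]],
                space$g2l[space$nvert + eidx])
  if (any(dofs == 0L))
    stop("boundary edge dofs not covered by this space", call. = FALSE)
  idx <- integer(0); val <- numeric(0)
  # 1D P2 shape on an edge (t in [0,1]): endpoints + midside
  for (qi in seq_along(q$t)) {
    t <- q$t[qi]
    sh <- c((1 - t) * (1 - 2 * t), t * (2 * t - 1), 4 * t * (1 - t))
    xq <- p1[, 1] + t * (p2[, 1] - p1[, 1])
    yq <- p1[, 2] + t * (p2[, 2] - p1[, 2])
    fq <- if (is.function(f)) f(xq, yq) else fvec
    wq <- q$w[qi] * len * fq
    for (a in 1:3) {
      idx <- c(idx, dofs[, a])
      val <- c(val, -wq * sh[a])
    }
  }
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# --- fields ----------------------------------------------------------------

#' Discrete P2 field
#'
#' @param space an [fe_space()].
#' @param coef coefficient vector of length `space$ndof`.
#' @return object of class `discrete_field`.
#' @export
discrete_field <- function(space, coef) {
  if (length(coef) != space$ndof)
    stop("coefficient length must equal the space dof count", call. = FALSE)
  structure(list(space = space, coef = as.numeric(coef)),
            class = "discrete_field")
}

field_coef <- function(field, space = NULL) {
  if (inherits(field, "discrete_field")) return(field$coef)
  if (!is.null(space) && length(field) != space$ndof)
    stop("coefficient length must equal the space dof count", call. = FALSE)
  as.numeric(field)
}

#' Interpolate a function into a P2 space
#'
#' Sets each dof to the function value at the dof location (vertices and
#' edge midpoints); exact for quadratic polynomials.
#'
#' @param space an [fe_space()].
#' @param fun function of (x, y) returning values, or a constant.
#' @return a `discrete_field`.
#' @export
interpolate_field <- function(space, fun) {
  v <- if (is.function(fun)) fun(space$xy[, 1], space$xy[, 2])
  else as.numeric(fun)
  if (length(v) == 1L) v <- rep(v, space$ndof)
  discrete_field(space, v)
}

# values of a field at the mesh vertices (NA -> 0 outside the region)
field_vertex_values <- function(field) {
  sp <- field$space
  out <- numeric(sp$nvert)
  vg <- seq_len(sp$nvert)
  loc <- sp$g2l[vg]
  out[vg[loc > 0L]] <- field$coef[loc[loc > 0L]]
  out
}

#' Evaluate a P2 field at a point
#'
#' Locates the triangle containing `point` (restricted to `region`'s side if
#' given, which matters on interfaces where gradients and concentrations are
#' one-sided) and evaluates the quadratic interpolant exactly.
#'
#' @param field a `discrete_field`.
#' @param point numeric length-2 (x, y) in um.
#' @param region optional region name selecting the side on an interface.
#' @param tol barycentric tolerance for point location.
#' @return numeric scalar.
#' @export
evaluate_field <- function(field, point, region = NULL, tol = 1e-9) {
  sp <- field$space
  mesh <- sp$mesh
  tris <- sp$tris
  if (!is.null(region)) {
    rc <- match(region, REGION_NAMES)
    keep <- mesh$region[tris] == rc
    if (!any(keep)) stop("field does not cover the requested region",
                         call. = FALSE)
    tsel <- which(keep)
  } else tsel <- seq_along(tris)
  tri <- mesh$tri[tris[tsel], , drop = FALSE]
  p1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tri[, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  l2 <- ((point[1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
           (p3[, 1] - p1[, 1]) * (point[2] - p1[, 2])) / det
  l3 <- ((p2[, 1] - p1[, 1]) * (point[2] - p1[, 2]) -
           (point[1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / det
  l1 <- 1 - l2 - l3
  inside <- pmin(l1, l2, l3)
  k <- which.max(inside)
  if (inside[k] < -tol)
    stop(sprintf("point (%g, %g) lies outside the field's region",
                 point[1], point[2]), call. = FALSE)
  e <- tsel[k]
  sh <- p2_shape(l2[k], l3[k])
  sum(sh * field$coef[sp$T6[e, ]])
}

#' Integrate a field over its region
#'
#' @param field a `discrete_field`.
#' @param region optional region restriction.
#' @return the integral (e.g. total moles per um of depth for a
#'   concentration field).
#' @export
integrate_field <- function(field, region = NULL) {
  sp <- field$space
  g <- space_geom(sp)
  msk <- region_mask(sp, region)
  cf <- matrix(field$coef[sp$T6], ncol = 6)
  vq <- cf %*% t(g$N)                 # m x nq values
  sum((vq %*% g$w) * g$detJ * msk)
}
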