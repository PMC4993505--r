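# Hierarchical a-posteriori error estimation for P2 solutions:
# gradient recovery by patch least squares, and the per-element degree-3
# correction whose third derivatives match the second derivatives of the
# recovered gradient.  The element error measures drive all four local mesh
# operations.

# --- gradient recovery -----------------------------------------------------

#' Recover a continuous gradient of a P2 field
#'
#' Superconvergent-patch-recovery style: for every mesh vertex a quadratic
#' polynomial (per gradient component) is fitted by least squares to the
#' broken P2 gradient sampled at the quadrature points of the surrounding
#' elements; vertex dof values are the fits at the vertex, midside values
#' average the fits of the edge endpoints.  Recovery is performed per region
#' (gradients are discontinuous across the membrane interfaces), yielding a
#' field continuous within each region whose restriction to any element is
#' again quadratic.
#'
#' @param field a `discrete_field` (typically the potential).
#' @return object of class `recovered_gradient`: per-element node values
#'   `gx`, `gy` (m x 6 matrices in the space's element order).
#' @export
recover_gradient <- function(field) {
  sp <- field$space
  mesh <- sp$mesh
  g <- space_geom(sp)
  mT <- nrow(sp$T6); nq <- length(g$w)
  cf <- matrix(field$coef[sp$T6], ncol = 6)
  # broken gradient at quadrature points
  bgx <- matrix(0, mT, nq); bgy <- matrix(0, mT, nq)
  for (i in 1:6) for (qi in seq_len(nq)) {
    bgx[, qi] <- bgx[, qi] + cf[, i] * g$gx[, qi, i]
    bgy[, qi] <- bgy[, qi] + cf[, i] * g$gy[, qi, i]
  }
  tri <- mesh$tri[sp$tris, , drop = FALSE]
  regs <- mesh$region[sp$tris]
  nvert <- nrow(mesh$nodes)
  # per (region, vertex) quadratic fits; store coefficient rows keyed by
  # region * (nvert+1) + vertex
  fits <- new.env(parent = emptyenv())
  for (r in sort(unique(regs))) {
    esel <- which(regs == r)
    verts <- sort(unique(as.vector(tri[esel, ])))
    # vertex -> incident elements (within region)
    inc <- split(rep(esel, 3L), as.vector(tri[esel, ]))
    for (v in verts) {
      el <- inc[[as.character(v)]]
      px <- as.vector(g$qx[el, , drop = FALSE])
      py <- as.vector(g$qy[el, , drop = FALSE])
      vx <- mesh$nodes[v, 1]; vy <- mesh$nodes[v, 2]
      sx <- max(abs(px - vx), 1e-300); sy <- max(abs(py - vy), 1e-300)
      X <- (px - vx) / sx; Y <- (py - vy) / sy
      A <- cbind(1, X, Y, X * X, X * Y, Y * Y)
      B <- cbind(as.vector(bgx[el, , drop = FALSE]),
                 as.vector(bgy[el, , drop = FALSE]))
      # quadrature-weighted fit (a local L2 projection): samples from
      # degenerate slivers carry negligible weight instead of poisoning
      # the patch polynomial
      wq <- sqrt(rep(g$detJ[el], length(g$w)) *
                   rep(g$w, each = length(el)))
      wq <- wq / max(wq)
      A <- A * wq
      B <- B * wq
      # ridge-regularized normal equations: anisotropic patches can make
      # the plain fit nearly rank deficient, which would inject spurious
      # derivative spikes into the estimate
      AtA <- crossprod(A)
      ridge <- 1e-10 * max(diag(AtA))
      co <- tryCatch(
        solve(AtA + diag(ridge, 6L), crossprod(A, B)),
        error = function(e) {
          qrL <- qr(A[, 1:3, drop = FALSE])
          rbind(qr.coef(qrL, B), matrix(0, 3, 2))
        })
      co[is.na(co)] <- 0
      fits[[paste0(r, ".", v)]] <- list(co = co, vx = vx, vy = vy,
                                        sx = sx, sy = sy)
    }
  }
  eval_fit <- function(f, x, y) {
    X <- (x - f$vx) / f$sx; Y <- (y - f$vy) / f$sy
    a <- c(1, X, Y, X * X, X * Y, Y * Y)
    as.numeric(a %*% f$co)
  }
  gx <- matrix(0, mT, 6); gy <- matrix(0, mT, 6)
  nodesx <- mesh$nodes[, 1]; nodesy <- mesh$nodes[, 2]
  for (e in seq_len(mT)) {
    r <- regs[e]
    vv <- tri[e, ]
    f1 <- fits[[paste0(r, ".", vv[1])]]
    f2 <- fits[[paste0(r, ".", vv[2])]]
    f3 <- fits[[paste0(r, ".", vv[3])]]
    fl <- list(f1, f2, f3)
    for (a in 1:3) {
      val <- eval_fit(fl[[a]], nodesx[vv[a]], nodesy[vv[a]])
      gx[e, a] <- val[1]; gy[e, a] <- val[2]
    }
    # midside dofs 4=(1,2), 5=(2,3), 6=(3,1): endpoint fits averaged at the
    # midpoint, with the deviation from the endpoint mean clamped to the
    # edge's own value variation -- an unbounded evaluation would
    # extrapolate a near-wall quadratic across a long graded edge and
    # inject spurious derivatives into large far-field elements
    pairs <- list(c(1, 2), c(2, 3), c(3, 1))
    for (a in 1:3) {
      p <- pairs[[a]]
      mx <- (nodesx[vv[p[1]]] + nodesx[vv[p[2]]]) / 2
      my <- (nodesy[vv[p[1]]] + nodesy[vv[p[2]]]) / 2
      v1 <- eval_fit(fl[[p[1]]], mx, my); v2 <- eval_fit(fl[[p[2]]], mx, my)
      for (comp in 1:2) {
        tgt <- if (comp == 1) gx else gy
        e1 <- tgt[e, p[1]]; e2 <- tgt[e, p[2]]
        mid <- (v1[comp] + v2[comp]) / 2
        lin <- (e1 + e2) / 2
        cap <- abs(e1 - e2)
        mid <- lin + max(-cap, min(cap, mid - lin))
        if (comp == 1) gx[e, 3 + a] <- mid else gy[e, 3 + a] <- mid
      }
    }
  }
  structure(list(gx = gx, gy = gy, tris = sp$tris, mesh = mesh),
            class = "recovered_gradient")
}

# second derivatives (constant per element) of a per-element P2 nodal field
p2_second_derivatives <- function(mesh, tris, vals) {
  tri <- mesh$tri[tris, , drop = FALSE]
  p1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tri[, 3], , drop = FALSE]
  x21 <- p2[, 1] - p1[, 1]; y21 <- p2[, 2] - p1[, 2]
  x31 <- p3[, 1] - p1[, 1]; y31 <- p3[, 2] - p1[, 2]
  detJ <- x21 * y31 - x31 * y21
  a11 <- y31 / detJ; a12 <- -x31 / detJ    # dxi/dx, dxi/dy
  a21 <- -y21 / detJ; a22 <- x21 / detJ    # deta/dx, deta/dy
  # ref second derivatives (per basis): u_xx = sum_i v_i * (J^-T H_ref J^-1)
  dxx <- 0; dxy <- 0; dyy <- 0
  for (i in 1:6) {
    hxx <- P2_D2REF[i, 1]; hxe <- P2_D2REF[i, 2]; hee <- P2_D2REF[i, 3]
    dxx <- dxx + vals[, i] *
      (hxx * a11 * a11 + 2 * hxe * a11 * a21 + hee * a21 * a21)
    dxy <- dxy + vals[, i] *
      (hxx * a11 * a12 + hxe * (a11 * a22 + a12 * a21) + hee * a21 * a22)
    dyy <- dyy + vals[, i] *
      (hxx * a12 * a12 + 2 * hxe * a12 * a22 + hee * a22 * a22)
  }
  cbind(dxx, dxy, dyy)
}

#' Hierarchical degree-3 correction from a recovered gradient
#'
#' On each element the cubic correction is pinned by matching its (constant)
#' third derivatives to the second derivatives of the recovered gradient.
#' The two cross conditions are over-determined (the mixed derivative is
#' reached from both components) and closed by least squares; all lower-order
#' content of the correction is set to zero about the element centroid.
#' Returns per-element third-derivative estimates and the L2 / H1-seminorm
#' of the correction computed by exact quadrature.
#'
#' @param field the P2 `discrete_field` the gradient was recovered from.
#' @param grad a `recovered_gradient` (defaults to `recover_gradient(field)`).
#' @return object of class `hierarchical_correction`: `der3` (m x 4 matrix
#'   of u_xxx, u_xxy, u_xyy, u_yyy), `l2sq`, `h1sq` (per-element squared
#'   norms), `tris` (element ids in the mesh).
#' @export
hierarchical_correction <- function(field, grad = recover_gradient(field)) {
  mesh <- grad$mesh
  d1 <- p2_second_derivatives(mesh, grad$tris, grad$gx)
  d2 <- p2_second_derivatives(mesh, grad$tris, grad$gy)
  der3 <- cbind(d1[, 1],                      # u_xxx
                (d1[, 2] + d2[, 1]) / 2,      # u_xxy
                (d1[, 3] + d2[, 2]) / 2,      # u_xyy
                d2[, 3])                      # u_yyy
  nn <- cubic_norms(mesh$nodes, mesh$tri[grad$tris, , drop = FALSE], der3)
  structure(list(der3 = der3, l2sq = nn$l2sq, h1sq = nn$h1sq,
                 tris = grad$tris),
            class = "hierarchical_correction")
}

# Squared L2 norm and H1 seminorm of the centred cubic correction
#   c(x) = a/6 X^3 + b/2 X^2 Y + c/2 X Y^2 + d/6 Y^3,  X,Y centred
# over each triangle (rows of `tri` into `nodes`), by a degree-7 rule.
# `der3` may stack several (scaled) fields as m x 4k; their squared norms
# add, so adaptation can be driven by the whole solution vector.
cubic_norms <- function(nodes, tri, der3) {
  if (nrow(tri) == 0) return(list(l2sq = numeric(0), h1sq = numeric(0)))
  q <- tri_quadrature(7)
  p1 <- nodes[tri[, 1], , drop = FALSE]
  p2 <- nodes[tri[, 2], , drop = FALSE]
  p3 <- nodes[tri[, 3], , drop = FALSE]
  x21 <- p2[, 1] - p1[, 1]; y21 <- p2[, 2] - p1[, 2]
  x31 <- p3[, 1] - p1[, 1]; y31 <- p3[, 2] - p1[, 2]
  detJ <- abs(x21 * y31 - x31 * y21)
  cx <- (p1[, 1] + p2[, 1] + p3[, 1]) / 3
  cy <- (p1[, 2] + p2[, 2] + p3[, 2]) / 3
  l2 <- 0; h1 <- 0
  for (blk in seq_len(ncol(der3) / 4L)) {
    a <- der3[, 4 * blk - 3]; b <- der3[, 4 * blk - 2]
    cc <- der3[, 4 * blk - 1]; d <- der3[, 4 * blk]
    for (qi in seq_along(q$w)) {
      X <- p1[, 1] + q$xi[qi] * x21 + q$eta[qi] * x31 - cx
      Y <- p1[, 2] + q$xi[qi] * y21 + q$eta[qi] * y31 - cy
      cval <- a / 6 * X^3 + b / 2 * X^2 * Y + cc / 2 * X * Y^2 + d / 6 * Y^3
      gxv <- a / 2 * X^2 + b * X * Y + cc / 2 * Y^2
      gyv <- b / 2 * X^2 + cc * X * Y + d / 2 * Y^2
      l2 <- l2 + q$w[qi] * cval^2
      h1 <- h1 + q$w[qi] * (gxv^2 + gyv^2)
    }
  }
  list(l2sq = l2 * detJ, h1sq = h1 * detJ)
}

#' Error targets for adaptation
#'
#' Distributes a global L2 error target over the elements proportionally to
#' their area: \eqn{e_\top^2 = e_\Omega^2\, meas(\top)/meas(\Omega)}; a patch
#' target is the same ratio with the patch measure.
#'
#' @param e_omega global L2 error target (potential units x area, mV um).
#' @param mesh a `pnp_mesh`.
#' @return list with `e_omega`, `area_total` and function
#'   `patch_target(area)`.
#' @export
error_targets <- function(e_omega, mesh) {
  stopifnot(e_omega > 0)
  A <- sum(mesh_areas(mesh))
  list(e_omega = e_omega, area_total = A,
       patch_target = function(area) e_omega^2 * area / A)
}
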