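# Coupled Poisson-Nernst-Planck solves: problem container, stationary Newton
# solve (time-derivative-free system with per-species mass constraints on
# closed regions), BDF2 time marching with a coupled Newton-Raphson iteration
# per step, and the iteration-count time-step controller.

#' Set up a PNP problem on a mesh
#'
#' Builds the P2 spaces (potential on the whole domain, concentrations on the
#' electrolyte only, implementing zero membrane concentration by exclusion),
#' assembles the iterate-independent blocks (mass, diffusion stiffness,
#' Faraday-scaled Poisson stiffness, charge matrices) and the initial fields
#' with per-region initial concentrations.
#'
#' @param mesh a `pnp_mesh`.
#' @param species data.frame as [default_species()].
#' @param constants list from [physical_constants()].
#' @param closed if `TRUE`, no Dirichlet condition is applied to the
#'   concentrations (fully closed electrolyte; the potential keeps its
#'   grounded outer boundary).  Used for conservation studies.
#' @return object of class `pnp_problem`.
#' @export
pnp_problem <- function(mesh, species = default_species(),
                        constants = physical_constants(), closed = FALSE) {
  st <- mesh_edges(mesh)
  Vh <- fe_space(mesh, "all", dirichlet_tags = "ext", struct = st)
  Ch <- fe_space(mesh, c("intra", "extra"),
                 dirichlet_tags = if (closed) character(0) else "ext",
                 struct = st)
  ns <- nrow(species)
  eps <- c(intra = eps_scaled(constants$eps_water, constants),
           membrane = eps_scaled(constants$eps_membrane, constants),
           extra = eps_scaled(constants$eps_water, constants))
  M <- assemble_mass(Ch)
  Dv <- assemble_stiffness(Vh, eps)
  Dk <- vector("list", ns); Sk <- vector("list", ns); dtil <- vector("list", ns)
  for (k in seq_len(ns)) {
    Dk[[k]] <- assemble_stiffness(Ch, c(intra = species$D[k],
                                        extra = species$D[k]))
    Sk[[k]] <- assemble_charge_matrix(Ch, Vh, species$z[k])
    mob <- drift_mobility(species$D[k], species$z[k], constants)
    dtil[[k]] <- c(intra = mob, extra = mob)
  }
  # region of each concentration dof (intra and extra never share dofs)
  dof_region <- integer(Ch$ndof)
  regs <- mesh$region[Ch$tris]
  for (r in c(REGION_INTRA, REGION_EXTRA)) {
    dofs <- unique(as.vector(Ch$T6[regs == r, ]))
    dof_region[dofs] <- r
  }
  # intracellular mass-constraint machinery (stationary solves)
  Mi <- assemble_mass(Ch, "intra")
  w_intra <- as.numeric(Mi %*% rep(1, Ch$ndof))
  area <- region_areas(mesh)
  c0 <- lapply(seq_len(ns), function(k) {
    v <- numeric(Ch$ndof)
    v[dof_region == REGION_INTRA] <- species$c0_in[k]
    v[dof_region == REGION_EXTRA] <- species$c0_out[k]
    v
  })
  free_c <- setdiff(seq_len(Ch$ndof), Ch$dirichlet)
  free_v <- setdiff(seq_len(Vh$ndof), Vh$dirichlet)
  structure(list(
    mesh = mesh, struct = st, species = species, constants = constants,
    closed = closed, Vh = Vh, Ch = Ch, ns = ns,
    M = M, Dv = Dv, Dk = Dk, Sk = Sk, dtilde = dtil,
    dof_region = dof_region, w_intra = w_intra,
    mass_intra0 = vapply(seq_len(ns),
                         function(k) species$c0_in[k] * area[["intra"]], 0),
    c0 = c0, free_c = free_c, free_v = free_v,
    scale_c = max(species$c0_in, species$c0_out), scale_v = 100
  ), class = "pnp_problem")
}

#' @export
print.pnp_problem <- function(x, ...) {
  cat(sprintf("<pnp_problem> %d species, %d c-dofs + %d V-dofs%s\n",
              x$ns, x$Ch$ndof, x$Vh$ndof,
              if (x$closed) " (closed)" else ""))
  invisible(x)
}

# Solve the linear Poisson equation for V given concentration fields.
solve_poisson <- function(problem, cfields) {
  rhs <- numeric(problem$Vh$ndof)
  for (k in seq_len(problem$ns))
    rhs <- rhs + as.numeric(problem$Sk[[k]] %*% cfields[[k]])
  V <- numeric(problem$Vh$ndof)
  fv <- problem$free_v
  V[fv] <- as.numeric(Matrix::solve(problem$Dv[fv, fv], -rhs[fv]))
  V
}

# Assemble coupling blocks for every species at the current iterate,
# sharing the potential-gradient evaluation.
coupling_all <- function(problem, cs, Vs) {
  lapply(seq_len(problem$ns), function(k)
    assemble_coupling(problem$Ch, problem$Vh, cs[[k]], Vs,
                      problem$dtilde[[k]]))
}

#' BDF2 finite-difference coefficients
#'
#' For the two-step scheme \eqn{\frac{3}{2}y_{r+1} = 2 y_r - \frac12 y_{r-1}
#' + \Delta t F(t_{r+1}, y_{r+1})}: \eqn{\alpha = 1/(2\Delta t)},
#' \eqn{\beta = -2/\Delta t}, \eqn{\gamma = 3/(2\Delta t)} so that the
#' discrete time derivative is \eqn{\gamma y_{r+1} + \beta y_r + \alpha
#' y_{r-1}}.  `order = 1` gives the backward-Euler startup coefficients
#' (0, -1/dt, 1/dt).
#'
#' @param dt time step, ms (> 0).
#' @param order 2 (BDF2) or 1 (backward Euler).
#' @return list with `alpha`, `beta`, `gamma` (ms^-1).
#' @export
#' @examples
#' unlist(bdf2_coefficients(0.1))   # (5, -20, 15)
bdf2_coefficients <- function(dt, order = 2) {
  if (!(dt > 0)) stop("dt must be > 0", call. = FALSE)
  if (order == 2) list(alpha = 1 / (2 * dt), beta = -2 / dt, gamma = 3 / (2 * dt))
  else list(alpha = 0, beta = -1 / dt, gamma = 1 / dt)
}

# Debye-screening mass matrix on the potential space: the linearized charge
# response int (sum_k z_k^2 c_k / V_T) phi_i phi_j over the electrolyte.
# In a transient step the ions only screen modes whose diffusive relaxation
# outruns the step (rate D k^2 against gamma = O(1/dt)); each element's
# contribution is damped by that factor at its own resolvable wavenumber.
screening_mass <- function(problem, cs, gamma = 0) {
  sp <- problem$Ch
  g <- space_geom(sp)
  vt <- thermal_voltage_mV(problem$constants)
  m <- nrow(sp$T6); nq <- length(g$w)
  wq <- matrix(0, m, nq)
  for (k in seq_len(problem$ns)) {
    cf <- matrix(cs[[k]][sp$T6], ncol = 6)
    wq <- wq + (problem$species$z[k]^2 / vt) * (cf %*% t(g$N))
  }
  wq <- pmax(wq, 0)
  if (gamma > 0) {
    tri <- sp$mesh$tri[sp$tris, , drop = FALSE]
    l2max <- pmax(
      rowSums((sp$mesh$nodes[tri[, 2], , drop = FALSE] -
                 sp$mesh$nodes[tri[, 1], , drop = FALSE])^2),
      rowSums((sp$mesh$nodes[tri[, 3], , drop = FALSE] -
                 sp$mesh$nodes[tri[, 2], , drop = FALSE])^2),
      rowSums((sp$mesh$nodes[tri[, 1], , drop = FALSE] -
                 sp$mesh$nodes[tri[, 3], , drop = FALSE])^2))
    hmin <- abs(g$detJ) / sqrt(l2max)          # short dimension
    Dbar <- mean(problem$species$D)
    rate <- Dbar * (pi / pmax(hmin, 1e-12))^2
    wq <- wq * (rate / (gamma + rate))
  }
  Tv <- map_tris(problem$Vh, sp$tris)
  ii <- integer(36L * m); jj <- integer(36L * m); vv <- numeric(36L * m)
  kk <- 0L
  for (i in 1:6) for (j in 1:6) {
    s <- 0
    for (qi in seq_len(nq))
      s <- s + g$w[qi] * g$N[qi, i] * g$N[qi, j] * wq[, qi]
    idx <- kk + seq_len(m)
    ii[idx] <- Tv[, i]; jj[idx] <- Tv[, j]; vv[idx] <- s * g$detJ
    kk <- kk + m
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                       dims = c(problem$Vh$ndof, problem$Vh$ndof))
}

# Solve the coupled linearized block system exactly; returns corrections.
#
# The system  [A B; S Dv] [dc; dv] = -[rc; rv]  (A = blockdiag over species
# of gamma*M + D_k + Dcc_k, B = Dcv blocks, S = charge blocks) is solved by
# right-preconditioned GMRES with the block-triangular preconditioner
# P = [A 0; S Dv + W], W the Debye-screening mass, iterated to 1e-13
# relative true residual (direct-solve accuracy).  A_k uses a sparse LU,
# the screened Poisson block a CHOLMOD Cholesky.
#
# residuals: list rc (per species, full length) and rv (full length);
# couplings from coupling_all(); gamma = time coefficient (0 stationary);
# constrain = integer row (c-dof) per species for mass-constraint row
# replacement (NA = none); cs = current concentration iterate (screening).
solve_block_system <- function(problem, couplings, rc, rv, gamma,
                               constrain = NULL, cs = NULL,
                               lintol = 1e-12) {
  fc <- problem$free_c; fv <- problem$free_v
  ns <- problem$ns
  nc <- length(fc); nv <- length(fv)
  Ak <- vector("list", ns); Bk <- vector("list", ns); Sf <- vector("list", ns)
  solveA <- vector("list", ns); crow_l <- rep(NA_integer_, ns)
  wfree <- problem$w_intra[fc]
  for (k in seq_len(ns)) {
    A <- problem$Dk[[k]] + couplings[[k]]$Dcc
    if (gamma != 0) A <- A + gamma * problem$M
    Akk <- methods::as(A[fc, fc, drop = FALSE], "CsparseMatrix")
    Bkk <- couplings[[k]]$Dcv[fc, fv, drop = FALSE]
    Ak[[k]] <- Akk
    Bk[[k]] <- Bkk
    Sf[[k]] <- problem$Sk[[k]][fv, fc, drop = FALSE]
    if (!is.null(constrain) && !is.na(constrain[k])) {
      # The closed-region stationary block is singular (rank deficiency 1);
      # the redundant row `row` is replaced by the dense mass-constraint row
      # w.  Factoring that dense row directly destroys sparsity, so the LU
      # is done on a sparsely regularized matrix (diagonal bump at the row)
      # and the replaced-row system is recovered by a Sherman-Morrison
      # rank-one update.
      row <- match(constrain[k], fc)
      crow_l[k] <- row
      s <- mean(abs(Matrix::diag(Akk)))
      Areg <- Akk + Matrix::sparseMatrix(i = row, j = row, x = s,
                                         dims = c(nc, nc))
      luA <- tryCatch(Matrix::lu(Areg, order = 3L),
                      error = function(e)
                        stop(sprintf("singular species block %d (%s)",
                                     k, e$message), call. = FALSE))
      v <- wfree - as.numeric(Areg[row, ])
      er <- numeric(nc); er[row] <- 1
      q <- as.numeric(Matrix::solve(luA, er))
      denom <- 1 + sum(v * q)
      need_refine <- local({
        b <- sin(seq_len(nc))
        y <- as.numeric(Matrix::solve(luA, b))
        max(abs(as.numeric(Areg %*% y) - b)) > 1e-9 * max(abs(b))
      })
      solveA[[k]] <- local({
        luA0 <- luA; q0 <- q; v0 <- v; d0 <- denom; A0 <- Areg
        ref <- need_refine
        function(b) {
          y <- as.numeric(Matrix::solve(luA0, b))
          if (ref)  # iterative refinement for badly conditioned anisotropy
            y <- y + as.numeric(Matrix::solve(luA0, b - as.numeric(A0 %*% y)))
          y - q0 * (sum(v0 * y) / d0)
        }
      })
    } else {
      luA <- tryCatch(Matrix::lu(Akk, order = 3L),
                      error = function(e)
                        stop(sprintf("singular species block %d (%s)",
                                     k, e$message), call. = FALSE))
      need_refine <- local({
        b <- sin(seq_len(nc))
        y <- as.numeric(Matrix::solve(luA, b))
        max(abs(as.numeric(Akk %*% y) - b)) > 1e-9 * max(abs(b))
      })
      solveA[[k]] <- local({
        luA0 <- luA; A0 <- Akk; ref <- need_refine
        function(b) {
          y <- as.numeric(Matrix::solve(luA0, b))
          if (ref)
            y <- y + as.numeric(Matrix::solve(luA0, b - as.numeric(A0 %*% y)))
          y
        }
      })
    }
  }
  # two preconditioning regimes for the screened Poisson block: at very
  # small steps (gamma large) the ionic response is diffusion limited and a
  # stiffness-like term dominates the Schur complement; at moderate steps
  # the (step-damped) Boltzmann screening mass is the better model
  use_kappa <- gamma > 5e3
  W <- screening_mass(problem, if (is.null(cs)) problem$c0 else cs,
                      gamma = gamma)
  Dvf <- problem$Dv[fv, fv, drop = FALSE]
  Phat <- Dvf + W[fv, fv, drop = FALSE]
  if (use_kappa) {
    # in a finite step the ionic response to a potential perturbation is
    # diffusion limited; the Schur complement then carries a stiffness-like
    # term kappa * grad^2 with kappa = sum_k z_k^2 D_k c_k / (V_T * gamma)
    css <- if (is.null(cs)) problem$c0 else cs
    vt <- thermal_voltage_mV(problem$constants)
    kap_c <- numeric(length(problem$Ch$tris))
    for (k in seq_len(ns)) {
      ce <- rowMeans(matrix(css[[k]][problem$Ch$T6], ncol = 6))
      kap_c <- kap_c + problem$species$z[k]^2 * problem$species$D[k] *
        pmax(ce, 0) / (vt * gamma)
    }
    kap_v <- numeric(nrow(problem$mesh$tri))
    kap_v[problem$Ch$tris] <- kap_c
    Kd <- assemble_stiffness(problem$Vh, kap_v)
    Phat <- Phat + Kd[fv, fv, drop = FALSE]
  }
  Phat <- Matrix::forceSymmetric(Phat)
  cholV <- tryCatch(Matrix::Cholesky(Phat, LDL = FALSE, super = TRUE),
                    error = function(e) NULL)
  if (is.null(cholV)) {
    # fall back to a ridge-stabilized factorization
    ridge <- 1e-10 * mean(abs(Matrix::diag(Phat)))
    cholV <- Matrix::Cholesky(Phat + ridge * Matrix::Diagonal(nv),
                              LDL = FALSE, super = TRUE)
  }
  R <- c(unlist(lapply(seq_len(ns), function(k) rc[[k]][fc])), rv[fv])
  # balance the residual norm across row blocks
  rsc <- c(rep(1, ns * nc),
           rep(1 / max(Matrix::diag(Phat)), nv))
  applyJ <- function(x) {
    xv <- x[ns * nc + seq_len(nv)]
    out <- numeric(ns * nc + nv)
    acc <- numeric(nv)
    for (k in seq_len(ns)) {
      xc <- x[(k - 1L) * nc + seq_len(nc)]
      yk <- as.numeric(Ak[[k]] %*% xc) + as.numeric(Bk[[k]] %*% xv)
      if (!is.na(crow_l[k])) yk[crow_l[k]] <- sum(wfree * xc)
      out[(k - 1L) * nc + seq_len(nc)] <- yk
      acc <- acc + as.numeric(Sf[[k]] %*% xc)
    }
    out[ns * nc + seq_len(nv)] <- acc + as.numeric(Dvf %*% xv)
    out
  }
  applyP <- function(r) {
    # block LDU solve with approximate Schur complement Dv + W:
    # forward species solves, screened-Poisson solve, back-substitution
    z <- numeric(ns * nc + nv)
    yc <- vector("list", ns)
    acc <- numeric(nv)
    for (k in seq_len(ns)) {
      yc[[k]] <- solveA[[k]](r[(k - 1L) * nc + seq_len(nc)])
      acc <- acc + as.numeric(Sf[[k]] %*% yc[[k]])
    }
    zv <- as.numeric(Matrix::solve(cholV, r[ns * nc + seq_len(nv)] - acc,
                                   system = "A"))
    for (k in seq_len(ns)) {
      t <- as.numeric(Bk[[k]] %*% zv)
      if (!is.na(crow_l[k])) t[crow_l[k]] <- 0
      z[(k - 1L) * nc + seq_len(nc)] <- yc[[k]] - solveA[[k]](t)
    }
    z[ns * nc + seq_len(nv)] <- zv
    z
  }
  nunk <- ns * nc + nv
  delta <- gmres_right(applyJ, applyP, -R, rowscale = rsc,
                       tol = lintol,
                       restart = as.integer(min(250L, nunk)),
                       max_restart = 2L)
  dc <- vector("list", ns)
  for (k in seq_len(ns))
    dc[[k]] <- delta[(k - 1L) * nc + seq_len(nc)]
  list(dc = dc, dv = delta[ns * nc + seq_len(nv)])
}

# Right-preconditioned restarted GMRES: solves A x = b with x = P(u);
# residuals are true residuals of the row-scaled system.
gmres_right <- function(applyA, applyP, b, rowscale = 1, tol = 1e-13,
                        restart = 60L, max_restart = 4L) {
  n <- length(b)
  x <- numeric(n)
  bs <- b * rowscale
  bnorm <- sqrt(sum(bs^2))
  if (bnorm == 0) return(x)
  beta_prev <- Inf
  for (outer in seq_len(max_restart)) {
    r <- (b - applyA(x)) * rowscale
    beta <- sqrt(sum(r^2))
    if (beta / bnorm <= tol) return(x)
    # a restart that no longer gains a decade has hit the accuracy floor
    if (beta > 0.1 * beta_prev) break
    beta_prev <- beta
    m <- restart
    V <- matrix(0, n, m + 1L)
    H <- matrix(0, m + 1L, m)
    cs_g <- numeric(m); sn_g <- numeric(m); g <- numeric(m + 1L)
    V[, 1] <- r / beta
    g[1] <- beta
    j_used <- 0L
    for (j in seq_len(m)) {
      w <- applyA(applyP(V[, j] / rowscale)) * rowscale
      # classical Gram-Schmidt with one reorthogonalization (BLAS-friendly)
      Vj <- V[, seq_len(j), drop = FALSE]
      h <- as.numeric(crossprod(Vj, w))
      w <- w - as.numeric(Vj %*% h)
      h2 <- as.numeric(crossprod(Vj, w))
      w <- w - as.numeric(Vj %*% h2)
      H[seq_len(j), j] <- h + h2
      H[j + 1L, j] <- sqrt(sum(w^2))
      if (H[j + 1L, j] > 0) V[, j + 1L] <- w / H[j + 1L, j]
      # Givens rotations
      for (i in seq_len(j - 1L)) {
        t <- cs_g[i] * H[i, j] + sn_g[i] * H[i + 1L, j]
        H[i + 1L, j] <- -sn_g[i] * H[i, j] + cs_g[i] * H[i + 1L, j]
        H[i, j] <- t
      }
      d <- sqrt(H[j, j]^2 + H[j + 1L, j]^2)
      cs_g[j] <- H[j, j] / d; sn_g[j] <- H[j + 1L, j] / d
      H[j, j] <- d; H[j + 1L, j] <- 0
      g[j + 1L] <- -sn_g[j] * g[j]
      g[j] <- cs_g[j] * g[j]
      j_used <- j
      if (abs(g[j + 1L]) / bnorm <= tol) break
    }
    y <- backsolve(H[seq_len(j_used), seq_len(j_used), drop = FALSE],
                   g[seq_len(j_used)])
    u <- V[, seq_len(j_used), drop = FALSE] %*% y
    x <- x + applyP(as.numeric(u) / rowscale)
    if (abs(g[j_used + 1L]) / bnorm <= tol) {
      rfin <- sqrt(sum(((b - applyA(x)) * rowscale)^2))
      if (rfin / bnorm <= 10 * tol) return(x)
    }
  }
  rfin <- sqrt(sum(((b - applyA(x)) * rowscale)^2)) / bnorm
  if (rfin > max(1e-8, 100 * tol))
    warning(sprintf("linear solve: GMRES stalled at relative residual %.2e",
                    rfin), call. = FALSE)
  x
}

# stationary residuals at iterate (cs, Vs): rc_k = (Dk + Dcc_k) c_k (+ load),
# with the constrained row carrying the mass defect; rv = sum S c + Dv V.
stationary_residual <- function(problem, couplings, cs, Vs, loads,
                                constrain) {
  ns <- problem$ns
  rc <- vector("list", ns)
  for (k in seq_len(ns)) {
    r <- as.numeric((problem$Dk[[k]] + couplings[[k]]$Dcc) %*% cs[[k]])
    if (!is.null(loads[[k]])) r <- r - loads[[k]]
    if (!is.na(constrain[k]))
      r[constrain[k]] <- sum(problem$w_intra * cs[[k]]) -
        problem$mass_intra0[k]
    rc[[k]] <- r
  }
  rv <- as.numeric(problem$Dv %*% Vs)
  for (k in seq_len(ns)) rv <- rv + as.numeric(problem$Sk[[k]] %*% cs[[k]])
  list(rc = rc, rv = rv)
}

resid_norm <- function(problem, res) {
  m <- max(vapply(seq_len(problem$ns),
                  function(k) max(abs(res$rc[[k]][problem$free_c])), 0))
  max(m, max(abs(res$rv[problem$free_v])))
}

#' Solve the stationary PNP system
#'
#' Newton-Raphson on the time-derivative-free coupled block system.  The
#' closed intracellular region makes the stationary species operators rank
#' deficient by one; the redundant equation is replaced by the species mass
#' constraint \eqn{\int_{intra} c_k = c_k^0 |\Omega_{intra}|}, which is what
#' time marching from the initial condition conserves.
#'
#' @param problem a [pnp_problem()].
#' @param tol relative Newton tolerance on the correction norms (concentration
#'   scaled by the largest initial concentration, potential by 100 mV).
#' @param max_iter maximum Newton iterations.
#' @param init optional list(c, V) initial iterate (full coefficient vectors).
#' @param loads optional per-species boundary load vectors.
#' @param verbose print per-iteration norms.
#' @return list with `c` (list of species coefficient vectors), `V`,
#'   `iterations`, `converged`.
#' @export
solve_stationary <- function(problem, tol = 1e-11, max_iter = 12,
                             init = NULL, loads = NULL, verbose = FALSE,
                             ramp = FALSE) {
  ns <- problem$ns
  if (is.null(loads)) loads <- vector("list", ns)
  if (ramp) {
    # pseudo-transient continuation: backward-Euler steps with a growing
    # step length carry the iterate into the basin of the stationary Newton
    # solve (each implicit step is strongly diagonally dominant and safe)
    cs0 <- if (is.null(init)) lapply(problem$c0, identity) else init$c
    state <- structure(list(c = cs0, c_prev = NULL,
                            V = if (is.null(init)) solve_poisson(problem, cs0)
                            else init$V,
                            t = 0, dt_prev = NA_real_, order = 1L),
                       class = "pnp_state")
    dt <- if (is.null(init)) 4e-3 else 0.02
    for (ps in seq_len(14)) {
      state$c_prev <- NULL          # force backward Euler
      st2 <- tryCatch(advance_time_step(problem, state, dt,
                                        loads = loads,
                                        settings = newton_settings(
                                          tol = 1e-8, max_iter = 6)),
                      error = function(e) NULL)
      if (is.null(st2)) { dt <- dt / 8; next }
      rate <- max(vapply(seq_len(ns), function(k)
        max(abs(st2$c[[k]] - state$c[[k]])), 0)) / (dt * problem$scale_c)
      state <- st2
      if (verbose)
        message(sprintf("  ramp %2d: dt = %.2e, rate = %.3e", ps, dt, rate))
      if (rate < 3e-10 || dt >= 1e4) break
      dt <- min(dt * 10, 1e4)
    }
    init <- list(c = state$c, V = state$V)
  }
  # constrained row per species: the intra dof with the largest mass weight
  intra_dofs <- which(problem$dof_region == REGION_INTRA)
  crow <- intra_dofs[which.max(problem$w_intra[intra_dofs])]
  constrain <- rep(crow, ns)
  if (problem$closed) {
    # extracellular component is closed too: constrain it as well?  The
    # stationary solve is not used for closed problems; guard explicitly.
    stop("stationary solve requires the Dirichlet (open) configuration",
         call. = FALSE)
  }
  cs <- if (is.null(init)) lapply(problem$c0, identity) else init$c
  Vs <- if (is.null(init)) solve_poisson(problem, cs) else init$V
  conv <- FALSE; it <- 0; stag <- 0L
  cp <- coupling_all(problem, cs, Vs)
  res <- stationary_residual(problem, cp, cs, Vs, loads, constrain)
  r_first <- resid_norm(problem, res)
  for (it in seq_len(max_iter)) {
    r0 <- resid_norm(problem, res)
    # inexact Newton: solve loosely while far from the root, tightly near it
    lintol <- max(1e-13, min(1e-5, 1e-3 * r0 / max(r_first, 1e-300)))
    sol <- solve_block_system(problem, cp, res$rc, res$rv, gamma = 0,
                              constrain = constrain, cs = cs,
                              lintol = lintol)
    # damped update; the trial couplings/residual are reused next iteration
    step <- 1
    accepted <- FALSE
    for (half in 0:10) {
      cn <- lapply(seq_len(ns), function(k) {
        v <- cs[[k]]; v[problem$free_c] <- v[problem$free_c] +
          step * sol$dc[[k]]; v })
      Vn <- Vs; Vn[problem$free_v] <- Vn[problem$free_v] + step * sol$dv
      cpn <- coupling_all(problem, cn, Vn)
      resn <- stationary_residual(problem, cpn, cn, Vn, loads, constrain)
      rn <- resid_norm(problem, resn)
      if (rn <= r0 * (1 - 1e-4 * step) || rn < 1e-14 ||
            (rn <= 1.001 * r0 && half >= 6)) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) {
      # no descent available: at a residual already far below the assembly
      # scale this is the attainable fixed point, not a failure
      conv <- r0 < 1e-3
      break
    }
    cs <- cn; Vs <- Vn; cp <- cpn; res <- resn
    dnorm <- max(max(vapply(sol$dc, function(d) max(abs(d)), 0)) /
                   problem$scale_c,
                 max(abs(sol$dv)) / problem$scale_v) * step
    if (verbose)
      message(sprintf("  newton %2d: |delta| = %.3e, |res| = %.3e -> %.3e",
                      it, dnorm, r0, rn))
    if (dnorm < tol) { conv <- TRUE; break }
    # on badly conditioned (strongly anisotropic) meshes the correction norm
    # floors at the linear-solver accuracy; a deep residual reduction (or an
    # absolute residual far below the assembly scale of these units) is then
    # the meaningful convergence signal
    if (rn < 1e-9 * max(r_first, 1) || rn < 1e-7) { conv <- TRUE; break }
    if (dnorm < 1e6 * tol && rn > 0.5 * r0) {
      stag <- stag + 1L
      if (stag >= 2L) { conv <- TRUE; break }
    } else stag <- 0L
  }
  list(c = cs, V = Vs, iterations = it, converged = conv)
}

#' One coupled Newton correction
#'
#' Assembles the coupling blocks at the supplied iterate and solves the full
#' linearized block system (all species plus potential simultaneously),
#' returning the corrections without applying any damping.  `gamma` is the
#' BDF time coefficient (0 for the stationary system); `rc`/`rv` the residual
#' vectors at the iterate.
#'
#' @param problem a [pnp_problem()].
#' @param cs,Vs current iterate (list of species vectors; potential vector).
#' @param rc,rv residuals at the iterate (full-length vectors).
#' @param gamma time coefficient multiplying the mass matrix.
#' @return list `dc` (per species, on free dofs), `dv` (free potential dofs).
#' @export
newton_step <- function(problem, cs, Vs, rc, rv, gamma = 0) {
  cp <- coupling_all(problem, cs, Vs)
  solve_block_system(problem, cp, rc, rv, gamma, cs = cs)
}

#' Three-branch time-step controller
#'
#' \deqn{\Delta t_r = (1+f_{min})\Delta t_{r-1} \ (N_{it} < N_{min});\quad
#' \Delta t_{r-1} \ (N_{min} \le N_{it} \le N_{max});\quad
#' (1-f_{max})\Delta t_{r-1} \ (N_{it} > N_{max})}
#' clamped to `[dt_min, dt_max]`.
#'
#' @param n_it Newton iteration count of the last step.
#' @param dt_prev previous step, ms.
#' @param controller list with `n_min`, `n_max`, `f_min`, `f_max`,
#'   `dt_min`, `dt_max` (see [time_controller()]).
#' @return next time step, ms.
#' @export
#' @examples
#' adapt_dt(2, 0.01, time_controller())   # grows by f_min
adapt_dt <- function(n_it, dt_prev, controller = time_controller()) {
  if (!(dt_prev > 0)) stop("dt_prev must be > 0", call. = FALSE)
  dt <- if (n_it < controller$n_min) (1 + controller$f_min) * dt_prev
  else if (n_it > controller$n_max) (1 - controller$f_max) * dt_prev
  else dt_prev
  min(max(dt, controller$dt_min), controller$dt_max)
}

#' Time-step controller settings
#'
#' Iteration-count targets and relative step changes for [adapt_dt()], plus
#' the step bounds.  Defaults: target 3..6 Newton iterations, 20% step
#' changes, steps in [1e-6, 0.05] ms starting from 1e-4 ms.
#'
#' @param n_min,n_max target Newton-iteration range.
#' @param f_min,f_max relative step increase/decrease (in (0,1)).
#' @param dt0,dt_min,dt_max initial and bounding steps, ms.
#' @return list of settings.
#' @export
time_controller <- function(n_min = 3, n_max = 6, f_min = 0.2, f_max = 0.2,
                            dt0 = 1e-4, dt_min = 1e-6, dt_max = 0.05) {
  stopifnot(n_min <= n_max, f_min > 0, f_min < 1, f_max > 0, f_max < 1)
  list(n_min = n_min, n_max = n_max, f_min = f_min, f_max = f_max,
       dt0 = dt0, dt_min = dt_min, dt_max = dt_max)
}

#' Newton solver settings for the transient steps
#' @param tol relative correction tolerance.
#' @param max_iter maximum iterations per time step.
#' @return list of settings.
#' @export
newton_settings <- function(tol = 1e-9, max_iter = 12) {
  stopifnot(tol > 0, max_iter >= 1)
  list(tol = tol, max_iter = max_iter)
}

#' Initial PNP state
#'
#' Uniform per-region concentrations with the consistent Poisson potential.
#'
#' @param problem a [pnp_problem()].
#' @return object of class `pnp_state` with fields `c`, `c_prev`, `V`,
#'   `t`, `dt_prev`, `order`.
#' @export
pnp_initial_state <- function(problem) {
  cs <- lapply(problem$c0, identity)
  structure(list(c = cs, c_prev = NULL, V = solve_poisson(problem, cs),
                 t = 0, dt_prev = NA_real_, order = 1L),
            class = "pnp_state")
}

#' Advance the PNP system by one implicit time step
#'
#' BDF2 step (backward-Euler on the first step, where no second history
#' level exists) solved by the coupled Newton-Raphson iteration.  If Newton
#' fails to converge, or any concentration becomes negative, the step is
#' rejected and retried with half the step (up to 5 rejections).
#'
#' @param problem a [pnp_problem()].
#' @param state a `pnp_state`.
#' @param dt requested time step, ms.
#' @param loads optional per-species boundary load vectors (transmembrane
#'   fluxes assembled with [assemble_boundary_load()]).
#' @param settings [newton_settings()].
#' @return new `pnp_state` with attributes `n_iter` (Newton iterations of
#'   the accepted step) and `dt_used`.
#' @export
advance_time_step <- function(problem, state, dt, loads = NULL,
                              settings = newton_settings()) {
  ns <- problem$ns
  if (is.null(loads)) loads <- vector("list", ns)
  for (rejection in 0:5) {
    order <- if (is.null(state$c_prev)) 1L else 2L
    co <- bdf2_coefficients(dt, order)
    # BDF2 with variable step uses the constant-step formula; the controller
    # changes dt by at most 20% per step, keeping the scheme second order.
    ctil <- lapply(seq_len(ns), function(k)
      co$beta * state$c[[k]] +
        (if (order == 2L) co$alpha * state$c_prev[[k]] else 0))
    cs <- lapply(state$c, identity)
    Vs <- state$V
    conv <- FALSE
    for (it in seq_len(settings$max_iter)) {
      cp <- coupling_all(problem, cs, Vs)
      rc <- vector("list", ns)
      for (k in seq_len(ns)) {
        r <- as.numeric((problem$Dk[[k]] + cp[[k]]$Dcc) %*% cs[[k]]) +
          co$gamma * as.numeric(problem$M %*% cs[[k]]) +
          as.numeric(problem$M %*% ctil[[k]])
        if (!is.null(loads[[k]])) r <- r - loads[[k]]
        rc[[k]] <- r
      }
      rv <- as.numeric(problem$Dv %*% Vs)
      for (k in seq_len(ns)) rv <- rv + as.numeric(problem$Sk[[k]] %*% cs[[k]])
      sol <- solve_block_system(problem, cp, rc, rv, gamma = co$gamma,
                                cs = cs)
      for (k in seq_len(ns))
        cs[[k]][problem$free_c] <- cs[[k]][problem$free_c] + sol$dc[[k]]
      Vs[problem$free_v] <- Vs[problem$free_v] + sol$dv
      dnorm <- max(max(vapply(sol$dc, function(d) max(abs(d)), 0)) /
                     problem$scale_c,
                   max(abs(sol$dv)) / problem$scale_v)
      if (dnorm < settings$tol) { conv <- TRUE; break }
    }
    neg <- any(vapply(cs, function(v) any(v < 0), TRUE))
    if (conv && !neg) {
      out <- structure(list(c = cs, c_prev = state$c, V = Vs,
                            t = state$t + dt, dt_prev = dt, order = order),
                       class = "pnp_state")
      attr(out, "n_iter") <- it
      attr(out, "dt_used") <- dt
      return(out)
    }
    dt <- dt / 2   # step rejected: halve and retry
  }
  stop(sprintf("time step rejected 5 times (t = %g ms)", state$t),
       call. = FALSE)
}

#' Total moles of each species in the electrolyte
#' @param problem a [pnp_problem()].
#' @param cs list of species coefficient vectors.
#' @return numeric vector (mM um^2 per unit depth).
#' @export
species_totals <- function(problem, cs) {
  vapply(cs, function(v) sum(as.numeric(problem$M %*% v)), 0)
}
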