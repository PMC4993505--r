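# Independent numerical oracles used across the tests.

# Gauss-Legendre nodes/weights on [0,1] via the Golub-Welsch eigenproblem
# (no dependency on the package's quadrature code).
gauss_legendre_01 <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- (e$values + 1) / 2
  w <- (2 * e$vectors[1, ]^2) / 2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

# Dense integration over the unit reference triangle {xi,eta>=0, xi+eta<=1}
# by the Duffy transform and a tensor Gauss rule; near machine precision for
# smooth integrands.
ref_triangle_integral <- function(f, n = 24) {
  q <- gauss_legendre_01(n)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- q$x[i]; v <- q$x[j]
    s <- s + q$w[i] * q$w[j] * u * f(u * (1 - v), u * v)
  }
  s
}

# Integral over an arbitrary triangle given by a 3x2 coordinate matrix.
triangle_integral <- function(f, P, n = 24) {
  J <- rbind(P[2, ] - P[1, ], P[3, ] - P[1, ])
  detJ <- abs(J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
  ref_triangle_integral(function(xi, eta) {
    x <- P[1, 1] + xi * J[1, 1] + eta * J[2, 1]
    y <- P[1, 2] + xi * J[1, 2] + eta * J[2, 2]
    f(x, y)
  }, n) * detJ
}

# P2 basis on the reference triangle (duplicated on purpose: the oracle must
# not share code with the implementation under test).
oracle_p2 <- function(xi, eta) {
  l1 <- 1 - xi - eta
  c(l1 * (2 * l1 - 1), xi * (2 * xi - 1), eta * (2 * eta - 1),
    4 * l1 * xi, 4 * xi * eta, 4 * eta * l1)
}

# 1D Gauss's-law oracle for the slab membrane potential: integrate the
# half-domain field from the symmetry plane with a uniform intracellular
# charge density, piecewise permittivity, V(y3) = 0.
slab_vmem_oracle_1d <- function(geom, species, constants, n = 20000) {
  qnet <- sum(species$z * species$c0_in)                      # mM
  epsw <- eps_scaled(constants$eps_water, constants)
  epsm <- eps_scaled(constants$eps_membrane, constants)
  y <- seq(0, geom$y3, length.out = n)
  dy <- y[2] - y[1]
  rho <- ifelse(y < geom$y1, qnet, 0)
  eps <- ifelse(y < geom$y1 | y > geom$y2, epsw, epsm)
  flux <- cumsum(rho) * dy                 # eps * E at height y
  E <- flux / eps
  V <- rev(cumsum(rev(E))) * dy            # V(y) = int_y^y3 E
  Vat <- function(yy) stats::approx(y, V, yy)$y
  Vat(geom$y1) - Vat(geom$y2)
}
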