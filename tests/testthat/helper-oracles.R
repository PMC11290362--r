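# Independent oracles used across the suite.  These never share code with
# the implementation paths they check.

# Brute-force Gauss-integral writhe of a segment pair by 2D Gauss-Legendre
# quadrature (pracma nodes); the production path uses the closed-form
# solid-angle formula instead.
quadrature_pair_writhe <- function(p1, p2, p3, p4, ngl = 24L, panels = 6L) {
  # composite rule: the integrand is near-singular when the segments come
  # close, so each segment is split into panels with a Gauss rule per panel
  brk <- seq(0, 1, length.out = panels + 1L)
  nodes <- numeric(0); wts <- numeric(0)
  for (k in seq_len(panels)) {
    gl <- pracma::gaussLegendre(ngl, brk[k], brk[k + 1L])
    nodes <- c(nodes, gl$x); wts <- c(wts, gl$w)
  }
  e1 <- p2 - p1
  e2 <- p4 - p3
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  np <- length(nodes)
  tot <- 0
  for (i in seq_len(np)) {
    r1 <- p1 + nodes[i] * e1
    d <- matrix(r1, np, 3, byrow = TRUE) -
      (matrix(p3, np, 3, byrow = TRUE) + outer(nodes, e2))
    tot <- tot + wts[i] * sum(wts * (d %*% cr) / rowSums(d * d)^1.5)
  }
  tot / (4 * pi)
}

# Polygonal writhe by the quadrature oracle (non-adjacent pairs, doubled).
quadrature_polygon_writhe <- function(v) {
  ne <- nrow(v) - 1L
  tot <- 0
  for (i in seq_len(ne - 2L)) {
    for (j in (i + 2L):ne) {
      tot <- tot + quadrature_pair_writhe(v[i, ], v[i + 1L, ],
                                          v[j, ], v[j + 1L, ])
    }
  }
  2 * tot
}

# Analytic derivatives of the circular helix
# (a cos wt, a sin wt, rise t) with respect to t.
helix_analytic_derivs <- function(t, a, rise, omega, order) {
  switch(order,
         `1` = c(-a * omega * sin(omega * t), a * omega * cos(omega * t),
                 rise),
         `2` = c(-a * omega^2 * cos(omega * t), -a * omega^2 * sin(omega * t),
                 0),
         `3` = c(a * omega^3 * sin(omega * t), -a * omega^3 * cos(omega * t),
                 0))
}

# Frenet curvature/torsion directly from analytic derivative vectors
# (symbolic evaluation of the defining formulas, independent of splines).
frenet_from_derivs <- function(d1, d2, d3) {
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  list(kappa = sqrt(sum(cr^2)) / sum(d1^2)^1.5,
       tau = sum(cr * d3) / sum(cr^2))
}

# Random rigid motion (uniform rotation via QR of Gaussian matrix + shift).
random_rigid_motion <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, b = stats::rnorm(3, sd = 20))
}

apply_motion <- function(coords, mot) {
  sweep(coords %*% t(mot$R), 2L, mot$b, "+")
}
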