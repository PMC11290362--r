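#' Curvature and torsion at a point of a backbone curve
#'
#' Computes the Frenet curvature and torsion of the parametric curve at
#' parameter `t` from Chebyshev-smoothed derivatives:
#' \deqn{\kappa = \frac{|\dot r \times \ddot r|}{|\dot r|^3}, \qquad
#'       \tau = \frac{(\dot r \times \ddot r)\cdot \dddot r}
#'                   {|\dot r \times \ddot r|^2}.}
#' Both are invariant under rigid motions and under reparameterization of
#' the same curve; curvature is a non-negative magnitude (units 1/Angstrom)
#' while torsion is signed and changes sign under mirror reflection.
#'
#' Where the curve is locally straight the torsion quotient is numerically
#' meaningless: when \eqn{|\dot r \times \ddot r|^2} falls below `cross_tol`
#' the torsion is flagged undefined (`NA`) instead of being returned as a
#' huge unstable number.  Residues whose clipped derivative window is
#' shorter than `min_window` (see [chebyshev_derivatives()]) have both
#' descriptors flagged undefined.
#'
#' @inheritParams chebyshev_derivatives
#' @param cross_tol tolerance on \eqn{|\dot r \times \ddot r|^2} below which
#'   torsion is undefined; default 1e-12.
#' @param speed_tol tolerance on \eqn{|\dot r|} below which the
#'   parameterization is degenerate and an error is thrown.
#' @return list with elements `kappa` (>= 0, or `NA` if undefined), `tau`
#'   (signed, or `NA` if undefined), `kappa_defined`, `tau_defined`.
#' @examples
#' hel <- helix_coords(30)
#' bc <- backbone_curve(hel)
#' curvature_torsion_at(bc, t = 15)
#' @export
curvature_torsion_at <- function(curve, t, segment = 1L,
                                 window_halfwidth = 1, n_points = 50L,
                                 degree = 5L, min_window = 1,
                                 cross_tol = 1e-12, speed_tol = 1e-9) {
  d <- chebyshev_derivatives(curve, t, segment = segment,
                             window_halfwidth = window_halfwidth,
                             n_points = n_points, degree = degree,
                             min_window = min_window)
  if (!d$defined)
    return(list(kappa = NA_real_, tau = NA_real_,
                kappa_defined = FALSE, tau_defined = FALSE))
  speed <- sqrt(sum(d$d1^2))
  if (speed < speed_tol)
    stop("degenerate parameterization: |r'(t)| is numerically zero")
  cr <- cross3(d$d1, d$d2)
  cn2 <- sum(cr^2)
  kappa <- sqrt(cn2) / speed^3
  if (cn2 < cross_tol)
    return(list(kappa = kappa, tau = NA_real_,
                kappa_defined = TRUE, tau_defined = FALSE))
  list(kappa = kappa, tau = sum(cr * d$d3) / cn2,
       kappa_defined = TRUE, tau_defined = TRUE)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Arc length along a backbone curve
#'
#' Cumulative arc length \eqn{\int_0^t |\dot r(s)|\,ds} from the start of
#' the contiguous segment to parameter `t`, evaluated by adaptive
#' quadrature on the spline speed.  Monotone non-decreasing in `t`.
#'
#' @inheritParams predict.backbone_curve
#' @param curve a [backbone_curve()] fit.
#' @return arc length in Angstrom (scalar; `t` must be a single value).
#' @export
arc_length_at <- function(curve, t, segment = 1L) {
  seg <- get_segment(curve, segment)
  stopifnot(length(t) == 1L)
  check_in_domain(seg, t)
  if (t <= 0) return(0)
  speed <- function(s) {
    d <- spline_eval(seg, s, deriv = 1L)
    sqrt(rowSums(d^2))
  }
  # integrate knot interval by knot interval: the integrand is smooth inside
  # each interval but only C1 at the knots
  ks <- unique(c(seq(0, floor(t)), t))
  total <- 0
  for (i in seq_len(length(ks) - 1L)) {
    if (ks[i + 1L] - ks[i] < 1e-14) next
    total <- total + stats::integrate(speed, ks[i], ks[i + 1L],
                                      rel.tol = 1e-10)$value
  }
  total
}
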