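#' Chebyshev-series derivatives of a backbone curve
#'
#' The piecewise-cubic spline is only C2: its third derivative jumps at the
#' knots, so differentiating the spline directly is numerically fragile
#' exactly where the torsion formula needs a third derivative.  Instead the
#' curve is sampled at `n_points` Chebyshev nodes on a window around the
#' residue of interest (by default one residue on each side, fifty points), a
#' Chebyshev series of moderate degree is fitted to the samples, and the
#' series is differentiated analytically.  The truncated series acts as a
#' gentle low-pass filter over the knot-scale artefacts of the spline while
#' remaining exact for any cubic, so first to third derivatives are obtained
#' stably and deterministically.
#'
#' At segment ends the window is clipped to the available domain; when the
#' clipped window spans less than `min_window` parameter units the
#' derivatives there are considered unreliable and the result is flagged
#' undefined (`defined = FALSE`).
#'
#' @param curve a [backbone_curve()] fit.
#' @param t parameter value (0-based within the segment) at which to
#'   evaluate.
#' @param segment which contiguous segment of the curve to use.
#' @param window_halfwidth half width of the fitting window in parameter
#'   units; default 1 (window from `t - 1` to `t + 1`).
#' @param n_points number of Chebyshev sample points in the window
#'   (default 50).
#' @param degree degree of the fitted Chebyshev series.  The default 5 is
#'   exact for cubics and, being well below `n_points`, filters the spline's
#'   third-derivative knot discontinuities; see the package vignette for the
#'   calibration on analytic benchmark curves.
#' @param min_window smallest clipped-window span (parameter units) for
#'   which derivatives are still reported as defined; default 1.
#'
#' @return list with elements `d1`, `d2`, `d3` (numeric 3-vectors: first,
#'   second and third derivative of (x, y, z) with respect to t), `defined`
#'   (logical) and `window` (the clipped window actually used).
#' @seealso [curvature_torsion_at()] which consumes these derivatives.
#' @export
chebyshev_derivatives <- function(curve, t, segment = 1L,
                                  window_halfwidth = 1, n_points = 50L,
                                  degree = 5L, min_window = 1) {
  seg <- get_segment(curve, segment)
  check_in_domain(seg, t)
  stopifnot(n_points >= degree + 1L, degree >= 3L)
  lo <- max(t - window_halfwidth, 0)
  hi <- min(t + window_halfwidth, seg$m - 1)
  defined <- (hi - lo) >= min_window - 1e-12

  # Chebyshev points of the first kind, mapped onto [lo, hi]
  xs <- cos(pi * (seq_len(n_points) - 0.5) / n_points)
  u <- lo + (hi - lo) * (xs + 1) / 2
  f <- spline_eval(seg, u)                      # n_points x 3

  co <- cheb_fit(xs, f, degree)                 # (degree+1) x 3
  x0 <- 2 * (t - lo) / (hi - lo) - 1
  scale <- 2 / (hi - lo)
  d <- vector("list", 3L)
  for (dd in 1:3) {
    co <- apply(co, 2L, cheb_der)
    if (is.null(dim(co))) co <- matrix(co, ncol = 3L)
    d[[dd]] <- as.numeric(cheb_val(x0, co)) * scale^dd
  }
  list(d1 = d[[1L]], d2 = d[[2L]], d3 = d[[3L]],
       defined = defined, window = c(lo, hi))
}

# Least-squares Chebyshev series fit at first-kind Chebyshev points xs.
# Discrete orthogonality of T_k at these points makes the normal equations
# diagonal, so the fit reduces to weighted sums -- exact, fast, and free of
# conditioning problems.  y may have several columns.
cheb_fit <- function(xs, y, degree) {
  n <- length(xs)
  Tm <- cheb_vander(xs, degree)                 # n x (degree+1)
  co <- (2 / n) * crossprod(Tm, as.matrix(y))
  co[1L, ] <- co[1L, ] / 2
  co
}

# Chebyshev-Vandermonde matrix T_k(x), k = 0..degree, by recurrence.
cheb_vander <- function(x, degree) {
  Tm <- matrix(0, length(x), degree + 1L)
  Tm[, 1L] <- 1
  if (degree >= 1L) Tm[, 2L] <- x
  if (degree >= 2L)
    for (k in 3:(degree + 1L)) Tm[, k] <- 2 * x * Tm[, k - 1L] - Tm[, k - 2L]
  Tm
}

# Coefficients of the derivative of a Chebyshev series (standard recurrence).
cheb_der <- function(co) {
  n <- length(co) - 1L
  if (n < 1L) return(0)
  der <- numeric(n)
  c2 <- co
  if (n >= 3L) {
    for (j in n:3) {
      der[j] <- 2 * j * c2[j + 1L]
      c2[j - 1L] <- c2[j - 1L] + j * c2[j + 1L] / (j - 2L)
    }
  }
  if (n >= 2L) der[2L] <- 4 * c2[3L]
  der[1L] <- c2[2L]
  der
}

# Evaluate Chebyshev series (columns of co) at scalar x by Clenshaw's rule.
cheb_val <- function(x, co) {
  co <- as.matrix(co)
  n <- nrow(co)
  b1 <- rep(0, ncol(co)); b2 <- b1
  if (n >= 2L) {
    for (k in n:2) {
      b0 <- 2 * x * b1 - b2 + co[k, ]
      b2 <- b1; b1 <- b0
    }
  }
  x * b1 - b2 + co[1L, ]
}
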