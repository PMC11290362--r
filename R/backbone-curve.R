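#' Fit a parametric cubic-spline space curve through a C-alpha trace
#'
#' Interpolates the three coordinates of an ordered C-alpha trace with cubic
#' splines, using the 0-based position within each contiguous stretch of the
#' chain as the curve parameter.  The result is a smooth parametric curve
#' \eqn{r(t) = (x(t), y(t), z(t))} that passes exactly through every input
#' atom and is twice continuously differentiable inside each contiguous
#' segment.  The curve is the starting point for all differential-geometry
#' descriptors in this package (see [curvature_torsion_at()],
#' [arc_length_at()], [describe_structure()]).
#'
#' The trace is split into independent segments wherever the chain is not
#' continuous: a gap in residue numbering larger than `gap_threshold`, or a
#' consecutive C-alpha distance above `break_distance` (Angstrom), starts a
#' new segment.  A cubic spline needs at least four support points, so
#' segments shorter than four residues are either an error (the default) or
#' silently marked as unfittable when `on_short = "drop"`; residues of
#' dropped segments carry no descriptors downstream.
#'
#' @param coords numeric matrix with one row per residue and columns x, y, z
#'   (Angstrom).
#' @param residue_ids strictly increasing integer vector of author residue
#'   numbers, one per row of `coords`.  Defaults to `1:nrow(coords)`.
#' @param chain_id single identifier attached to the fit.
#' @param boundary spline end condition: `"not-a-knot"` (default; third
#'   derivative continuous across the first and last interior knots, exact
#'   for data sampled from a single cubic) or `"natural"` (zero second
#'   derivative at the ends).
#' @param gap_threshold residue-numbering gap above which the trace is split
#'   (default 1, i.e. any missing residue number splits).
#' @param break_distance C-alpha to C-alpha distance (Angstrom) above which
#'   the trace is split; default 4.5.
#' @param on_short `"error"` to reject segments with fewer than four
#'   residues, `"drop"` to keep them in the object but mark them unfittable.
#'
#' @return An object of class `"backbone_curve"`: a list with elements
#'   `chain_id`, `boundary` and `segments`, the latter a list with one entry
#'   per contiguous segment holding the residue ids, the interpolated points
#'   and the spline second-derivative values from which all piecewise
#'   coefficients derive.  Methods: [predict.backbone_curve()],
#'   [coef.backbone_curve()], [residuals.backbone_curve()],
#'   [print.backbone_curve()], [plot.backbone_curve()].
#'
#' @examples
#' t <- 0:19
#' xyz <- cbind(2.3 * cos(1.745 * t), 2.3 * sin(1.745 * t), 1.5 * t)
#' bc <- backbone_curve(xyz)
#' max(abs(residuals(bc)))        # interpolation: ~1e-15
#' predict(bc, t = 2.5)           # point between residues 3 and 4
#' @export
backbone_curve <- function(coords, residue_ids = NULL, chain_id = "A",
                           boundary = c("not-a-knot", "natural"),
                           gap_threshold = 1, break_distance = 4.5,
                           on_short = c("error", "drop")) {
  boundary <- match.arg(boundary)
  on_short <- match.arg(on_short)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("invalid coordinate: expected an n x 3 matrix")
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  if (length(residue_ids) != n)
    stop("residue_ids must have one entry per coordinate row")
  if (anyNA(coords) || any(!is.finite(coords)))
    stop("invalid coordinate: NaN or non-finite value in trace")
  if (n > 1L && any(diff(residue_ids) <= 0))
    stop("unsorted trace: residue_ids must be strictly increasing")

  breaks <- trace_breaks(coords, residue_ids, gap_threshold, break_distance)
  segments <- vector("list", length(breaks))
  for (k in seq_along(breaks)) {
    idx <- breaks[[k]]
    m <- length(idx)
    if (m < 4L) {
      if (on_short == "error")
        stop(sprintf(
          "segment too short: residues %s-%s (chain %s) span %d residues; a cubic spline needs at least 4",
          residue_ids[idx[1L]], residue_ids[idx[m]], chain_id, m))
      segments[[k]] <- list(index = idx, residue_ids = residue_ids[idx],
                            y = coords[idx, , drop = FALSE], M = NULL,
                            m = m, fittable = FALSE)
      next
    }
    y <- coords[idx, , drop = FALSE]
    segments[[k]] <- list(index = idx, residue_ids = residue_ids[idx],
                          y = y, M = spline_second_derivs(y, boundary),
                          m = m, fittable = TRUE)
  }
  structure(list(chain_id = chain_id, boundary = boundary,
                 gap_threshold = gap_threshold,
                 break_distance = break_distance,
                 segments = segments, call = match.call()),
            class = "backbone_curve")
}

# Split indices 1..n into contiguous stretches at numbering gaps and long bonds.
trace_breaks <- function(coords, residue_ids, gap_threshold, break_distance) {
  n <- nrow(coords)
  if (n == 1L) return(list(1L))
  dids <- diff(residue_ids)
  dxyz <- sqrt(rowSums((coords[-1L, , drop = FALSE] -
                        coords[-n, , drop = FALSE])^2))
  cut <- which(dids > gap_threshold | dxyz > break_distance)
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
}

# Second derivatives M_i of the interpolating cubic spline on the uniform
# knot grid t = 0, 1, ..., m-1 (h = 1).  y may have several columns; each is
# fitted independently.  Boundary rows implement the not-a-knot condition
# (third-derivative continuity at knots 1 and m-2) or the natural condition.
spline_second_derivs <- function(y, boundary) {
  y <- as.matrix(y)
  m <- nrow(y)
  A <- matrix(0, m, m)
  b <- matrix(0, m, ncol(y))
  for (i in 2:(m - 1L)) {
    A[i, (i - 1L):(i + 1L)] <- c(1, 4, 1)
    b[i, ] <- 6 * (y[i - 1L, ] - 2 * y[i, ] + y[i + 1L, ])
  }
  if (boundary == "natural") {
    A[1L, 1L] <- 1
    A[m, m] <- 1
  } else {  # not-a-knot: M linear across the first/last interior knot
    A[1L, 1:3] <- c(1, -2, 1)
    A[m, (m - 2L):m] <- c(1, -2, 1)
  }
  solve(A, b)
}

# Evaluate one spline segment (or a derivative) at parameter values t in
# [0, m-1].  Returns an length(t) x 3 matrix.
spline_eval <- function(seg, t, deriv = 0L) {
  m <- seg$m
  i <- pmin(pmax(floor(t), 0), m - 2L)     # interval index, 0-based
  u <- t - i
  i1 <- i + 1L                             # R indices of left knot
  y0 <- seg$y[i1, , drop = FALSE]
  y1 <- seg$y[i1 + 1L, , drop = FALSE]
  M0 <- seg$M[i1, , drop = FALSE]
  M1 <- seg$M[i1 + 1L, , drop = FALSE]
  v <- 1 - u
  out <- switch(as.character(deriv),
    "0" = y0 * v + y1 * u + M0 * (v^3 - v) / 6 + M1 * (u^3 - u) / 6,
    "1" = (y1 - y0) + M0 * (1 - 3 * v^2) / 6 + M1 * (3 * u^2 - 1) / 6,
    "2" = M0 * v + M1 * u,
    "3" = M1 - M0,
    stop("deriv must be 0, 1, 2 or 3"))
  out
}

get_segment <- function(object, segment) {
  if (segment < 1L || segment > length(object$segments))
    stop(sprintf("segment %d does not exist (curve has %d)", segment,
                 length(object$segments)))
  seg <- object$segments[[segment]]
  if (!seg$fittable)
    stop(sprintf("segment too short: segment %d has %d residues", segment,
                 seg$m))
  seg
}

check_in_domain <- function(seg, t) {
  if (any(t < -1e-12 | t > seg$m - 1 + 1e-12))
    stop(sprintf("parameter out of range: t must lie in [0, %d]", seg$m - 1L))
}

#' Evaluate a fitted backbone curve
#'
#' Evaluates the parametric spline (or one of its derivatives) at arbitrary
#' parameter values.  The parameter is 0-based within the chosen contiguous
#' segment: `t = 0` is the first residue of the segment, `t = 1` the second,
#' and non-integer values interpolate between residues.
#'
#' @param object a [backbone_curve()] fit.
#' @param t numeric vector of parameter values in `[0, m - 1]` where `m` is
#'   the number of residues in the segment.
#' @param segment which contiguous segment to evaluate (default 1).
#' @param deriv derivative order 0 (position), 1, 2 or 3.  Derivatives here
#'   are the raw piecewise-polynomial derivatives of the spline; for the
#'   smoothed derivatives used by the descriptor pipeline see
#'   [chebyshev_derivatives()].
#' @param ... unused.
#' @return numeric matrix `length(t)` x 3 with columns x, y, z.
#' @export
predict.backbone_curve <- function(object, t, segment = 1L, deriv = 0L, ...) {
  seg <- get_segment(object, segment)
  check_in_domain(seg, t)
  out <- spline_eval(seg, t, deriv)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Piecewise-polynomial coefficients of a backbone curve
#'
#' Returns, for each contiguous segment, the coefficients of the cubic
#' polynomial on each knot interval, in the local variable `u = t - i`
#' (so column `c0` is the position at the left knot, `c1` the first
#' derivative there, and so on).
#'
#' @param object a [backbone_curve()] fit.
#' @param ... unused.
#' @return list with one entry per segment; each entry is a list `x`, `y`,
#'   `z` of `(m - 1)` x 4 coefficient matrices.
#' @export
coef.backbone_curve <- function(object, ...) {
  lapply(object$segments, function(seg) {
    if (!seg$fittable) return(NULL)
    m <- seg$m
    i <- seq_len(m - 1L)
    per_coord <- lapply(1:3, function(k) {
      y0 <- seg$y[i, k]; y1 <- seg$y[i + 1L, k]
      M0 <- seg$M[i, k]; M1 <- seg$M[i + 1L, k]
      cbind(c0 = y0,
            c1 = (y1 - y0) - (2 * M0 + M1) / 6,
            c2 = M0 / 2,
            c3 = (M1 - M0) / 6)
    })
    names(per_coord) <- c("x", "y", "z")
    per_coord
  })
}

#' @export
residuals.backbone_curve <- function(object, ...) {
  res <- lapply(object$segments, function(seg) {
    if (!seg$fittable) return(NULL)
    spline_eval(seg, seq_len(seg$m) - 1) - seg$y
  })
  do.call(rbind, res)
}

#' @export
print.backbone_curve <- function(x, ...) {
  ns <- length(x$segments)
  nres <- sum(vapply(x$segments, function(s) s$m, integer(1)))
  cat(sprintf("Backbone curve, chain %s: %d residue%s in %d contiguous segment%s\n",
              x$chain_id, nres, if (nres == 1) "" else "s",
              ns, if (ns == 1) "" else "s"))
  cat(sprintf("Cubic spline interpolation, %s end condition\n", x$boundary))
  for (k in seq_along(x$segments)) {
    s <- x$segments[[k]]
    cat(sprintf("  segment %d: residues %s-%s (%d)%s\n", k,
                s$residue_ids[1], s$residue_ids[s$m], s$m,
                if (s$fittable) "" else " [too short to fit]"))
  }
  invisible(x)
}

#' Plot a backbone curve
#'
#' Draws the xy and xz projections of the fitted curve with the input
#' C-alpha positions overlaid.
#'
#' @param x a [backbone_curve()] fit.
#' @param points_per_residue curve sampling density for drawing.
#' @param ... passed to [graphics::plot()].
#' @export
plot.backbone_curve <- function(x, points_per_residue = 20, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (proj in list(c(1L, 2L), c(1L, 3L))) {
    lab <- c("x", "y", "z")[proj]
    first <- TRUE
    for (seg in x$segments) {
      if (!seg$fittable) next
      tt <- seq(0, seg$m - 1, length.out = (seg$m - 1) * points_per_residue + 1)
      p <- spline_eval(seg, tt)
      if (first) {
        graphics::plot(p[, proj[1]], p[, proj[2]], type = "l",
                       xlab = paste0(lab[1], " (Å)"),
                       ylab = paste0(lab[2], " (Å)"),
                       main = paste(lab, collapse = ""), ...)
        first <- FALSE
      } else {
        graphics::lines(p[, proj[1]], p[, proj[2]])
      }
      graphics::points(seg$y[, proj[1]], seg$y[, proj[2]], pch = 16, cex = 0.6)
    }
  }
  invisible(x)
}
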