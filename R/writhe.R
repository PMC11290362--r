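#' Gauss-integral writhe contribution of a pair of line segments
#'
#' Evaluates, in closed form, the contribution of one ordered pair of
#' directed line segments to the writhing number: the Gauss double integral
#' \deqn{\frac{1}{4\pi}\int_a\!\!\int_b
#'   \frac{(dr_a \times dr_b)\cdot(r_a - r_b)}{|r_a - r_b|^3}}
#' computed as the signed solid angle subtended by the two segments divided
#' by \eqn{4\pi} (the Klenin-Langowski tetrahedron formula).  Right-handed
#' crossings count positive.  The value is symmetric in the two segments and
#' antisymmetric under reversing the direction of either one.
#'
#' Coplanar pairs contribute exactly zero.  A pair of segments that actually
#' intersect has no defined contribution and returns `NA` with a warning.
#'
#' @param seg_a,seg_b 2 x 3 numeric matrices; row 1 is the segment start,
#'   row 2 the end (Angstrom).
#' @return scalar writhe contribution (unitless), or `NA` for intersecting
#'   segments.
#' @references Klenin K., Langowski J. (2000) Computation of writhe in
#'   modeling of supercoiled DNA. Biopolymers 54:307-317.
#' @export
segment_pair_writhe <- function(seg_a, seg_b) {
  seg_a <- as.matrix(seg_a); seg_b <- as.matrix(seg_b)
  p1 <- seg_a[1L, ]; p2 <- seg_a[2L, ]
  p3 <- seg_b[1L, ]; p4 <- seg_b[2L, ]
  r12 <- p2 - p1; r34 <- p4 - p3
  if (sqrt(sum(r12^2)) < 1e-9 || sqrt(sum(r34^2)) < 1e-9)
    stop("degenerate segment: zero-length segment in writhe computation")
  r13 <- p3 - p1; r14 <- p4 - p1
  r23 <- p3 - p2; r24 <- p4 - p2

  n1 <- unit_or_null(cross3(r13, r14))
  n2 <- unit_or_null(cross3(r14, r24))
  n3 <- unit_or_null(cross3(r24, r23))
  n4 <- unit_or_null(cross3(r23, r13))
  sgn <- sum(cross3(r34, r12) * r13)

  if (is.null(n1) || is.null(n2) || is.null(n3) || is.null(n4) ||
      abs(sgn) < 1e-14) {
    # coplanar configuration: zero contribution unless the segments cross
    if (segments_intersect_coplanar(p1, p2, p3, p4)) {
      warning("intersecting segments: writhe contribution undefined")
      return(NA_real_)
    }
    return(0)
  }
  omega <- asin(clamp1(sum(n1 * n2))) + asin(clamp1(sum(n2 * n3))) +
           asin(clamp1(sum(n3 * n4))) + asin(clamp1(sum(n4 * n1)))
  omega * sign(sgn) / (4 * pi)
}

clamp1 <- function(x) min(1, max(-1, x))

unit_or_null <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(NULL)
  v / n
}

# Do two segments that lie in a common plane (or line) properly intersect?
segments_intersect_coplanar <- function(p1, p2, p3, p4) {
  e1 <- p2 - p1; e2 <- p4 - p3
  # build a 2D basis in the common plane
  b1 <- unit_or_null(e1)
  if (is.null(b1)) return(FALSE)
  w <- p3 - p1
  b2 <- unit_or_null(e2 - sum(e2 * b1) * b1)
  if (is.null(b2)) b2 <- unit_or_null(w - sum(w * b1) * b1)
  if (is.null(b2)) {
    # everything collinear: overlap test on the line
    s <- sort(c(0, sum(e1 * b1)))
    u <- sort(c(sum(w * b1), sum((p4 - p1) * b1)))
    return(max(s[1], u[1]) <= min(s[2], u[2]) + 1e-12)
  }
  to2d <- function(p) c(sum((p - p1) * b1), sum((p - p1) * b2))
  a <- to2d(p1); b <- to2d(p2); cc <- to2d(p3); d <- to2d(p4)
  orient <- function(p, q, r)
    (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  o1 <- orient(a, b, cc); o2 <- orient(a, b, d)
  o3 <- orient(cc, d, a); o4 <- orient(cc, d, b)
  (o1 * o2 < 0) && (o3 * o4 < 0)
}

#' Writhing number of a five-residue window
#'
#' The writhing number Wr of the polygonal curve formed by the five C-alpha
#' positions centred on a residue: the standard polygonal double sum
#' \deqn{Wr = 2 \sum_{i<j\ \mathrm{non\,adjacent}} w_{ij}} over the four
#' directed edges of the window, where each \eqn{w_{ij}} is the closed-form
#' Gauss-integral contribution of an edge pair
#' ([segment_pair_writhe()]).  Adjacent edge pairs contribute zero for
#' straight segments sharing a vertex and are excluded.  Wr is unitless and
#' signed: a right-handed alpha-helical window gives a positive value, its
#' mirror image the exact negative.  Unlike the differential-geometry
#' curvature, which is a non-negative magnitude, Wr can take either sign.
#'
#' The window needs two residues on each side of the centre inside one
#' contiguous segment; centres closer than that to a segment end return
#' `NA` (undefined).
#'
#' @param trace numeric matrix (n x 3) of contiguous C-alpha positions in
#'   Angstrom, or a [backbone_curve()] (in which case `segment` selects the
#'   contiguous segment).
#' @param center_index 1-based index of the central residue within the
#'   trace/segment.
#' @param segment segment number when `trace` is a backbone curve.
#' @return scalar Wr, or `NA` when the window does not fit.
#' @export
writhe_at <- function(trace, center_index, segment = 1L) {
  if (inherits(trace, "backbone_curve"))
    trace <- trace$segments[[segment]]$y
  trace <- as.matrix(trace)
  n <- nrow(trace)
  if (center_index < 3L || center_index > n - 2L) return(NA_real_)
  v <- trace[(center_index - 2L):(center_index + 2L), , drop = FALSE]
  polygon_writhe(v)
}

# Writhe of an open polygonal arc given its vertices (double sum over
# non-adjacent edge pairs).
polygon_writhe <- function(v) {
  ne <- nrow(v) - 1L
  total <- 0
  for (i in seq_len(ne - 2L)) {
    for (j in (i + 2L):ne) {
      w <- segment_pair_writhe(v[i:(i + 1L), ], v[j:(j + 1L), ])
      if (is.na(w)) return(NA_real_)
      total <- total + w
    }
  }
  2 * total
}
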