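#' Per-residue geometry descriptors for one or more chains
#'
#' Runs the full descriptor pipeline on C-alpha traces: fits a parametric
#' cubic-spline curve per chain ([backbone_curve()]), evaluates curvature
#' and torsion at every residue via Chebyshev-smoothed derivatives
#' ([curvature_torsion_at()]), accumulates arc length along the chain
#' ([arc_length_at()]) and computes the five-residue writhing number
#' ([writhe_at()]).  Chains are processed independently: descriptors near an
#' inter-chain boundary are unaffected by the other chain, and chain breaks
#' split a chain into independent segments.
#'
#' Descriptors that cannot be computed reliably are `NA` ("undefined"):
#' curvature/torsion where the clipped derivative window is shorter than
#' `min_window`, torsion additionally where the curve is locally straight,
#' writhe at the two first and last residues of each segment, and everything
#' on segments shorter than four residues.
#'
#' @param chains the input traces, any of: a `structure_trace` from
#'   [read_calpha_trace()]; a single numeric n x 3 coordinate matrix; or a
#'   list of chains, each a list with elements `chain_id`, `coords`
#'   (n x 3 matrix, Angstrom), `residue_ids` (optional) and `residue_names`
#'   (optional 3-letter codes).
#' @inheritParams curvature_torsion_at
#' @param boundary,gap_threshold,break_distance passed to [backbone_curve()].
#' @return A data frame of class `"geometry_table"` with columns `chain`,
#'   `resseq`, `icode`, `resname`, `curvature` (1/Angstrom), `torsion`
#'   (1/Angstrom, signed), `arc_length` (Angstrom, cumulative along the
#'   chain), `writhe` (unitless) and `segment` (contiguous-segment number
#'   within the chain).  Undefined descriptors are `NA`.
#' @examples
#' tab <- describe_structure(helix_coords(30))
#' summary(tab)
#' @export
describe_structure <- function(chains,
                               boundary = c("not-a-knot", "natural"),
                               gap_threshold = 1, break_distance = 4.5,
                               window_halfwidth = 1, n_points = 50L,
                               degree = 5L, min_window = 1,
                               cross_tol = 1e-12) {
  boundary <- match.arg(boundary)
  chains <- normalize_chain_input(chains)
  out <- lapply(chains, function(ch) {
    describe_chain(ch, boundary, gap_threshold, break_distance,
                   window_halfwidth, n_points, degree, min_window, cross_tol)
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("geometry_table", "data.frame")
  tab
}

normalize_chain_input <- function(chains) {
  if (inherits(chains, "structure_trace")) {
    return(lapply(chains$chains, function(ch) {
      list(chain_id = ch$chain_id,
           coords = as.matrix(ch$residues[, c("x", "y", "z")]),
           residue_ids = ch$residues$resseq,
           icode = ch$residues$icode,
           residue_names = ch$residues$resname)
    }))
  }
  if (is.matrix(chains) || is.data.frame(chains))
    chains <- list(list(chain_id = "A", coords = as.matrix(chains)))
  if (!is.null(chains$coords))  # a single chain spec, not a list of them
    chains <- list(chains)
  lapply(chains, function(ch) {
    n <- nrow(ch$coords)
    if (is.null(ch$chain_id)) ch$chain_id <- "A"
    if (is.null(ch$residue_ids)) ch$residue_ids <- seq_len(n)
    if (is.null(ch$icode)) ch$icode <- rep("", n)
    if (is.null(ch$residue_names)) ch$residue_names <- rep("ALA", n)
    ch
  })
}

describe_chain <- function(ch, boundary, gap_threshold, break_distance,
                           window_halfwidth, n_points, degree, min_window,
                           cross_tol) {
  curve <- withCallingHandlers(
    backbone_curve(ch$coords, ch$residue_ids, chain_id = ch$chain_id,
                   boundary = boundary, gap_threshold = gap_threshold,
                   break_distance = break_distance, on_short = "drop"),
    error = function(e)
      stop(sprintf("chain %s: %s", ch$chain_id, conditionMessage(e))))
  n <- nrow(ch$coords)
  kappa <- tau <- arc <- wr <- rep(NA_real_, n)
  segno <- rep(NA_integer_, n)
  arc_offset <- 0
  for (k in seq_along(curve$segments)) {
    seg <- curve$segments[[k]]
    segno[seg$index] <- k
    if (!seg$fittable) next
    m <- seg$m
    # arc length accumulated interval by interval, then along the chain
    sp <- vapply(seq_len(m - 1L), function(i) {
      stats::integrate(function(s)
        sqrt(rowSums(spline_eval(seg, s, deriv = 1L)^2)),
        i - 1, i, rel.tol = 1e-10)$value
    }, numeric(1))
    cum <- c(0, cumsum(sp))
    for (i in seq_len(m)) {
      idx <- seg$index[i]
      kt <- curvature_torsion_at(curve, i - 1, segment = k,
                                 window_halfwidth = window_halfwidth,
                                 n_points = n_points, degree = degree,
                                 min_window = min_window,
                                 cross_tol = cross_tol)
      kappa[idx] <- kt$kappa
      tau[idx] <- kt$tau
      arc[idx] <- arc_offset + cum[i]
      wr[idx] <- writhe_at(seg$y, i)
    }
    arc_offset <- arc_offset + cum[m]
  }
  data.frame(chain = ch$chain_id, resseq = ch$residue_ids,
             icode = ch$icode, resname = ch$residue_names,
             curvature = kappa, torsion = tau, arc_length = arc,
             writhe = wr, segment = segno, stringsAsFactors = FALSE)
}

#' @export
print.geometry_table <- function(x, ...) {
  cat(sprintf("Geometry table: %d residues, %d chain%s\n", nrow(x),
              length(unique(x$chain)),
              if (length(unique(x$chain)) == 1) "" else "s"))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
summary.geometry_table <- function(object, ...) {
  per_chain <- split(as.data.frame(object), object$chain)
  out <- do.call(rbind, lapply(per_chain, function(d) {
    data.frame(chain = d$chain[1L], n = nrow(d),
               defined = sum(!is.na(d$curvature)),
               mean_curvature = mean(d$curvature, na.rm = TRUE),
               mean_torsion = mean(d$torsion, na.rm = TRUE),
               mean_writhe = mean(d$writhe, na.rm = TRUE),
               total_arc = max(d$arc_length, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}

#' Plot descriptor profiles
#'
#' Draws curvature, torsion and writhe against residue number, one panel
#' per descriptor, chains overlaid.
#'
#' @param x a [describe_structure()] table.
#' @param ... passed to [graphics::plot()].
#' @export
plot.geometry_table <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  chains <- unique(x$chain)
  cols <- grDevices::hcl.colors(max(3L, length(chains)), "Dark 3")
  for (what in c("curvature", "torsion", "writhe")) {
    graphics::plot(range(x$resseq), range(x[[what]], na.rm = TRUE),
                   type = "n", xlab = "residue", ylab = what, ...)
    for (i in seq_along(chains)) {
      d <- x[x$chain == chains[i], ]
      graphics::lines(d$resseq, d[[what]], col = cols[i])
    }
  }
  invisible(x)
}

#' Write a geometry table to CSV
#'
#' Exports the descriptor columns in a fixed order with undefined values as
#' empty fields.
#'
#' @param x a [describe_structure()] table.
#' @param path output file path.
#' @export
write_geometry_csv <- function(x, path) {
  cols <- c("chain", "resseq", "resname", "curvature", "torsion",
            "arc_length", "writhe")
  utils::write.csv(as.data.frame(x)[, cols], path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}
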