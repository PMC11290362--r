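#' Default secondary-structure boxes in descriptor space
#'
#' Rectangular regions of the (curvature, torsion) plane used by
#' [classify_geometry()].  The boxes are anchored to the descriptor values
#' the pipeline actually produces for ideal geometries at the default
#' settings: an ideal right-handed alpha-helix evaluates to
#' kappa = 0.457, tau = +0.111 per Angstrom at interior residues, and an
#' extended beta-strand-like repeat to kappa = 0.67-0.73 with small |tau|
#' (see the vignette for the calibration).  Boxes are checked in order;
#' anything matching no box is classified `"other"`.
#'
#' @return named list of boxes, each with `kappa` and `tau` ranges and a
#'   flag `tau_abs` (match on |tau|).
#' @export
ss_boxes <- function() {
  list(helix = list(kappa = c(0.36, 0.56), tau = c(0.02, 0.20),
                    tau_abs = FALSE),
       strand = list(kappa = c(0.60, 0.95), tau = c(0, 0.16),
                     tau_abs = TRUE))
}

#' Classify residue environments from geometry
#'
#' Assigns each (curvature, torsion) pair to an environment class —
#' `"helix"`, `"strand"` or `"other"` — by a rectangle rule in descriptor
#' space.  The parametric spline representation preserves the geometric
#' signatures of the regular secondary structures, so helical and extended
#' residues occupy distinct regions of the (kappa, tau) plane.
#'
#' @param kappa,tau numeric vectors of descriptors (1/Angstrom).  Undefined
#'   (NA) inputs are an error: classification needs defined descriptors.
#' @param boxes class boxes, see [ss_boxes()].
#' @return character vector of class names.
#' @export
classify_geometry <- function(kappa, tau, boxes = ss_boxes()) {
  if (anyNA(kappa) || anyNA(tau))
    stop("undefined descriptor: classification needs defined curvature and torsion")
  out <- rep("other", length(kappa))
  for (cls in rev(names(boxes))) {   # earlier boxes take precedence
    b <- boxes[[cls]]
    tv <- if (isTRUE(b$tau_abs)) abs(tau) else tau
    hit <- kappa >= b$kappa[1L] & kappa <= b$kappa[2L] &
           tv >= b$tau[1L] & tv <= b$tau[2L]
    out[hit] <- cls
  }
  out
}

#' Load an environment-specific propensity table
#'
#' Reads the documented plain-text propensity format: optional `#` comment
#' lines, then a header row of the twenty amino-acid one-letter codes, then
#' one row per environment class (`class-id` followed by twenty numeric
#' scores).  With `normalize = TRUE` each row is scaled to sum to one, i.e.
#' converted into amino-acid probabilities conditional on the class.
#'
#' @param x file path or character vector of lines.
#' @param normalize scale each row to probabilities (default FALSE).
#' @return object of class `"propensity_table"`: numeric matrix (classes x
#'   amino acids) with attributes `normalized` and `provenance`.
#' @export
load_propensity_table <- function(x, normalize = FALSE) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
             readLines(x, warn = FALSE)
           else if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1L]]
           else x
  prov <- sub("^#\\s*", "", grep("^#", lines, value = TRUE))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L)
    stop("malformed table: need a header row and at least one class row")
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(header) != 20L)
    stop(sprintf("malformed table: header has %d amino-acid columns, expected 20",
                 length(header)))
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  bad <- which(lengths(rows) != 21L)
  if (length(bad) > 0L)
    stop(sprintf("malformed table: row %d has %d fields, expected 21 (class + 20 scores)",
                 bad[1L], lengths(rows)[bad[1L]]))
  classes <- vapply(rows, `[`, character(1), 1L)
  scores <- suppressWarnings(
    t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(20L))))
  if (anyNA(scores)) stop("parse error: non-numeric propensity score")
  if (any(!is.finite(scores))) stop("malformed table: non-finite score")
  dimnames(scores) <- list(classes, header)
  if (normalize) scores <- scores / rowSums(scores)
  structure(scores, class = c("propensity_table", "matrix"),
            normalized = normalize,
            provenance = if (length(prov)) paste(prov, collapse = "; ")
                         else "unspecified")
}

#' Serialize a propensity table to the plain-text format
#'
#' @param table a [load_propensity_table()] object (or classes x 20 matrix).
#' @param path output file, or NULL to return the lines.
#' @param digits significant digits written.
#' @return the text lines, invisibly when writing to a file.
#' @export
write_propensity_table <- function(table, path = NULL, digits = 6) {
  lines <- c(paste("#", attr(table, "provenance") %||% "propensity table"),
             paste(colnames(table), collapse = " "),
             vapply(seq_len(nrow(table)), function(i)
               paste(c(rownames(table)[i],
                       format(table[i, ], digits = digits, trim = TRUE)),
                     collapse = " "), character(1)))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.propensity_table <- function(x, ...) {
  cat(sprintf("Propensity table: %d environment class%s x %d amino acids%s\n",
              nrow(x), if (nrow(x) == 1) "" else "es", ncol(x),
              if (isTRUE(attr(x, "normalized"))) " (row-normalized)" else ""))
  m <- unclass(x)
  attr(m, "normalized") <- NULL
  attr(m, "provenance") <- NULL
  print(m, digits = 3)
  invisible(x)
}

#' Kernel density estimate over (curvature, torsion) per environment class
#'
#' Builds, for each environment class with enough residues, a bivariate
#' Gaussian kernel density over the (kappa, tau) pairs of that class.  The
#' densities summarize where a structural environment lives in descriptor
#' space and can be evaluated ([predict.descriptor_pdf()]), sampled
#' reproducibly ([simulate.descriptor_pdf()]) and used to generate
#' restraints for conformational sampling.  Bandwidths follow Scott's rule
#' per dimension, \eqn{h_k = \hat\sigma_k n^{-1/6}}, with a small floor so
#' degenerate (zero-variance) samples stay well defined.
#'
#' @param geometry a [describe_structure()] table or a list of them
#'   (rows pooled).
#' @param classes optional character vector of per-residue classes aligned
#'   with the pooled rows; default classifies defined residues with
#'   [classify_geometry()].
#' @param min_n minimum residues per class (default 20); smaller classes
#'   are skipped with a warning.
#' @return named list of `"descriptor_pdf"` objects (one per class), each
#'   with the sample matrix, bandwidths and class id.
#' @export
build_descriptor_pdf <- function(geometry, classes = NULL, min_n = 20L) {
  if (inherits(geometry, "geometry_table")) geometry <- list(geometry)
  tab <- do.call(rbind, lapply(geometry, as.data.frame))
  ok <- !is.na(tab$curvature) & !is.na(tab$torsion)
  tab <- tab[ok, , drop = FALSE]
  if (is.null(classes)) classes <- classify_geometry(tab$curvature, tab$torsion)
  else classes <- classes[ok]
  out <- list()
  for (cls in unique(classes)) {
    x <- as.matrix(tab[classes == cls, c("curvature", "torsion")])
    if (nrow(x) < min_n) {
      warning(sprintf("class '%s' has %d residues (< %d); skipped",
                      cls, nrow(x), min_n))
      next
    }
    n <- nrow(x)
    h <- pmax(apply(x, 2L, stats::sd) * n^(-1 / 6), 1e-9)
    out[[cls]] <- structure(list(class = cls, x = x, h = h, n = n),
                            class = "descriptor_pdf")
  }
  out
}

#' @export
print.descriptor_pdf <- function(x, ...) {
  cat(sprintf("Descriptor density, class '%s': %d residues, bandwidths (%.4g, %.4g)\n",
              x$class, x$n, x$h[1L], x$h[2L]))
  invisible(x)
}

#' Evaluate a descriptor density
#'
#' @param object a [build_descriptor_pdf()] density.
#' @param newdata numeric matrix (or length-2 vector) of (kappa, tau)
#'   points.
#' @param ... unused.
#' @return numeric vector of density values (non-negative; integrates to 1
#'   over the plane).
#' @export
predict.descriptor_pdf <- function(object, newdata, ...) {
  p <- if (is.null(dim(newdata))) matrix(newdata, ncol = 2L)
       else as.matrix(newdata)
  vapply(seq_len(nrow(p)), function(i) {
    mean(stats::dnorm(p[i, 1L], object$x[, 1L], object$h[1L]) *
         stats::dnorm(p[i, 2L], object$x[, 2L], object$h[2L]))
  }, numeric(1))
}

#' Sample from a descriptor density
#'
#' Draws (kappa, tau) pairs from the kernel density: a data point is picked
#' uniformly and Gaussian kernel noise added.  With `seed` set the draw is
#' reproducible bit for bit.
#'
#' @param object a [build_descriptor_pdf()] density.
#' @param nsim number of samples.
#' @param seed optional RNG seed; the caller's RNG state is left untouched.
#' @param ... unused.
#' @return nsim x 2 matrix of samples.
#' @export
simulate.descriptor_pdf <- function(object, nsim = 1L, seed = NULL, ...) {
  draw <- function() {
    i <- sample.int(object$n, nsim, replace = TRUE)
    cbind(curvature = stats::rnorm(nsim, object$x[i, 1L], object$h[1L]),
          torsion = stats::rnorm(nsim, object$x[i, 2L], object$h[2L]))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Mode of a descriptor density
#'
#' Locates the highest-density point by evaluating the density at every
#' sample point and polishing the best one with Nelder-Mead.
#'
#' @param object a [build_descriptor_pdf()] density.
#' @return length-2 vector (kappa, tau) of the mode.
#' @export
pdf_mode <- function(object) {
  dens <- predict(object, object$x)
  start <- object$x[which.max(dens), ]
  opt <- stats::optim(start, function(p) -predict(object, p),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12))
  stats::setNames(opt$par, c("kappa", "tau"))
}

#' Numerical mass check of a descriptor density
#'
#' Integrates the density on a regular grid over a bounding box extending
#' `nsd` bandwidths beyond the data range; the result should be 1 up to
#' grid error.
#'
#' @param object a [build_descriptor_pdf()] density.
#' @param nsd bounding-box margin in bandwidths (default 6).
#' @param n grid points per axis (default 201).
#' @return scalar numerical integral.
#' @export
pdf_integral <- function(object, nsd = 6, n = 201L) {
  r1 <- range(object$x[, 1L]) + c(-1, 1) * nsd * object$h[1L]
  r2 <- range(object$x[, 2L]) + c(-1, 1) * nsd * object$h[2L]
  g1 <- seq(r1[1L], r1[2L], length.out = n)
  g2 <- seq(r2[1L], r2[2L], length.out = n)
  vals <- outer(g1, g2, function(a, b) predict(object, cbind(a, b)))
  sum(vals) * diff(r1) * diff(r2) / (n - 1L)^2
}
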