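#' Ideal helix C-alpha coordinates
#'
#' Points on a circular helix
#' \eqn{(a\cos\omega i,\ a\sin\omega i,\ \mathrm{rise}\cdot i)} sampled one
#' residue apart.  The defaults are the canonical alpha-helix: radius
#' 2.3 Angstrom, rise 1.5 Angstrom per residue, 100 degrees of turn per
#' residue (3.6 residues per turn).  A negative `twist` gives the
#' left-handed mirror image.  The smooth generating curve has the closed
#' forms \eqn{\kappa = a/(a^2+c^2)} and \eqn{\tau = c/(a^2+c^2)} with
#' \eqn{c} the rise per radian; note that these describe the smooth helix
#' through the points, not the spline interpolant that the descriptor
#' pipeline fits through the same points (see the vignette).
#'
#' @param n number of residues.
#' @param radius helix radius a (Angstrom).
#' @param rise rise per residue (Angstrom).
#' @param twist turn per residue (degrees; sign sets handedness).
#' @return n x 3 coordinate matrix.
#' @export
helix_coords <- function(n = 30L, radius = 2.3, rise = 1.5, twist = 100) {
  if (radius <= 0) stop("invalid fixture spec: radius must be positive")
  if (n < 5L) stop("invalid fixture spec: need at least 5 residues")
  omega <- twist * pi / 180
  i <- seq_len(n) - 1L
  cbind(x = radius * cos(omega * i), y = radius * sin(omega * i),
        z = rise * i)
}

#' Closed-form curvature and torsion of the smooth helix
#'
#' @inheritParams helix_coords
#' @return named vector `c(kappa, tau)` in 1/Angstrom, for the smooth
#'   circular helix through the fixture points.
#' @export
helix_closed_form <- function(radius = 2.3, rise = 1.5, twist = 100) {
  cz <- rise / abs(twist * pi / 180)
  c(kappa = radius / (radius^2 + cz^2),
    tau = sign(twist) * cz / (radius^2 + cz^2))
}

#' Synthetic C-alpha fixture generator
#'
#' Deterministically generates minimal, fully valid CA-only PDB fixtures
#' with known geometry, used throughout the test suite and documentation so
#' that no external structure files are needed.  Kinds:
#' \describe{
#'   \item{helix}{circular helix; params `radius`, `rise`, `twist`
#'     (see [helix_coords()]); closed-form truth attached.}
#'   \item{line}{collinear points along x, spacing `spacing` (default 3.8);
#'     truth curvature 0.}
#'   \item{circle}{planar circle of radius `radius` (default 7.5, which
#'     keeps the 0.5-radian default sampling step within C-alpha bonding
#'     distance); truth curvature 1/radius, torsion 0.}
#'   \item{strand}{extended beta-strand-like 2-residue repeat: rise
#'     `rise` (default 3.3) along x, pleat amplitude `amplitude`
#'     (default 0.94) alternating in sign, optional slow pleat `twist`
#'     (degrees/residue) about the strand axis.}
#'   \item{zigzag}{planar zigzag in the z = 0 plane (writhe is exactly 0).}
#'   \item{twisted_cubic}{the curve (s, s^2, s^3) with
#'     `s = scale * (i - (n-1)/2)`; the default `scale = 0.2` keeps point
#'     spacing within bonding distance.}
#'   \item{perturbed}{any of the above plus isotropic Gaussian coordinate
#'     noise of sd `noise_sd`, seeded by `seed` (byte-reproducible).}
#' }
#'
#' @param kind fixture kind, see Details.
#' @param n number of residues.
#' @param radius,rise,twist,spacing,amplitude,step_rad,scale geometry
#'   parameters, used according to `kind`.
#' @param base for `kind = "perturbed"`, the underlying kind.
#' @param noise_sd Gaussian noise sd in Angstrom (perturbed only).
#' @param seed RNG seed (perturbed only); same spec + seed gives
#'   byte-identical output.
#' @param chain_id,resname chain id and 3-letter residue name written into
#'   the PDB records.
#' @return list of class `"fixture"` with elements `kind`, `params`,
#'   `coords` (exact, unrounded), `residue_ids`, `pdb` (character vector of
#'   PDB lines; coordinates rounded to the PDB's 3 decimals) and `truth`
#'   (data frame of analytic per-residue `kappa`/`tau` where a closed form
#'   exists, otherwise NA).
#' @examples
#' fx <- generate_fixture("helix", n = 30)
#' fx$truth[1, ]
#' @export
generate_fixture <- function(kind = c("helix", "line", "circle", "strand",
                                      "zigzag", "twisted_cubic", "perturbed"),
                             n = 30L, radius = NULL, rise = NULL,
                             twist = NULL, spacing = 3.8, amplitude = 0.94,
                             step_rad = 0.5, scale = 0.2, base = "helix",
                             noise_sd = 0.1, seed = 1L, chain_id = "A",
                             resname = "ALA") {
  kind <- match.arg(kind)
  if (n < 5L) stop("invalid fixture spec: need at least 5 residues")
  # kind-specific defaults: the ideal alpha-helix, a 10 A circle, a
  # beta-strand-like 3.3 A-rise repeat
  base_kind <- if (kind == "perturbed") base else kind
  if (is.null(radius)) radius <- if (base_kind == "circle") 7.5 else 2.3
  if (is.null(rise)) rise <- if (base_kind == "strand") 3.3 else 1.5
  if (is.null(twist)) twist <- if (base_kind == "strand") 0 else 100
  i <- seq_len(n) - 1L
  truth <- data.frame(resseq = i + 1L, kappa = NA_real_, tau = NA_real_)
  coords <- switch(kind,
    helix = {
      cf <- helix_closed_form(radius, rise, twist)
      truth$kappa <- cf[["kappa"]]; truth$tau <- cf[["tau"]]
      helix_coords(n, radius, rise, twist)
    },
    line = {
      truth$kappa <- 0
      cbind(x = spacing * i, y = 0 * i, z = 0 * i)
    },
    circle = {
      if (radius <= 0) stop("invalid fixture spec: radius must be positive")
      truth$kappa <- 1 / radius; truth$tau <- 0
      th <- step_rad * i
      cbind(x = radius * cos(th), y = radius * sin(th), z = 0 * i)
    },
    strand = {
      ph <- pi * i + twist * pi / 180 * i
      cbind(x = rise * i, y = amplitude * cos(ph), z = amplitude * sin(ph))
    },
    zigzag = {
      cbind(x = spacing * i, y = amplitude * (-1)^i, z = 0 * i)
    },
    twisted_cubic = {
      s <- scale * (i - (n - 1) / 2)
      cbind(x = s, y = s^2, z = s^3)
    },
    perturbed = {
      if (noise_sd < 0) stop("invalid fixture spec: noise_sd must be >= 0")
      fx <- generate_fixture(base, n = n, radius = radius, rise = rise,
                             twist = twist, spacing = spacing,
                             amplitude = amplitude, step_rad = step_rad,
                             scale = scale)
      truth$kappa <- NA_real_; truth$tau <- NA_real_
      fx$coords + with_seed(seed, matrix(stats::rnorm(3 * n, 0, noise_sd),
                                         ncol = 3L))
    })
  colnames(coords) <- c("x", "y", "z")
  pdb <- fixture_pdb_lines(coords, residue_ids = i + 1L,
                           chain_id = chain_id, resname = resname,
                           title = sprintf("protgeom synthetic fixture: %s",
                                           kind))
  structure(list(kind = kind, coords = coords, residue_ids = i + 1L,
                 pdb = pdb, truth = truth,
                 params = list(n = n, radius = radius, rise = rise,
                               twist = twist, spacing = spacing,
                               amplitude = amplitude, step_rad = step_rad,
                               scale = scale, base = base,
                               noise_sd = noise_sd, seed = seed)),
            class = "fixture")
}

# Run code with a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Minimal CA-only PDB serialization (fixed-width ATOM records).
fixture_pdb_lines <- function(coords, residue_ids, chain_id = "A",
                              resname = "ALA", title = "synthetic fixture") {
  n <- nrow(coords)
  resname <- rep_len(resname, n)
  atoms <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), resname, chain_id, residue_ids,
    coords[, 1L], coords[, 2L], coords[, 3L], 1, 0)
  c(sprintf("REMARK   6 %s", title), atoms,
    sprintf("TER   %5d      %3s %1s%4d", n + 1L, resname[n], chain_id,
            residue_ids[n]),
    "END")
}

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf("Synthetic fixture '%s': %d residues\n", x$kind,
              nrow(x$coords)))
  if (!all(is.na(x$truth$kappa)))
    cat(sprintf("  closed-form truth: kappa = %.4f, tau = %s\n",
                x$truth$kappa[1L],
                if (is.na(x$truth$tau[1L])) "undefined"
                else sprintf("%.4f", x$truth$tau[1L])))
  invisible(x)
}

#' Write a fixture to a PDB file
#'
#' @param fixture a [generate_fixture()] object.
#' @param path output path.
#' @export
write_fixture <- function(fixture, path) {
  writeLines(fixture$pdb, path)
  invisible(path)
}
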