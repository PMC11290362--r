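#' Read a multiple sequence alignment
#'
#' Reads a protein MSA in FASTA or Clustal format (via Biostrings) and
#' returns it as a character matrix, one row per sequence, one column per
#' alignment column, with sequence names as row names.
#'
#' @param path alignment file.
#' @param format `"auto"` (default; Clustal is detected from the header
#'   line), `"fasta"` or `"clustal"`.
#' @return character matrix of aligned residues/gaps.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal"
              else "fasta"
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  ss <- Biostrings::unmasked(aln)
  chars <- strsplit(as.character(ss), "", fixed = TRUE)
  m <- do.call(rbind, chars)
  rownames(m) <- names(ss)
  m
}

#' Map alignment columns to structure residues
#'
#' Builds the bijection between non-gap alignment cells and the residues of
#' each sequence's structure trace.  The ungapped one-letter sequence of
#' every alignment row must equal the trace sequence (nonstandard residues
#' compare as `X`, MSE as `M`); any difference is reported with the
#' sequence name and the first differing position.
#'
#' @param msa character matrix from [read_msa()] (or equivalent).
#' @param traces named list of [read_calpha_trace()] objects; names must
#'   match the MSA row names.
#' @return list of class `"alignment_mapping"` with `msa`, `traces` and
#'   `map`, an integer matrix (sequences x columns) giving for every
#'   non-gap cell the 1-based residue index within the trace (chains
#'   concatenated in file order); gap cells are `NA`.
#' @export
map_alignment_to_structures <- function(msa, traces) {
  seqs <- rownames(msa)
  if (is.null(seqs)) stop("alignment has no sequence names")
  missing <- setdiff(seqs, names(traces))
  if (length(missing) > 0L)
    stop(sprintf("alignment/structure mismatch: no structure for sequence '%s'",
                 missing[1L]))
  map <- matrix(NA_integer_, nrow(msa), ncol(msa), dimnames = dimnames(msa))
  for (s in seqs) {
    row <- msa[s, ]
    isres <- !(row %in% c("-", ".", " "))
    aln_seq <- toupper(row[isres])
    trc_seq <- strsplit(trace_sequence(traces[[s]]), "")[[1L]]
    if (length(aln_seq) != length(trc_seq)) {
      stop(sprintf(
        "alignment/structure mismatch: sequence '%s' has %d aligned residues but the structure has %d",
        s, length(aln_seq), length(trc_seq)))
    }
    diffpos <- which(aln_seq != trc_seq & aln_seq != "X" & trc_seq != "X")
    if (length(diffpos) > 0L)
      stop(sprintf(
        "alignment/structure mismatch: sequence '%s' differs from its structure at position %d ('%s' vs '%s')",
        s, diffpos[1L], aln_seq[diffpos[1L]], trc_seq[diffpos[1L]]))
    map[s, isres] <- seq_along(aln_seq)
  }
  structure(list(msa = msa, traces = traces, map = map),
            class = "alignment_mapping")
}

#' Metric distance between descriptor vectors
#'
#' Weighted Euclidean distance between two (curvature, torsion, writhe)
#' descriptor vectors:
#' \eqn{d(a,b) = \sqrt{\sum_k w_k (a_k - b_k)^2}}.  With positive weights
#' this is a true metric: non-negative, zero iff the vectors are equal,
#' symmetric, and satisfying the triangle inequality — which is what makes
#' the descriptors usable with clustering algorithms (unlike RMSD, which
#' violates the triangle inequality).
#'
#' @param a,b numeric length-3 vectors (curvature, torsion, writhe).  All
#'   components must be defined (non-NA).
#' @param weights non-negative weights, default `c(1, 1, 1)`.
#' @return scalar distance >= 0.
#' @export
descriptor_distance <- function(a, b, weights = c(1, 1, 1)) {
  if (anyNA(a) || anyNA(b))
    stop("undefined descriptor: distance needs fully defined vectors")
  if (any(weights < 0)) stop("weights must be non-negative")
  sqrt(sum(weights * (a - b)^2))
}

#' Cluster alignment columns into blocks of equivalent geometry
#'
#' For every alignment column, the sequences present (non-gap, all three
#' descriptors defined) are clustered on their (curvature, torsion, writhe)
#' vectors by complete-linkage agglomerative clustering, cut at `cutoff`.
#' Descriptors are standardized with the family's pooled mean and standard
#' deviation per descriptor, so the cutoff is expressed in comparable,
#' unitless terms across families.  Per-column labels are deterministic:
#' the cluster containing the first (present) sequence gets label 1, the
#' next new cluster label 2, and so on.
#'
#' Column labellings are then smoothed into blocks: only runs of at least
#' `min_block_len` consecutive columns with an identical partition of the
#' same present sequences keep their labels; shorter runs are relabelled
#' unclustered (`NA`).  Columns with fewer than two present sequences, or
#' any undefined mapped descriptor, are never labelled.
#'
#' @param mapping an [map_alignment_to_structures()] result.
#' @param geometry named list of [describe_structure()] tables, one per
#'   sequence (rows in trace residue order), or NULL to compute them from
#'   the mapping's traces.
#' @param cutoff complete-linkage cut height in standardized descriptor
#'   units (default 1.0).
#' @param weights descriptor weights for the metric (default `c(1, 1, 1)`).
#' @param min_block_len minimum run of identically partitioned columns that
#'   keeps its labels (default 3).
#' @return object of class `"alignment_annotation"`: list with `msa`,
#'   `map`, `labels` (integer matrix sequences x columns; `NA` =
#'   unclustered/gap), `colors` (character matrix, PyMOL colour per cell)
#'   and `n_clusters` per column.
#' @export
cluster_alignment_columns <- function(mapping, geometry = NULL, cutoff = 1.0,
                                      weights = c(1, 1, 1),
                                      min_block_len = 3L) {
  stopifnot(inherits(mapping, "alignment_mapping"))
  seqs <- rownames(mapping$map)
  if (is.null(geometry))
    geometry <- lapply(mapping$traces[seqs], describe_structure)
  # descriptor array: sequences x columns x 3
  nc <- ncol(mapping$map)
  desc <- array(NA_real_, c(length(seqs), nc, 3L),
                dimnames = list(seqs, NULL, c("curvature", "torsion",
                                              "writhe")))
  for (s in seqs) {
    g <- geometry[[s]]
    idx <- mapping$map[s, ]
    ok <- !is.na(idx)
    desc[s, ok, ] <- as.matrix(g[idx[ok], c("curvature", "torsion",
                                            "writhe")])
  }
  # pooled standardization per descriptor
  for (k in 1:3) {
    v <- desc[, , k]
    mu <- mean(v, na.rm = TRUE)
    sd_k <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sd_k) || sd_k < 1e-12) sd_k <- 1
    desc[, , k] <- (v - mu) / sd_k
  }

  labels <- matrix(NA_integer_, length(seqs), nc,
                   dimnames = list(seqs, NULL))
  any_clusterable <- FALSE
  for (j in seq_len(nc)) {
    present <- which(apply(!is.na(desc[, j, , drop = FALSE]), 1L, all))
    if (length(present) < 2L) next
    any_clusterable <- TRUE
    pts <- sweep(desc[present, j, , drop = TRUE], 2L, sqrt(weights), `*`)
    cl <- if (is.finite(cutoff))
      stats::cutree(stats::hclust(stats::dist(pts), method = "complete"),
                    h = cutoff)
    else rep(1L, length(present))
    labels[present, j] <- match(cl, unique(cl))  # first sequence -> label 1
  }
  if (!any_clusterable)
    stop("nothing to cluster: no column has two sequences with defined descriptors")

  labels <- smooth_label_blocks(labels, min_block_len)
  colors <- matrix(NA_character_, nrow(labels), ncol(labels),
                   dimnames = dimnames(labels))
  has <- !is.na(labels)
  if (any(has)) colors[has] <- cluster_palette(max(labels[has]))[labels[has]]
  structure(list(msa = mapping$msa, map = mapping$map,
                 traces = mapping$traces, labels = labels, colors = colors,
                 cutoff = cutoff, min_block_len = min_block_len),
            class = "alignment_annotation")
}

# Keep labels only on runs of >= min_block_len consecutive columns that
# carry an identical partition over an identical set of present sequences.
smooth_label_blocks <- function(labels, min_block_len) {
  nc <- ncol(labels)
  sig <- vapply(seq_len(nc), function(j)
    paste(ifelse(is.na(labels[, j]), ".", labels[, j]), collapse = ""),
    character(1))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (b in seq_along(r$lengths)) {
    if (r$lengths[b] < min_block_len)
      labels[, starts[b]:ends[b]] <- NA_integer_
  }
  labels
}

#' @export
print.alignment_annotation <- function(x, ...) {
  nlab <- sum(!is.na(x$labels[1L, ]) | colSums(!is.na(x$labels)) > 0)
  cat(sprintf(
    "Alignment annotation: %d sequences, %d columns, %d labelled column%s (cutoff %.2f)\n",
    nrow(x$labels), ncol(x$labels), sum(colSums(!is.na(x$labels)) > 0),
    if (nlab == 1) "" else "s", x$cutoff))
  invisible(x)
}

#' Render an annotated alignment
#'
#' Produces a fixed-width plain-text report with a cluster-label line under
#' each sequence line, and (optionally) a companion PyMOL script that
#' colours the same residues with the same palette, so the text report and
#' the 3D view are colour-consistent.
#'
#' @param annotation a [cluster_alignment_columns()] result.
#' @param structures named character vector of PDB paths (names = sequence
#'   names) for the PyMOL script; NULL to skip the script.
#' @param width columns per text block (default 60).
#' @return list with `report` (character vector of lines) and `script`
#'   (character vector of PyMOL lines, or NULL).
#' @export
render_annotated_alignment <- function(annotation, structures = NULL,
                                       width = 60L) {
  msa <- annotation$msa
  labels <- annotation$labels
  seqs <- rownames(msa)
  namew <- max(nchar(seqs)) + 2L
  nc <- ncol(msa)
  report <- character(0)
  for (start in seq(1L, nc, by = width)) {
    end <- min(start + width - 1L, nc)
    report <- c(report, sprintf("# columns %d-%d", start, end))
    for (s in seqs) {
      seqline <- paste(msa[s, start:end], collapse = "")
      lab <- labels[s, start:end]
      labline <- paste(ifelse(msa[s, start:end] %in% c("-", ".", " "), "-",
                              ifelse(is.na(lab), ".",
                                     as.character(lab %% 10L))),
                       collapse = "")
      report <- c(report,
                  paste0(formatC(s, width = -namew), seqline),
                  paste0(strrep(" ", namew), labline))
    }
    report <- c(report, "")
  }
  script <- NULL
  if (!is.null(structures)) {
    colors <- annotation_color_table(annotation)
    script <- write_pymol_script(structures, colors = colors)
  }
  list(report = report, script = script)
}

# Per-residue colour table (object, chain, resseq, color) for the PyMOL
# script, derived from the annotation labels via the shared palette.
annotation_color_table <- function(annotation) {
  out <- list()
  for (s in rownames(annotation$labels)) {
    res <- trace_residues(annotation$traces[[s]])
    j <- which(!is.na(annotation$labels[s, ]))
    if (length(j) == 0L) next
    idx <- annotation$map[s, j]
    out[[s]] <- data.frame(object = s, chain = res$chain[idx],
                           resseq = res$resseq[idx],
                           color = annotation$colors[s, j],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
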