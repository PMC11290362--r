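#' Default palette for cluster colouring
#'
#' PyMOL colour names assigned to cluster labels 1, 2, ...; recycled when
#' there are more labels than colours.  The mapping from label to colour is
#' a pure function, so the same label always gets the same colour in the
#' text report and in the PyMOL script.
#'
#' @param n number of colours wanted.
#' @return character vector of PyMOL colour names.
#' @export
cluster_palette <- function(n) {
  base <- c("red", "green", "blue", "yellow", "magenta", "cyan",
            "orange", "purple", "salmon", "teal", "olive", "slate")
  rep_len(base, n)
}

#' Generate a PyMOL colouring script
#'
#' Serializes a deterministic `.pml` script that loads the given structures,
#' aligns them onto the first one (superposition is delegated to the
#' viewer), and colours residues.  Two modes:
#' per-residue cluster colours (`colors`: one colour statement per
#' structure/colour group with a `resi` selection list), or b-factor
#' spectrum mode (`spectrum = TRUE`: structures are expected to carry
#' values in their b-factor column, see [write_bfactor_pdb()]).
#'
#' @param structures named character vector of PDB file paths; the names are
#'   used as PyMOL object ids.
#' @param colors optional data frame with columns `object`, `chain`,
#'   `resseq` and `color` giving per-residue colours.
#' @param spectrum if TRUE, emit a `spectrum b` command per object instead
#'   of (or in addition to) explicit colours.
#' @param superpose align all objects onto the first (default TRUE when
#'   more than one structure).
#' @return character vector of script lines.
#' @export
write_pymol_script <- function(structures, colors = NULL, spectrum = FALSE,
                               superpose = length(structures) > 1L) {
  if (is.null(names(structures)) || any(names(structures) == ""))
    names(structures) <- sub("\\.(pdb|ent)$", "", basename(structures))
  if (is.null(colors) && !spectrum)
    stop("annotation is empty: provide colors or set spectrum = TRUE")
  objs <- names(structures)
  out <- c("# generated by protgeom", "bg_color white")
  for (i in seq_along(structures))
    out <- c(out, sprintf("load %s, %s", structures[[i]], objs[i]))
  out <- c(out, "hide everything", "show cartoon", "set cartoon_tube_radius, 0.5")
  if (superpose && length(objs) > 1L)
    for (i in 2:length(objs))
      out <- c(out, sprintf("align %s, %s", objs[i], objs[1L]))
  if (!is.null(colors) && nrow(colors) > 0L) {
    out <- c(out, "color grey80")
    # deterministic order: objects as given, then colour name, then residue
    colors <- colors[order(match(colors$object, objs), colors$color,
                           colors$chain, colors$resseq), , drop = FALSE]
    key <- paste(colors$object, colors$color, colors$chain, sep = "\r")
    for (k in unique(key)) {
      g <- colors[key == k, , drop = FALSE]
      if (nrow(g) == 0L) next
      out <- c(out, sprintf("color %s, %s and chain %s and resi %s",
                            g$color[1L], g$object[1L], g$chain[1L],
                            paste(g$resseq, collapse = "+")))
    }
  }
  if (spectrum)
    for (obj in objs)
      out <- c(out, sprintf("spectrum b, rainbow, %s", obj))
  out <- c(out, "zoom")
  out
}
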