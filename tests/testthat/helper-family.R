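# A synthetic protein family for alignment-annotation tests: helical
# structures with an optional strand-like middle block and staggered gaps,
# written as PDB + FASTA files under a temp dir.  Returns paths, traces and
# the constructed column<->residue ground truth.

make_family <- function(dir, n = 24L, strand_middle = FALSE,
                        gaps = list(s1 = integer(0), s2 = integer(0),
                                    s3 = integer(0))) {
  build_coords <- function(strandish) {
    if (!strandish) return(helix_coords(n))
    # helix ends with a strand-like middle third
    k <- floor(n / 3)
    top <- helix_coords(k)
    mid <- generate_fixture("strand", n = n - 2 * k)$coords
    mid <- sweep(mid, 2, mid[1, ] - (top[k, ] + c(3.8, 0, 0)), "-")
    bot <- helix_coords(k)
    bot <- sweep(bot, 2, bot[1, ] - (mid[nrow(mid), ] + c(3.8, 0, 0)), "-")
    rbind(top, mid, bot)
  }
  paths <- character(0)
  seqs <- list()
  for (i in 1:3) {
    nm <- paste0("s", i)
    fx_coords <- build_coords(strand_middle && i == 3)
    f <- file.path(dir, paste0(nm, ".pdb"))
    writeLines(protgeom:::fixture_pdb_lines(fx_coords, seq_len(n)), f)
    paths[nm] <- f
    aa <- rep("A", n)
    # insert gaps into the aligned sequence at the requested columns
    gap_cols <- gaps[[nm]]
    ali <- character(n + length(gap_cols))
    ali[gap_cols] <- "-"
    ali[setdiff(seq_along(ali), gap_cols)] <- aa
    seqs[[nm]] <- ali
  }
  # pad to the common alignment length
  len <- max(lengths(seqs))
  fasta <- unlist(lapply(names(seqs), function(nm) {
    s <- c(seqs[[nm]], rep("-", len - length(seqs[[nm]])))
    c(paste0(">", nm), paste(s, collapse = ""))
  }))
  msa_file <- file.path(dir, "family.fasta")
  writeLines(fasta, msa_file)
  list(paths = paths, msa_file = msa_file,
       traces = lapply(paths, read_calpha_trace))
}
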