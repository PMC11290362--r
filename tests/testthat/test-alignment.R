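test_that("FASTA and Clustal alignments read to the same matrix", {
  d <- withr::local_tempdir()
  fasta <- file.path(d, "a.fasta")
  writeLines(c(">s1", "AC-DE", ">s2", "ACQDE"), fasta)
  m <- read_msa(fasta)
  expect_equal(dim(m), c(2L, 5L))
  expect_equal(unname(m["s1", 3]), "-")
  clustal <- file.path(d, "a.aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               "s1              AC-DE", "s2              ACQDE"), clustal)
  m2 <- read_msa(clustal)
  expect_equal(unname(m2), unname(m))
})

test_that("a gapless alignment of identical sequences maps as the identity", {
  d <- withr::local_tempdir()
  fam <- make_family(d, n = 12)
  msa <- read_msa(fam$msa_file)
  mp <- map_alignment_to_structures(msa, fam$traces)
  for (s in rownames(mp$map)) expect_equal(unname(mp$map[s, ]), 1:12)
})

test_that("a gap shifts all downstream residues by one", {
  d <- withr::local_tempdir()
  fam <- make_family(d, n = 12, gaps = list(s1 = integer(0), s2 = 5L,
                                            s3 = integer(0)))
  mp <- map_alignment_to_structures(read_msa(fam$msa_file), fam$traces)
  expect_equal(unname(mp$map["s2", ]), c(1:4, NA, 5:12))
  expect_equal(unname(mp$map["s1", ]), c(1:12, NA))
})

test_that("staggered gaps map cell-by-cell against constructed truth", {
  d <- withr::local_tempdir()
  fam <- make_family(d, n = 10,
                     gaps = list(s1 = c(2L, 7L), s2 = 4L, s3 = integer(0)))
  mp <- map_alignment_to_structures(read_msa(fam$msa_file), fam$traces)
  truth_s1 <- rep(NA_integer_, 12); truth_s1[setdiff(1:12, c(2, 7))] <- 1:10
  truth_s2 <- rep(NA_integer_, 12); truth_s2[setdiff(1:11, 4)] <- 1:10
  truth_s3 <- c(1:10, NA, NA)
  expect_equal(unname(mp$map["s1", ]), truth_s1)
  expect_equal(unname(mp$map["s2", ]), truth_s2)
  expect_equal(unname(mp$map["s3", ]), truth_s3)
})

test_that("sequence/structure mismatches are reported with name and position", {
  d <- withr::local_tempdir()
  fam <- make_family(d, n = 10)
  msa <- read_msa(fam$msa_file)
  msa["s2", 4] <- "W"   # structure has all-ALA
  expect_error(map_alignment_to_structures(msa, fam$traces),
               "alignment/structure mismatch.*'s2'.*position 4")
  msa2 <- read_msa(fam$msa_file)[, 1:9]
  expect_error(map_alignment_to_structures(msa2, fam$traces),
               "alignment/structure mismatch.*'s1'")
})

test_that("descriptor distance satisfies the metric axioms on random triples", {
  set.seed(31)
  n_triples <- 2000
  a <- matrix(rnorm(3 * n_triples), ncol = 3)
  b <- matrix(rnorm(3 * n_triples), ncol = 3)
  cc <- matrix(rnorm(3 * n_triples), ncol = 3)
  for (i in seq_len(n_triples)) {
    dab <- descriptor_distance(a[i, ], b[i, ])
    expect_gte(dab, 0)
    expect_identical(dab, descriptor_distance(b[i, ], a[i, ]))
    expect_lte(descriptor_distance(a[i, ], cc[i, ]),
               dab + descriptor_distance(b[i, ], cc[i, ]) + 1e-12)
  }
  expect_identical(descriptor_distance(a[1, ], a[1, ]), 0)
  expect_gt(descriptor_distance(a[1, ], a[1, ] + c(0, 1e-9, 0)), 0)
  expect_error(descriptor_distance(c(1, NA, 0), c(0, 0, 0)),
               "undefined descriptor")
})

test_that("an identical-structure family collapses to one cluster per column", {
  d <- withr::local_tempdir()
  fam <- make_family(d, n = 18)
  mp <- map_alignment_to_structures(read_msa(fam$msa_file), fam$traces)
  ann <- cluster_alignment_columns(mp)
  lab <- ann$labels
  mapped <- which(colSums(!is.na(lab)) > 0)
  expect_gt(length(mapped), 8)
  expect_true(all(lab[, mapped] == 1L))
  # one colour everywhere
  expect_equal(unique(stats::na.omit(as.vector(ann$colors))),
               cluster_palette(1)[1])
})

test_that("a divergent conformation separates into its own cluster over the divergent block", {
  d <- withr::local_tempdir()
  fam <- make_family(d, n = 24, strand_middle = TRUE)
  mp <- map_alignment_to_structures(read_msa(fam$msa_file), fam$traces)
  ann <- cluster_alignment_columns(mp)
  lab <- ann$labels
  # middle block: s1/s2 together, s3 apart
  mid <- 11:14
  expect_true(all(lab["s1", mid] == lab["s2", mid]))
  expect_true(all(lab["s3", mid] != lab["s1", mid]))
  # helical ends: all together
  ends <- c(4:6, 20:21)
  expect_true(all(lab["s3", ends] == lab["s1", ends], na.rm = TRUE))
})

test_that("cutoff limits behave as expected", {
  d <- withr::local_tempdir()
  fam <- make_family(d, n = 24, strand_middle = TRUE)
  mp <- map_alignment_to_structures(read_msa(fam$msa_file), fam$traces)
  # infinite cutoff: a single cluster everywhere
  ann_inf <- cluster_alignment_columns(mp, cutoff = Inf)
  lab <- ann_inf$labels
  expect_true(all(lab[, colSums(!is.na(lab)) > 0] == 1L, na.rm = TRUE))
  # zero cutoff: distinct structures split into singletons, which block
  # smoothing keeps only where the partition is stable
  ann0 <- cluster_alignment_columns(mp, cutoff = 1e-12)
  mid <- 11:14
  expect_true(all(ann0$labels["s3", mid] != ann0$labels["s1", mid],
                  na.rm = TRUE))
})

test_that("clustering is invariant to sequence order up to relabelling", {
  d <- withr::local_tempdir()
  fam <- make_family(d, n = 24, strand_middle = TRUE)
  msa <- read_msa(fam$msa_file)
  mp <- map_alignment_to_structures(msa, fam$traces)
  ann <- cluster_alignment_columns(mp)
  perm <- c("s3", "s1", "s2")
  mp2 <- map_alignment_to_structures(msa[perm, ], fam$traces[perm])
  ann2 <- cluster_alignment_columns(mp2)
  for (j in seq_len(ncol(ann$labels))) {
    a <- ann$labels[, j]
    b <- ann2$labels[perm[c(2, 3, 1)], j][c(3, 1, 2)]
    b <- ann2$labels[, j][match(rownames(ann$labels), rownames(ann2$labels))]
    # same partition: co-membership must agree
    for (p in 1:2) for (q in (p + 1):3) {
      expect_identical(is.na(a[p]), is.na(b[p]))
      if (!is.na(a[p]) && !is.na(a[q]))
        expect_identical(a[p] == a[q], b[p] == b[q])
    }
  }
})

test_that("short unstable runs are relabelled unclustered by block smoothing", {
  lab <- matrix(1L, 2, 9)
  lab[2, 5] <- 2L   # a single-column deviation
  sm <- protgeom:::smooth_label_blocks(lab, 3L)
  expect_true(all(is.na(sm[, 5])))
  expect_true(all(sm[, c(1:4, 6:9)] == 1L))
  lab2 <- matrix(1L, 2, 4)
  expect_identical(protgeom:::smooth_label_blocks(lab2, 3L), lab2)
})

test_that("columns with undefined descriptors are never labelled", {
  d <- withr::local_tempdir()
  fam <- make_family(d, n = 18)
  mp <- map_alignment_to_structures(read_msa(fam$msa_file), fam$traces)
  ann <- cluster_alignment_columns(mp)
  # writhe is undefined at the two terminal residues of every chain
  expect_true(all(is.na(ann$labels[, c(1, 2, 17, 18)])))
})

test_that("the text report and PyMOL script agree label for label", {
  d <- withr::local_tempdir()
  fam <- make_family(d, n = 24, strand_middle = TRUE)
  mp <- map_alignment_to_structures(read_msa(fam$msa_file), fam$traces)
  ann <- cluster_alignment_columns(mp)
  r <- render_annotated_alignment(ann, structures = fam$paths)
  expect_false(is.null(r$script))
  # rendering is deterministic
  r2 <- render_annotated_alignment(ann, structures = fam$paths)
  expect_identical(r, r2)
  # every labelled cell appears in the script with the palette colour
  for (s in rownames(ann$labels)) {
    for (j in which(!is.na(ann$labels[s, ]))) {
      col <- ann$colors[s, j]
      resseq <- mp$map[s, j]
      hits <- grep(sprintf("^color %s, %s and chain A and resi ", col, s),
                   r$script, value = TRUE)
      expect_true(any(vapply(hits, function(h) {
        resis <- as.integer(strsplit(sub(".*resi ", "", h), "+",
                                     fixed = TRUE)[[1]])
        resseq %in% resis
      }, logical(1))))
    }
  }
  # label lines under each sequence line use the digit of the label
  lab_line <- r$report[3]   # first block, s1 label line
  expect_match(lab_line, "^\\s+[-.0-9]+$")
})

test_that("a family with no clusterable columns errors", {
  d <- withr::local_tempdir()
  fam <- make_family(d, n = 12)
  msa <- read_msa(fam$msa_file)
  mp <- map_alignment_to_structures(msa, fam$traces)
  short <- mp
  short$map[2:3, ] <- NA_integer_   # pretend all but one sequence unmapped
  expect_error(cluster_alignment_columns(short), "nothing to cluster")
})
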