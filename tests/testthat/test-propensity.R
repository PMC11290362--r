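synthetic_table_lines <- function() {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  c("# synthetic 3-class fixture",
    paste(aa, collapse = " "),
    paste("helix", paste(seq(0.5, 10, length.out = 20), collapse = " ")),
    paste("strand", paste(rep(1, 20), collapse = " ")),
    paste("other", paste(c(1, rep(0, 19)), collapse = " ")))
}

test_that("a uniform table normalizes to 1/20 and a delta row to probability 1", {
  tab <- load_propensity_table(synthetic_table_lines(), normalize = TRUE)
  expect_equal(unname(tab["strand", ]), rep(0.05, 20))
  expect_equal(unname(tab["other", "A"]), 1)
  expect_equal(unname(tab["other", "C"]), 0)
  expect_equal(unname(rowSums(tab)), rep(1, 3), tolerance = 1e-12)
})

test_that("the shipped synthetic example table loads and normalizes", {
  f <- system.file("extdata", "synthetic_propensity.tab",
                   package = "protgeom")
  tab <- load_propensity_table(f, normalize = TRUE)
  expect_equal(dim(tab), c(3L, 20L))
  expect_equal(unname(rowSums(tab)), rep(1, 3), tolerance = 1e-12)
  expect_match(attr(tab, "provenance"), "synthetic")
})

test_that("propensity tables round-trip through the text format", {
  tab <- load_propensity_table(synthetic_table_lines())
  f <- withr::local_tempfile(fileext = ".tab")
  write_propensity_table(tab, f)
  tab2 <- load_propensity_table(f)
  expect_equal(unclass(tab2), unclass(tab), ignore_attr = TRUE)
  expect_equal(rownames(tab2), rownames(tab))
})

test_that("malformed tables are rejected with clear messages", {
  lines <- synthetic_table_lines()
  expect_error(load_propensity_table(lines[1:2]), "malformed table")
  short_header <- c("A C D", "helix 1 2 3")
  expect_error(load_propensity_table(short_header), "malformed table")
  bad_row <- lines; bad_row[3] <- "helix 1 2 3"
  expect_error(load_propensity_table(bad_row), "malformed table")
  nonnum <- lines; nonnum[4] <- paste("strand", paste(rep("x", 20), collapse = " "))
  expect_error(load_propensity_table(nonnum), "parse error")
})

test_that("ideal fixtures classify into their secondary-structure boxes", {
  hel <- describe_structure(helix_coords(30))
  mid <- hel[8:23, ]
  expect_true(all(classify_geometry(mid$curvature, mid$torsion) == "helix"))
  st <- describe_structure(generate_fixture("strand", n = 20)$coords)
  stmid <- st[6:15, ]
  expect_true(all(classify_geometry(stmid$curvature, stmid$torsion) == "strand"))
  # left-handed helix has negative torsion: not helix
  lh <- describe_structure(helix_coords(30, twist = -100))[8:23, ]
  expect_true(all(classify_geometry(lh$curvature, lh$torsion) != "helix"))
  # a straight line has undefined torsion: classification must refuse
  line <- describe_structure(cbind(3.8 * (0:9), 0, 0))
  expect_error(classify_geometry(line$curvature, line$torsion),
               "undefined descriptor")
  # pure function: same input, same class
  expect_identical(classify_geometry(0.45, 0.11), classify_geometry(0.45, 0.11))
})

test_that("descriptor densities integrate to one and concentrate on the data", {
  set.seed(41)
  x <- cbind(curvature = rnorm(60, 0.45, 0.02),
             torsion = rnorm(60, 0.11, 0.02))
  g <- structure(data.frame(curvature = x[, 1], torsion = x[, 2]),
                 class = c("geometry_table", "data.frame"))
  pdfs <- build_descriptor_pdf(g, classes = rep("helix", 60))
  expect_named(pdfs, "helix")
  p <- pdfs$helix
  expect_equal(pdf_integral(p), 1, tolerance = 1e-3)
  expect_true(all(predict(p, cbind(runif(50), runif(50))) >= 0))
  # degenerate case: all samples identical -> mode at that point
  g2 <- structure(data.frame(curvature = rep(0.4, 25), torsion = rep(0.1, 25)),
                  class = c("geometry_table", "data.frame"))
  p2 <- build_descriptor_pdf(g2, classes = rep("x", 25))$x
  expect_equal(unname(pdf_mode(p2)), c(0.4, 0.1), tolerance = 1e-6)
})

test_that("a helix-family density peaks at the pipeline's ideal-helix descriptors", {
  set.seed(43)
  tabs <- lapply(1:10, function(i)
    describe_structure(generate_fixture("perturbed", base = "helix", n = 30,
                                        noise_sd = 0.02, seed = i)$coords))
  pdfs <- build_descriptor_pdf(tabs)
  expect_true("helix" %in% names(pdfs))
  m <- pdf_mode(pdfs$helix)
  # mode within 0.02 of the ideal-helix descriptor point (0.4569, 0.1107)
  expect_lt(abs(m[["kappa"]] - 0.4569), 0.02)
  expect_lt(abs(m[["tau"]] - 0.1107), 0.02)
})

test_that("small classes are skipped with a warning", {
  g <- structure(data.frame(curvature = rep(0.4, 5), torsion = rep(0.1, 5)),
                 class = c("geometry_table", "data.frame"))
  expect_warning(pdfs <- build_descriptor_pdf(g, classes = rep("tiny", 5)),
                 "skipped")
  expect_length(pdfs, 0)
})

test_that("density sampling is seed-reproducible and consistent with the density", {
  set.seed(44)
  x <- cbind(curvature = rnorm(200, 0.45, 0.03),
             torsion = rnorm(200, 0.11, 0.03))
  g <- structure(data.frame(curvature = x[, 1], torsion = x[, 2]),
                 class = c("geometry_table", "data.frame"))
  p <- build_descriptor_pdf(g, classes = rep("helix", 200))$helix
  s1 <- simulate(p, nsim = 500, seed = 7)
  s2 <- simulate(p, nsim = 500, seed = 7)
  expect_identical(s1, s2)
  # chi-square sanity: histogram of samples vs density mass on a coarse grid
  s <- simulate(p, nsim = 10000, seed = 8)
  br1 <- c(min(s[, 1]) - 1e-9, quantile(x[, 1], c(0.25, 0.5, 0.75)),
           max(s[, 1]) + 1e-9)
  br2 <- c(min(s[, 2]) - 1e-9, quantile(x[, 2], 0.5), max(s[, 2]) + 1e-9)
  obs <- table(cut(s[, 1], br1), cut(s[, 2], br2))
  exp_mass <- matrix(0, 4, 2)
  for (i in 1:4) for (j in 1:2) {
    gr1 <- seq(br1[i], br1[i + 1], length.out = 120)
    gr2 <- seq(br2[j], br2[j + 1], length.out = 120)
    vals <- outer(gr1, gr2, function(a, b) predict(p, cbind(a, b)))
    exp_mass[i, j] <- sum(vals) * diff(br1[i:(i + 1)]) *
      diff(br2[j:(j + 1)]) / 119^2
  }
  exp_counts <- exp_mass / sum(exp_mass) * 10000
  chi2 <- sum((as.vector(obs) - as.vector(exp_counts))^2 / as.vector(exp_counts))
  # 7 degrees of freedom; generous bound against flakiness
  expect_lt(chi2, 30)
})
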