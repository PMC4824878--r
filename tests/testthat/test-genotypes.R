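test_that("GenePop decoding handles 2- and 3-digit coding, missing calls and errors", {
  txt <- c("toy file", "loc1", "loc2",
           "POP", "a1 , 327341 094100", "a2 , 000000 094094",
           "POP", "b1 , 341341 100100")
  tab <- read_genepop(text = txt)
  expect_equal(tab$loci, c("loc1", "loc2"))
  ## first genotype decodes to the unordered pair {327, 341}
  expect_equal(sort(c(tab$a1["a1", "loc1"], tab$a2["a1", "loc1"])), c(327, 341))
  ## exactly one missing call from the all-zeros code
  expect_equal(sum(is.na(tab$a1)), 1)
  expect_true(is.na(tab$a1["a2", "loc1"]))
  ## 2-digit coding decodes too
  expect_equal(c(tab$a1["a1", "loc2"], tab$a2["a1", "loc2"]), c(94, 100))
  ## populations map to species labels in order
  expect_equal(tab$metadata$species, c("A", "A", "B"))

  expect_error(read_genepop(text = c("t", "l1", "POP", "x1 , 094")),
               "4 or 6")
  expect_error(read_genepop(text = c("t", "l1", "l2", "POP", "x1 , 094094")),
               "parse error")
})

test_that("GenePop write/read round-trips bit-exact on canonical form", {
  set.seed(4)
  tab <- sample_pure_genotypes(fixture_profile(), "A", 15, missing_rate = 0.1)
  lines <- write_genepop(tab, title = "rt")
  tab2 <- read_genepop(text = lines, pop_labels = "A")
  expect_identical(unname(tab$a1), unname(tab2$a1))
  expect_identical(unname(tab$a2), unname(tab2$a2))
  expect_identical(write_genepop(tab2, title = "rt"), lines)
})

test_that("calls are unordered pairs stored canonically", {
  t1 <- toy_table(matrix(c(140L, 144L), 2, 1), matrix(c(144L, 140L), 2, 1))
  expect_equal(t1$a1[, 1], c(i1 = 140L, i2 = 140L))
  expect_equal(t1$a2[, 1], c(i1 = 144L, i2 = 144L))
  expect_error(msat_table("x", matrix(1L), matrix(NA_integer_), "L1"),
               "half-missing")
})

test_that("locus subsetting reproduces the reduced panels and preserves alignment", {
  sim <- fixture_homoplasy_sim()
  tab <- sim$table
  expect_equal(length(tab$loci), 9)
  ## 9 -> 8: drop one high-null locus, individuals retained
  t8 <- subset_loci(tab, drop = "MP8894")
  expect_equal(length(t8$loci), 8)
  expect_identical(t8$individuals, tab$individuals)
  expect_identical(t8$metadata, tab$metadata)
  ## 9 -> 6: drop the diagnostic/outlier trio
  t6 <- subset_loci(tab, drop = c("MP318", "MP8450", "Mmerhk-3b"))
  expect_equal(length(t6$loci), 6)
  expect_false(any(c("MP318", "MP8450", "Mmerhk-3b") %in% t6$loci))
  ## no-op and error cases
  expect_identical(subset_loci(tab)$loci, tab$loci)
  expect_error(subset_loci(tab, drop = "nope"), "unknown locus")
  ## truth channel follows individual subsetting
  ts <- subset_individuals(tab, tab$individuals[5:10])
  expect_equal(ts$truth$hybrid_class, tab$truth$hybrid_class[5:10])
  expect_equal(ts$metadata$region, tab$metadata$region[5:10])
})

test_that("allele frequency spectra sum to one over observed support", {
  sim <- fixture_homoplasy_sim()
  af <- allele_freqs(sim$table)
  for (locus in names(af)) for (pop in names(af[[locus]])) {
    sp <- af[[locus]][[pop]]
    expect_equal(sum(sp$freq), 1, tolerance = 1e-9)
    expect_gt(sp$n_gene_copies, 0)
  }
})

test_that("metadata sidecar round-trips and validates the region vocabulary", {
  md <- data.frame(id = c("a", "b"), species = c("A", "B"),
                   region = c("SW", "N"), year = c(2012L, 2013L))
  f <- tempfile(fileext = ".tsv")
  write_metadata(md, f)
  expect_equal(read_metadata(f), md)
  md$region[1] <- "XX"
  write_metadata(md, f)
  expect_error(read_metadata(f), "region")
})
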