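test_that("heterozygosity and inbreeding match the hand-worked example", {
  ## genotypes {140/140, 140/144, 144/144, 140/144, 140/140}
  tab <- toy_table(matrix(c(140L, 140L, 144L, 140L, 140L), 5, 1),
                   matrix(c(140L, 144L, 144L, 144L, 140L), 5, 1))
  rep <- diversity_report(tab, group = rep("P", 5), n_perm = 0)
  expect_equal(rep$ho, 0.400, tolerance = 1e-12)
  expect_equal(rep$he, (10 / 9) * (1 - (0.6^2 + 0.4^2)), tolerance = 1e-12)
  expect_equal(rep$he, 0.5333, tolerance = 1e-4)
  ## Nei-form inbreeding as the cross-check oracle: 1 - Ho/He = 0.25
  expect_equal(1 - rep$ho / rep$he, 0.25, tolerance = 1e-12)
  ## the reported estimator is Weir-Cockerham f; brute-force oracle agreement
  expect_equal(rep$fis, oracle_fis_wc(table_to_genolist(tab)), tolerance = 1e-12)
  expect_equal(rep$na, 2)
})

test_that("monomorphic loci report He = Ho = 0 and undefined FIS", {
  tab <- toy_table(matrix(100L, 6, 1), matrix(100L, 6, 1))
  rep <- diversity_report(tab, group = rep("P", 6), n_perm = 100)
  expect_equal(rep$he, 0)
  expect_equal(rep$ho, 0)
  expect_true(is.na(rep$fis))
  expect_true(is.na(rep$fis_p))
})

test_that("rarefaction allelic richness obeys its identities", {
  counts <- c(6, 3, 1)          # 10 gene copies, 3 alleles
  expect_equal(allelic_richness(counts, 10), 3)        # g = 2N recovers Na
  expect_lt(allelic_richness(counts, 4), 3)            # rarefying loses alleles
  expect_gt(allelic_richness(counts, 4), 1)
  expect_error(allelic_richness(counts, 12), "exceeds")
  ## report-level: AR <= Na everywhere on real-ish data
  sim <- fixture_homoplasy_sim()
  rep <- diversity_report(sim$table, n_perm = 0)
  expect_true(all(rep$ar <= rep$na + 1e-9))
  expect_true(all(rep$he >= 0 & rep$he <= 1))
  expect_true(all(rep$ho >= 0 & rep$ho <= 1))
  expect_true(all(is.na(rep$fis) | (rep$fis >= -1 & rep$fis <= 1)))
})

test_that("null-allele EM recovers the simulated null frequency", {
  p <- fixture_profile()
  set.seed(33)
  tab <- sample_pure_genotypes(p, "B", 500)
  em <- null_allele_em(tab, "MP8894")
  expect_true(em$converged)
  expect_lt(abs(em$null_freq - p$loci$MP8894$null_b), 0.04)
  expect_equal(sum(em$visible_freq), 1, tolerance = 1e-9)
  ## clean locus: estimate collapses to ~0
  tabc <- sample_pure_genotypes(p, "B", 500, use_nulls = FALSE)
  emc <- null_allele_em(tabc, "MP8748")
  expect_lt(emc$null_freq, 0.02)
})

test_that("diversity statistics are invariant under allele relabelling", {
  p <- fixture_profile()
  set.seed(35)
  tab <- sample_pure_genotypes(p, "A", 80, use_nulls = FALSE)
  shifted <- msat_table(tab$individuals, tab$a1 + 10L, tab$a2 + 10L, tab$loci,
                        metadata = tab$metadata)
  r1 <- diversity_report(tab, group = rep("A", 80), n_perm = 0)
  r2 <- diversity_report(shifted, group = rep("A", 80), n_perm = 0)
  expect_equal(r1$he, r2$he)
  expect_equal(r1$ho, r2$ho)
  expect_equal(r1$fis, r2$fis)
  expect_equal(r1$ar, r2$ar)
})

test_that("haplotype and nucleotide diversity match hand arithmetic", {
  base <- strrep("A", 406)
  mut <- paste0("C", substr(base, 2, 406))
  ## ten sequences, two equifrequent haplotypes differing at 1 of 406 sites
  aln <- seq_alignment(setNames(c(rep(base, 5), rep(mut, 5)),
                                paste0("s", 1:10)), marker = "CR")
  d <- mtdna_diversity(aln)
  expect_equal(d$n_haplotypes, 2)
  expect_equal(d$h, (10 / 9) * 0.5, tolerance = 1e-12)
  expect_equal(d$pi, 0.5 * (1 / 406), tolerance = 1e-9)

  ## all identical
  d1 <- mtdna_diversity(seq_alignment(setNames(rep(base, 4), paste0("s", 1:4))))
  expect_equal(d1$n_haplotypes, 1)
  expect_equal(d1$h, 0)
  expect_equal(d1$pi, 0)

  ## all unique: unbiased h reaches 1
  uniq <- vapply(1:6, function(i) {
    s <- strsplit(base, "")[[1]]; s[i * 3] <- "G"; paste(s, collapse = "")
  }, character(1))
  d2 <- mtdna_diversity(seq_alignment(setNames(uniq, paste0("u", 1:6))))
  expect_equal(d2$h, 1, tolerance = 1e-12)

  ## single sequence: 0 by convention
  d3 <- mtdna_diversity(seq_alignment(c(only = base)))
  expect_equal(d3$h, 0)
  expect_equal(d3$pi, 0)

  ## N-containing sequences collapse onto compatible haplotypes
  withN <- paste0("N", substr(base, 2, 406))
  d4 <- mtdna_diversity(seq_alignment(setNames(c(base, base, withN),
                                               paste0("x", 1:3))))
  expect_equal(d4$n_haplotypes, 1)
})

test_that("simulated mtDNA pools land near their diversity targets", {
  sim <- fixture_homoplasy_sim()
  truth <- sim$table$truth$true_species
  d <- mtdna_diversity(sim$cr, group = truth)
  hA <- d$h[d$population == "A"]; hB <- d$h[d$population == "B"]
  expect_equal(hA, 0.541, tolerance = 0.12)
  expect_equal(hB, 0.893, tolerance = 0.12)
  expect_gt(d$pi[d$population == "B"], d$pi[d$population == "A"])
})
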