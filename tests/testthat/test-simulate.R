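test_that("pure genotypes follow Hardy-Weinberg when null alleles are off", {
  p <- fixture_profile()
  set.seed(21)
  tab <- sample_pure_genotypes(p, "A", 500, use_nulls = FALSE)
  rep <- diversity_report(tab, group = rep("A", 500), n_perm = 0)
  ## observed Ho tracks unbiased He within binomial error at n = 500
  expect_true(all(abs(rep$ho - rep$he) < 0.06))
  expect_equal(sum(is.na(tab$a1)), 0)
})

test_that("null alleles create apparent missingness at rate ~ r^2", {
  p <- fixture_profile()
  r <- p$loci$MP8894$null_b       # 0.2286, the strongest null in the template
  set.seed(22)
  tab <- sample_pure_genotypes(p, "B", 4000)
  miss <- mean(is.na(tab$a1[, "MP8894"]))
  expect_lt(abs(miss - r^2), 0.012)
  ## and a matching homozygote excess at that locus
  rep <- diversity_report(subset_loci(tab, keep = "MP8894"),
                          group = rep("B", 4000), n_perm = 0)
  expect_gt(rep$he - rep$ho, 0.1)
})

test_that("simulation is reproducible under a fixed seed", {
  p <- fixture_profile()
  cfg <- scenario_config("homoplasy", n_a = 40, n_b = 40, seed = 5)
  s1 <- simulate_dataset(p, cfg)
  s2 <- simulate_dataset(p, cfg)
  expect_identical(s1$table$a1, s2$table$a1)
  expect_identical(s1$cr$sequences, s2$cr$sequences)
  expect_identical(s1$flanking$sequences, s2$flanking$sequences)
})

test_that("mislabel injection flips the stated fraction and keeps the truth", {
  p <- fixture_profile()
  set.seed(30)
  tab <- rbind_tables(sample_pure_genotypes(p, "A", 569),
                      sample_pure_genotypes(p, "B", 568))
  t0 <- inject_mislabels(tab, 0, seed = 1)
  expect_identical(t0$metadata$species, tab$metadata$species)
  t1 <- inject_mislabels(tab, 1, seed = 1)
  expect_true(all(t1$metadata$species != tab$metadata$species))
  ## survey-scale rate: ~47 of 1137 expected, binomial 99.9% bounds
  tr <- inject_mislabels(tab, 0.0413, seed = 2)
  flips <- sum(tr$truth$mislabelled)
  expect_gt(flips, 25)
  expect_lt(flips, 72)
  ## truth channel still knows the origin
  expect_true(all(tr$truth$true_species %in% c("A", "B")))
  flipped <- which(tr$truth$mislabelled)
  expect_true(all(tr$metadata$species[flipped] != tr$truth$true_species[flipped]))
})

test_that("flanking haplotypes separate homoplasy from true hybridization", {
  sim <- fixture_homoplasy_sim()
  verd <- flanking_verdicts(sim$flanking)
  ## homoplasy scenario: nobody is heterozygous at diagnostic positions,
  ## including carriers of the shared convergent allele
  expect_true(all(verd$verdict == "OWN-SPECIES"))
  expect_true(all(verd$n_het_diagnostic == 0))
  carriers <- sim$table$individuals[
    !is.na(sim$table$a1[, "Mmerhk-3b"]) &
      (sim$table$a1[, "Mmerhk-3b"] %in% c(227, 241) |
         sim$table$a2[, "Mmerhk-3b"] %in% c(227, 241))]
  expect_gt(length(carriers), 0)
  expect_true(all(verd$verdict[verd$id %in% carriers] == "OWN-SPECIES"))

  ## hybridization scenario: every true F1 is heterozygous at all six
  p <- fixture_profile()
  cfg <- scenario_config("hybridization", n_a = 40, n_b = 40,
                         hybrid_fractions = c(F1 = 0.1), seed = 77,
                         mislabel_rate = 0)
  hs <- simulate_dataset(p, cfg)
  f1 <- hs$table$individuals[hs$table$truth$hybrid_class == "F1"]
  expect_gt(length(f1), 0)
  vf <- flanking_verdicts(hs$flanking, ids = f1)
  expect_true(all(vf$verdict == "HYBRID"))
  expect_true(all(vf$n_het_diagnostic == 6))
})

test_that("mtDNA follows the maternal species and mislabels create apparent discordance", {
  sim <- fixture_homoplasy_sim()
  mt <- assign_mtdna_species(sim$cr, sim$profile)
  expect_identical(unname(mt), sim$table$truth$mother_species)
  mism <- which(sim$table$truth$mislabelled)
  expect_true(all(mt[mism] != sim$table$metadata$species[mism]))
})

test_that("exports carry no trace of the truth channel", {
  p <- fixture_profile()
  cfg <- scenario_config("hybridization", n_a = 30, n_b = 30,
                         hybrid_fractions = c(F1 = 0.1, F2 = 0.05), seed = 9)
  sim <- simulate_dataset(p, cfg)
  gp <- write_genepop(sim$table)
  expect_false(any(grepl("F1|F2|Bc|Pure|hybrid", gp)))
  expect_false(any(grepl("F1|F2|Bc", names(sim$flanking$sequences))))
})
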