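test_that("class ancestry distributions are the Mendelian ones", {
  phi <- hybrid_class_phi()
  expect_equal(rowSums(phi), setNames(rep(1, 6), rownames(phi)))
  expect_equal(unname(phi["PureA", ]), c(1, 0, 0))
  expect_equal(unname(phi["PureB", ]), c(0, 0, 1))
  expect_equal(unname(phi["F1", ]), c(0, 1, 0))
  expect_equal(unname(phi["F2", ]), c(1 / 4, 1 / 2, 1 / 4))
  expect_equal(unname(phi["BcA", ]), c(1 / 2, 1 / 2, 0))
  expect_equal(unname(phi["BcB", ]), c(0, 1 / 2, 1 / 2))
  ## implied heterozygosity at a fixed-difference locus (likelihood unit)
  expect_equal(unname(phi[c("F1", "F2", "BcA"), "AB"]), c(1, 1 / 2, 1 / 2))
})

test_that("simulated classes obey exact Mendelian ratios at a fixed-difference locus", {
  fa <- list(L = c(`100` = 1))
  fb <- list(L = c(`200` = 1))
  ## F1: always heterozygous A-allele/B-allele
  f1 <- simulate_class("F1", fa, fb, 200, seed = 6)
  expect_true(all(f1$a1[, 1] == 100 & f1$a2[, 1] == 200))
  ## F2 at n = 10000: 1:2:1 within multinomial error (chi-square alpha 0.01)
  f2 <- simulate_class("F2", fa, fb, 10000, seed = 6)
  gt <- paste(f2$a1[, 1], f2$a2[, 1])
  counts <- c(sum(gt == "100 100"), sum(gt == "100 200"), sum(gt == "200 200"))
  expect_gt(stats::chisq.test(counts, p = c(1, 2, 1) / 4)$p.value, 0.01)
  ## BcA at n = 10000: 1:1 AA:AB and zero BB
  bca <- simulate_class("BcA", fa, fb, 10000, seed = 7)
  gtb <- paste(bca$a1[, 1], bca$a2[, 1])
  expect_equal(sum(gtb == "200 200"), 0)
  cb <- c(sum(gtb == "100 100"), sum(gtb == "100 200"))
  expect_gt(stats::chisq.test(cb, p = c(1, 1) / 2)$p.value, 0.01)
})

test_that("per-locus allele-origin proportions converge to phi", {
  ## two diagnostic loci let us read the origin off the allele size
  fa <- list(L1 = c(`100` = 0.5, `102` = 0.5), L2 = c(`140` = 1))
  fb <- list(L1 = c(`200` = 0.5, `202` = 0.5), L2 = c(`240` = 1))
  set.seed(8)
  for (cls in c("F2", "BcA", "BcB")) {
    sim <- simulate_class(cls, fa, fb, 10000)
    from_a <- (sim$a1[, 2] == 140) + (sim$a2[, 2] == 140)
    counts <- c(sum(from_a == 2), sum(from_a == 1), sum(from_a == 0))
    want <- hybrid_class_phi()[cls, ]
    keep <- want > 0
    expect_gt(stats::chisq.test(counts[keep], p = want[keep])$p.value, 0.01)
    if (any(!keep)) expect_equal(sum(counts[!keep]), 0)
  }
})

test_that("simulated pure genotypes keep the source heterozygosity", {
  p <- fixture_profile()
  fa <- lapply(p$loci, `[[`, "freq_a")
  fb <- lapply(p$loci, `[[`, "freq_b")
  pa <- simulate_class("PureA", fa, fb, 400, seed = 9)
  rep <- diversity_report(pa, group = rep("A", 400), n_perm = 0)
  he_src <- vapply(fa, function(f) 1 - sum(f^2), numeric(1))
  expect_true(all(abs(rep$he - he_src[rep$locus]) < 0.06))
  ## no missing data in panels, by construction
  expect_equal(sum(is.na(pa$a1)), 0)
})

test_that("reference selection honours the ancestry cut-off and sample size", {
  sim <- fixture_homoplasy_sim()
  n <- length(sim$table$individuals)
  q <- cbind(ifelse(sim$table$metadata$species == "A", 0.98, 0.02), 0)
  q[, 2] <- 1 - q[, 1]
  ## plant two boundary individuals just below the cut-off
  ia <- which(sim$table$metadata$species == "A")[1]
  q[ia, ] <- c(0.89, 0.11)
  anc <- fake_ancestry(q)
  rownames(anc$q) <- sim$table$individuals
  refs <- select_reference_pure(sim$table, anc, n_per_species = 50,
                                q_cut = 0.9, seed = 3)
  expect_equal(length(refs$A$individuals), 50)
  expect_equal(length(refs$B$individuals), 50)
  expect_false(sim$table$individuals[ia] %in% refs$A$individuals)
  ## reproducible under the seed
  refs2 <- select_reference_pure(sim$table, anc, n_per_species = 50,
                                 q_cut = 0.9, seed = 3)
  expect_identical(refs$A$individuals, refs2$A$individuals)
  ## shortfall errors
  expect_error(select_reference_pure(sim$table, anc, n_per_species = 5000),
               "reach q")
})

test_that("panel construction gives requested counts with disjoint ID spaces", {
  sim <- fixture_homoplasy_sim()
  q <- cbind(ifelse(sim$table$metadata$species == "A", 0.99, 0.01), 0)
  q[, 2] <- 1 - q[, 1]
  anc <- fake_ancestry(q)
  rownames(anc$q) <- sim$table$individuals
  pan <- build_panel(sim$table, anc, per_class_n = 20, n_ref = 30, seed = 5)
  cls <- pan$panel$truth$hybrid_class
  expect_equal(sum(cls %in% c("F1", "F2", "BcA", "BcB")), 80)
  expect_equal(unname(table(cls)[c("F1", "F2", "BcA", "BcB")]),
               rep(20L, 4), ignore_attr = TRUE)
  expect_equal(sum(cls == "PureA"), 30)
  expect_false(anyDuplicated(pan$panel$individuals) > 0)
  ## empty panel
  pan0 <- build_panel(sim$table, anc, per_class_n = 0, n_ref = 10,
                      include_refs = FALSE, seed = 5)
  expect_equal(length(pan0$panel$individuals), 0)
  ## deterministic
  pan2 <- build_panel(sim$table, anc, per_class_n = 20, n_ref = 30, seed = 5)
  expect_identical(pan$panel$a1, pan2$panel$a1)
})
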