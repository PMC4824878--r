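test_that("Weir-Cockerham theta matches the brute-force oracle to 1e-12", {
  ## toy 2-pop, 1-locus table: pop1 90xA,10xB gene copies; pop2 reversed
  mk <- function(n_a, n_b) {
    copies <- c(rep(300L, n_a), rep(302L, n_b))
    matrix(copies, ncol = 2, byrow = FALSE)
  }
  g1 <- mk(90, 10); g2 <- mk(10, 90)
  t1 <- toy_table(g1[, 1, drop = FALSE], g1[, 2, drop = FALSE])
  t2 <- toy_table(g2[, 1, drop = FALSE], g2[, 2, drop = FALSE])
  got <- fst_wc(t1, t2, n_perm = 0)$theta
  want <- oracle_theta_wc(list(g1), list(g2))
  expect_equal(got, want, tolerance = 1e-12)

  ## multilocus, unequal n, missing data, on simulated data
  p <- fixture_profile()
  set.seed(41)
  ta <- sample_pure_genotypes(p, "A", 45, missing_rate = 0.05)
  tb <- sample_pure_genotypes(p, "B", 60, missing_rate = 0.05)
  got2 <- fst_wc(ta, tb, n_perm = 0)$theta
  want2 <- oracle_theta_wc(table_to_genolist(ta), table_to_genolist(tb))
  expect_equal(got2, want2, tolerance = 1e-12)
})

test_that("theta behaves at the boundaries of differentiation", {
  p <- fixture_profile()
  set.seed(42)
  ## same spectrum -> no differentiation
  ta <- sample_pure_genotypes(p, "A", 500, use_nulls = FALSE)
  tb <- sample_pure_genotypes(p, "A", 500, use_nulls = FALSE)
  tb$metadata$species <- "B"
  expect_lt(abs(fst_wc(ta, tb, n_perm = 0)$theta), 0.01)
  ## fixed differences everywhere -> theta near 1
  f1 <- toy_table(matrix(100L, 200, 2)[, 1, drop = FALSE],
                  matrix(100L, 200, 2)[, 2, drop = FALSE])
  f2 <- toy_table(matrix(200L, 200, 2)[, 1, drop = FALSE],
                  matrix(200L, 200, 2)[, 2, drop = FALSE])
  expect_gt(fst_wc(f1, f2, n_perm = 0)$theta, 0.99)
  ## monomorphic locus contributes nothing, never NaN
  both <- cbind(matrix(c(100L, 200L), 10, 1), matrix(150L, 10, 1))
  ta2 <- toy_table(both, both, loci = c("v", "mono"))
  tb2 <- toy_table(both[, 2:1], both[, 2:1], loci = c("v", "mono"))
  th <- fst_wc(ta2, tb2, n_perm = 0)
  expect_true(is.finite(th$theta))
})

test_that("ENA-corrected theta equals uncorrected exactly when no nulls are estimated", {
  ## clean HWE data with no missing calls: every EM estimate is ~0
  p <- fixture_profile()
  set.seed(43)
  ta <- sample_pure_genotypes(p, "A", 120, use_nulls = FALSE)
  tb <- sample_pure_genotypes(p, "B", 120, use_nulls = FALSE)
  wc <- fst_wc(ta, tb, n_perm = 0)
  ## every per-locus EM null estimate is ~0 on clean data; the corrected
  ## estimator must then coincide with the uncorrected one exactly
  em_max <- max(vapply(ta$loci, function(l)
    max(null_allele_em(ta, l)$null_freq, null_allele_em(tb, l)$null_freq),
    numeric(1)))
  expect_lt(em_max, 0.05)
  ena <- fst_ena(ta, tb, null_tol = em_max + 1e-9)
  expect_identical(ena$theta, wc$theta)
  expect_identical(ena$per_locus, wc$per_locus)
  ## with nulls on, the corrected estimate is defined wherever uncorrected is
  ta2 <- sample_pure_genotypes(p, "A", 120)
  tb2 <- sample_pure_genotypes(p, "B", 120)
  ena2 <- fst_ena(ta2, tb2)
  expect_true(is.finite(ena2$theta))
  expect_equal(is.na(ena2$per_locus), is.na(fst_wc(ta2, tb2, n_perm = 0)$per_locus))
})

test_that("FIS matches the brute-force oracle on multilocus data", {
  p <- fixture_profile()
  set.seed(44)
  tab <- sample_pure_genotypes(p, "B", 50)
  rep <- diversity_report(tab, group = rep("B", 50), n_perm = 0)
  ## multilocus oracle vs per-locus report recombined
  for (l in seq_along(tab$loci)) {
    got <- rep$fis[rep$locus == tab$loci[l]]
    want <- oracle_fis_wc(table_to_genolist(tab)[l])
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("permutation p-value of theta is significant for real structure only", {
  p <- fixture_profile()
  set.seed(45)
  ta <- sample_pure_genotypes(p, "A", 50, use_nulls = FALSE)
  tb <- sample_pure_genotypes(p, "B", 50, use_nulls = FALSE)
  expect_lt(fst_wc(ta, tb, n_perm = 99, seed = 2)$p_value, 0.05)
  ta2 <- sample_pure_genotypes(p, "A", 50, use_nulls = FALSE)
  tb2 <- sample_pure_genotypes(p, "A", 50, use_nulls = FALSE)
  expect_gt(fst_wc(ta2, tb2, n_perm = 99, seed = 2)$p_value, 0.05)
})

test_that("linkage test finds self-association and not independent loci", {
  p <- fixture_profile()
  set.seed(46)
  tab <- sample_pure_genotypes(p, "A", 120, use_nulls = FALSE)
  ## locus against itself: maximal association, minimal attainable p
  self <- ld_test(tab, c("MP8748", "MP8748"), n_perm = 199, seed = 3)
  expect_equal(self$p_value, 1 / 200, tolerance = 1e-12)
  ## independently simulated loci: no association at a fixed seed
  ind <- ld_test(tab, c("MP8748", "Mmerhk-20"), n_perm = 199, seed = 3)
  expect_gt(ind$p_value, 0.05)
  ## too few shared individuals -> NA with warning
  small <- subset_individuals(tab, tab$individuals[1:5])
  expect_warning(res <- ld_test(small, c("MP8748", "Mmerhk-20"), n_perm = 10),
                 "fewer than 10")
  expect_true(is.na(res$p_value))
})

test_that("LD permutation p-values are uniform under independence", {
  p <- fixture_profile()
  set.seed(47)
  pvals <- vapply(1:60, function(i) {
    tab <- sample_pure_genotypes(p, "A", 40, use_nulls = FALSE)
    ld_test(tab, c("MP51", "MP374"), n_perm = 59, seed = i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(pvals <= 0.05), 0.15)
})

test_that("allele-dosage PCA separates the species and centres its axes", {
  p <- fixture_profile()
  set.seed(48)
  ta <- sample_pure_genotypes(p, "A", 60)
  tb <- sample_pure_genotypes(p, "B", 60)
  tab <- rbind_tables(ta, tb)
  pc <- pca_allele_freq(tab)
  sp <- tab$metadata$species
  centred <- colMeans(pc$scores)
  expect_true(all(abs(centred) < 1e-8))
  d <- abs(mean(pc$scores[sp == "A", 1]) - mean(pc$scores[sp == "B", 1]))
  sdw <- sqrt(mean(c(var(pc$scores[sp == "A", 1]), var(pc$scores[sp == "B", 1]))))
  expect_gt(d / sdw, 4)
  ## species-A centroid forced negative on axis 1
  expect_lt(mean(pc$scores[sp == "A", 1]), 0)
  ## duplicated individuals map to identical coordinates
  rows <- c(1, 1, 2)
  dup <- msat_table(c("a", "b", "c"), tab$a1[rows, ], tab$a2[rows, ], tab$loci)
  pc2 <- pca_allele_freq(dup)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ], tolerance = 1e-9)
})
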