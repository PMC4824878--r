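# Small panels with diagnostic loci let short chains resolve ancestry.

mini_panel <- function(n_pure = 25, n_f1 = 0, seed = 61) {
  fa <- list(L1 = c(`100` = 0.6, `102` = 0.4), L2 = c(`140` = 0.7, `142` = 0.3),
             L3 = c(`180` = 0.5, `182` = 0.5))
  fb <- list(L1 = c(`200` = 0.6, `202` = 0.4), L2 = c(`240` = 0.7, `242` = 0.3),
             L3 = c(`280` = 0.5, `282` = 0.5))
  set.seed(seed)
  parts <- list(simulate_class("PureA", fa, fb, n_pure),
                simulate_class("PureB", fa, fb, n_pure))
  if (n_f1 > 0) parts <- c(parts, list(simulate_class("F1", fa, fb, n_f1)))
  Reduce(rbind_tables, parts)
}

quick_spec <- function(...) {
  admixture_spec(burnin = 300, steps = 1200, thin = 4, n_runs = 2, seed = 31, ...)
}

test_that("pure individuals get decisive own-cluster ancestry with separated intervals", {
  tab <- mini_panel()
  anc <- run_admixture(tab, quick_spec(admixture = FALSE))
  cls <- tab$truth$hybrid_class
  ## q rows sum to one
  expect_equal(unname(rowSums(anc$q)), rep(1, nrow(anc$q)), tolerance = 1e-9)
  expect_true(all(anc$q[cls == "PureA", 1] >= 0.9))
  expect_true(all(anc$q[cls == "PureB", 2] >= 0.9))
  ## intervals lie inside [0,1] and bracket the posterior mean
  expect_true(all(anc$ci_lo >= 0 & anc$ci_hi <= 1))
  expect_true(all(anc$ci_lo <= anc$q + 1e-9 & anc$q <= anc$ci_hi + 1e-9))
  ## species-A and species-B interval bands do not overlap on component 1
  expect_gt(min(anc$ci_lo[cls == "PureA", 1]), max(anc$ci_hi[cls == "PureB", 1]))
})

test_that("F1 ancestry is near one half under the admixture model", {
  tab <- mini_panel(n_pure = 30, n_f1 = 12)
  anc <- run_admixture(tab, quick_spec(admixture = TRUE))
  f1 <- tab$truth$hybrid_class == "F1"
  expect_true(all(abs(anc$q[f1, 1] - 0.5) < 0.15))
  expect_equal(unname(rowSums(anc$q)), rep(1, nrow(anc$q)), tolerance = 1e-9)
})

test_that("the correlated-frequency variant still separates the species", {
  tab <- mini_panel()
  anc <- run_admixture(tab, quick_spec(admixture = TRUE, correlated = TRUE))
  cls <- tab$truth$hybrid_class
  expect_gt(mean(anc$q[cls == "PureA", 1]), 0.85)
  expect_lt(mean(anc$q[cls == "PureB", 1]), 0.15)
})

test_that("run alignment undoes label switching and averaging reduces noise", {
  q <- matrix(c(0.9, 0.8, 0.1, 0.2), 4, 1)
  q <- cbind(q, 1 - q)
  samples <- array(rep(q, 3), c(4, 2, 3))
  run1 <- list(q = q, ci_lo = q - 0.05, ci_hi = q + 0.05, samples = samples)
  flipped <- list(q = q[, 2:1], ci_lo = q[, 2:1] - 0.05, ci_hi = q[, 2:1] + 0.05,
                  samples = samples[, 2:1, , drop = FALSE])
  comb <- align_runs(list(run1, flipped))
  expect_equal(comb$q, q, tolerance = 1e-12)
  ## identical runs average to themselves
  comb2 <- align_runs(list(run1, run1))
  expect_equal(comb2$q, q, tolerance = 1e-12)
  ## combined estimate lies within the per-run spread
  noisy <- lapply(1:5, function(i) {
    qq <- pmin(pmax(q + matrix(stats::rnorm(8, 0, 0.02), 4, 2), 0), 1)
    qq <- qq / rowSums(qq)
    list(q = qq, ci_lo = qq - 0.05, ci_hi = qq + 0.05,
         samples = array(rep(qq, 3), c(4, 2, 3)))
  })
  combn_ <- align_runs(noisy)
  qs <- sapply(noisy, function(r) r$q[1, 1])
  expect_gte(combn_$q[1, 1], min(qs))
  expect_lte(combn_$q[1, 1], max(qs))
  ## inconsistent individual sets refuse to combine
  bad <- list(q = q[1:3, ], ci_lo = q[1:3, ], ci_hi = q[1:3, ],
              samples = samples[1:3, , , drop = FALSE])
  expect_error(align_runs(list(run1, bad)), "inconsistent")
})

test_that("chains are reproducible and robust to doubled length", {
  tab <- mini_panel()
  a1 <- run_admixture(tab, quick_spec(admixture = TRUE))
  a2 <- run_admixture(tab, quick_spec(admixture = TRUE))
  expect_identical(a1$q, a2$q)
  long <- run_admixture(tab, admixture_spec(admixture = TRUE, burnin = 300,
                                            steps = 2400, thin = 4,
                                            n_runs = 2, seed = 31))
  expect_lt(max(abs(a1$q - long$q)), 0.02)
})
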