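# Six diagnostic loci give the category likelihoods enough information for
# short chains.

diag_panel <- function(n_pure = 20, n_f1 = 10, n_f2 = 0, seed = 71) {
  fa <- lapply(1:6, function(i) setNames(c(0.7, 0.3), c(100 + 10 * i, 102 + 10 * i)))
  fb <- lapply(1:6, function(i) setNames(c(0.7, 0.3), c(200 + 10 * i, 202 + 10 * i)))
  names(fa) <- names(fb) <- paste0("L", 1:6)
  set.seed(seed)
  parts <- list(simulate_class("PureA", fa, fb, n_pure),
                simulate_class("PureB", fa, fb, n_pure))
  if (n_f1 > 0) parts <- c(parts, list(simulate_class("F1", fa, fb, n_f1)))
  if (n_f2 > 0) parts <- c(parts, list(simulate_class("F2", fa, fb, n_f2)))
  Reduce(rbind_tables, parts)
}

nh_quick <- function(...) newhybrids_spec(burnin = 400, steps = 1600, thin = 4,
                                          n_runs = 2, seed = 17, ...)

test_that("diagnostic-locus F1 individuals get decisive F1 posteriors", {
  tab <- diag_panel()
  nh <- run_newhybrids(tab, nh_quick())
  cls <- tab$truth$hybrid_class
  ## posterior rows are distributions
  expect_equal(unname(rowSums(nh$prob)), rep(1, nrow(nh$prob)), tolerance = 1e-9)
  expect_true(all(nh$prob[cls == "F1", "F1"] > 0.9))
  expect_true(all(nh$map[cls == "F1"] == "F1"))
  ## pure individuals are dominated by their pure class
  expect_true(all(nh$prob[cls == "PureA", "PureA"] > 0.5))
  expect_true(all(nh$prob[cls == "PureB", "PureB"] > 0.5))
  expect_true(all(nh$map[cls %in% c("PureA", "PureB")] %in% c("PureA", "PureB")))
  ## the q < 0.5 rule flags the F1s and not the pures
  expect_true(all(nh$is_hybrid[cls == "F1"]))
  expect_false(any(nh$is_hybrid[cls %in% c("PureA", "PureB")]))
})

test_that("six-class posteriors are reproducible and jeffreys/uniform priors agree broadly", {
  tab <- diag_panel(n_pure = 15, n_f1 = 8)
  nh1 <- run_newhybrids(tab, nh_quick())
  nh2 <- run_newhybrids(tab, nh_quick())
  expect_identical(nh1$prob, nh2$prob)
  nhu <- run_newhybrids(tab, nh_quick(prior = "uniform"))
  expect_lt(max(abs(nh1$prob - nhu$prob)), 0.2)
})

test_that("threshold classification follows the stated arithmetic and CI rule", {
  q <- rbind(c(0.95, 0.05), c(0.85, 0.15), c(0.75, 0.25), c(0.5, 0.5))
  lo <- rbind(c(0.90, 0.00), c(0.60, 0.00), c(0.60, 0.12), c(0.40, 0.40))
  hi <- rbind(c(1.00, 0.10), c(1.00, 0.40), c(0.88, 0.40), c(0.60, 0.60))
  anc <- fake_ancestry(q, lo, hi)
  calls <- classify_hybrids(anc, thresholds = c(0.1, 0.2), pure_band = 0.05)
  ## q = (0.95, 0.05): pure at both thresholds
  expect_false(calls$admixed_q0.1[1]); expect_false(calls$admixed_q0.2[1])
  ## q = (0.85, 0.15): admixed at 0.1, pure at 0.2
  expect_true(calls$admixed_q0.1[2]); expect_false(calls$admixed_q0.2[2])
  ## interval (0.00, 0.40) overlaps the pure band: not retained
  expect_false(calls$retained[2])
  ## interval (0.12, 0.40) clears the band: retained
  expect_true(calls$retained[3])
  ## boundary: exactly at threshold counts as admixed
  expect_true(calls$admixed_q0.2[4])
  ## calls at 0.2 are a subset of calls at 0.1 -- also under random ancestry
  set.seed(81)
  qr <- matrix(stats::runif(200), 100, 2); qr <- qr / rowSums(qr)
  cr <- classify_hybrids(fake_ancestry(qr), thresholds = c(0.1, 0.2))
  expect_true(all(!cr$admixed_q0.2 | cr$admixed_q0.1))
  expect_true(all(!cr$retained | cr$admixed_q0.1))
})
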