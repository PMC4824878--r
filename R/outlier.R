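#' FST/heterozygosity outlier scan under a stepwise-mutation island model
#'
#' Simulates neutral loci in a finite island model (forward-time, stepwise
#' mutation) with the migration rate tuned so the expected FST matches the
#' observed multilocus theta, samples two demes with the observed sample
#' sizes, and builds a neutral envelope of per-locus theta conditioned on
#' heterozygosity (equal-count He bins, [0.025, 0.975] quantiles). Observed
#' loci falling outside the envelope of their He bin are flagged.
#'
#' @param table_a,table_b [msat_table()]s over a shared locus panel.
#' @param n_sims simulated neutral loci (>= 1000).
#' @param n_demes demes in the island model (default 100).
#' @param deme_size diploid individuals per deme (default 25).
#' @param generations forward generations simulated (default 200).
#' @param n_bins He bins for the envelope (default 20).
#' @param alpha two-sided flagging level (default 0.05).
#' @param seed seed.
#' @return list: `loci` (data frame per observed locus: he, theta, lower,
#'   upper, outlier in {"high","low","no"}), `sims` (simulated he/theta),
#'   `m` (tuned migration rate), `theta_target`.
#' @export
fdist_outlier_scan <- function(table_a, table_b, n_sims = 5000, n_demes = 100,
                               deme_size = 25, generations = 200, n_bins = 20,
                               alpha = 0.05, seed = 1) {
  if (n_sims < 1000) stop("n_sims must be at least 1000")
  stopifnot(identical(table_a$loci, table_b$loci))
  set.seed(as.integer(seed))

  obs <- fst_wc(table_a, table_b, n_perm = 0)
  theta_target <- obs$theta
  if (!is.finite(theta_target) || theta_target <= 0 || theta_target >= 1)
    stop(sprintf("cannot tune island model to target theta = %s", format(theta_target)))
  ## island-model equilibrium: FST ~ 1 / (1 + 4Nm (d/(d-1))^2)
  m <- ((1 / theta_target - 1) / (4 * deme_size)) * ((n_demes - 1) / n_demes)^2
  if (m <= 0 || m >= 1)
    stop(sprintf("tuned migration rate %.4g outside (0,1); adjust deme_size", m))

  ## observed per-locus He (pooled, weighted) and theta
  he_obs <- numeric(length(table_a$loci))
  for (l in seq_along(table_a$loci)) {
    sa <- locus_group_stats(table_a, l, seq_along(table_a$individuals))
    sb <- locus_group_stats(table_b, l, seq_along(table_b$individuals))
    if (is.null(sa) || is.null(sb)) { he_obs[l] <- NA; next }
    he_a <- 1 - sum(sa$p^2); he_b <- 1 - sum(sb$p^2)
    he_obs[l] <- (sa$n * he_a + sb$n * he_b) / (sa$n + sb$n)
  }
  n1 <- max(1, round(mean(colSums(!is.na(table_a$a1)))))
  n2 <- max(1, round(mean(colSums(!is.na(table_b$a1)))))

  copies_per_deme <- 2L * deme_size
  ncopies <- n_demes * copies_per_deme
  deme_of <- rep(seq_len(n_demes), each = copies_per_deme)
  offset <- (deme_of - 1L) * copies_per_deme

  sim_one <- function(mu) {
    ## start from equilibrium-scale dispersion (pairwise size variance ~
    ## 4*N_total*mu under SMM) so the forward phase only has to relax the
    ## island-model structure, not build diversity from a monomorphic start
    lam0 <- mu * 2 * n_demes * deme_size
    k <- stats::rpois(ncopies, lam0)
    state <- 100L + as.integer(2 * stats::rbinom(ncopies, k, 0.5) - k)
    for (g in seq_len(generations)) {
      migr <- stats::runif(ncopies) < m
      pd <- deme_of
      if (any(migr)) pd[migr] <- sample.int(n_demes, sum(migr), replace = TRUE)
      parent <- (pd - 1L) * copies_per_deme +
        sample.int(copies_per_deme, ncopies, replace = TRUE)
      state <- state[parent]
      nmut <- stats::rbinom(1, ncopies, mu)
      if (nmut > 0) {
        who <- sample.int(ncopies, nmut)
        state[who] <- state[who] + sample(c(-1L, 1L), nmut, replace = TRUE)
      }
    }
    ## sample two demes with the observed sample sizes (with replacement if needed)
    dd <- sample.int(n_demes, 2)
    take <- function(d, n) {
      pool <- state[deme_of == d]
      matrix(sample(pool, 2 * n, replace = 2 * n > length(pool)), ncol = 2)
    }
    s1 <- take(dd[1], n1); s2 <- take(dd[2], n2)
    comp <- wc_theta_components(s1[, 1, drop = FALSE], s1[, 2, drop = FALSE],
                                s2[, 1, drop = FALSE], s2[, 2, drop = FALSE])
    th <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
    p1 <- table(c(s1)) / (2 * n1); p2 <- table(c(s2)) / (2 * n2)
    he <- (n1 * (1 - sum(p1^2)) + n2 * (1 - sum(p2^2))) / (n1 + n2)
    c(he = he, theta = if (is.finite(th)) th else NA_real_)
  }

  mus <- 10^stats::runif(n_sims, -4.3, -1.4)
  sims <- t(vapply(mus, sim_one, numeric(2)))
  sims <- sims[stats::complete.cases(sims) & sims[, "he"] > 0, , drop = FALSE]
  if (nrow(sims) < 100) stop("too few informative neutral simulations; increase n_sims")

  ## equal-count He bins
  qs <- unique(stats::quantile(sims[, "he"], probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(sims[, "he"], qs, include.lowest = TRUE)
  lo_of <- tapply(sims[, "theta"], bin, stats::quantile, probs = alpha / 2, na.rm = TRUE)
  hi_of <- tapply(sims[, "theta"], bin, stats::quantile, probs = 1 - alpha / 2, na.rm = TRUE)

  res <- data.frame(locus = table_a$loci, he = he_obs,
                    theta = obs$per_locus, lower = NA_real_, upper = NA_real_,
                    outlier = "no", stringsAsFactors = FALSE)
  for (l in seq_len(nrow(res))) {
    if (is.na(res$he[l]) || is.na(res$theta[l])) next
    b <- cut(min(max(res$he[l], min(sims[, "he"])), max(sims[, "he"])),
             qs, include.lowest = TRUE)
    res$lower[l] <- lo_of[[as.character(b)]]
    res$upper[l] <- hi_of[[as.character(b)]]
    if (res$theta[l] > res$upper[l]) res$outlier[l] <- "high"
    else if (res$theta[l] < res$lower[l]) res$outlier[l] <- "low"
  }
  list(loci = res, sims = as.data.frame(sims), m = m, theta_target = theta_target)
}
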