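# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are built once per test session and memoized here.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

fixture_profile <- function() memo("profile", make_profile(seed = 3))

## small homoplasy-scenario survey reused across tests
fixture_homoplasy_sim <- function() memo("hsim", {
  simulate_dataset(fixture_profile(),
                   scenario_config("homoplasy", n_a = 120, n_b = 120,
                                   seed = 11, mislabel_rate = 0.04))
})

## tiny msat_table built by hand
toy_table <- function(a1, a2, species = NULL, loci = paste0("L", seq_len(ncol(a1)))) {
  n <- nrow(a1)
  ids <- paste0("i", seq_len(n))
  md <- data.frame(id = ids,
                   species = if (is.null(species)) rep("A", n) else species,
                   region = NA_character_, year = NA_integer_,
                   stringsAsFactors = FALSE)
  msat_table(ids, a1, a2, loci, metadata = md)
}

## -------- independent brute-force variance-components oracles --------------
## Written directly from the published component formulas with explicit
## loops; deliberately structured unlike the package implementation.

oracle_theta_wc <- function(genos1, genos2) {
  ## genos*: list of two-column matrices (one per locus) of allele sizes
  num <- 0; den <- 0
  for (l in seq_along(genos1)) {
    g1 <- genos1[[l]]; g2 <- genos2[[l]]
    g1 <- g1[!is.na(g1[, 1]), , drop = FALSE]
    g2 <- g2[!is.na(g2[, 1]), , drop = FALSE]
    n1 <- nrow(g1); n2 <- nrow(g2)
    alleles <- sort(unique(c(g1, g2)))
    if (length(alleles) < 2 || n1 == 0 || n2 == 0) next
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    for (al in alleles) {
      p1 <- sum(g1 == al) / (2 * n1)
      p2 <- sum(g2 == al) / (2 * n2)
      h1 <- 0
      for (i in seq_len(n1)) if (xor(g1[i, 1] == al, g1[i, 2] == al)) h1 <- h1 + 1
      h1 <- h1 / n1
      h2 <- 0
      for (i in seq_len(n2)) if (xor(g2[i, 1] == al, g2[i, 2] == al)) h2 <- h2 + 1
      h2 <- h2 / n2
      pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                    hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

oracle_fis_wc <- function(genos) {
  ## genos: list of two-column matrices, one population
  bsum <- 0; csum <- 0
  for (l in seq_along(genos)) {
    g <- genos[[l]]
    g <- g[!is.na(g[, 1]), , drop = FALSE]
    n <- nrow(g)
    alleles <- sort(unique(c(g)))
    if (length(alleles) < 2 || n < 2) next
    for (al in alleles) {
      p <- sum(g == al) / (2 * n)
      h <- 0
      for (i in seq_len(n)) if (xor(g[i, 1] == al, g[i, 2] == al)) h <- h + 1
      h <- h / n
      bsum <- bsum + (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      csum <- csum + h / 2
    }
  }
  1 - csum / (bsum + csum)
}

table_to_genolist <- function(tab) {
  lapply(seq_along(tab$loci), function(l) cbind(tab$a1[, l], tab$a2[, l]))
}

## minimal ancestry_result constructor for classification tests
fake_ancestry <- function(q, ci_lo = NULL, ci_hi = NULL, level = 0.9) {
  if (is.null(ci_lo)) ci_lo <- pmax(q - 0.1, 0)
  if (is.null(ci_hi)) ci_hi <- pmin(q + 0.1, 1)
  rownames(q) <- rownames(ci_lo) <- rownames(ci_hi) <- paste0("i", seq_len(nrow(q)))
  structure(list(q = q, ci_lo = ci_lo, ci_hi = ci_hi, level = level,
                 runs = list()),
            class = "ancestry_result")
}
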