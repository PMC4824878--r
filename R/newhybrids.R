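#' Specification for the six-class hybrid-category sampler
#'
#' @param prior `"jeffreys"` (Dirichlet(1/2) on allele frequencies) or
#'   `"uniform"` (Dirichlet(1)).
#' @param burnin,steps,thin MCMC schedule (defaults 50000 / 250000 / 10).
#' @param n_runs independent runs with different seeds, combined by
#'   averaging (default 5).
#' @param seed master seed; run r uses `seed + r`.
#' @param max_kept cap on retained draws per run.
#' @return list of class `newhybrids_spec`.
#' @export
newhybrids_spec <- function(prior = c("jeffreys", "uniform"),
                            burnin = 50000, steps = 250000, thin = 10,
                            n_runs = 5, seed = 7, max_kept = 2000) {
  prior <- match.arg(prior)
  stopifnot(burnin > 0, steps > 0, thin >= 1, n_runs >= 1)
  structure(list(prior = prior, burnin = burnin, steps = steps, thin = thin,
                 n_runs = n_runs, seed = seed, max_kept = max_kept),
            class = "newhybrids_spec")
}

## per-locus n x 3 genotype probabilities given pair origin (AA, AB, BB)
genotype_probs_pair <- function(pa, pb, i1, i2) {
  het <- i1 != i2
  gAA <- pa[i1] * pa[i2] * ifelse(het, 2, 1)
  gBB <- pb[i1] * pb[i2] * ifelse(het, 2, 1)
  gAB <- ifelse(het, pa[i1] * pb[i2] + pa[i2] * pb[i1], pa[i1] * pb[i1])
  cbind(AA = gAA, AB = gAB, BB = gBB)
}

newhybrids_run <- function(enc, spec, seed) {
  set.seed(as.integer(seed))
  n <- enc$n; L <- enc$L
  I1 <- enc$I1; I2 <- enc$I2
  nall <- vapply(enc$sizes, length, integer(1))
  typed <- !is.na(I1)
  phi <- hybrid_class_phi()
  C <- nrow(phi)
  classes <- rownames(phi)
  prior_a <- if (spec$prior == "jeffreys") 0.5 else 1

  total_sweeps <- spec$burnin + spec$steps
  thin <- spec$thin
  if (floor(spec$steps / thin) > spec$max_kept)
    thin <- ceiling(spec$steps / spec$max_kept)
  keep_at <- seq(spec$burnin + thin, total_sweeps, by = thin)
  n_keep <- length(keep_at)

  pA <- lapply(nall, function(a) rdirichlet1(rep(1, a)))
  pB <- lapply(nall, function(a) rdirichlet1(rep(1, a)))
  pi_mix <- rep(1 / C, C)
  cls <- sample.int(C, n, replace = TRUE)
  prob_keep <- array(NA_real_, c(n, C, n_keep))
  ki <- 0L

  for (sweep in seq_len(total_sweeps)) {
    ## class log-likelihoods and per-locus origin-pair probabilities
    ll <- matrix(0, n, C)
    G <- vector("list", L)
    for (l in seq_len(L)) {
      t <- which(typed[, l])
      g <- genotype_probs_pair(pA[[l]], pB[[l]], I1[t, l], I2[t, l])
      G[[l]] <- list(rows = t, g = g)
      lk <- g %*% t(phi)                    # |t| x C
      ll[t, ] <- ll[t, ] + log(pmax(lk, 1e-300))
    }
    ll <- sweep(ll, 2, log(pi_mix), `+`)
    ll <- ll - apply(ll, 1, max)
    W <- exp(ll); W <- W / rowSums(W)
    u <- stats::runif(n)
    cw <- t(apply(W, 1, cumsum)); cw[, C] <- 1
    cls <- max.col(u < cw, ties.method = "first")
    pi_mix <- rdirichlet1(1 + tabulate(cls, nbins = C))

    ## pair origins, phase, and allele counts
    for (l in seq_len(L)) {
      t <- G[[l]]$rows
      g <- G[[l]]$g
      pw <- phi[cls[t], , drop = FALSE] * g
      pw <- pw / rowSums(pw)
      u <- stats::runif(length(t))
      w <- ifelse(u < pw[, 1], 1L, ifelse(u < pw[, 1] + pw[, 2], 2L, 3L))
      i1 <- I1[t, l]; i2 <- I2[t, l]
      het <- i1 != i2
      ## phase for heterozygotes with one copy from each species
      pa <- pA[[l]]; pb <- pB[[l]]
      ph <- pa[i1] * pb[i2] / pmax(pa[i1] * pb[i2] + pa[i2] * pb[i1], 1e-300)
      a_from_1 <- stats::runif(length(t)) < ph
      toA <- integer(0); toB <- integer(0)
      sel <- w == 1L                       # both copies from A
      toA <- c(toA, i1[sel], i2[sel])
      sel <- w == 3L                       # both from B
      toB <- c(toB, i1[sel], i2[sel])
      sel <- w == 2L & het & a_from_1
      toA <- c(toA, i1[sel]); toB <- c(toB, i2[sel])
      sel <- w == 2L & het & !a_from_1
      toA <- c(toA, i2[sel]); toB <- c(toB, i1[sel])
      sel <- w == 2L & !het
      toA <- c(toA, i1[sel]); toB <- c(toB, i1[sel])
      pA[[l]] <- rdirichlet1(prior_a + tabulate(toA, nbins = nall[l]))
      pB[[l]] <- rdirichlet1(prior_a + tabulate(toB, nbins = nall[l]))
    }

    if (ki < n_keep && sweep == keep_at[ki + 1L]) {
      ki <- ki + 1L
      prob_keep[, , ki] <- W
    }
  }
  prob <- apply(prob_keep, c(1, 2), mean)
  colnames(prob) <- classes
  list(prob = prob, seed = seed)
}

#' Run the six-class hybrid-category sampler
#'
#' MCMC over per-individual genotype-frequency class (PureA, PureB, F1, F2,
#' BcA, BcB) and per-species allele frequencies. The genotype likelihood per
#' class mixes the three unordered two-copy origin configurations with the
#' class's ancestry distribution: `P(g | class) = phi_AA g(p_A, p_A) +
#' phi_AB g(p_A, p_B) + phi_BB g(p_B, p_B)`. Missing genotypes are
#' marginalized. Runs are combined by averaging after orienting the species
#' labels to the field labels (swapping A and B maps PureA<->PureB and
#' BcA<->BcB).
#'
#' @param table an [msat_table()].
#' @param spec a [newhybrids_spec()].
#' @return object of class `hybrid_posterior`: `prob` (n x 6 posterior class
#'   probabilities), `map` (MAP class), `p_hybrid` (posterior mass on the
#'   four hybrid classes), `is_hybrid` (pure-class posterior below 0.5),
#'   `individuals`, `runs`.
#' @export
run_newhybrids <- function(table, spec = newhybrids_spec()) {
  stopifnot(inherits(table, "msat_table"), inherits(spec, "newhybrids_spec"))
  enc <- encode_genotypes(table)
  runs <- lapply(seq_len(spec$n_runs), function(r)
    newhybrids_run(enc, spec, seed = spec$seed + r))
  sp <- table$metadata$species
  orient <- function(prob) {
    ## species-label symmetry: flip when field-A individuals carry more
    ## PureB than PureA mass
    if (!any(sp == "A", na.rm = TRUE) || !any(sp == "B", na.rm = TRUE)) return(prob)
    rows_a <- which(sp == "A")
    if (mean(prob[rows_a, "PureA"]) < mean(prob[rows_a, "PureB"])) {
      prob <- prob[, c("PureB", "PureA", "F1", "F2", "BcB", "BcA"), drop = FALSE]
      colnames(prob) <- c("PureA", "PureB", "F1", "F2", "BcA", "BcB")
    }
    prob
  }
  probs <- lapply(runs, function(r) orient(r$prob))
  prob <- Reduce(`+`, probs) / length(probs)
  rownames(prob) <- table$individuals
  map <- colnames(prob)[max.col(prob, ties.method = "first")]
  p_hyb <- rowSums(prob[, c("F1", "F2", "BcA", "BcB"), drop = FALSE])
  structure(list(prob = prob, map = map, p_hybrid = unname(p_hyb),
                 is_hybrid = unname(prob[, "PureA"] + prob[, "PureB"] < 0.5),
                 individuals = table$individuals, runs = runs, spec = spec),
            class = "hybrid_posterior")
}

#' @export
print.hybrid_posterior <- function(x, ...) {
  cat(sprintf("<hybrid_posterior> %d individuals; MAP classes: %s\n",
              nrow(x$prob),
              paste(names(table(x$map)), table(x$map), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Threshold-based hybrid calls from ancestry coefficients
#'
#' An individual is called admixed at threshold `t` when its minority
#' ancestry component is at least `t` (ties call admixed). It is *retained*
#' as a putative hybrid only when the credibility interval of the minority
#' component excludes the pure reference band `[0, pure_band]` — the
#' non-overlap rule.
#'
#' @param ancestry an `ancestry_result`.
#' @param thresholds admixture thresholds (default `c(0.1, 0.2)`).
#' @param pure_band upper edge of the pure reference band the interval must
#'   clear (default 0.05).
#' @return data frame per individual: `q_min`, `ci_lo_min`, one logical
#'   column `admixed_q<t>` per threshold, and `retained`.
#' @export
classify_hybrids <- function(ancestry, thresholds = c(0.1, 0.2), pure_band = 0.05) {
  stopifnot(inherits(ancestry, "ancestry_result"))
  q <- ancestry$q
  minc <- apply(q, 1, which.min)
  q_min <- q[cbind(seq_len(nrow(q)), minc)]
  ci_lo_min <- ancestry$ci_lo[cbind(seq_len(nrow(q)), minc)]
  out <- data.frame(id = rownames(q), q_min = q_min, ci_lo_min = ci_lo_min,
                    stringsAsFactors = FALSE)
  for (t in thresholds)
    out[[sprintf("admixed_q%g", t)]] <- q_min >= t
  ## retained hybrids are a subset of the calls at the laxest threshold
  out$retained <- (q_min >= min(thresholds)) & ci_lo_min > pure_band
  out
}
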