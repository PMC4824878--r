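#' Specification for the admixture Gibbs sampler
#'
#' The four model variants of the analysis are the crossings of
#' `admixture` x `correlated`: (i) no admixture + independent frequencies,
#' (ii) no admixture + correlated, (iii) admixture + independent,
#' (iv) admixture + correlated.
#'
#' @param k number of clusters (default 2).
#' @param admixture per-gene-copy ancestry (TRUE) or whole-individual origin
#'   (FALSE).
#' @param correlated tie cluster frequencies to an ancestral vector via the
#'   F-model with per-cluster drift.
#' @param lambda Dirichlet prior parameter for allele frequencies (default 1).
#' @param alpha_init,alpha_sd,alpha_max Dirichlet ancestry hyperparameter:
#'   initial value, Gaussian Metropolis step width, and the upper bound of
#'   its uniform prior.
#' @param f_init,f_sd drift parameter per cluster (correlated model):
#'   initial value and logit-scale Metropolis step width; uniform(0,1) prior.
#' @param burnin,steps,thin MCMC schedule (defaults 50000 / 250000 / 10;
#'   at most `max_kept` post-burnin draws are retained for interval
#'   estimation, extra thinning is applied beyond that).
#' @param n_runs independent runs combined by [align_runs()] (default 5).
#' @param ci_level equal-tailed credibility level (default 0.90).
#' @param seed master seed; run r uses `seed + r`.
#' @return list of class `admixture_spec`.
#' @export
admixture_spec <- function(k = 2, admixture = FALSE, correlated = FALSE,
                           lambda = 1, alpha_init = 1, alpha_sd = 0.25,
                           alpha_max = 10, f_init = 0.1, f_sd = 0.3,
                           burnin = 50000, steps = 250000, thin = 10,
                           n_runs = 5, ci_level = 0.90, seed = 99,
                           max_kept = 2000) {
  stopifnot(k >= 2, burnin > 0, steps > 0, thin >= 1, n_runs >= 1,
            lambda > 0, ci_level > 0, ci_level < 1)
  structure(as.list(environment()), class = "admixture_spec")
}

#' The four canonical model variants
#' @param model one of `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @param ... passed to [admixture_spec()].
#' @return an `admixture_spec`.
#' @export
model_variant <- function(model = c("i", "ii", "iii", "iv"), ...) {
  model <- match.arg(model)
  admixture_spec(admixture = model %in% c("iii", "iv"),
                 correlated = model %in% c("ii", "iv"), ...)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  s <- sum(x)
  if (s == 0) { x[which.max(alpha)] <- 1; s <- 1 }
  x / s
}

ddirichlet_log <- function(x, alpha) {
  eps <- 1e-300
  sum((alpha - 1) * log(pmax(x, eps))) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

## integer-coded genotypes: I1/I2 are n x L allele indices into sizes[[l]]
encode_genotypes <- function(table) {
  L <- length(table$loci)
  n <- length(table$individuals)
  I1 <- I2 <- matrix(NA_integer_, n, L)
  sizes <- vector("list", L)
  for (l in seq_len(L)) {
    al <- sort(unique(c(table$a1[, l], table$a2[, l])))
    al <- al[!is.na(al)]
    sizes[[l]] <- al
    I1[, l] <- match(table$a1[, l], al)
    I2[, l] <- match(table$a2[, l], al)
  }
  list(I1 = I1, I2 = I2, sizes = sizes, n = n, L = L)
}

## one MCMC run of the admixture/no-admixture sampler; returns posterior mean
## q, equal-tailed interval and the retained q draws
admixture_run <- function(enc, spec, seed) {
  set.seed(as.integer(seed))
  n <- enc$n; L <- enc$L; K <- spec$k
  I1 <- enc$I1; I2 <- enc$I2
  nall <- vapply(enc$sizes, length, integer(1))
  typed <- !is.na(I1)

  total_sweeps <- spec$burnin + spec$steps
  thin <- spec$thin
  kept_target <- floor(spec$steps / thin)
  if (kept_target > spec$max_kept)
    thin <- ceiling(spec$steps / spec$max_kept)
  keep_at <- seq(spec$burnin + thin, total_sweeps, by = thin)
  n_keep <- length(keep_at)

  ## init
  P <- lapply(seq_len(L), function(l) {
    m <- matrix(0, K, nall[l])
    for (k in seq_len(K)) m[k, ] <- rdirichlet1(rep(spec$lambda, nall[l]))
    m
  })
  pA <- lapply(seq_len(L), function(l) rdirichlet1(rep(1, nall[l])))
  Fk <- rep(spec$f_init, K)
  alpha <- spec$alpha_init
  Q <- matrix(1 / K, n, K)
  Z <- sample.int(K, n, replace = TRUE)
  O1 <- matrix(sample.int(K, n * L, replace = TRUE), n, L)
  O2 <- matrix(sample.int(K, n * L, replace = TRUE), n, L)

  q_keep <- array(NA_real_, c(n, K, n_keep))
  alpha_keep <- numeric(n_keep)
  ki <- 0L

  for (sweep in seq_len(total_sweeps)) {
    if (!spec$admixture) {
      ## whole-individual origin
      ll <- matrix(0, n, K)
      for (l in seq_len(L)) {
        t <- typed[, l]
        lp <- log(P[[l]])
        for (k in seq_len(K))
          ll[t, k] <- ll[t, k] + lp[k, I1[t, l]] + lp[k, I2[t, l]]
      }
      ll <- ll - apply(ll, 1, max)
      W <- exp(ll)
      W <- W / rowSums(W)
      u <- stats::runif(n)
      cw <- t(apply(W, 1, cumsum))
      cw[, K] <- 1
      Z <- max.col(u < cw, ties.method = "first")
      Qprob <- W
      ## allele counts per cluster
      counts <- lapply(seq_len(L), function(l) {
        m <- matrix(0, K, nall[l])
        t <- typed[, l]
        for (k in seq_len(K)) {
          sel <- t & Z == k
          m[k, ] <- tabulate(c(I1[sel, l], I2[sel, l]), nbins = nall[l])
        }
        m
      })
    } else {
      ## per-gene-copy origin
      for (l in seq_len(L)) {
        t <- which(typed[, l])
        for (copy in 1:2) {
          Ic <- if (copy == 1) I1 else I2
          W <- Q[t, , drop = FALSE]
          for (k in seq_len(K)) W[, k] <- W[, k] * P[[l]][k, Ic[t, l]]
          W <- W / rowSums(W)
          u <- stats::runif(length(t))
          cw <- W[, 1]
          o <- rep.int(K, length(t))
          done <- u < cw
          o[done] <- 1L
          if (K > 2) for (k in 2:(K - 1)) {
            cw <- cw + W[, k]
            newly <- !done & u < cw
            o[newly] <- k
            done <- done | newly
          }
          if (copy == 1) O1[t, l] <- o else O2[t, l] <- o
        }
      }
      counts <- lapply(seq_len(L), function(l) {
        m <- matrix(0, K, nall[l])
        t <- typed[, l]
        for (k in seq_len(K))
          m[k, ] <- tabulate(c(I1[t & O1[, l] == k, l], I2[t & O2[, l] == k, l]),
                             nbins = nall[l])
        m
      })
      ## q update
      Mk <- matrix(0, n, K)
      for (k in seq_len(K))
        Mk[, k] <- rowSums((O1 == k) & typed) + rowSums((O2 == k) & typed)
      G <- matrix(stats::rgamma(n * K, shape = alpha + Mk), n, K)
      Q <- G / rowSums(G)
      Qprob <- Q
      ## alpha Metropolis (uniform(0, alpha_max) prior)
      aprop <- alpha + stats::rnorm(1, 0, spec$alpha_sd)
      if (aprop > 0 && aprop < spec$alpha_max) {
        slq <- sum(log(pmax(Q, 1e-300)))
        logr <- n * (lgamma(K * aprop) - K * lgamma(aprop) -
                       lgamma(K * alpha) + K * lgamma(alpha)) +
          (aprop - alpha) * slq
        if (log(stats::runif(1)) < logr) alpha <- aprop
      }
    }

    ## frequency update
    if (!spec$correlated) {
      for (l in seq_len(L)) {
        for (k in seq_len(K))
          P[[l]][k, ] <- rdirichlet1(spec$lambda + counts[[l]][k, ])
      }
    } else {
      for (l in seq_len(L)) {
        for (k in seq_len(K)) {
          prior_k <- pA[[l]] * (1 - Fk[k]) / Fk[k]
          P[[l]][k, ] <- rdirichlet1(prior_k + counts[[l]][k, ])
        }
        ## ancestral frequency Metropolis: Dirichlet proposal around current
        conc <- 50
        prop <- rdirichlet1(conc * pA[[l]] + 0.05)
        logr <- ddirichlet_log(prop, rep(spec$lambda, nall[l])) -
          ddirichlet_log(pA[[l]], rep(spec$lambda, nall[l]))
        for (k in seq_len(K)) {
          logr <- logr +
            ddirichlet_log(P[[l]][k, ], prop * (1 - Fk[k]) / Fk[k]) -
            ddirichlet_log(P[[l]][k, ], pA[[l]] * (1 - Fk[k]) / Fk[k])
        }
        logr <- logr + ddirichlet_log(pA[[l]], conc * prop + 0.05) -
          ddirichlet_log(prop, conc * pA[[l]] + 0.05)
        if (log(stats::runif(1)) < logr) pA[[l]] <- prop
      }
      ## drift Metropolis on the logit scale, uniform(0,1) prior
      for (k in seq_len(K)) {
        lo <- stats::qlogis(Fk[k]) + stats::rnorm(1, 0, spec$f_sd)
        fp <- stats::plogis(lo)
        logr <- log(fp * (1 - fp)) - log(Fk[k] * (1 - Fk[k]))  # Jacobian
        for (l in seq_len(L)) {
          logr <- logr +
            ddirichlet_log(P[[l]][k, ], pA[[l]] * (1 - fp) / fp) -
            ddirichlet_log(P[[l]][k, ], pA[[l]] * (1 - Fk[k]) / Fk[k])
        }
        if (log(stats::runif(1)) < logr) Fk[k] <- fp
      }
    }

    if (ki < n_keep && sweep == keep_at[ki + 1L]) {
      ki <- ki + 1L
      q_keep[, , ki] <- Qprob
      alpha_keep[ki] <- alpha
    }
  }

  q_mean <- apply(q_keep, c(1, 2), mean)
  pr <- (1 - spec$ci_level) / 2
  ci_lo <- apply(q_keep, c(1, 2), stats::quantile, probs = pr)
  ci_hi <- apply(q_keep, c(1, 2), stats::quantile, probs = 1 - pr)
  list(q = q_mean, ci_lo = ci_lo, ci_hi = ci_hi, samples = q_keep,
       alpha = alpha_keep, seed = seed)
}

#' Run the Bayesian admixture sampler
#'
#' Gibbs sampler over cluster allele frequencies and individual ancestry.
#' Without admixture, a latent whole-individual origin is updated from the
#' genotype likelihood and frequencies from Dirichlet(lambda + counts); with
#' admixture, per-gene-copy origins and per-individual ancestry vectors
#' `q_i ~ Dirichlet(alpha)` are sampled, with `alpha` updated by Metropolis
#' under a uniform(0, 10) prior. The correlated-frequency variant ties
#' cluster frequencies to an ancestral vector through the F-model with
#' per-cluster drift updated by Metropolis. Missing genotypes contribute
#' nothing to the likelihood. Multiple runs are aligned and averaged by
#' [align_runs()]; cluster 1 is oriented to species A using the field labels
#' when available.
#'
#' @param table an [msat_table()].
#' @param spec an [admixture_spec()].
#' @return object of class `ancestry_result`: posterior mean `q` (n x K),
#'   `ci_lo`/`ci_hi` equal-tailed bounds, `level`, `runs` (per-run results),
#'   `spec`, `individuals`.
#' @export
run_admixture <- function(table, spec = admixture_spec()) {
  stopifnot(inherits(table, "msat_table"), inherits(spec, "admixture_spec"))
  if (length(table$individuals) < 2) stop("need at least 2 individuals")
  enc <- encode_genotypes(table)
  runs <- lapply(seq_len(spec$n_runs), function(r)
    admixture_run(enc, spec, seed = spec$seed + r))
  res <- align_runs(runs, level = spec$ci_level)
  res$individuals <- table$individuals
  res$spec <- spec
  rownames(res$q) <- rownames(res$ci_lo) <- rownames(res$ci_hi) <- table$individuals
  ## orient cluster 1 to species A via the field labels (majority are correct)
  sp <- table$metadata$species
  if (any(sp == "A", na.rm = TRUE) && any(sp == "B", na.rm = TRUE) &&
      spec$k == 2) {
    if (mean(res$q[which(sp == "A"), 1]) < mean(res$q[which(sp == "B"), 1])) {
      res$q <- res$q[, 2:1]
      tmp <- res$ci_lo[, 2:1]; res$ci_lo <- tmp
      res$ci_hi <- res$ci_hi[, 2:1]
      res$runs <- lapply(res$runs, function(r) {
        r$q <- r$q[, 2:1]; r$ci_lo <- r$ci_lo[, 2:1]; r$ci_hi <- r$ci_hi[, 2:1]
        r$samples <- r$samples[, 2:1, , drop = FALSE]
        r
      })
    }
  }
  res
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    sub <- all_perms(k - 1)
    for (s in sub) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(k), i)[s])
  }
  out
}

#' Align and combine multiple sampler runs
#'
#' Chooses, for every run, the cluster permutation minimizing the summed
#' absolute difference of posterior mean ancestry to a reference run, then
#' averages the aligned runs; credibility intervals are re-estimated from the
#' pooled aligned draws. Enumerates permutations, practical for K <= 4.
#'
#' @param runs list of per-run results (each with `q`, `ci_lo`, `ci_hi`,
#'   `samples`), or an `ancestry_result` holding them in `$runs`.
#' @param reference reference run (default the first).
#' @param level credibility level for the pooled intervals.
#' @return combined result of class `ancestry_result`.
#' @export
align_runs <- function(runs, reference = NULL, level = 0.90) {
  if (inherits(runs, "ancestry_result")) runs <- runs$runs
  stopifnot(length(runs) >= 1)
  n <- nrow(runs[[1]]$q); K <- ncol(runs[[1]]$q)
  for (r in runs) if (!identical(dim(r$q), c(n, K)))
    stop("runs have inconsistent individual sets or K")
  if (is.null(reference)) reference <- runs[[1]]
  perms <- all_perms(K)
  aligned <- lapply(runs, function(r) {
    costs <- vapply(perms, function(p) sum(abs(r$q[, p] - reference$q)), numeric(1))
    p <- perms[[which.min(costs)]]
    r$q <- r$q[, p, drop = FALSE]
    r$ci_lo <- r$ci_lo[, p, drop = FALSE]
    r$ci_hi <- r$ci_hi[, p, drop = FALSE]
    r$samples <- r$samples[, p, , drop = FALSE]
    r
  })
  q <- Reduce(`+`, lapply(aligned, `[[`, "q")) / length(aligned)
  pooled <- do.call(abind3, lapply(aligned, `[[`, "samples"))
  pr <- (1 - level) / 2
  ci_lo <- apply(pooled, c(1, 2), stats::quantile, probs = pr)
  ci_hi <- apply(pooled, c(1, 2), stats::quantile, probs = 1 - pr)
  structure(list(q = q, ci_lo = ci_lo, ci_hi = ci_hi, level = level,
                 runs = aligned),
            class = "ancestry_result")
}

## bind 3-d arrays along the third margin
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(NA_real_, c(d[1], d[2], sum(vapply(xs, function(x) dim(x)[3], numeric(1)))))
  at <- 0L
  for (x in xs) {
    out[, , at + seq_len(dim(x)[3])] <- x
    at <- at + dim(x)[3]
  }
  out
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat(sprintf("<ancestry_result> %d individuals, K = %d, %d run(s), %.0f%% intervals\n",
              nrow(x$q), ncol(x$q), length(x$runs), 100 * x$level))
  invisible(x)
}
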