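#' Configuration for the SMM divergence simulation
#'
#' @param mu per-generation, per-copy mutation probability (default 5e-4).
#' @param t generations since the two populations were isolated.
#' @param n diploid population size per species.
#' @param replicates independent replicates.
#' @param seed seed.
#' @return list of class `smm_config`.
#' @export
smm_config <- function(mu = 5e-4, t = 6000, n = 1000, replicates = 200, seed = 1) {
  stopifnot(mu > 0, mu < 1, t >= 0, n >= 1, replicates >= 1)
  structure(list(mu = mu, t = t, n = n, replicates = replicates, seed = seed),
            class = "smm_config")
}

#' Stepwise-mutation divergence simulation with exact IBD bookkeeping
#'
#' Two Wright-Fisher populations of `2n` gene copies each start from a common
#' monomorphic ancestral allele and evolve independently for `t` generations;
#' every copy mutates by +/-1 repeat unit with probability `mu` per
#' generation (fair direction). Each lineage carries its mutation count since
#' the founder, so identity in state can be split exactly into identity by
#' descent (both lineages unmutated) and homoplasy (identical in state with
#' at least one mutation in either history — including back-mutations).
#'
#' @param config an [smm_config()].
#' @return object of class `smm_report`: per-replicate data frame
#'   (`p_iis` cross-population identity-in-state probability, `p_homoplasic`
#'   proportion of identical-in-state pairs that are homoplasic,
#'   `p_unmutated` per-lineage unmutated fraction, `var_diff` cross-population
#'   size-difference variance) and a `summary` of replicate means.
#' @export
smm_divergence_sim <- function(config = smm_config()) {
  stopifnot(inherits(config, "smm_config"))
  set.seed(as.integer(config$seed))
  copies <- 2L * config$n
  res <- matrix(NA_real_, config$replicates, 4,
                dimnames = list(NULL, c("p_iis", "p_homoplasic", "p_unmutated", "var_diff")))
  ibd <- numeric(config$replicates)
  ## The population is exchangeable, so per-copy bookkeeping collapses to
  ## counts per (state, mutation-count) class: Wright-Fisher reproduction is
  ## a multinomial resampling of the class counts and mutation moves
  ## binomial thinnings to the (state +/- 1, mut + 1) classes. This is an
  ## exact reformulation of the per-copy model.
  lam <- config$mu * config$t
  smax <- max(5L, ceiling(6 * sqrt(max(lam, 1e-12))) + 3L)
  mmax <- max(5L, ceiling(stats::qpois(1 - 1e-12, max(lam, 1e-12))) + 3L)
  ns <- 2L * smax + 1L                        # states -smax..smax
  nm_ <- mmax + 1L                            # mutation counts 0..mmax
  evolve <- function() {
    A <- matrix(0, ns, nm_)
    A[smax + 1L, 1L] <- copies                # all copies: founder state, 0 mutations
    if (config$t > 0) for (g in seq_len(config$t)) {
      A[] <- stats::rmultinom(1L, copies, as.vector(A))
      nmut <- stats::rbinom(length(A), A, config$mu)
      up <- stats::rbinom(length(A), nmut, 0.5)
      dn <- matrix(nmut - up, ns, nm_); up <- matrix(up, ns, nm_)
      A <- A - matrix(nmut, ns, nm_)
      A[2:ns, 2:nm_] <- A[2:ns, 2:nm_] + up[1:(ns - 1), 1:(nm_ - 1)]
      A[1:(ns - 1), 2:nm_] <- A[1:(ns - 1), 2:nm_] + dn[2:ns, 1:(nm_ - 1)]
    }
    A
  }
  states <- (-smax):smax
  for (r in seq_len(config$replicates)) {
    A1 <- evolve(); A2 <- evolve()
    f1 <- rowSums(A1) / copies; f2 <- rowSums(A2) / copies
    p_iis <- sum(f1 * f2)
    ## both-unmutated pairs are the only identical-in-state pairs that are IBD
    u1 <- A1[smax + 1L, 1L] / copies; u2 <- A2[smax + 1L, 1L] / copies
    p_hom <- if (p_iis > 0) 1 - (u1 * u2) / p_iis else NA_real_
    ## E[(s_i - s_j)^2] for cross-population pairs equals the two
    ## populations' mean-square displacements; with fair +/-1 steps
    ## E[D^2 | K mutations] = K exactly, so the Rao-Blackwellized estimate
    ## is the mean mutation count per copy summed over the populations
    muts <- 0:(nm_ - 1L)
    mk1 <- sum(colSums(A1) * muts) / copies
    mk2 <- sum(colSums(A2) * muts) / copies
    var_diff <- if (config$t == 0) 0 else mk1 + mk2
    unmut <- (sum(A1[, 1L]) + sum(A2[, 1L])) / (2 * copies)
    res[r, ] <- c(p_iis, p_hom, unmut, var_diff)
    ibd[r] <- u1 * u2
  }
  df <- as.data.frame(res)
  summ <- as.list(colMeans(df, na.rm = TRUE))
  ## ensemble-level conditional proportion: IBD pair mass over IIS pair mass
  summ$p_homoplasic <- if (sum(df$p_iis) > 0) 1 - sum(ibd) / sum(df$p_iis) else NA_real_
  structure(list(replicates = df,
                 summary = summ,
                 config = config),
            class = "smm_report")
}

#' @export
print.smm_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<smm_report> mu=%g, t=%d, N=%d, %d replicate(s)\n",
                     "  P(identical in state, cross-pop)  %.4f\n",
                     "  P(homoplasic | identical in state) %.4f\n",
                     "  P(lineage unmutated)               %.4f  [(1-mu)^t = %.4f]\n",
                     "  Var(cross-pop size difference)     %.3f  [2*mu*t = %.3f]\n"),
              x$config$mu, x$config$t, x$config$n, x$config$replicates,
              s$p_iis, s$p_homoplasic, s$p_unmutated,
              (1 - x$config$mu)^x$config$t,
              s$var_diff, 2 * x$config$mu * x$config$t))
  invisible(x)
}
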