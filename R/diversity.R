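#' Unbiased expected heterozygosity (Nei 1978)
#'
#' `(2n/(2n-1)) * (1 - sum(p^2))` with `n` the number of genotyped
#' individuals.
#'
#' @param freq allele frequency vector (sums to 1).
#' @param n number of genotyped individuals.
#' @return numeric scalar.
#' @export
expected_het <- function(freq, n) {
  if (n <= 0 || length(freq) == 0) return(NA_real_)
  (2 * n / (2 * n - 1)) * (1 - sum(freq^2))
}

## per-locus per-group summaries used by several estimators:
## counts of gene copies, het indicator frequencies per allele, sample sizes
locus_group_stats <- function(table, l, rows) {
  rows <- rows[!is.na(table$a1[rows, l])]
  n <- length(rows)
  if (n == 0) return(NULL)
  a1 <- table$a1[rows, l]; a2 <- table$a2[rows, l]
  alleles <- sort(unique(c(a1, a2)))
  counts <- vapply(alleles, function(a) sum(a1 == a) + sum(a2 == a), numeric(1))
  het <- a1 != a2
  ## h[a]: proportion of individuals heterozygous *for allele a*
  h <- vapply(alleles, function(a) sum(het & (a1 == a | a2 == a)) / n, numeric(1))
  list(n = n, alleles = alleles, counts = counts, p = counts / (2 * n),
       h = h, ho = mean(het))
}

## Weir-Cockerham within-population components (r = 1): per-allele b and c
wc_fis_components <- function(st) {
  n <- st$n
  if (n < 2) return(c(b = NA_real_, c = NA_real_))
  b <- (n / (n - 1)) * (st$p * (1 - st$p) - (2 * n - 1) / (4 * n) * st$h)
  c(b = sum(b), c = sum(st$h) / 2)
}

#' Rarefaction allelic richness
#'
#' Expected number of alleles in a subsample of `g` gene copies:
#' `sum_a [1 - choose(2N - N_a, g) / choose(2N, g)]`.
#'
#' @param counts allele copy counts.
#' @param g rarefaction sample size in gene copies.
#' @return numeric scalar.
#' @export
allelic_richness <- function(counts, g) {
  total <- sum(counts)
  if (g > total) stop("rarefaction size exceeds available gene copies")
  sum(1 - exp(lchoose(total - counts, g) - lchoose(total, g)))
}

#' Null-allele frequency by expectation-maximization
#'
#' Maximum-likelihood null-allele frequency under Hardy-Weinberg genotype
#' proportions, where a heterozygote carrying one null allele is observed as
#' a homozygote for its visible allele and a null homozygote is observed as a
#' missing call. Iterated until the null-frequency change is below `tol`.
#'
#' @param table an [msat_table()].
#' @param locus locus name.
#' @param rows optional individual subset (indices) defining the population;
#'   default all.
#' @param tol convergence tolerance on the null frequency (default 1e-8).
#' @param max_iter iteration cap (default 10000); non-convergence is flagged,
#'   not an error.
#' @return list with `null_freq`, `visible_freq` (renormalized over visible
#'   alleles), `converged`, `iterations`.
#' @export
null_allele_em <- function(table, locus, rows = NULL, tol = 1e-8, max_iter = 10000) {
  l <- match(locus, table$loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  if (is.null(rows)) rows <- seq_along(table$individuals)
  a1 <- table$a1[rows, l]; a2 <- table$a2[rows, l]
  n_missing <- sum(is.na(a1))
  typed <- !is.na(a1)
  a1 <- a1[typed]; a2 <- a2[typed]
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k == 0) return(list(null_freq = NA_real_, visible_freq = numeric(0),
                          converged = FALSE, iterations = 0L))
  het <- a1 != a2
  ## fixed counts: het gene copies per allele; observed-homozygote individuals
  het_copies <- vapply(alleles, function(a)
    sum(het & a1 == a) + sum(het & a2 == a), numeric(1))
  hom_obs <- vapply(alleles, function(a) sum(!het & a1 == a), numeric(1))
  n_ind <- length(a1) + n_missing
  total_copies <- 2 * n_ind

  p <- het_copies + 2 * hom_obs
  p <- p / sum(p) * (1 - 0.05)        # start with a small null mass
  p0 <- 0.05
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ## E-step: split each observed homozygote class between true homozygotes
    ## and heterozygotes-with-null
    denom <- p^2 + 2 * p * p0
    w_null <- ifelse(denom > 0, (2 * p * p0) / denom, 0)
    vis_copies <- het_copies + hom_obs * (2 - w_null)
    null_copies <- sum(hom_obs * w_null) + 2 * n_missing
    new_p0 <- null_copies / total_copies
    new_p <- vis_copies / total_copies
    delta <- abs(new_p0 - p0)
    p0 <- new_p0; p <- new_p
    if (delta < tol) { converged <- TRUE; break }
  }
  vis <- if (sum(p) > 0) p / sum(p) else p
  names(vis) <- alleles
  list(null_freq = p0, visible_freq = vis, converged = converged, iterations = it)
}

#' Per-locus, per-population diversity report
#'
#' Computes, for every locus within every grouping level: number of
#' individuals genotyped, number of alleles, null-allele percentage (EM
#' estimate), rarefaction allelic richness, unbiased expected and observed
#' heterozygosity, and the Weir-Cockerham within-population inbreeding
#' coefficient with a permutation p-value (gene copies permuted among
#' individuals within the group; one-sided for heterozygote deficit).
#'
#' @param table an [msat_table()].
#' @param group factor/character per individual (default the species label).
#' @param rarefaction_g rarefaction size in gene copies; default twice the
#'   smallest per-locus-per-group genotyped count. Must not exceed the
#'   available gene copies anywhere.
#' @param n_perm permutations for the FIS test (default 10000; 0 disables).
#' @param seed seed for the permutations.
#' @return data frame with one row per locus x group.
#' @export
diversity_report <- function(table, group = table$metadata$species,
                             rarefaction_g = NULL, n_perm = 10000, seed = 1) {
  group <- as.character(group)
  groups <- unique(group[!is.na(group)])
  set.seed(as.integer(seed))
  ## smallest genotyped count anywhere defines the default rarefaction size
  min_n <- Inf
  for (l in seq_along(table$loci)) for (g in groups) {
    n <- sum(group == g & !is.na(table$a1[, l]))
    if (n > 0) min_n <- min(min_n, n)
  }
  if (is.null(rarefaction_g)) rarefaction_g <- 2 * min_n
  if (rarefaction_g > 2 * min_n)
    stop("rarefaction_g exceeds available gene copies in some locus/group")

  out <- list()
  for (l in seq_along(table$loci)) for (g in groups) {
    rows <- which(group == g)
    st <- locus_group_stats(table, l, rows)
    if (is.null(st)) next
    he <- expected_het(st$p, st$n)
    mono <- length(st$alleles) < 2
    fis <- fis_p <- NA_real_
    if (!mono) {
      comp <- wc_fis_components(st)
      fis <- 1 - comp["c"] / (comp["b"] + comp["c"])
      if (n_perm > 0) {
        ## permute gene copies among individuals within the group
        typed <- rows[!is.na(table$a1[rows, l])]
        copies <- c(table$a1[typed, l], table$a2[typed, l])
        n <- length(typed)
        exceed <- 0L
        for (b in seq_len(n_perm)) {
          perm <- sample(copies)
          p1 <- perm[seq_len(n)]; p2 <- perm[n + seq_len(n)]
          het <- p1 != p2
          hperm <- vapply(st$alleles, function(a)
            sum(het & (p1 == a | p2 == a)) / n, numeric(1))
          cp <- wc_fis_components(list(n = n, p = st$p, h = hperm))
          fperm <- 1 - cp["c"] / (cp["b"] + cp["c"])
          if (!is.na(fperm) && fperm >= fis) exceed <- exceed + 1L
        }
        fis_p <- (1 + exceed) / (n_perm + 1)
      }
    }
    em <- null_allele_em(table, table$loci[l], rows = rows)
    out[[length(out) + 1L]] <- data.frame(
      locus = table$loci[l], population = g, n = st$n,
      na = length(st$alleles),
      nal = 100 * em$null_freq,
      ar = allelic_richness(st$counts, rarefaction_g),
      he = if (mono) 0 else he, ho = st$ho,
      fis = unname(fis), fis_p = unname(fis_p),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Haplotype and nucleotide diversity of an alignment
#'
#' Haplotypes collapse by exact sequence identity; sequences containing `N`
#' are matched on their non-N positions to the first compatible haplotype.
#' `h = (n/(n-1)) (1 - sum f_i^2)`; `pi` is the mean pairwise proportion of
#' differing sites with pairwise deletion of gaps and `N`.
#'
#' @param aln a [seq_alignment()].
#' @param group optional factor per record; statistics are returned per level
#'   (plus `"all"` when `NULL`).
#' @return data frame with columns `population, n, n_haplotypes, h, pi`.
#' @export
mtdna_diversity <- function(aln, group = NULL) {
  ids <- names(aln$sequences)
  if (is.null(group)) group <- rep("all", length(ids))
  group <- as.character(group)
  res <- list()
  for (g in unique(group[!is.na(group)])) {
    seqs <- aln$sequences[group == g]
    n <- length(seqs)
    if (n == 0) next
    mat <- do.call(rbind, strsplit(seqs, ""))
    ## collapse haplotypes, N-tolerant
    hap_idx <- integer(n); reps <- list()
    for (i in seq_len(n)) {
      assigned <- 0L
      for (j in seq_along(reps)) {
        a <- mat[i, ]; b <- reps[[j]]
        ok <- a != "N" & b != "N"
        if (all(a[ok] == b[ok])) { assigned <- j; break }
      }
      if (assigned == 0L) { reps[[length(reps) + 1L]] <- mat[i, ]; assigned <- length(reps) }
      hap_idx[i] <- assigned
    }
    f <- tabulate(hap_idx) / n
    h <- if (n < 2) 0 else (n / (n - 1)) * (1 - sum(f^2))
    ## plug-in pi: sum over haplotype pairs of f_u f_v d_uv (d on shared
    ## unambiguous sites; gaps and N deleted pairwise)
    H <- length(reps)
    pi <- 0
    if (n >= 2 && H >= 2) {
      for (u in seq_len(H - 1)) for (v in (u + 1):H) {
        a <- reps[[u]]; b <- reps[[v]]
        use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
        d <- if (sum(use) == 0) 0 else sum(a[use] != b[use]) / sum(use)
        pi <- pi + 2 * f[u] * f[v] * d
      }
    }
    res[[length(res) + 1L]] <- data.frame(
      population = g, n = n, n_haplotypes = H, h = h, pi = pi,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}
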