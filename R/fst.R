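#' Weir-Cockerham FST between two populations
#'
#' Per-locus and multilocus theta from the 1984 variance-components
#' estimator, the multilocus value being the ratio of summed components.
#' Significance is assessed by permuting individuals among the two
#' populations and recomputing theta (add-one permutation p-value,
#' one-sided).
#'
#' A locus monomorphic across both populations contributes zero components
#' (it is effectively skipped), never `NaN`.
#'
#' @param table_a,table_b [msat_table()]s over a shared locus panel.
#' @param n_perm permutations (default 10000; 0 disables the test).
#' @param seed permutation seed.
#' @return list of class `fst_result`: `theta` (multilocus), `per_locus`
#'   (named vector), `p_value`, `n_perm`.
#' @export
fst_wc <- function(table_a, table_b, n_perm = 10000, seed = 1) {
  stopifnot(identical(table_a$loci, table_b$loci))
  comp <- wc_theta_components(table_a$a1, table_a$a2, table_b$a1, table_b$a2)
  theta <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  per_locus <- comp$a / (comp$a + comp$b + comp$c)
  names(per_locus) <- table_a$loci
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(as.integer(seed))
    A1 <- rbind(table_a$a1, table_b$a1); A2 <- rbind(table_a$a2, table_b$a2)
    na <- nrow(table_a$a1); ntot <- nrow(A1)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(ntot)
      ia <- idx[seq_len(na)]; ib <- idx[(na + 1):ntot]
      cp <- wc_theta_components(A1[ia, , drop = FALSE], A2[ia, , drop = FALSE],
                                A1[ib, , drop = FALSE], A2[ib, , drop = FALSE])
      tperm <- sum(cp$a) / sum(cp$a + cp$b + cp$c)
      if (!is.na(tperm) && tperm >= theta) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  structure(list(theta = theta, per_locus = per_locus, p_value = p,
                 n_perm = n_perm, corrected = FALSE),
            class = "fst_result")
}

## Weir-Cockerham (1984) components for r = 2 populations, per locus.
## Optionally uses externally supplied allele frequencies (ENA correction)
## in place of the observed counts-based frequencies.
wc_theta_components <- function(a1x, a2x, a1y, a2y,
                                freq_override_a = NULL, freq_override_b = NULL) {
  L <- ncol(a1x)
  a_comp <- b_comp <- c_comp <- numeric(L)
  for (l in seq_len(L)) {
    x1 <- a1x[, l]; x2 <- a2x[, l]; y1 <- a1y[, l]; y2 <- a2y[, l]
    tx <- !is.na(x1); ty <- !is.na(y1)
    n1 <- sum(tx); n2 <- sum(ty)
    if (n1 == 0 || n2 == 0) next
    alleles <- sort(unique(c(x1[tx], x2[tx], y1[ty], y2[ty])))
    if (length(alleles) < 2) next
    p1 <- vapply(alleles, function(a) (sum(x1[tx] == a) + sum(x2[tx] == a)) / (2 * n1), numeric(1))
    p2 <- vapply(alleles, function(a) (sum(y1[ty] == a) + sum(y2[ty] == a)) / (2 * n2), numeric(1))
    if (!is.null(freq_override_a)) {
      ov <- freq_override_a[[l]]
      p1 <- ifelse(as.character(alleles) %in% names(ov), ov[as.character(alleles)], 0)
    }
    if (!is.null(freq_override_b)) {
      ov <- freq_override_b[[l]]
      p2 <- ifelse(as.character(alleles) %in% names(ov), ov[as.character(alleles)], 0)
    }
    hx <- x1[tx] != x2[tx]; hy <- y1[ty] != y2[ty]
    h1 <- vapply(alleles, function(a) sum(hx & (x1[tx] == a | x2[tx] == a)) / n1, numeric(1))
    h2 <- vapply(alleles, function(a) sum(hy & (y1[ty] == a | y2[ty] == a)) / n2, numeric(1))
    r <- 2
    nbar <- (n1 + n2) / 2
    if (nbar <= 1) next
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    a_comp[l] <- sum(a); b_comp[l] <- sum(b); c_comp[l] <- sum(cc)
  }
  list(a = a_comp, b = b_comp, c = c_comp)
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result%s> multilocus theta = %.4f (p = %s, %d permutations)\n",
              if (isTRUE(x$corrected)) " ENA" else "", x$theta,
              format(x$p_value), x$n_perm))
  invisible(x)
}

#' ENA-corrected FST
#'
#' Like [fst_wc()] but with each population's per-locus allele frequencies
#' replaced by the null-allele-excluded frequencies from [null_allele_em()]
#' (the estimated null class is removed and the visible frequencies
#' renormalized). When every estimated null frequency is below `null_tol`
#' the observed frequencies are used unchanged, so the corrected estimate
#' then equals the uncorrected one exactly.
#'
#' @inheritParams fst_wc
#' @param null_tol null-frequency threshold below which no correction is
#'   applied at a locus/population (default 1e-6).
#' @return an `fst_result` (with `corrected = TRUE` and the per-locus,
#'   per-population null estimates in `$null_freq`).
#' @export
fst_ena <- function(table_a, table_b, n_perm = 10000, seed = 1, null_tol = 1e-6) {
  stopifnot(identical(table_a$loci, table_b$loci))
  L <- length(table_a$loci)
  ov_a <- vector("list", L); ov_b <- vector("list", L)
  null_est <- matrix(NA_real_, L, 2, dimnames = list(table_a$loci, c("A", "B")))
  for (l in seq_len(L)) {
    ea <- null_allele_em(table_a, table_a$loci[l])
    eb <- null_allele_em(table_b, table_b$loci[l])
    null_est[l, ] <- c(ea$null_freq, eb$null_freq)
    if (!is.na(ea$null_freq) && ea$null_freq > null_tol) ov_a[[l]] <- ea$visible_freq
    if (!is.na(eb$null_freq) && eb$null_freq > null_tol) ov_b[[l]] <- eb$visible_freq
  }
  has_ov_a <- any(!vapply(ov_a, is.null, logical(1)))
  has_ov_b <- any(!vapply(ov_b, is.null, logical(1)))
  fill <- function(ov, tab) {
    for (l in seq_len(L)) if (is.null(ov[[l]])) {
      st <- locus_group_stats(tab, l, seq_along(tab$individuals))
      ov[[l]] <- if (is.null(st)) stats::setNames(numeric(0), character(0))
                 else stats::setNames(st$p, st$alleles)
    }
    ov
  }
  comp <- if (!has_ov_a && !has_ov_b) {
    wc_theta_components(table_a$a1, table_a$a2, table_b$a1, table_b$a2)
  } else {
    wc_theta_components(table_a$a1, table_a$a2, table_b$a1, table_b$a2,
                        freq_override_a = fill(ov_a, table_a),
                        freq_override_b = fill(ov_b, table_b))
  }
  theta <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  per_locus <- comp$a / (comp$a + comp$b + comp$c)
  names(per_locus) <- table_a$loci
  structure(list(theta = theta, per_locus = per_locus, p_value = NA_real_,
                 n_perm = 0L, corrected = TRUE, null_freq = null_est),
            class = "fst_result")
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' Log-likelihood G statistic on the two-locus genotype contingency table,
#' with the null distribution obtained by permuting one locus's genotypes
#' among individuals within population. `p = (1 + #{G_perm >= G_obs}) /
#' (n_perm + 1)`.
#'
#' @param table an [msat_table()].
#' @param locus_pair character vector of two locus names.
#' @param n_perm permutations (default 10000).
#' @param group optional population factor; permutation is within levels.
#' @param seed seed.
#' @return list: `g` (observed statistic), `p_value`, `n_shared`.
#' @export
ld_test <- function(table, locus_pair, n_perm = 10000, group = NULL, seed = 1) {
  stopifnot(length(locus_pair) == 2)
  l1 <- match(locus_pair[1], table$loci); l2 <- match(locus_pair[2], table$loci)
  if (anyNA(c(l1, l2))) stop("unknown locus name")
  g1 <- paste(table$a1[, l1], table$a2[, l1])
  g2 <- paste(table$a1[, l2], table$a2[, l2])
  ok <- !is.na(table$a1[, l1]) & !is.na(table$a1[, l2])
  if (sum(ok) < 10) {
    warning("fewer than 10 individuals genotyped at both loci")
    return(list(g = NA_real_, p_value = NA_real_, n_shared = sum(ok)))
  }
  if (is.null(group)) group <- rep("all", length(g1))
  group <- as.character(group)[ok]
  g1 <- g1[ok]; g2 <- g2[ok]
  gstat <- function(x, y, grp) {
    total <- 0
    for (g in unique(grp)) {
      sel <- grp == g
      tab <- table(x[sel], y[sel])
      if (nrow(tab) < 2 || ncol(tab) < 2) next
      e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      nz <- tab > 0
      total <- total + 2 * sum(tab[nz] * log(tab[nz] / e[nz]))
    }
    total
  }
  g_obs <- gstat(g1, g2, group)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    g2p <- g2
    for (g in unique(group)) {
      sel <- which(group == g)
      g2p[sel] <- g2[sample(sel)]
    }
    if (gstat(g1, g2p, group) >= g_obs) exceed <- exceed + 1L
  }
  list(g = g_obs, p_value = (1 + exceed) / (n_perm + 1), n_shared = length(g1))
}

#' Principal component analysis on allele dosages
#'
#' Individuals are encoded as allele-dosage vectors (0 / 0.5 / 1 per allele),
#' columns are mean-imputed for missing calls and centered, and coordinates
#' come from the singular value decomposition. The sign of axis 1 is fixed so
#' the species-A centroid is negative.
#'
#' @param table an [msat_table()].
#' @param n_axes number of axes to return (default 2).
#' @return list: `scores` (n x n_axes), `explained` (variance fractions),
#'   `dropped` (all-missing columns removed).
#' @export
pca_allele_freq <- function(table, n_axes = 2) {
  n <- length(table$individuals)
  if (n < 2) stop("PCA needs at least 2 individuals")
  cols <- list()
  for (l in seq_along(table$loci)) {
    a1 <- table$a1[, l]; a2 <- table$a2[, l]
    alleles <- sort(unique(c(a1[!is.na(a1)], a2[!is.na(a2)])))
    for (a in alleles) {
      d <- ((a1 == a) + (a2 == a)) / 2
      cols[[paste0(table$loci[l], ".", a)]] <- d
    }
  }
  X <- do.call(cbind, cols)
  all_na <- colSums(!is.na(X)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " all-missing dosage column(s) dropped")
    X <- X[, !all_na, drop = FALSE]
  }
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = n_axes, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_axes)], n_axes)
  rownames(scores) <- table$individuals
  sp <- table$metadata$species
  if (any(sp == "A", na.rm = TRUE) &&
      mean(scores[which(sp == "A"), 1]) > 0) {
    scores[, 1] <- -scores[, 1]
  }
  list(scores = scores, explained = sv$d^2 / sum(sv$d^2), dropped = names(all_na)[all_na])
}
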