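#' Hybrid classes and their ancestry distributions
#'
#' For each genotype-frequency class, the probability that an unordered pair
#' of gene copies at a locus has both copies from species A, one from each,
#' or both from B.
#'
#' @return 6 x 3 matrix (rows PureA, PureB, F1, F2, BcA, BcB; columns AA, AB,
#'   BB), each row summing to 1.
#' @export
hybrid_class_phi <- function() {
  m <- rbind(
    PureA = c(1, 0, 0),
    PureB = c(0, 0, 1),
    F1 = c(0, 1, 0),
    F2 = c(1 / 4, 1 / 2, 1 / 4),
    BcA = c(1 / 2, 1 / 2, 0),
    BcB = c(0, 1 / 2, 1 / 2)
  )
  colnames(m) <- c("AA", "AB", "BB")
  m
}

#' Select reference pure individuals from a prior assignment
#'
#' Retains individuals whose ancestry coefficient for their own cluster is at
#' least `q_cut` (default 0.9) and subsamples a fixed number per species.
#'
#' @param table an [msat_table()].
#' @param ancestry an `ancestry_result` from [run_admixture()] on `table`
#'   (cluster 1 aligned to species A).
#' @param n_per_species how many reference individuals to keep per species.
#' @param q_cut ancestry-coefficient cut-off in (0.5, 1].
#' @param seed seed for the subsample.
#' @return list with `A` and `B`: msat_tables of the selected individuals.
#' @export
select_reference_pure <- function(table, ancestry, n_per_species = 80,
                                  q_cut = 0.9, seed = 1) {
  stopifnot(q_cut > 0.5, q_cut <= 1)
  q <- ancestry$q
  sp <- table$metadata$species
  pick <- function(species, col) {
    ok <- which(sp == species & q[, col] >= q_cut)
    if (length(ok) < n_per_species)
      stop(sprintf("only %d individuals of species %s reach q >= %.2f (need %d)",
                   length(ok), species, q_cut, n_per_species))
    ok
  }
  ok_a <- pick("A", 1); ok_b <- pick("B", 2)
  set.seed(as.integer(seed))
  sel_a <- sort(sample(ok_a, n_per_species))
  sel_b <- sort(sample(ok_b, n_per_species))
  list(A = subset_individuals(table, sel_a),
       B = subset_individuals(table, sel_b))
}

#' Simulate genotypes of one hybrid class from allele-frequency spectra
#'
#' The simulator draws gametes per locus from the parental spectra: pure
#' classes take two independent gametes from their own spectrum (HWE, linkage
#' equilibrium); F1 takes one from each; F2 gametes each come from an
#' independently simulated F1 parent (one of its two alleles per locus, fair
#' coin); backcrosses take one F1 gamete and one pure gamete. Loci are
#' independent and panels contain no missing data.
#'
#' @param class one of `"PureA"`, `"PureB"`, `"F1"`, `"F2"`, `"BcA"`, `"BcB"`.
#' @param freqs_a,freqs_b named lists of per-locus frequency vectors (names
#'   are allele sizes), same locus names in both.
#' @param n number of individuals.
#' @param seed optional seed.
#' @param ids optional IDs.
#' @return an [msat_table()] with truth channel `hybrid_class`.
#' @export
simulate_class <- function(class, freqs_a, freqs_b, n, seed = NULL, ids = NULL) {
  stopifnot(identical(names(freqs_a), names(freqs_b)), n >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  loci <- names(freqs_a)
  if (n == 0) {
    return(msat_table(character(0), matrix(integer(0), 0, length(loci)),
                      matrix(integer(0), 0, length(loci)), loci,
                      truth = data.frame(true_species = character(0),
                                         hybrid_class = character(0),
                                         mother_species = character(0))))
  }
  empty <- vapply(loci, function(l) length(freqs_a[[l]]) == 0 || length(freqs_b[[l]]) == 0,
                  logical(1))
  if (any(empty)) stop("empty allele spectrum at locus ", loci[which(empty)[1]])
  if (is.null(ids)) ids <- sprintf("sim_%s_%04d", class, seq_len(n))
  L <- length(loci)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    g <- class_gametes(class, freqs_a[[l]], freqs_b[[l]], n)
    a1[, l] <- g[[1]]; a2[, l] <- g[[2]]
  }
  tr <- data.frame(
    true_species = rep(switch(class, PureA = "A", PureB = "B", "H"), n),
    hybrid_class = class,
    mother_species = switch(class, PureA = "A", PureB = "B",
                            BcA = NA_character_, BcB = NA_character_,
                            NA_character_),
    stringsAsFactors = FALSE)
  md <- data.frame(id = ids,
                   species = switch(class, PureA = "A", PureB = "B", BcA = "A",
                                    BcB = "B", NA_character_),
                   region = NA_character_, year = NA_integer_,
                   stringsAsFactors = FALSE)
  msat_table(ids, a1, a2, loci, metadata = md, truth = tr)
}

#' Build a simulation panel of pure and hybrid genotypes
#'
#' Selects reference pure individuals (ancestry cut-off `q_cut`), recomputes
#' allele frequencies from those references only, and simulates the requested
#' number of genotypes per class. The panel combines the reference
#' individuals with the simulated hybrids; truth labels cover every simulated
#' individual and reference/simulated ID spaces are disjoint.
#'
#' @inheritParams select_reference_pure
#' @param per_class_n simulated individuals per hybrid class (default 80).
#' @param classes which classes to simulate.
#' @param include_refs include the reference individuals in the panel table.
#' @return list with `panel` (msat_table), `refs` (list A/B), `freqs_a`,
#'   `freqs_b`, `seed`.
#' @export
build_panel <- function(table, ancestry, per_class_n = 80, n_ref = 80,
                        q_cut = 0.9, classes = c("F1", "F2", "BcA", "BcB"),
                        include_refs = TRUE, seed = 1) {
  refs <- select_reference_pure(table, ancestry, n_per_species = n_ref,
                                q_cut = q_cut, seed = seed)
  fa <- lapply(allele_freqs(refs$A, group = rep("A", length(refs$A$individuals))),
               function(x) x$A$freq)
  fb <- lapply(allele_freqs(refs$B, group = rep("B", length(refs$B$individuals))),
               function(x) x$B$freq)
  set.seed(as.integer(seed) + 1L)
  sims <- lapply(classes, function(cls)
    simulate_class(cls, fa, fb, per_class_n))
  parts <- if (include_refs) {
    ra <- refs$A; rb <- refs$B
    ra$truth <- data.frame(true_species = "A", hybrid_class = "PureA",
                           mother_species = "A",
                           mislabelled = FALSE)[rep(1, length(ra$individuals)), ]
    rb$truth <- data.frame(true_species = "B", hybrid_class = "PureB",
                           mother_species = "B",
                           mislabelled = FALSE)[rep(1, length(rb$individuals)), ]
    c(list(ra, rb), sims)
  } else sims
  panel <- Reduce(rbind_tables, parts)
  if (anyDuplicated(panel$individuals))
    stop("reference and simulated ID spaces overlap")
  list(panel = panel, refs = refs, freqs_a = fa, freqs_b = fb, seed = seed)
}
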