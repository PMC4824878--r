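#' @name synthetic-data
#' @title Two-species synthetic dataset generator
#' @description
#' Generates genotype tables, mtDNA control-region sequences and
#' flanking-region haplotypes with the statistical structure the downstream
#' analyses assume: Hardy-Weinberg and linkage equilibrium within species,
#' per-locus null alleles (a hidden allele whose carriers look like
#' homozygotes and whose homozygotes look like missing data), occasional
#' field mislabels, and species-diagnostic flanking haplotypes. A hidden
#' truth channel records every individual's true origin for scoring; it is
#' never written to standard-format exports.
NULL

## one gene copy per row; null allele encoded as 0L
draw_gametes <- function(freq, n, null_freq = 0) {
  sizes <- as.integer(names(freq))
  if (null_freq > 0) {
    sizes <- c(sizes, 0L)
    freq <- c(freq * (1 - null_freq), null_freq)
  }
  sizes[sample.int(length(sizes), n, replace = TRUE, prob = freq)]
}

## convert two latent gamete vectors (0 = null) into observed calls
observe_calls <- function(c1, c2) {
  bothnull <- c1 == 0L & c2 == 0L
  onenull <- xor(c1 == 0L, c2 == 0L)
  vis <- pmax(c1, c2)                  # the visible allele when one is null
  o1 <- ifelse(onenull, vis, c1)
  o2 <- ifelse(onenull, vis, c2)
  o1[bothnull] <- NA_integer_
  o2[bothnull] <- NA_integer_
  list(a1 = o1, a2 = o2)
}

#' Sample pure-species genotypes from a profile
#'
#' Draws `n` diploid multilocus genotypes for one species under
#' Hardy-Weinberg and linkage equilibrium. Null alleles act as a hidden
#' allele: a heterozygote carrying one null appears homozygous for its
#' visible allele, a null homozygote appears missing.
#'
#' @param profile a [make_profile()] result.
#' @param species `"A"` or `"B"`.
#' @param n number of individuals.
#' @param ids optional individual IDs.
#' @param use_nulls apply the profile's null-allele frequencies (default TRUE).
#' @param missing_rate extra whole-call dropout probability.
#' @return an [msat_table()] with truth channel columns `true_species`,
#'   `hybrid_class` and `mother_species`.
#' @export
sample_pure_genotypes <- function(profile, species, n, ids = NULL,
                                  use_nulls = TRUE, missing_rate = 0) {
  stopifnot(species %in% c("A", "B"), n >= 1)
  if (is.null(ids)) ids <- sprintf("%s%04d", species, seq_len(n))
  L <- length(profile$loci)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    lc <- profile$loci[[l]]
    freq <- if (species == "A") lc$freq_a else lc$freq_b
    nf <- if (!use_nulls) 0 else if (species == "A") lc$null_a else lc$null_b
    obs <- observe_calls(draw_gametes(freq, n, nf), draw_gametes(freq, n, nf))
    a1[, l] <- obs$a1; a2[, l] <- obs$a2
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n * L) < missing_rate, n, L)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  md <- data.frame(id = ids, species = species, region = NA_character_,
                   year = NA_integer_, stringsAsFactors = FALSE)
  tr <- data.frame(true_species = rep(species, n),
                   hybrid_class = paste0("Pure", species),
                   mother_species = species, stringsAsFactors = FALSE)
  msat_table(ids, a1, a2, names(profile$loci), metadata = md, truth = tr)
}

## gamete from a simulated F1 parent: per locus one of its two alleles.
## With per-locus independence this is equivalent to drawing the allele's
## species of origin fairly and then an allele from that species' spectrum.
f1_gamete <- function(freq_a, freq_b, n, null_a = 0, null_b = 0) {
  from_a <- stats::runif(n) < 0.5
  out <- integer(n)
  if (any(from_a)) out[from_a] <- draw_gametes(freq_a, sum(from_a), null_a)
  if (any(!from_a)) out[!from_a] <- draw_gametes(freq_b, sum(!from_a), null_b)
  out
}

## latent gamete pair (possibly with nulls) for one hybrid class at one locus
class_gametes <- function(class, freq_a, freq_b, n, null_a = 0, null_b = 0) {
  ga <- function(n) draw_gametes(freq_a, n, null_a)
  gb <- function(n) draw_gametes(freq_b, n, null_b)
  gf1 <- function(n) f1_gamete(freq_a, freq_b, n, null_a, null_b)
  switch(class,
    PureA = list(ga(n), ga(n)),
    PureB = list(gb(n), gb(n)),
    F1 = list(ga(n), gb(n)),
    F2 = list(gf1(n), gf1(n)),
    BcA = list(gf1(n), ga(n)),
    BcB = list(gf1(n), gb(n)),
    stop("unknown hybrid class: ", class))
}

#' Simulate true-hybrid genotypes at dataset level
#'
#' Like the panel simulator but with the profile's null-allele frequencies
#' active, so dataset-level hybrids are subject to the same genotyping
#' artefacts as pure individuals.
#'
#' @inheritParams sample_pure_genotypes
#' @param class one of `"F1"`, `"F2"`, `"BcA"`, `"BcB"`.
#' @keywords internal
sample_hybrid_genotypes <- function(profile, class, n, ids = NULL,
                                    use_nulls = TRUE, missing_rate = 0) {
  if (is.null(ids)) ids <- sprintf("%s%04d", class, seq_len(n))
  L <- length(profile$loci)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    lc <- profile$loci[[l]]
    na <- if (use_nulls) lc$null_a else 0
    nb <- if (use_nulls) lc$null_b else 0
    g <- class_gametes(class, lc$freq_a, lc$freq_b, n, na, nb)
    obs <- observe_calls(g[[1]], g[[2]])
    a1[, l] <- obs$a1; a2[, l] <- obs$a2
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n * L) < missing_rate, n, L)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  ## maternal species: F1/F2 mothers are species A or B with equal odds (an F1
  ## or random F1 mother); backcross mothers are the pure parent or the F1
  ## with equal odds, giving 3:1 odds for the backcrossed-to species
  mother <- switch(class,
    F1 = sample(c("A", "B"), n, replace = TRUE),
    F2 = sample(c("A", "B"), n, replace = TRUE),
    BcA = sample(c("A", "B"), n, replace = TRUE, prob = c(0.75, 0.25)),
    BcB = sample(c("A", "B"), n, replace = TRUE, prob = c(0.25, 0.75)))
  field <- switch(class, BcA = "A", BcB = "B",
                  sample(c("A", "B"), n, replace = TRUE))
  md <- data.frame(id = ids, species = rep_len(field, n), region = NA_character_,
                   year = NA_integer_, stringsAsFactors = FALSE)
  tr <- data.frame(true_species = "H", hybrid_class = class,
                   mother_species = mother, stringsAsFactors = FALSE)
  msat_table(ids, a1, a2, names(profile$loci), metadata = md, truth = tr)
}

#' Flip field species labels at a given rate
#'
#' Emulates misidentification during sampling: a Bernoulli(`rate`) subset of
#' individuals has its field species label flipped between `"A"` and `"B"`.
#' The true origin is retained in the hidden truth channel.
#'
#' @param table an [msat_table()].
#' @param rate mislabel probability in `[0, 1]`.
#' @param seed optional seed.
#' @return the relabelled table; `truth$mislabelled` records which rows flipped.
#' @export
inject_mislabels <- function(table, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(table$truth)) {
    table$truth <- data.frame(true_species = table$metadata$species,
                              stringsAsFactors = FALSE)
  }
  flip <- stats::runif(length(table$individuals)) < rate
  sp <- table$metadata$species
  sp[flip] <- ifelse(sp[flip] == "A", "B", "A")
  table$metadata$species <- sp
  table$truth$mislabelled <- flip
  table
}

#' Attach mtDNA and flanking-region sequences to a simulated table
#'
#' Control-region haplotypes are drawn from the maternal species' pool, so
#' field mislabels create *apparent* and true hybrids create *real*
#' mito-nuclear discordance. Flanking haplotype pairs follow the individual's
#' true class: pure individuals (including carriers of the convergent
#' microsatellite allele — the homoplasy signature) get two own-species
#' template copies; true hybrids draw each copy's species of origin from the
#' class's ancestry distribution, so every F1 is heterozygous at all
#' diagnostic positions. A small number of private neutral mutations is added
#' away from the diagnostic positions.
#'
#' @param table an [msat_table()] with a truth channel (`hybrid_class`,
#'   `mother_species`).
#' @param profile the [make_profile()] used to simulate the table.
#' @param private_mut_rate Poisson mean of private substitutions per haplotype.
#' @return list with `cr` and `flanking` [seq_alignment()]s (flanking records
#'   are named `<id>_1` / `<id>_2`).
#' @export
attach_sequences <- function(table, profile, private_mut_rate = 0.7) {
  if (is.null(table$truth) || is.null(table$truth$hybrid_class) ||
      is.null(table$truth$mother_species))
    stop("table lacks a truth channel with true-origin annotation")
  n <- length(table$individuals)
  diag <- profile$flanking$diagnostics
  protect <- c(diag$snp$position, diag$indel$positions)
  phi <- hybrid_class_phi()

  cr <- character(n)
  fl1 <- fl2 <- character(n)
  for (i in seq_len(n)) {
    mo <- table$truth$mother_species[i]
    pool <- profile$mtdna[[mo]]
    cr[i] <- pool$haplotypes[sample(length(pool$freq), 1, prob = pool$freq)]
    cls <- table$truth$hybrid_class[i]
    pr <- phi[cls, ]
    pair <- sample(c("AA", "AB", "BB"), 1, prob = pr)
    sp <- switch(pair, AA = c("A", "A"), AB = c("A", "B"), BB = c("B", "B"))
    h1 <- profile$flanking[[sp[1]]]
    h2 <- profile$flanking[[sp[2]]]
    fl1[i] <- mutate_seq(h1, stats::rpois(1, private_mut_rate), protect = protect)
    fl2[i] <- mutate_seq(h2, stats::rpois(1, private_mut_rate), protect = protect)
  }
  ids <- table$individuals
  list(
    cr = seq_alignment(stats::setNames(cr, ids), marker = "CR"),
    flanking = seq_alignment(
      stats::setNames(c(fl1, fl2), c(paste0(ids, "_1"), paste0(ids, "_2"))),
      marker = "flanking")
  )
}

#' Simulate a complete two-species survey
#'
#' Orchestrates the generator: pure genotypes for both species (with null
#' alleles and dropout), true hybrids at the scenario's class fractions,
#' region/year metadata, field mislabels, and the attached mtDNA and
#' flanking-region alignments.
#'
#' @param profile a [make_profile()] result.
#' @param config a [scenario_config()].
#' @return list with elements `table` (msat_table, truth channel included),
#'   `cr`, `flanking` (seq_alignments), `profile`, `config`.
#' @export
simulate_dataset <- function(profile, config = scenario_config()) {
  set.seed(as.integer(config$seed))
  total <- config$n_a + config$n_b
  n_hyb <- round(config$hybrid_fractions * total)
  n_pure_a <- config$n_a - ceiling(sum(n_hyb) / 2)
  n_pure_b <- config$n_b - floor(sum(n_hyb) / 2)
  stopifnot(n_pure_a > 0, n_pure_b > 0)

  parts <- list(
    sample_pure_genotypes(profile, "A", n_pure_a, missing_rate = config$missing_rate),
    sample_pure_genotypes(profile, "B", n_pure_b, missing_rate = config$missing_rate)
  )
  for (cls in names(n_hyb)) {
    if (n_hyb[[cls]] > 0) {
      parts[[length(parts) + 1L]] <-
        sample_hybrid_genotypes(profile, cls, n_hyb[[cls]],
                                missing_rate = config$missing_rate)
    }
  }
  table <- Reduce(rbind_tables, parts)
  n <- length(table$individuals)
  ## neutral survey-style IDs in shuffled order, so exported files carry no
  ## trace of the truth channel
  ord <- sample.int(n)
  table <- subset_individuals(table, ord)
  ids <- sprintf("smp_%04d", seq_len(n))
  dimnames(table$a1) <- dimnames(table$a2) <- list(ids, table$loci)
  table$individuals <- ids
  table$metadata$id <- ids
  table$metadata$region <- sample(names(config$region_probs), n, replace = TRUE,
                                  prob = config$region_probs)
  table$metadata$year <- sample(c(2012L, 2013L), n, replace = TRUE)
  table <- inject_mislabels(table, config$mislabel_rate)
  seqs <- attach_sequences(table, profile)
  list(table = table, cr = seqs$cr, flanking = seqs$flanking,
       profile = profile, config = config)
}
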