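#' Geometric-decay allele frequencies hitting a target heterozygosity
#'
#' Solves `p_i` proportional to `r^(i-1)` for the rate `r` such that the
#' expected heterozygosity `1 - sum(p^2)` equals `he_target`. The maximum
#' attainable He for `n` alleles is `1 - 1/n` (uniform frequencies).
#'
#' @param n_alleles number of alleles (>= 1).
#' @param he_target target expected heterozygosity in `[0, 1 - 1/n)`.
#' @return numeric frequency vector of length `n_alleles` summing to 1.
#' @export
decay_freq <- function(n_alleles, he_target) {
  stopifnot(n_alleles >= 1, he_target >= 0)
  if (n_alleles == 1) {
    if (he_target > 1e-9) stop("target He infeasible for requested allele count")
    return(1)
  }
  cap <- 1 - 1 / n_alleles
  if (he_target >= cap - 1e-9)
    stop(sprintf("target He %.3f infeasible for %d alleles (max %.3f)",
                 he_target, n_alleles, cap))
  he_of <- function(r) {
    p <- r^(seq_len(n_alleles) - 1); p <- p / sum(p)
    1 - sum(p^2)
  }
  r <- stats::uniroot(function(r) he_of(r) - he_target,
                      interval = c(1e-9, 1 - 1e-12), tol = 1e-12)$root
  p <- r^(seq_len(n_alleles) - 1)
  p / sum(p)
}

## Re-sharpen a frequency vector (power transform) to restore a target He
## after mixing has flattened it; preserves the ordering of frequencies.
sharpen_freq <- function(p, he_target) {
  pos <- p > 0
  if (sum(pos) == 1) return(p)
  he_of <- function(g) {
    q <- p; q[pos] <- p[pos]^g; q <- q / sum(q)
    1 - sum(q^2)
  }
  lo <- 1e-3; hi <- 200
  if (he_of(hi) > he_target || he_of(lo) < he_target) return(p / sum(p))
  g <- stats::uniroot(function(g) he_of(g) - he_target, c(lo, hi), tol = 1e-10)$root
  q <- p; q[pos] <- p[pos]^g
  q / sum(q)
}

## Large-sample Weir-Cockerham variance components for one locus from known
## population frequencies (two populations, equal weight). In the n -> Inf
## limit the heterozygosity terms of the b and c components cancel, so
## theta_inf = sum(s2) / sum(s2/2 + pbar*(1-pbar)) — independent of the
## within-population mating structure (and hence of null alleles). Returns
## c(num, den) so loci combine as a ratio of sums.
theta_param_locus <- function(p1, p2) {
  alleles <- union(names(p1), names(p2))
  q1 <- stats::setNames(numeric(length(alleles)), alleles)
  q2 <- q1
  q1[names(p1)] <- p1; q2[names(p2)] <- p2
  pbar <- (q1 + q2) / 2
  s2 <- (q1 - q2)^2 / 2
  num <- sum(s2)
  den <- sum(s2 / 2 + pbar * (1 - pbar))
  c(num = num, den = den)
}

#' Expected multilocus FST implied by a species-pair profile
#'
#' Large-sample Weir-Cockerham theta computed from the profile's per-locus
#' allele frequencies (ratio of summed variance components).
#'
#' @param profile a [make_profile()] result.
#' @return numeric scalar.
#' @export
profile_expected_theta <- function(profile) {
  comp <- vapply(profile$loci, function(lc)
    theta_param_locus(lc$freq_a, lc$freq_b), numeric(2))
  sum(comp["num", ]) / sum(comp["den", ])
}

#' Default nine-locus template
#'
#' Per-locus allele counts, target expected heterozygosities and null-allele
#' percentages for the two species (A: *M. paradoxus*-like, B: *M.
#' capensis*-like), mirroring the study's diversity table: two
#' species-diagnostic loci with disjoint allele-size ranges, one convergent
#' locus carrying same-size alleles of independent origin, and six loci with
#' overlapping ranges.
#'
#' @return data frame with one row per locus.
#' @export
default_locus_template <- function() {
  data.frame(
    locus = c("MP318", "MP8748", "MP51", "MP8894", "MP374", "MP8450",
              "Mmerhk-20", "Mmerhk-29", "Mmerhk-3b"),
    na_a  = c(14, 27, 14, 22, 5, 45, 39, 27, 9),
    he_a  = c(0.737, 0.868, 0.526, 0.657, 0.349, 0.949, 0.908, 0.893, 0.322),
    nal_a = c(1.44, 0.99, 0.16, 1.13, 0.01, 4.13, 3.14, 2.78, 2.72),
    na_b  = c(10, 33, 13, 8, 5, 28, 27, 30, 10),
    he_b  = c(0.275, 0.870, 0.307, 0.540, 0.240, 0.906, 0.908, 0.911, 0.614),
    nal_b = c(8.05, 1.64, 0.19, 22.86, 6.93, 3.62, 0.59, 7.00, 11.92),
    role  = c("diagnostic", "", "", "", "", "diagnostic", "", "", "convergent"),
    base  = c(100, 400, 150, 500, 180, 300, 600, 700, 213),
    stringsAsFactors = FALSE
  )
}

#' Diagnostic positions of the flanking-region alignment
#'
#' The five fixed single-nucleotide differences and the 10 bp indel that
#' separate the two focal species over the 190 bp flanking fragment, plus the
#' outgroup states used to polarize them. Coordinates are 1-based, inclusive.
#'
#' @return list with `snp` (data frame: position, state for species A and B,
#'   outgroup state) and `indel` (positions 123-132; present in A, absent in
#'   B and the outgroup).
#' @export
flanking_diagnostics <- function() {
  list(
    snp = data.frame(
      position = c(62L, 106L, 120L, 156L, 189L),
      state_a = c("C", "A", "T", "T", "A"),
      state_b = c("T", "G", "C", "C", "G"),
      state_out = c("C", "G", "C", "T", "G"),
      stringsAsFactors = FALSE
    ),
    indel = list(positions = 123:132, present_in = "A",
                 insert_seq = "CTAATTACTA", state_out = "absent"),
    length = 190L
  )
}

## mutate a sequence at k distinct positions, avoiding a protected set
mutate_seq <- function(seq, k, protect = integer(0)) {
  if (k == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  ok <- setdiff(which(chars %in% c("A", "C", "G", "T")), protect)
  pos <- sample(ok, min(k, length(ok)))
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

## haplotype pool for one species: frequencies hit target haplotype diversity,
## sequences are the ancestral CR plus private mutations (controls pi roughly)
make_mtdna_pool <- function(ancestral, n_hap, h_target, mean_muts) {
  freq <- decay_freq(n_hap, h_target)
  seqs <- character(n_hap)
  seqs[1] <- ancestral
  if (n_hap > 1) {
    for (i in 2:n_hap) {
      k <- 1 + stats::rpois(1, max(mean_muts - 1, 0))
      seqs[i] <- mutate_seq(ancestral, k)
    }
  }
  names(freq) <- paste0("hap", seq_len(n_hap))
  list(haplotypes = stats::setNames(seqs, names(freq)), freq = freq)
}

#' Build a two-species profile
#'
#' Generates per-locus allele-size supports and frequency vectors for both
#' species so that (a) each locus hits its target expected heterozygosity
#' within tolerance, (b) diagnostic loci have disjoint supports, (c) the
#' convergent locus shares two allele sizes between species (the homoplasic
#' pair), and (d) the implied multilocus FST is calibrated towards
#' `theta_target` by blending the non-diagnostic loci's species frequencies
#' towards a common vector. Also builds species mtDNA haplotype pools and the
#' flanking-region haplotype templates (fixed SNPs + 10 bp indel, plus an
#' outgroup template).
#'
#' @param template data frame as [default_locus_template()].
#' @param seed integer seed.
#' @param theta_target calibration target for the expected multilocus FST.
#' @param convergent_share frequency given to the other species' homoplasic
#'   allele at the convergent locus.
#' @return object of class `species_pair_profile`.
#' @export
make_profile <- function(template = default_locus_template(), seed = 1,
                         theta_target = 0.126, convergent_share = 0.02) {
  stopifnot(all(c("locus", "na_a", "he_a", "na_b", "he_b", "role", "base") %in%
                  names(template)))
  set.seed(as.integer(seed))

  build_locus <- function(row, w) {
    base <- row$base
    if (row$role == "diagnostic") {
      sizes_a <- base + 2 * (seq_len(row$na_a) - 1)
      sizes_b <- max(sizes_a) + 6 + 2 * (seq_len(row$na_b) - 1)
      fa <- stats::setNames(decay_freq(row$na_a, row$he_a), sizes_a)
      fb <- stats::setNames(decay_freq(row$na_b, row$he_b), sizes_b)
    } else if (row$role == "convergent") {
      ## A centred on 241, B on 227; each carries the other's top allele at
      ## a small frequency (same size, independent origin)
      sizes_a <- c(241 + 2 * (seq_len(row$na_a - 1) - 1), 227)
      sizes_b <- c(227 - 2 * (seq_len(row$na_b - 1) - 1), 241)
      fa <- decay_freq(row$na_a - 1, row$he_a)
      fb <- decay_freq(row$na_b - 1, row$he_b)
      fa <- c(fa * (1 - convergent_share), convergent_share)
      fb <- c(fb * (1 - convergent_share), convergent_share)
      fa <- stats::setNames(sharpen_freq(fa, row$he_a), sizes_a)
      fb <- stats::setNames(sharpen_freq(fb, row$he_b), sizes_b)
    } else {
      S <- max(row$na_a, row$na_b) + 4
      sizes <- base + 2 * (0:(S - 1))
      pa_al <- pb_al <- pa_dv <- pb_dv <- stats::setNames(numeric(S), sizes)
      da <- decay_freq(row$na_a, row$he_a)
      db <- decay_freq(row$na_b, row$he_b)
      pa_al[seq_len(row$na_a)] <- da
      pb_al[seq_len(row$na_b)] <- db
      pa_dv[seq_len(row$na_a)] <- da
      pb_dv[S + 1 - seq_len(row$na_b)] <- db
      fa <- (1 - w) * pa_dv + w * pa_al
      fb <- (1 - w) * pb_dv + w * pb_al
      fa <- sharpen_freq(fa, row$he_a)
      fb <- sharpen_freq(fb, row$he_b)
    }
    list(name = row$locus, freq_a = fa, freq_b = fb,
         diagnostic = row$role == "diagnostic",
         convergent = row$role == "convergent",
         null_a = row$nal_a / 100, null_b = row$nal_b / 100)
  }

  build_all <- function(w) {
    lapply(seq_len(nrow(template)), function(i) build_locus(template[i, ], w))
  }
  theta_of <- function(w) {
    loci <- build_all(w)
    comp <- vapply(loci, function(lc)
      theta_param_locus(lc$freq_a, lc$freq_b), numeric(2))
    sum(comp["num", ]) / sum(comp["den", ])
  }
  t0 <- theta_of(0); t1 <- theta_of(1)
  if (!is.finite(t0) || !is.finite(t1)) stop("profile FST calibration failed")
  w <- if ((t0 - theta_target) * (t1 - theta_target) < 0) {
    stats::uniroot(function(w) theta_of(w) - theta_target, c(0, 1), tol = 1e-6)$root
  } else if (abs(t1 - theta_target) < abs(t0 - theta_target)) 1 else 0
  loci <- build_all(w)
  names(loci) <- template$locus
  if (any(is.na(loci))) stop("profile construction failed")

  ## null-allele frequencies must stay in the modelled range
  nal <- c(vapply(loci, `[[`, numeric(1), "null_a"),
           vapply(loci, `[[`, numeric(1), "null_b"))
  stopifnot(all(nal >= 0 & nal <= 0.30))

  ## mtDNA control region: two divergent ancestral sequences
  cr_len <- 406L
  anc_a <- paste(sample(c("A", "C", "G", "T"), cr_len, replace = TRUE), collapse = "")
  anc_b <- mutate_seq(anc_a, round(0.08 * cr_len))
  mtdna <- list(
    A = make_mtdna_pool(anc_a, n_hap = 8, h_target = 0.541, mean_muts = 1.0),
    B = make_mtdna_pool(anc_b, n_hap = 24, h_target = 0.893, mean_muts = 2.0)
  )

  ## flanking-region templates over a 190 bp alignment (indel kept as gaps)
  diag <- flanking_diagnostics()
  base_chars <- sample(c("A", "C", "G", "T"), diag$length, replace = TRUE)
  tmpl_a <- tmpl_b <- tmpl_out <- base_chars
  for (i in seq_len(nrow(diag$snp))) {
    p <- diag$snp$position[i]
    tmpl_a[p] <- diag$snp$state_a[i]
    tmpl_b[p] <- diag$snp$state_b[i]
    tmpl_out[p] <- diag$snp$state_out[i]
  }
  ins <- strsplit(diag$indel$insert_seq, "")[[1]]
  tmpl_a[diag$indel$positions] <- ins
  tmpl_b[diag$indel$positions] <- "-"
  tmpl_out[diag$indel$positions] <- "-"
  protect <- c(diag$snp$position, diag$indel$positions)
  flanking <- list(
    A = paste(tmpl_a, collapse = ""),
    B = paste(tmpl_b, collapse = ""),
    outgroup = mutate_seq(paste(tmpl_out, collapse = ""), 6, protect = protect),
    diagnostics = diag
  )

  out <- structure(list(loci = loci, mtdna = mtdna, flanking = flanking,
                        template = template, blend_w = w, seed = seed),
                   class = "species_pair_profile")
  out$theta_expected <- profile_expected_theta(out)
  out
}

#' @export
print.species_pair_profile <- function(x, ...) {
  cat(sprintf("<species_pair_profile> %d loci (%d diagnostic, %d convergent); expected multilocus FST %.3f\n",
              length(x$loci),
              sum(vapply(x$loci, `[[`, logical(1), "diagnostic")),
              sum(vapply(x$loci, `[[`, logical(1), "convergent")),
              x$theta_expected))
  invisible(x)
}

#' Scenario configuration for dataset simulation
#'
#' Encodes the study conditions of a simulated survey: how many individuals
#' per species, their distribution over the four sampling regions, which true
#' hybrid classes are present and at what fractions, the field mislabelling
#' rate, and the genotype dropout rate.
#'
#' @param scenario `"homoplasy"` (no real hybrids; apparent ones arise from
#'   convergent allele sizes) or `"hybridization"` (true hybrids present).
#' @param n_a,n_b individuals per species (defaults mirror the survey scale,
#'   ~1,140 total).
#' @param hybrid_fractions named fractions for F1, F2, BcA, BcB (of the total
#'   sample). Must be all zero in the homoplasy scenario.
#' @param region_probs sampling weights for regions N, W, SW, S.
#' @param mislabel_rate probability a field species label is flipped.
#' @param missing_rate extra whole-call dropout probability (on top of
#'   null-allele homozygosity).
#' @param seed integer seed.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("homoplasy", "hybridization"),
                            n_a = 570, n_b = 570,
                            hybrid_fractions = NULL,
                            region_probs = c(N = 413, W = 302, SW = 288, S = 160) / 1163,
                            mislabel_rate = 0.0413,
                            missing_rate = 0.02,
                            seed = 1) {
  scenario <- match.arg(scenario)
  if (is.null(hybrid_fractions)) {
    hybrid_fractions <- if (scenario == "homoplasy")
      c(F1 = 0, F2 = 0, BcA = 0, BcB = 0)
    else c(F1 = 0.05, F2 = 0, BcA = 0, BcB = 0)
  }
  hf <- hybrid_fractions[c("F1", "F2", "BcA", "BcB")]
  hf[is.na(hf)] <- 0
  names(hf) <- c("F1", "F2", "BcA", "BcB")
  if (any(hf < 0 | hf > 1)) stop("hybrid fractions must be in [0, 1]")
  if (scenario == "homoplasy" && any(hf > 0))
    stop("homoplasy scenario cannot contain true hybrids")
  stopifnot(mislabel_rate >= 0, mislabel_rate <= 1, missing_rate >= 0, missing_rate < 1)
  structure(list(scenario = scenario, n_a = n_a, n_b = n_b,
                 hybrid_fractions = hf, region_probs = region_probs,
                 mislabel_rate = mislabel_rate, missing_rate = missing_rate,
                 seed = seed),
            class = "scenario_config")
}
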