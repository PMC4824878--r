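#' @name flanking-verification
#' @title Flanking-region diagnostics
#' @description
#' An individual of admixed origin must be heterozygous at flanking-region
#' positions carrying species-specific fixed differences (one haplotype from
#' each species), while a pure individual whose microsatellite allele merely
#' converged in size carries two own-species haplotypes. These functions
#' genotype the diagnostic positions, classify individuals, and polarize
#' shared characters with an outgroup.
NULL

iupac_pairs <- c(A = "AA", C = "CC", G = "GG", T = "TT",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

## species call for one character at one diagnostic SNP
snp_state_call <- function(ch, a, b) {
  if (ch == a) "A" else if (ch == b) "B" else NA_character_
}

#' Genotype one individual's flanking haplotype pair at diagnostic positions
#'
#' Accepts either two phased haplotypes or a single consensus sequence with
#' IUPAC ambiguity codes (expanded into an arbitrary-phase pair; phase does
#' not matter for the verdict). The verdict is `HYBRID` when at least one
#' diagnostic position is heterozygous with species-opposed states or when
#' the two haplotypes assign to different species; `OWN-SPECIES` otherwise.
#' The indel is scored as presence/absence.
#'
#' @param hap1,hap2 haplotype strings over the alignment; `hap2` may be `NULL`
#'   when `hap1` is an IUPAC consensus.
#' @param diagnostics a [flanking_diagnostics()] list.
#' @return list: `verdict`, `species` (per-haplotype calls), `n_het_diagnostic`,
#'   `positions` (per-position detail data frame).
#' @export
flanking_genotype <- function(hap1, hap2 = NULL, diagnostics = flanking_diagnostics()) {
  if (is.null(hap2)) {
    ch <- strsplit(toupper(hap1), "")[[1]]
    amb <- iupac_pairs[ch]
    amb[is.na(amb)] <- paste0(ch[is.na(amb)], ch[is.na(amb)])
    hap1 <- paste(substr(amb, 1, 1), collapse = "")
    hap2 <- paste(substr(amb, 2, 2), collapse = "")
  }
  need <- max(diagnostics$snp$position, diagnostics$indel$positions)
  if (nchar(hap1) < need || nchar(hap2) < need)
    stop("alignment does not cover the diagnostic positions")
  c1 <- strsplit(toupper(hap1), "")[[1]]
  c2 <- strsplit(toupper(hap2), "")[[1]]

  rows <- list()
  for (i in seq_len(nrow(diagnostics$snp))) {
    p <- diagnostics$snp$position[i]
    s1 <- snp_state_call(c1[p], diagnostics$snp$state_a[i], diagnostics$snp$state_b[i])
    s2 <- snp_state_call(c2[p], diagnostics$snp$state_a[i], diagnostics$snp$state_b[i])
    rows[[length(rows) + 1L]] <- data.frame(
      position = p, type = "snp", hap1 = c1[p], hap2 = c2[p],
      call1 = s1, call2 = s2,
      het_opposed = !is.na(s1) && !is.na(s2) && s1 != s2,
      stringsAsFactors = FALSE)
  }
  ipos <- diagnostics$indel$positions
  pres1 <- !all(c1[ipos] == "-"); pres2 <- !all(c2[ipos] == "-")
  ## insertion present = species-A state, absent = species-B state
  i1 <- if (pres1) "A" else "B"; i2 <- if (pres2) "A" else "B"
  rows[[length(rows) + 1L]] <- data.frame(
    position = ipos[1], type = "indel",
    hap1 = if (pres1) "present" else "absent",
    hap2 = if (pres2) "present" else "absent",
    call1 = i1, call2 = i2, het_opposed = i1 != i2,
    stringsAsFactors = FALSE)
  pos <- do.call(rbind, rows)

  vote <- function(calls) {
    calls <- calls[!is.na(calls)]
    if (!length(calls)) return(NA_character_)
    if (sum(calls == "A") == sum(calls == "B")) return(NA_character_)
    if (sum(calls == "A") > sum(calls == "B")) "A" else "B"
  }
  sp1 <- vote(pos$call1); sp2 <- vote(pos$call2)
  hybrid <- any(pos$het_opposed) ||
    (!is.na(sp1) && !is.na(sp2) && sp1 != sp2)
  list(verdict = if (hybrid) "HYBRID" else "OWN-SPECIES",
       species = c(sp1, sp2),
       n_het_diagnostic = sum(pos$het_opposed),
       positions = pos)
}

#' Flanking verdicts for every individual in an alignment
#'
#' Pairs records named `<id>_1` / `<id>_2` (as produced by
#' [attach_sequences()]) and applies [flanking_genotype()] to each pair.
#'
#' @param aln a [seq_alignment()] of phased flanking haplotypes.
#' @param diagnostics a [flanking_diagnostics()] list.
#' @param ids individuals to score (default: all inferred from record names).
#' @return data frame per individual: `id`, `verdict`, `species` (consensus
#'   of the two haplotype calls, `"A/B"` when they disagree),
#'   `n_het_diagnostic`.
#' @export
flanking_verdicts <- function(aln, diagnostics = flanking_diagnostics(), ids = NULL) {
  nm <- names(aln$sequences)
  base <- unique(sub("_[12]$", "", nm))
  if (is.null(ids)) ids <- base
  out <- lapply(ids, function(id) {
    k1 <- paste0(id, "_1"); k2 <- paste0(id, "_2")
    if (!k1 %in% nm || !k2 %in% nm) stop("missing haplotype pair for ", id)
    fg <- flanking_genotype(aln$sequences[[k1]], aln$sequences[[k2]], diagnostics)
    sp <- fg$species
    lab <- if (any(is.na(sp))) NA_character_
           else if (sp[1] == sp[2]) sp[1] else "A/B"
    data.frame(id = id, verdict = fg$verdict, species = lab,
               n_het_diagnostic = fg$n_het_diagnostic, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Polarize shared diagnostic characters with an outgroup
#'
#' For each diagnostic character, compares the two focal species' states with
#' the outgroup: a state shared with the outgroup is (possibly) ancestral,
#' while a derived state private to one species (the 10 bp insertion) marks
#' that lineage and rules out identity by descent for allele sizes shared
#' between the focal species. The per-locus verdict is
#' `"ancestral-polymorphism-compatible"` only if no lineage-private derived
#' character separates the species; otherwise `"homoplasy"`.
#'
#' @param diagnostics a [flanking_diagnostics()] list with outgroup states.
#' @return list: `characters` (per-character classification data frame) and
#'   `verdict`.
#' @export
ancestral_vs_convergent <- function(diagnostics = flanking_diagnostics()) {
  rows <- list()
  for (i in seq_len(nrow(diagnostics$snp))) {
    s <- diagnostics$snp[i, ]
    cl <- if (is.na(s$state_out)) {
      warning("missing outgroup state at position ", s$position, "; skipped")
      next
    } else if (s$state_out == s$state_a && s$state_out == s$state_b) {
      "uninformative"
    } else if (s$state_out == s$state_a) {
      "ancestral in A; derived in B"
    } else if (s$state_out == s$state_b) {
      "ancestral in B; derived in A"
    } else {
      "uninformative (outgroup matches neither)"
    }
    rows[[length(rows) + 1L]] <- data.frame(position = s$position, type = "snp",
                                            classification = cl,
                                            private_derived = FALSE,
                                            stringsAsFactors = FALSE)
  }
  ## the indel: insertion present in A only, absent in B and the outgroup
  ins_private <- identical(diagnostics$indel$present_in, "A") &&
    identical(diagnostics$indel$state_out, "absent")
  rows[[length(rows) + 1L]] <- data.frame(
    position = diagnostics$indel$positions[1], type = "indel",
    classification = if (ins_private) "derived insertion private to A; not IBD"
                     else "insertion shared with outgroup",
    private_derived = ins_private, stringsAsFactors = FALSE)
  chars <- do.call(rbind, rows)
  verdict <- if (any(chars$private_derived)) "homoplasy"
             else "ancestral-polymorphism-compatible"
  list(characters = chars, verdict = verdict)
}
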