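---
title: "Hybridization or homoplasy? Methods behind the hakecheck workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybridization or homoplasy? Methods behind the hakecheck workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hakecheck)
```

## The problem

Two deeply divergent, partially sympatric marine fish species are surveyed
with a panel of nine microsatellite loci plus a mitochondrial control-region
(CR) fragment. Bayesian assignment on the microsatellites flags a number of
individuals as admixed. Three mechanisms can produce that signal:

1. **real heterospecific crosses** (F1, F2, backcrosses),
2. **retained ancestral polymorphism** (incomplete lineage sorting), and
3. **size homoplasy** — alleles identical in fragment size but not identical
   by descent, which the stepwise mutation model (SMM) produces readily.

`hakecheck` implements the complete decision workflow: simulate data with a
known truth, quantify how reliably each assignment model detects each hybrid
class, scan the empirical data across locus panels, and arbitrate flagged
individuals with the sequence of the microsatellite's flanking region, where
fixed single-nucleotide differences and a 10 bp indel distinguish the
species unambiguously.

## The synthetic-data generator

`make_profile()` builds a two-species profile mirroring the published
per-locus diversity table: nine loci with 5–45 alleles per species and
target expected heterozygosities between 0.24 and 0.95. Per-locus frequency
vectors are geometric-decay profiles whose rate is solved (by
`uniroot`) so that `1 - sum(p^2)` hits the target exactly; species
divergence at the six non-diagnostic loci comes from blending a
species-aligned and a species-reversed ordering of those weights, with the
blend weight calibrated towards a large-sample multilocus Weir–Cockerham
FST of 0.126, the study's empirical anchor (a power re-sharpening restores
each He after blending). With truly disjoint diagnostic ranges and the
published per-locus heterozygosities the implied FST has an attainable
floor of about 0.158 — in the large-sample limit
`theta = sum(s2) / sum(s2/2 + pbar(1-pbar))` a disjoint locus's
contribution is fixed by `1 - He` alone — so the default profile carries
that floor, the closest attainable value to the anchor; measured FST on
simulated surveys agrees with it. Two loci are *diagnostic*
(disjoint allele-size ranges); one locus is *convergent*: its supports are
disjoint except for two shared sizes (227 and 241 bp) carried at ~2%
frequency in the "wrong" species — the homoplasy signature.

Null alleles are modelled as one hidden allele per locus and species at the
published per-locus percentages (0–23%): a heterozygote carrying one null
looks homozygous, a null homozygote looks like a missing call. This is
exactly the estimand of the EM null-allele estimator, so parameter recovery
is testable. Field mislabelling flips the recorded species of a
Bernoulli(4.13%) subset; the simulated survey defaults to ~570 individuals
per species spread over the four sampling regions in the published
proportions (413:302:288:160). Desk-scale analyses in the tests and the
acceptance script use 120–300 individuals per species; those sizes are this
package's choice for routine re-runs and are stated where used.

mtDNA pools use a stick-breaking-style construction: per-species haplotype
frequencies follow a geometric decay solved to hit the target haplotype
diversities (0.541 / 0.893), with haplotypes derived from a species
ancestral sequence by private mutations (the two species' ancestral CRs
differ at ~8% of sites, so pool assignment is unambiguous). Flanking
haplotype templates carry the five fixed SNPs (positions 62, 106, 120, 156,
189; 1-based) and the 10 bp indel at 123–132, plus an outgroup template
matching the published outgroup states. What the generator does *not*
emulate: coalescent-realistic CR genealogies, linkage, ascertainment bias,
allele-size constraints, or genotyping error beyond nulls and dropout —
passing tests therefore demonstrate correctness of the machinery under the
stated model, not robustness to every artefact of real surveys.

## Hybrid-class simulation

`simulate_class()` draws gametes per locus from reference allele-frequency
spectra: pure classes take two own-spectrum gametes (HWE, linkage
equilibrium), F1 one from each species, F2 gametes each come from an
independently simulated F1 parent (one of its two alleles per locus, fair
coin), and backcrosses combine an F1 gamete with a pure one. Using a fresh
F1 parent per offspring avoids sibling structure in the panels. Reference
frequencies are recomputed from the selected reference individuals only
(ancestry coefficient at least 0.9 in a preliminary strict-assignment run;
80 per species by default), and panels default to 80 simulated individuals
per hybrid class.

## The Bayesian samplers

Both samplers are Gibbs samplers written for this package.

**Admixture model (K = 2).** Cluster allele frequencies get a
Dirichlet(λ = 1) prior. Without admixture, a latent whole-individual origin
is sampled from the genotype likelihood; with admixture, each gene copy
carries its own origin and individuals have `q ~ Dirichlet(α)` with a single
α updated by Gaussian Metropolis (step 0.25) under a uniform(0, 10) prior.
The correlated-frequency variant ties cluster frequencies to an ancestral
vector through the F-model, `p_k | p_A ~ Dirichlet(p_A (1 - F_k)/F_k)`, with
per-cluster drift `F_k` updated on the logit scale (uniform(0, 1) prior) and
the ancestral vector by a Dirichlet-proposal Metropolis step. The four
crossings of admixture × correlated are the study's models i–iv. Missing
genotypes are marginalized. Five independent runs (two at desk scale) are
aligned by the cluster permutation minimizing the summed absolute difference
of posterior mean ancestry to a reference run, then averaged; equal-tailed
credibility intervals are re-estimated from the pooled aligned draws. The
interval level defaults to 90% — the original analysis does not state one,
so it is a package choice and configurable.

**Six-class model.** Each individual belongs to one of PureA, PureB, F1,
F2, BcA, BcB. A class is characterized by the probability triple φ that an
unordered pair of gene copies has both copies from A, one from each, or
both from B — (1,0,0), (0,0,1), (0,1,0), (¼,½,¼), (½,½,0), (0,½,½). The
genotype likelihood per class mixes the three origin configurations:
`P(g | class) = φ_AA g(p_A, p_A) + φ_AB g(p_A, p_B) + φ_BB g(p_B, p_B)`.
Latent pair-origins (and, for heterozygotes with mixed origin, the phase)
are sampled per locus, allele frequencies get a Jeffreys Dirichlet(½) prior
by default, and class mixing proportions a Dirichlet(1). An individual is
called hybrid when the posterior mass of its two pure classes drops below
0.5; accuracy is scored on the maximum-a-posteriori class.

Chain schedules default to the study's 50,000 burn-in + 250,000 iterations
with 5 runs; the tests and the acceptance script run 300–2,000 burn-in with
1,200–8,000 iterations and 2 runs, which the chain-length robustness test
shows is sufficient on these panels (doubling the schedule moves posterior
means by < 0.02). At most 2,000 retained draws per run are stored for
interval estimation; thinning is increased automatically beyond that.

**Thresholds.** An individual is *admixed at t* when its minority ancestry
component is ≥ t (both t = 0.1 and t = 0.2 are always reported; ties count
as admixed). It is *retained* as a putative hybrid only when the 90%
credibility interval of the minority component clears a pure reference band,
`[0, 0.05]` by default. The original analysis says only "non-overlapping
credibility intervals"; comparing against the complementary component
instead would contradict its own worked outcome, so the pure-band rule is
used and both the band and the level are arguments.

## Population-genetic estimators

* Unbiased expected heterozygosity `(2n/(2n-1))(1 - Σp²)`; observed
  heterozygosity as the fraction of heterozygous genotyped individuals.
* Inbreeding: Weir–Cockerham's within-population *f* (the report documents
  the Nei form `1 - Ho/He` only as a cross-check); significance from 10,000
  within-population permutations of gene copies (add-one estimator,
  one-sided for heterozygote deficit).
* Allelic richness by rarefaction to a standard number of gene copies,
  `Σ_a [1 - C(2N - N_a, g)/C(2N, g)]`.
* Null alleles by EM under HWE with the null-homozygote-is-missing
  convention (tolerance 1e-8, cap 10,000 iterations; non-convergence is
  flagged, not thrown). The original software's exact missing-data variant
  is not published, so this convention is documented rather than asserted.
* FST: Weir–Cockerham θ, multilocus as the ratio of summed variance
  components; loci monomorphic across both populations contribute zero
  components. The ENA correction replaces each population's per-locus
  frequencies with the EM's null-excluded, renormalized visible
  frequencies; when every null estimate is ~0 the corrected estimator
  coincides with the uncorrected one exactly.
* Linkage disequilibrium: G statistic on the two-locus genotype table with
  within-population permutation of one locus.
* PCA on allele dosages (0/0.5/1), mean-imputed and column-centred, via
  SVD; axis 1 is oriented so species A sits on the negative side.
* The FST/He outlier scan simulates neutral SMM loci in a 100-deme island
  model whose migration rate is solved from the equilibrium
  `FST = 1/(1 + 4Nm (d/(d-1))²)` at the observed multilocus θ. Copies are
  initialized at equilibrium-scale dispersion so the forward phase (200
  generations by default) only relaxes the island structure. The envelope
  is the [0.025, 0.975] θ band conditional on He in 20 equal-count bins.
  This is a desk-scale forward replacement for the original coalescent
  implementation: same decision rule, not the same machinery.

## Homoplasy verification

`smm_divergence_sim()` evolves two Wright–Fisher populations independently
from a common monomorphic founder under strictly single-step symmetric
mutation (rate μ = 5e-4 per copy per generation by default), tracking every
copy's mutation count since the founder. Exchangeability lets the per-copy
model collapse to counts per (state, mutation-count) class — multinomial
resampling plus binomial mutation flows — which is exact and fast. Identity
in state then splits exactly: a cross-population pair identical in state is
identical by descent only when both lineages are unmutated, otherwise it is
homoplasic (back-mutations included). The reported summaries are the
cross-population identity-in-state probability, the ensemble proportion of
identical-in-state pairs that are homoplasic, the per-lineage unmutated
fraction (closed form `(1-μ)^t`), and the cross-population size-difference
variance. The variance is reported in Rao-Blackwellized form: with fair ±1
steps, `E[D² | K mutations] = K`, so the estimator is the mean mutation
count per copy summed over the two populations (closed form `2μt`); this
removes the mutation-direction Monte-Carlo noise while leaving the
genealogical variability, which at the default conditions (N = 1000,
t = 6000, 200 replicates) still contributes a standard error of roughly
2–3% of the expectation.

Flanking verification reads the five diagnostic SNPs and the indel
(presence/absence) from a phased haplotype pair or an IUPAC consensus:
HYBRID requires at least one heterozygous species-opposed position or
haplotypes assigning to different species. Outgroup polarization classifies
each diagnostic character; a derived character private to one species (the
insertion) rules out identity by descent for allele sizes shared between
the focal species. Tree checks use the K80 distance
`-½ ln((1-2P-Q)√(1-2Q))` with pairwise deletion (saturated pairs report
infinity with a warning and are capped at twice the largest finite distance
before tree building) and neighbor joining; monophyly is the unrooted
bipartition test. Maximum-likelihood search and branch support are
deliberately out of scope — reciprocal monophyly is the conclusion the
workflow actually uses.

## Numerical and design choices worth knowing

* All unordered genotype pairs are stored smaller-size-first; `{a,b}` and
  `{b,a}` are the same call; a whole call is either present or missing.
* Permutation p-values always use the add-one estimator.
* One master seed drives every stage; per-run and per-stage substreams are
  derived by fixed offsets, so the whole pipeline is bit-reproducible.
* `decay_freq()` refuses heterozygosity targets above the `1 - 1/Na` cap.
* The profile's FST calibration solves for the blend weight in [0, 1]; if
  the target is outside the attainable range the closer endpoint is used.
* Reduced locus panels are data-driven: the 8-locus panel drops loci whose
  EM null-frequency estimate exceeds 15% in either species, the 6-locus
  panel additionally drops the diagnostic/outlier trio (the published names
  are the defaults, the rules are arguments).
* "Identified by more than one method" is operationalized as flagged by at
  least 2 of the model × threshold columns; configurable.
* The six-class sampler's species labels are oriented against the field
  labels (majority correct); the admixture sampler orients cluster 1 to
  species A the same way.

## Limitations

Backcross detection is weak at nine loci — that is a finding, not a defect:
the panels carry limited information beyond F1. The ENA correction here
follows the null-excluded renormalized-frequency definition; it reproduces
the estimator's invariants, not necessarily the original implementation's
third-decimal behaviour. The outlier scan's island model is a structural
surrogate; its envelope is calibrated to the observed multilocus θ only.
CR sequences are generated without recombination or rate heterogeneity.
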