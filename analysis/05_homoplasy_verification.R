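#!/usr/bin/env Rscript
# Arbitration step: are the microsatellite-flagged "hybrids" heterospecific
# crosses, retained ancestral polymorphism, or size homoplasy? Uses the
# flanking-region diagnostic positions, an outgroup-polarized character
# table, a K80 neighbor-joining gene tree, and the stepwise-mutation
# divergence simulation.

suppressPackageStartupMessages(library(hakecheck))
sim <- readRDS("results/survey.rds")
tab <- sim$table
calls <- utils::read.delim("results/hybrid_calls_p9.tsv")
flagged <- calls$id[calls$consensus >= 2]
cat(sprintf("%d individuals flagged by two or more method/threshold columns\n",
            length(flagged)))

## 1. diagnostic-position genotyping of the flagged individuals
verd <- flanking_verdicts(sim$flanking, ids = if (length(flagged)) flagged
                                              else tab$individuals[1:10])
utils::write.table(verd, "results/flanking_verdicts.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("flanking verdicts: %d OWN-SPECIES, %d HYBRID; heterozygous sites: %d\n",
            sum(verd$verdict == "OWN-SPECIES"), sum(verd$verdict == "HYBRID"),
            sum(verd$n_het_diagnostic)))

## 2. outgroup polarization of the shared characters
pol <- ancestral_vs_convergent(sim$profile$flanking$diagnostics)
utils::write.table(pol$characters, "results/character_polarization.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("character polarization verdict: %s\n", pol$verdict))

## 3. K80 neighbor-joining gene tree with the outgroup
set.seed(5)
sp <- sim$table$truth$true_species
ids <- c(sample(tab$individuals[sp == "A"], 15),
         sample(tab$individuals[sp == "B"], 15), flagged)
ids <- unique(ids)
seqs <- c(sim$flanking$sequences[paste0(ids, "_1")],
          outgroup = sim$profile$flanking$outgroup)
labels <- setNames(c(sp[match(ids, tab$individuals)], NA), names(seqs))
tree <- nj_monophyly(seq_alignment(seqs), labels)
writeLines(tree$newick, "results/flanking_nj.nwk")
cat(sprintf("reciprocal monophyly: A %s, B %s\n",
            tree$monophyly[["A"]], tree$monophyly[["B"]]))

## 4. how fast does size homoplasy accumulate under stepwise mutation?
smm <- smm_divergence_sim(smm_config(mu = 5e-4, t = 6000, n = 1000,
                                     replicates = 200, seed = 6))
print(smm)
utils::write.table(smm$replicates, "results/smm_replicates.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nafter 6,000 generations at mu = 5e-4 essentially every cross-species\n")
cat("size match is homoplasic: shared allele sizes are not shared descent.\n")
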