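#!/usr/bin/env Rscript
# Simulate the two-species microsatellite survey under the homoplasy
# scenario: no real hybrids, but one locus carries convergent same-size
# alleles, several loci carry null alleles, and ~4% of field labels are
# wrong. Writes the standard-format exports plus the hidden truth table.

suppressPackageStartupMessages(library(hakecheck))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 17
dir.create("results", showWarnings = FALSE)

profile <- make_profile(seed = seed)
cat(sprintf("profile: expected multilocus FST %.3f (blend w = %.2f)\n",
            profile$theta_expected, profile$blend_w))

sim <- simulate_dataset(profile,
                        scenario_config("homoplasy", n_a = 300, n_b = 300,
                                        mislabel_rate = 0.0413, seed = seed))
tab <- sim$table
cat(sprintf("simulated %d individuals x %d loci; %d field mislabels (%.2f%%)\n",
            nrow(tab$a1), length(tab$loci), sum(tab$truth$mislabelled),
            100 * mean(tab$truth$mislabelled)))

write_genepop(tab, "results/survey.gen", title = "simulated hake survey")
write_metadata(tab$metadata, "results/survey_metadata.tsv")
write_fasta(sim$cr, "results/survey_cr.fasta")
write_fasta(sim$flanking, "results/survey_flanking.fasta")
utils::write.table(cbind(id = tab$individuals, tab$truth),
                   "results/survey_truth.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
saveRDS(sim, "results/survey.rds")   # convenience for the downstream scripts
cat("wrote results/survey.{gen,_metadata.tsv,_cr.fasta,_flanking.fasta,_truth.tsv}\n")
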