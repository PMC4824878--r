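#!/usr/bin/env Rscript
# Descriptive and inferential population genetics of the simulated survey:
# per-locus diversity, mtDNA diversity, species differentiation with and
# without the null-allele (ENA) correction, allele-dosage PCA, and the
# FST/He outlier scan.

suppressPackageStartupMessages(library(hakecheck))
sim <- readRDS("results/survey.rds")
tab <- sim$table
sp <- tab$truth$true_species

div <- diversity_report(tab, group = sp, n_perm = 1000, seed = 1)
utils::write.table(div, "results/diversity_by_locus.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("mean Ho: species A %.3f, species B %.3f\n",
            mean(div$ho[div$population == "A"]),
            mean(div$ho[div$population == "B"])))
cat(sprintf("loci with FIS p < 0.05: %d of %d tests\n",
            sum(div$fis_p < 0.05, na.rm = TRUE), sum(!is.na(div$fis_p))))

mt <- mtdna_diversity(sim$cr, group = sp)
utils::write.table(mt, "results/mtdna_diversity.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(mt)

ta <- subset_individuals(tab, which(sp == "A"))
tb <- subset_individuals(tab, which(sp == "B"))
wc <- fst_wc(ta, tb, n_perm = 999, seed = 2)
ena <- fst_ena(ta, tb)
cat(sprintf("multilocus FST: %.3f uncorrected (p = %.3f), %.3f ENA-corrected\n",
            wc$theta, wc$p_value, ena$theta))

pc <- pca_allele_freq(tab)
utils::write.table(data.frame(id = tab$individuals, species = sp,
                              axis1 = pc$scores[, 1], axis2 = pc$scores[, 2]),
                   "results/pca_coordinates.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("PCA axis 1 explains %.1f%% of dosage variance\n",
            100 * pc$explained[1]))

scan <- fdist_outlier_scan(ta, tb, n_sims = 2000, seed = 3)
utils::write.table(scan$loci, "results/outlier_scan.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("outlier loci (high):",
    paste(scan$loci$locus[scan$loci$outlier == "high"], collapse = ", "), "\n")
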