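#!/usr/bin/env Rscript
# Empirical hybrid scan on the simulated survey: the full nine-locus panel,
# the panel without high-null-allele loci, and the panel without the
# diagnostic/outlier loci, plus the mito-nuclear reconciliation.

suppressPackageStartupMessages(library(hakecheck))
sim <- readRDS("results/survey.rds")
tab <- sim$table

mtsp <- assign_mtdna_species(sim$cr, sim$profile)
cfg <- study_config(models = c("i", "ii", "iii", "iv"),
                    burnin = 1000, steps = 4000, thin = 10, n_runs = 2,
                    seed = 4321)
scan <- empirical_scan(tab, config = cfg, mtdna_species = mtsp, run_nh = TRUE)

for (pn in names(scan$calls)) {
  utils::write.table(scan$calls[[pn]],
                     sprintf("results/hybrid_calls_%s.tsv", pn),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
utils::write.table(scan$summary, "results/hybrid_call_summary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(scan$summary, row.names = FALSE)
cat("\ndropping the diagnostic loci inflates the apparent hybrid count;\n")
cat("few calls survive the credibility-interval non-overlap rule.\n\n")

## mito-nuclear reconciliation using the model-free nuclear majority call
prelim <- run_admixture(tab, admixture_spec(admixture = FALSE, burnin = 500,
                                            steps = 2000, thin = 5,
                                            n_runs = 2, seed = 99))
recon <- mitonuclear_discordance(nuclear_species(prelim), mtsp,
                                 setNames(tab$metadata$species, tab$individuals))
utils::write.table(recon, "results/mitonuclear_reconciliation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("mito-nuclear: %d field mislabels recovered, %d true discordances\n",
            sum(recon$status == "field mislabel"),
            sum(recon$status == "discordant")))
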