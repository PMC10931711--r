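#!/usr/bin/env Rscript
# Simulate the two-cohort immunotherapy study design: a discovery cohort of
# 23 responders / 82 non-responders and a replicate cohort of 14 / 13, sharing
# one planted structure (50 differential PDUI events of size 0.2, 20 of them
# coupled to immune pathways, a hub APA factor regulating 30 of the
# differential events, survival driven by a response-linked latent score).
# Writes the pipeline input files plus the ground-truth record.

suppressMessages(library(irapass))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- simulation_config(seed = 1)
pair <- simulate_cohort_pair(cfg)

for (nm in names(pair)) {
  co <- pair[[nm]]
  write_pdui_table(co$pdui, file.path(out, paste0(nm, "_pdui.tsv")))
  write_expression(co$expr, file.path(out, paste0(nm, "_expression.tsv")))
  write_clinical(co$clinical, file.path(out, paste0(nm, "_clinical.tsv")))
}
write_gmt(pair$cohort1$gene_sets, file.path(out, "gene_sets.gmt"))
write_interactions(pair$cohort1$interactions, file.path(out, "interactions.tsv"))
writeLines(pair$cohort1$truth$factors, file.path(out, "apa_factors.txt"))

truth <- pair$cohort1$truth
write.table(truth$planted_diff_events, file.path(out, "truth_diff_events.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(truth$immune_events, file.path(out, "truth_immune_events.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(truth$factor_targets, file.path(out, "truth_factor_targets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# T-cell proportion table for the subgroup analyses
tc <- simulate_tcell_proportions(nrow(pair$cohort1$clinical), seed = 1)
write.table(data.frame(sample_id = rownames(tc$proportions), tc$proportions,
                       archetype = tc$archetype, check.names = FALSE),
            file.path(out, "tcell_proportions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("cohort1:", nrow(pair$cohort1$clinical), "samples;",
    nrow(pair$cohort1$pdui), "events;", nrow(pair$cohort1$expr), "genes\n")
cat("planted:", nrow(truth$planted_diff_events), "differential events,",
    nrow(truth$immune_events), "immune-coupled; hub factor",
    truth$hub_factor, "\n")
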