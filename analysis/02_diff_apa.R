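#!/usr/bin/env Rscript
# Differential 3'-UTR usage between responders and non-responders in each
# cohort (|delta PDUI| >= 0.1 and permutation p < 0.05, B = 1000), plus the
# T-cell subgroup analyses: one-vs-rest contrasts over TA/TS/TN and events
# with a monotone PDUI gradient across the subgroup order.

suppressMessages(library(irapass))

inp <- "results/synthetic"; out <- "results/diff_apa"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (nm in c("cohort1", "cohort2")) {
  pdui <- read_pdui_table(file.path(inp, paste0(nm, "_pdui.tsv")))
  clin <- read_clinical(file.path(inp, paste0(nm, "_clinical.tsv")))
  lab <- setNames(clin$response, clin$sample_id)
  res <- diff_apa(pdui, lab, B = 1000, seed = 1)
  write_diff_apa(res, file.path(out, paste0(nm, "_diff_apa.tsv")))
  cat(nm, ":", sum(res$called), "differential events (",
      sum(res$direction == "shortened"), "shortened /",
      sum(res$direction == "lengthened"), "lengthened in non-responders )\n")
}

# subgroups from the simulated T-cell proportions of cohort 1
tc <- read.delim(file.path(inp, "tcell_proportions.tsv"), check.names = FALSE)
prop <- as.matrix(tc[, names(tcell_population_classes())])
rownames(prop) <- tc$sample_id
sub <- assign_tcell_subgroup(prop)
cat("subgroup sizes:", paste(names(table(sub)), table(sub), collapse = "; "), "\n")

pdui1 <- read_pdui_table(file.path(inp, "cohort1_pdui.tsv"))
ovr <- one_vs_rest_differential(pdui1, sub[colnames(pdui1)], B = 1000, seed = 1)
for (g in names(ovr)) {
  write_diff_apa(ovr[[g]], file.path(out, paste0("subgroup_", g, "_vs_rest.tsv")))
  cat("contrast", g, "vs rest:", sum(ovr[[g]]$called), "events\n")
}

gm <- group_mean_pdui(pdui1, sub[colnames(pdui1)])
grad <- gradient_events(gm)
write.table(grad, file.path(out, "gradient_events.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("gradient events across TA -> TS -> TN:", nrow(grad), "\n")
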