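#!/usr/bin/env Rscript
# Extract the feature-based module: take the largest connected component of
# the protein-interaction network, seed personalized PageRank (damping 0.85)
# on the parental genes of the fitted model's features, and keep the top 200
# genes by impact score.

suppressMessages(library(irapass))

inp <- "results/synthetic"; out <- "results/ppi_module"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ppi <- read_interactions(file.path(inp, "interactions.tsv"))
coefs <- read.delim("results/irapass/model_coefficients.tsv")
model <- irapass_model(coefs$event_id, coefs$coefficient)

res <- ppi_feature_module(ppi, model, top_k = 200)
cat("largest component:", res$component_size, "nodes;",
    length(res$seeds), "seed genes present\n")
write.table(res$module, file.path(out, "feature_module.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("top 5 module genes:", paste(head(res$module$gene, 5), collapse = ", "), "\n")
cat("seed genes inside the module:", sum(res$module$is_seed), "\n")
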