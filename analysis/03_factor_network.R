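#!/usr/bin/env Rscript
# Build the APA-events-to-APA-factors (ATF) network of cohort 1: Spearman
# correlation edges between the 98 APA factors and the differential events,
# augmented with protein-interaction edges, then rank nodes with the twelve
# topology algorithms and aggregate factor ranks (Borda) into master factors.

suppressMessages(library(irapass))

inp <- "results/synthetic"; out <- "results/factor_network"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pdui <- read_pdui_table(file.path(inp, "cohort1_pdui.tsv"))
expr <- read_expression(file.path(inp, "cohort1_expression.tsv"))
factors <- read_gene_list(file.path(inp, "apa_factors.txt"))
ppi <- read_interactions(file.path(inp, "interactions.tsv"))
diff <- read_diff_apa("results/diff_apa/cohort1_diff_apa.tsv")

called <- diff$event_id[diff$called]
fx <- expression_table(unclass(expr)[factors, , drop = FALSE])
pd <- pdui_table(unclass(pdui)[called, , drop = FALSE])
edges <- factor_event_correlation(fx, pd)
write.table(edges, file.path(out, "correlation_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

g <- build_atf_network(edges, ppi, factors, called,
                       setNames(diff$direction, diff$event_id)[called])
cat("ATF network:", igraph::vcount(g), "nodes,", igraph::ecount(g), "edges (",
    sum(igraph::V(g)$type == "factor"), "factors )\n")

cs <- centrality_suite(g, seed = 1)
write.table(data.frame(node = rownames(cs$scores), cs$scores,
                       check.names = FALSE),
            file.path(out, "centrality_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

mf <- master_factors(cs, g, k = 10)
write.table(mf, file.path(out, "master_factors.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("top master factors:", paste(head(attr(mf, "master"), 5), collapse = ", "), "\n")

truth_targets <- read.delim(file.path(inp, "truth_factor_targets.tsv"))
hub <- names(sort(table(truth_targets$factor), decreasing = TRUE))[1]
cat("planted hub", hub, "has Borda rank", which(mf$factor == hub), "\n")
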