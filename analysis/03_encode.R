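#!/usr/bin/env Rscript
# Pathway preselection and image encoding: restrict the expression matrix
# to genes belonging to at least one pathway (dropping unmapped pathway
# members), then lay each sample out as a pathways x gene-slots image,
# rows grouped by the eight KEGG-style groups, min-max scaled on the
# training partition.

suppressMessages(library(teptools))
expr <- read_expr_tsv("results/data/expression.tsv",
                      "results/data/expr_metadata.tsv")
db <- read_gmt("results/data/pathways.gmt")

split <- stratified_split(sample_labels(expr), seed = 20260928L)
genes <- preselect_features(db, expr)
cat(sprintf("preselection: %d of %d measured genes belong to a pathway\n",
            length(genes), nrow(expr$values)))

imgs <- build_images(expr, db, train_ids = split$train_ids)
print(imgs)
cat(sprintf("image grid: %d pathway rows x %d gene slots; scaling [%.3f, %.3f] from %d training samples\n",
            dim(imgs$values)[1], dim(imgs$values)[2],
            imgs$scale["min"], imgs$scale["max"], length(split$train_ids)))

dir.create("results", showWarnings = FALSE)
write.table(data.frame(gene = genes), "results/preselected_features.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
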