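#!/usr/bin/env Rscript
# Stage 7: descriptive structure of the fitted dimensions.
#
# Agglomerative clustering of dimensions over their image profiles with the
# dimension correlation matrix, and a 2-D t-SNE map of the similarity space
# (classical-MDS initialization, dual perplexities 5 and 30, 1,000
# iterations).

suppressPackageStartupMessages(library(spose2afc))

out <- "results/synthetic-study"
seed <- 20260924
emb <- read_embedding(file.path(out, "embedding.tsv"))
sim_model <- read_similarity(file.path(out, "similarity_model.csv"))

cl <- cluster_dimensions(emb)
write.csv(cl$cor_matrix, file.path(out, "dimension_correlations.csv"))
cat(sprintf(
  "dimension correlations: mean %.2f, SD %.2f, range %.2f to %.2f\n",
  cl$cor_summary["mean"], cl$cor_summary["sd"], cl$cor_summary["min"],
  cl$cor_summary["max"]))
merge_order <- paste(apply(cl$hclust$merge, 1, paste, collapse = "+"),
                     collapse = "; ")
cat("dendrogram merge order:", merge_order, "\n")

coords <- export_map(sim_model, perplexities = c(5, 30), n_iter = 1000,
                     seed = seed + 14)
write.csv(coords, file.path(out, "tsne_coordinates.csv"), row.names = FALSE)
cat(sprintf("t-SNE map written for %d images\n", nrow(coords)))
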