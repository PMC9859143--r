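#!/usr/bin/env Rscript
# Step 4 — topological features per patient node.
#
# Degree (plus in/out/weighted under the undirected convention), closeness,
# betweenness, eigenvector, HITS hub/authority, PageRank, local clustering,
# Louvain community, the 3 nearest embedding-space neighbours and the mean
# Jaccard neighbour-set similarity to them.

suppressMessages(library(lbwgraph))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

g <- import_graph("results/knowledge_graph")
emb <- read_embeddings("results/embeddings.csv")
topo <- compute_topo_table(g, emb, k = 3, seed = seed + 3000L)
write_topo_table(topo, "results/topo_features.csv")

cat(sprintf("topological table: %d patients, %d communities, PageRank total %.6f\n",
            nrow(topo), length(unique(topo$community)),
            attr(topo, "pagerank_total")))
cat("wrote results/topo_features.csv\n")
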