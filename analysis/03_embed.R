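#!/usr/bin/env Rscript
# Step 3 — biased random walks and node embeddings.
#
# Second-order walks (return parameter p, in-out parameter q) explore the
# knowledge graph; a skip-gram model with negative sampling over the walk
# sequences yields a 64-dimensional vector per node. Patients who share
# complications end up close in embedding space.

suppressMessages(library(lbwgraph))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

g <- import_graph("results/knowledge_graph")
wp <- walk_params(p = 1, q = 1, walk_length = 80, walks_per_node = 10,
                  seed = seed + 1000L)
corpus <- generate_walks(g, wp)
cat(sprintf("walk corpus: %d walks over %d nodes\n",
            length(corpus$walks), length(corpus$nodes)))

emb <- train_embeddings(corpus, embedding_params(dimensions = 64,
                                                 seed = seed + 2000L))
write_embeddings(emb, "results/embeddings.csv")
cat(sprintf("embeddings: %d x %d, written to results/embeddings.csv\n",
            nrow(emb), ncol(emb)))
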