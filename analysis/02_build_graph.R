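#!/usr/bin/env Rscript
# Step 2 — build the patient-complication knowledge graph.
#
# Binary complications and categorical factors become entity nodes; each
# patient links to the complications they have and to their category values.
# Continuous measures (age, BMI, ...) stay on the patient node as
# properties, and the outcome label never enters the graph.

suppressMessages(library(lbwgraph))
cohort <- read_cohort("results/cohort.csv")

fac_cols <- setdiff(names(cohort), c("patient_id", "label"))
entity_cols <- fac_cols[vapply(fac_cols, function(cn)
  lbwgraph:::is_binaryish(cohort[[cn]]) || !is.numeric(cohort[[cn]]),
  logical(1))]
property_cols <- setdiff(fac_cols, entity_cols)

g <- build_graph(cohort, property_columns = property_cols,
                 entity_columns = entity_cols)
export_graph(g, "results/knowledge_graph")

cat(sprintf("graph: %d nodes (%d patients, %d entities), %d edges\n",
            igraph::vcount(g), length(patient_nodes(g)),
            length(entity_nodes(g)), igraph::ecount(g)))
cat("wrote results/knowledge_graph.edges.tsv, results/knowledge_graph.nodes.csv\n")
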