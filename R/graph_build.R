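#' Build a patient-complication knowledge graph
#'
#' Transforms a cohort table into an undirected bipartite graph G = (V, E).
#' Every patient is a node; every binary entity column contributes a single
#' entity node, with an edge to each patient whose value is positive (a
#' patient with gestational diabetes is linked to the gestational-diabetes
#' node); every categorical entity column contributes one entity node per
#' observed category (blood group "A", ...), each patient linking to exactly
#' the node of its value. Continuous measures listed in `property_columns`
#' become patient-node properties, never nodes. The outcome label is
#' structurally barred from the graph.
#'
#' @param cohort A `cohort_table` (or data.frame with `patient_id`).
#' @param entity_columns Columns turned into entity nodes (binary or
#'   categorical).
#' @param property_columns Columns attached to patient nodes as properties.
#' @return An igraph object of class `c("kg", "igraph")` with vertex
#'   attributes `name` (`"p<id>"` for patients, `"<column>:<value>"` or
#'   `"<column>"` for entities), `kind` (`"patient"`/`"entity"`) and one
#'   attribute per property column on patient nodes. All edge weights are 1.
#' @export
build_graph <- function(cohort, property_columns = character(),
                        entity_columns) {
  stopifnot(is.data.frame(cohort), "patient_id" %in% names(cohort))
  unknown <- setdiff(c(property_columns, entity_columns), names(cohort))
  if (length(unknown))
    stop("unknown columns: ", paste(unknown, collapse = ", "))
  if ("label" %in% c(property_columns, entity_columns))
    stop("the outcome label may not enter the graph (leakage guard)")
  if (length(intersect(property_columns, entity_columns)))
    stop("property_columns and entity_columns must be disjoint")

  pat_names <- paste0("p", cohort$patient_id)
  ent_names <- character(0)
  from <- character(0); to <- character(0)
  for (cn in entity_columns) {
    v <- cohort[[cn]]
    if (is_binaryish(v)) {
      ent <- cn
      ent_names <- c(ent_names, ent)
      pos <- !is.na(v) & as.numeric(v) > 0
      from <- c(from, pat_names[pos]); to <- c(to, rep(ent, sum(pos)))
    } else {
      lev <- sort(unique(as.character(v[!is.na(v)])))
      ents <- paste0(cn, ":", lev)
      ent_names <- c(ent_names, ents)
      ok <- !is.na(v)
      from <- c(from, pat_names[ok])
      to <- c(to, paste0(cn, ":", as.character(v[ok])))
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(pat_names), name = pat_names,
                            kind = "patient")
  g <- igraph::add_vertices(g, length(ent_names), name = ent_names,
                            kind = "entity")
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), weight = 1)
  else
    g <- igraph::set_edge_attr(g, "weight", value = numeric(0))
  for (cn in property_columns) {
    vals <- rep(NA, igraph::vcount(g))
    vals[seq_along(pat_names)] <- cohort[[cn]]
    g <- igraph::set_vertex_attr(g, cn, value = vals)
  }
  class(g) <- c("kg", class(g))
  g
}

is_binaryish <- function(v) {
  (is.numeric(v) || is.logical(v) || is.integer(v)) &&
    all(stats::na.omit(as.numeric(v)) %in% c(0, 1))
}

#' Patient / entity node names of a knowledge graph
#' @param graph A `kg` graph.
#' @return Character vector of vertex names.
#' @export
patient_nodes <- function(graph) {
  igraph::V(graph)$name[igraph::V(graph)$kind == "patient"]
}

#' @rdname patient_nodes
#' @export
entity_nodes <- function(graph) {
  igraph::V(graph)$name[igraph::V(graph)$kind == "entity"]
}

#' Export / import a knowledge graph as plain text
#'
#' Writes a tab-separated edge list (`source`, `target`, `weight`) and a node
#' table CSV (`node_id`, `kind`, plus one column per patient property). The
#' pair round-trips losslessly through [import_graph()].
#'
#' @param graph A `kg` graph.
#' @param path Basename; `<path>.edges.tsv` and `<path>.nodes.csv` are
#'   written.
#' @return Invisibly, the two file paths.
#' @export
export_graph <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  edge_path <- paste0(path, ".edges.tsv")
  node_path <- paste0(path, ".nodes.csv")
  utils::write.table(
    data.frame(source = el[, 1], target = el[, 2], weight = w),
    edge_path, sep = "\t", row.names = FALSE, quote = FALSE)
  attrs <- igraph::vertex_attr_names(graph)
  nt <- data.frame(node_id = igraph::V(graph)$name,
                   kind = igraph::V(graph)$kind,
                   stringsAsFactors = FALSE)
  for (a in setdiff(attrs, c("name", "kind")))
    nt[[a]] <- igraph::vertex_attr(graph, a)
  utils::write.csv(nt, node_path, row.names = FALSE)
  invisible(c(edges = edge_path, nodes = node_path))
}

#' @rdname export_graph
#' @export
import_graph <- function(path) {
  edge_path <- paste0(path, ".edges.tsv")
  node_path <- paste0(path, ".nodes.csv")
  nt <- utils::read.csv(node_path, stringsAsFactors = FALSE)
  et <- utils::read.table(edge_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(nt), name = nt$node_id, kind = nt$kind)
  if (nrow(et))
    g <- igraph::add_edges(g, rbind(et$source, et$target), weight = et$weight)
  else
    g <- igraph::set_edge_attr(g, "weight", value = numeric(0))
  for (a in setdiff(names(nt), c("node_id", "kind")))
    g <- igraph::set_vertex_attr(g, a, value = nt[[a]])
  class(g) <- c("kg", class(g))
  g
}
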