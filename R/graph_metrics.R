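#' Degree features of a node
#'
#' On the undirected patient-complication graph a node's degree is its
#' neighbour count; in-degree and out-degree both equal the degree (an
#' undirected edge is counted in both directions) and the weighted degree is
#' their sum, i.e. twice the degree.
#'
#' @param graph A `kg`/igraph graph.
#' @param node Vertex name.
#' @return Named numeric vector `(degree, in_degree, out_degree,
#'   weighted_degree)`.
#' @export
degree_features <- function(graph, node) {
  check_node(graph, node)
  d <- igraph::degree(graph, node)
  c(degree = unname(d), in_degree = unname(d), out_degree = unname(d),
    weighted_degree = unname(2 * d))
}

#' Closeness centrality
#'
#' Reciprocal of the sum of shortest-path distances from the node to every
#' other node reachable from it (distances restricted to the node's connected
#' component); 0 for isolated nodes.
#'
#' @inheritParams degree_features
#' @param node Vertex name, or `NULL` (default) for a named vector over all
#'   nodes.
#' @return Nonnegative real (named vector when `node` is `NULL`).
#' @export
closeness_centrality <- function(graph, node = NULL) {
  if (!is.null(node)) check_node(graph, node)
  d <- igraph::distances(graph, v = if (is.null(node)) igraph::V(graph)
                                    else node)
  d[!is.finite(d)] <- 0
  s <- rowSums(d)
  out <- ifelse(s == 0, 0, 1 / s)
  if (is.null(node)) stats::setNames(out, igraph::V(graph)$name)
  else unname(out)
}

#' Betweenness centrality
#'
#' Sum over unordered pairs of other nodes of the fraction of shortest paths
#' between them that pass through the node; unnormalized.
#'
#' @inheritParams closeness_centrality
#' @return Nonnegative real (named vector when `node` is `NULL`).
#' @export
betweenness_centrality <- function(graph, node = NULL) {
  if (is.null(node))
    return(igraph::betweenness(graph, directed = FALSE))
  check_node(graph, node)
  unname(igraph::betweenness(graph, v = node, directed = FALSE))
}

#' Eigenvector centrality
#'
#' Leading eigenvector of the adjacency matrix, nonnegative and normalized to
#' unit Euclidean length. Nodes in components other than the one carrying the
#' leading eigenvalue get (numerically) zero scores.
#'
#' @param graph A `kg`/igraph graph with at least one edge.
#' @return Named nonnegative numeric vector over all nodes, unit L2 norm.
#' @export
eigenvector_centrality <- function(graph) {
  if (igraph::ecount(graph) == 0) stop("eigenvector centrality needs >= 1 edge")
  ad <- igraph::arpack_defaults
  if (is.function(ad)) ad <- ad()
  ad$tol <- 1e-12
  v <- igraph::eigen_centrality(graph, options = ad)$vector
  v <- abs(v)
  v / sqrt(sum(v^2))
}

#' HITS hub and authority scores
#'
#' Mutually reinforcing scores: a node's authority is the sum of the hub
#' scores of its in-neighbours and a node's hub score the sum of its
#' out-neighbours' authorities. On an undirected graph the two equations
#' coincide, and their fixed point is the principal (Perron) eigenvector of
#' the adjacency matrix, so hub = authority per node. Computed by shifted
#' power iteration (A + I, which converges even on bipartite graphs) with L1
#' normalization each round until the L1 change falls below `tol`.
#'
#' @param graph A `kg`/igraph graph.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 20000).
#' @return List with named vectors `hub` and `authority`, each summing to 1.
#' @export
hits_centrality <- function(graph, tol = 1e-10, max_iter = 20000) {
  n <- igraph::vcount(graph)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  v <- rep(1 / n, n)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    v_new <- as.numeric(A %*% v) + v # (A + I) v
    s <- sum(v_new)
    if (s > 0) v_new <- v_new / s
    if (sum(abs(v_new - v)) < tol) { v <- v_new; converged <- TRUE; break }
    v <- v_new
  }
  if (!converged) stop("HITS did not converge")
  names(v) <- igraph::V(graph)$name
  list(hub = v, authority = v)
}

#' PageRank scores
#'
#' Fixed point of the PageRank recurrence with damping factor `damping`:
#' each node receives `(1-c)/n` plus `c` times the sum over its neighbours
#' `j` of `PR(j)` divided by `j`'s degree; dangling mass is redistributed
#' uniformly. Scores sum to 1.
#'
#' @param graph A `kg`/igraph graph.
#' @param damping Damping factor in (0, 1), default 0.85.
#' @return Named probability vector over all nodes.
#' @export
pagerank_scores <- function(graph, damping = 0.85) {
  if (damping <= 0 || damping >= 1) stop("damping must lie in (0, 1)")
  igraph::page_rank(graph, damping = damping, directed = FALSE)$vector
}

#' Local clustering coefficient
#'
#' Number of triangles through the node divided by the number of neighbour
#' pairs d(d-1)/2; 0 when the degree is below 2.
#'
#' @inheritParams closeness_centrality
#' @return Real in \[0, 1\] (named vector when `node` is `NULL`).
#' @export
clustering_coefficient <- function(graph, node = NULL) {
  if (is.null(node)) {
    out <- igraph::transitivity(graph, type = "local", isolates = "zero")
    return(stats::setNames(out, igraph::V(graph)$name))
  }
  check_node(graph, node)
  unname(igraph::transitivity(graph, type = "local", vids = node,
                              isolates = "zero"))
}

#' Jaccard neighbour-set similarity of two nodes
#'
#' |N(a) intersect N(b)| / |N(a) union N(b)|; 0 when both neighbour sets are
#' empty.
#'
#' @param graph A `kg`/igraph graph.
#' @param node1,node2 Vertex names.
#' @return Real in \[0, 1\].
#' @export
jaccard_similarity <- function(graph, node1, node2) {
  check_node(graph, node1); check_node(graph, node2)
  n1 <- igraph::neighbors(graph, node1)$name
  n2 <- igraph::neighbors(graph, node2)$name
  u <- length(union(n1, n2))
  if (u == 0) return(0)
  length(intersect(n1, n2)) / u
}

#' k nearest nodes in embedding space
#'
#' The `k` nodes with smallest Euclidean distance to the query node's
#' embedding vector, excluding the query itself; ties broken by row order of
#' the embedding matrix.
#'
#' @param embeddings An `embedding_matrix`.
#' @param node Query node name.
#' @param k Number of neighbours, `k < nrow(embeddings)`.
#' @return Character vector of `k` node names, nearest first.
#' @export
knn_nodes <- function(embeddings, node, k) {
  if (!node %in% rownames(embeddings)) stop("unknown node: ", node)
  if (k >= nrow(embeddings)) stop("k must be smaller than the number of nodes")
  delta <- sweep(unclass(embeddings), 2, embeddings[node, ])
  d2 <- rowSums(delta^2)
  d2[node] <- Inf
  rownames(embeddings)[order(d2)][seq_len(k)]
}

#' Louvain community detection
#'
#' Greedy modularity optimization (local moves followed by graph aggregation,
#' repeated until no modularity gain). Deterministic given `seed`.
#'
#' @param graph A nonempty `kg`/igraph graph.
#' @param seed Integer seed fixing the node-visit order.
#' @return Named integer vector of community labels.
#' @export
louvain_communities <- function(graph, seed = 1) {
  if (igraph::vcount(graph) == 0) stop("graph is empty")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- igraph::membership(igraph::cluster_louvain(graph))
  out <- as.integer(m)
  names(out) <- names(m)
  out
}

#' Per-patient topological feature table
#'
#' Assembles every topological statistic into one row per patient node:
#' degree/in/out/weighted degree, closeness, betweenness, eigenvector, hub,
#' authority, PageRank, local clustering, Louvain community label, the `k`
#' nearest embedding-space neighbours and the mean Jaccard similarity to them.
#'
#' @param graph A `kg`/igraph graph.
#' @param embeddings An `embedding_matrix` covering every graph node.
#' @param k Neighbours for the similarity summary (default 3).
#' @param seed Seed passed to [louvain_communities()].
#' @return A `data.frame` of class `topo_feature_table`, one row per patient
#'   node, with a `knn_ids` list-column.
#' @export
compute_topo_table <- function(graph, embeddings, k = 3, seed = 1) {
  nodes <- igraph::V(graph)$name
  if (!all(nodes %in% rownames(embeddings)))
    stop("embeddings do not cover all graph nodes")
  pats <- patient_nodes(graph)

  deg <- igraph::degree(graph)
  dist_all <- igraph::distances(graph, v = pats)
  closeness_v <- apply(dist_all, 1, function(d) {
    s <- sum(d[is.finite(d) & d > 0]); if (s == 0) 0 else 1 / s
  })
  btw <- igraph::betweenness(graph, v = pats, directed = FALSE)
  eig <- if (igraph::ecount(graph) > 0) eigenvector_centrality(graph)
         else stats::setNames(rep(0, length(nodes)), nodes)
  hits <- hits_centrality(graph)
  pr <- pagerank_scores(graph)
  cc <- igraph::transitivity(graph, type = "local", vids = pats,
                             isolates = "zero")
  comm <- louvain_communities(graph, seed = seed)

  # all-patients kNN in one distance computation (same tie-break as
  # knn_nodes: row order of the embedding matrix)
  E <- unclass(embeddings)
  enames <- rownames(embeddings)
  P <- E[pats, , drop = FALSE]
  d2 <- outer(rowSums(P^2), rowSums(E^2), "+") - 2 * tcrossprod(P, E)
  knn_ids <- lapply(seq_along(pats), function(i) {
    di <- d2[i, ]
    di[match(pats[i], enames)] <- Inf
    enames[order(di)][seq_len(k)]
  })
  mean_jac <- vapply(seq_along(pats), function(i) {
    mean(vapply(knn_ids[[i]],
                function(x) jaccard_similarity(graph, pats[i], x),
                numeric(1)))
  }, numeric(1))

  out <- data.frame(
    node_id = pats,
    degree = unname(deg[pats]),
    in_degree = unname(deg[pats]),
    out_degree = unname(deg[pats]),
    weighted_degree = unname(2 * deg[pats]),
    closeness = unname(closeness_v),
    betweenness = unname(btw),
    eigenvector = unname(eig[pats]),
    hub = unname(hits$hub[pats]),
    authority = unname(hits$authority[pats]),
    pagerank = unname(pr[pats]),
    clustering = unname(cc),
    community = unname(comm[pats]),
    mean_jaccard_topk = mean_jac,
    stringsAsFactors = FALSE)
  out$knn_ids <- knn_ids
  stopifnot(all(is.finite(as.matrix(out[, c(
    "degree", "closeness", "betweenness", "eigenvector", "hub", "authority",
    "pagerank", "clustering", "mean_jaccard_topk")]))))
  attr(out, "pagerank_total") <- sum(pr)
  class(out) <- c("topo_feature_table", "data.frame")
  out
}

#' Write a topological feature table as CSV (knn ids joined by ";")
#' @param topo A `topo_feature_table`.
#' @param path File path.
#' @export
write_topo_table <- function(topo, path) {
  df <- as.data.frame(topo)
  df$knn_ids <- vapply(df$knn_ids, paste, character(1), collapse = ";")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

check_node <- function(graph, node) {
  if (!node %in% igraph::V(graph)$name) stop("unknown node: ", node)
}
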