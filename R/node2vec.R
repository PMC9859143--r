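#' Walk parameters for the second-order biased random walk
#'
#' The return parameter `p` controls the likelihood of stepping back to the
#' node just left; the in-out parameter `q` interpolates between breadth-first
#' behaviour (large `q`, walks stay local) and depth-first behaviour (small
#' `q`, walks move outward).
#'
#' @param p,q Positive reals (defaults 1, 1).
#' @param walk_length Steps per walk, >= 2 (default 80).
#' @param walks_per_node Walks started at every node, >= 1 (default 10).
#' @param seed Integer seed for the walk sampler.
#' @return A `walk_params` list.
#' @export
walk_params <- function(p = 1, q = 1, walk_length = 80, walks_per_node = 10,
                        seed = 1) {
  if (p <= 0 || q <= 0) stop("p and q must be > 0")
  if (walk_length < 2) stop("walk_length must be >= 2")
  if (walks_per_node < 1) stop("walks_per_node must be >= 1")
  structure(list(p = p, q = q, walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 seed = as.integer(seed)),
            class = "walk_params")
}

#' Embedding training parameters
#'
#' @param dimensions Embedding dimensionality, >= 2 (default 64).
#' @param window Context window over walk sequences, >= 1 (default 5).
#' @param epochs Training passes (default 5).
#' @param negative_samples Negative samples per positive pair (default 5).
#' @param learning_rate Initial learning rate (default 0.025).
#' @param seed Integer seed for initialization and sampling.
#' @return An `embedding_params` list.
#' @export
embedding_params <- function(dimensions = 64, window = 5, epochs = 5,
                             negative_samples = 5, learning_rate = 0.025,
                             seed = 1) {
  if (dimensions < 2) stop("dimensions must be >= 2")
  if (window < 1) stop("window must be >= 1")
  structure(list(dimensions = as.integer(dimensions),
                 window = as.integer(window), epochs = as.integer(epochs),
                 negative_samples = as.integer(negative_samples),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "embedding_params")
}

#' Walk transition bias
#'
#' The unnormalized bias applied to a candidate next node `x` when the walk
#' sits at `n` having arrived from `t`, as a function of the shortest-path
#' distance `d_tx` between `t` and `x`: `1/p` for returning (d = 0), `1` for a
#' common neighbour (d = 1), `1/q` for moving outward (d = 2).
#'
#' @param d_tx Integer distance in \{0, 1, 2\}.
#' @param p,q Positive reals.
#' @return The bias, a nonnegative real.
#' @export
search_bias <- function(d_tx, p, q) {
  if (!d_tx %in% c(0L, 1L, 2L)) stop("d_tx must be 0, 1 or 2")
  if (d_tx == 0) 1 / p else if (d_tx == 1) 1 else 1 / q
}

#' Normalized transition distribution of the biased walk
#'
#' For a walk at `curr_node` that arrived from `prev_node`, returns the
#' probability of each neighbour `x` of `curr_node`, proportional to
#' `search_bias(d(prev, x), p, q) * w(curr, x)`. The distance `d(prev, x)` is
#' computed locally: 0 if `x` is the previous node, 1 if `x` is adjacent to
#' it, 2 otherwise (exact in a walk context).
#'
#' @param graph A `kg`/igraph graph.
#' @param prev_node,curr_node Vertex names; must be joined by an edge.
#' @param params A [walk_params()].
#' @return Named numeric vector of probabilities summing to 1.
#' @export
transition_distribution <- function(graph, prev_node, curr_node, params) {
  if (!igraph::are_adjacent(graph, prev_node, curr_node))
    stop("prev_node and curr_node must be adjacent")
  nbrs <- igraph::neighbors(graph, curr_node)$name
  if (length(nbrs) == 0) stop("curr_node has no neighbors")
  prev_nbrs <- igraph::neighbors(graph, prev_node)$name
  w <- edge_weight_to(graph, curr_node, nbrs)
  alpha <- vapply(nbrs, function(x) {
    d <- if (x == prev_node) 0L else if (x %in% prev_nbrs) 1L else 2L
    search_bias(d, params$p, params$q)
  }, numeric(1))
  pr <- alpha * w
  pr / sum(pr)
}

edge_weight_to <- function(graph, node, nbrs) {
  w <- igraph::E(graph)$weight
  if (is.null(w)) return(rep(1, length(nbrs)))
  ids <- igraph::get_edge_ids(graph, rbind(rep(node, length(nbrs)), nbrs))
  w[ids]
}

#' Generate a corpus of biased random walks
#'
#' Starts `walks_per_node` walks at every node. The first step is uniform
#' over neighbours (the second-order rule needs a predecessor); later steps
#' follow [transition_distribution()]. Isolated start nodes yield length-1
#' walks. Deterministic given `params$seed`.
#'
#' @param graph A `kg`/igraph graph.
#' @param params A [walk_params()].
#' @return A `walk_corpus`: list with `walks` (integer-index sequences) and
#'   `nodes` (vertex names the indices refer to).
#' @export
generate_walks <- function(graph, params) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("graph is empty")
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"),
                function(v) sort(unique(as.integer(v))))
  deg <- lengths(adj)
  off <- c(0L, cumsum(deg))
  adj_flat <- unlist(adj, use.names = FALSE) - 1L
  if (is.null(adj_flat)) adj_flat <- integer(0)
  # weights aligned with the flattened adjacency (multi-edges collapsed to 1)
  w_flat <- rep(1, length(adj_flat))
  walks <- cpp_generate_walks(adj_flat, as.integer(off), w_flat,
                              params$p, params$q, params$walk_length,
                              params$walks_per_node, params$seed)
  structure(list(walks = walks, nodes = igraph::V(graph)$name),
            class = "walk_corpus")
}

#' Train node embeddings from a walk corpus
#'
#' The default backend is skip-gram with negative sampling over the walk
#' sequences (the standard node2vec trainer). A deterministic alternative
#' factorizes the positive pointwise-mutual-information matrix of windowed
#' walk co-occurrences by truncated SVD. Nodes absent from every walk get a
#' zero vector. Both backends are single-threaded and deterministic given
#' `params$seed`.
#'
#' @param corpus A `walk_corpus` from [generate_walks()].
#' @param params An [embedding_params()].
#' @param backend `"sgns"` (default) or `"svd"`.
#' @return An `embedding_matrix`: numeric matrix, one row per node
#'   (rownames = node names), `params$dimensions` columns.
#' @export
train_embeddings <- function(corpus, params, backend = c("sgns", "svd")) {
  backend <- match.arg(backend)
  if (!inherits(corpus, "walk_corpus")) stop("corpus must be a walk_corpus")
  if (length(corpus$walks) == 0) stop("empty walk corpus")
  n <- length(corpus$nodes)
  if (backend == "sgns") {
    emb <- cpp_train_sgns(corpus$walks, n, params$dimensions, params$window,
                          params$epochs, params$negative_samples,
                          params$learning_rate, params$seed)
  } else {
    emb <- ppmi_svd_embed(corpus, n, params)
  }
  if (any(!is.finite(emb))) stop("non-finite embedding values")
  rownames(emb) <- corpus$nodes
  class(emb) <- c("embedding_matrix", class(emb))
  emb
}

# PPMI of windowed co-occurrence counts, factorized by seeded subspace
# iteration (randomized truncated SVD); embedding = U * sqrt(S).
ppmi_svd_embed <- function(corpus, n, params) {
  M <- cpp_cooccurrence(corpus$walks, n, params$window)
  tot <- sum(M)
  if (tot == 0) return(matrix(0, n, params$dimensions))
  rs <- rowSums(M)
  pos <- rs > 0
  P <- matrix(0, n, n)
  nz <- which(M > 0, arr.ind = TRUE)
  pmi <- log(M[nz] * tot / (rs[nz[, 1]] * rs[nz[, 2]]))
  P[nz] <- pmax(pmi, 0)
  k <- min(params$dimensions, n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  Om <- matrix(stats::rnorm(n * k), n, k)
  Q <- qr.Q(qr(P %*% Om))
  for (i in 1:4) Q <- qr.Q(qr(P %*% (t(P) %*% Q)))
  B <- t(Q) %*% P
  sv <- svd(B, nu = k, nv = 0)
  emb <- (Q %*% sv$u) %*% diag(sqrt(sv$d[seq_len(k)]), k)
  if (k < params$dimensions)
    emb <- cbind(emb, matrix(0, n, params$dimensions - k))
  emb[rs == 0, ] <- 0
  emb
}

#' Write / read an embedding matrix as CSV
#'
#' One row per node: `node_id` followed by the numeric dimensions.
#'
#' @param embeddings An `embedding_matrix`.
#' @param path File path.
#' @return `read_embeddings` returns an `embedding_matrix`.
#' @export
write_embeddings <- function(embeddings, path) {
  df <- data.frame(node_id = rownames(embeddings),
                   unclass(embeddings), row.names = NULL)
  names(df) <- c("node_id", paste0("dim_", seq_len(ncol(embeddings))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  emb <- as.matrix(df[, -1, drop = FALSE])
  rownames(emb) <- df$node_id
  colnames(emb) <- NULL
  class(emb) <- c("embedding_matrix", class(emb))
  emb
}
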