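# Toy graph builders and independent brute-force oracles used across the
# suite. The oracles work on dense adjacency matrices with base R linear
# algebra only, so they share no code path with the igraph-backed
# implementations they check.

kg_from_edges <- function(edges, n = NULL, kind = NULL) {
  # edges: 2-column character matrix (or NULL); isolated nodes via `n` names
  verts <- unique(c(as.vector(edges), n))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (is.null(kind)) kind <- rep("patient", length(verts))
  g <- igraph::add_vertices(g, length(verts), name = verts, kind = kind)
  if (!is.null(edges) && length(edges))
    g <- igraph::add_edges(g, t(edges), weight = 1)
  class(g) <- c("kg", class(g))
  g
}

kg_from_adjacency <- function(A) {
  dimnames(A) <- list(paste0("v", seq_len(nrow(A))),
                      paste0("v", seq_len(nrow(A))))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  g <- igraph::set_vertex_attr(g, "kind", value = "patient")
  class(g) <- c("kg", class(g))
  g
}

toy_cohort <- function() {
  # 3 patients; GDM positive for p1, p3; blood groups A, A, B
  structure(data.frame(patient_id = 1:3,
                       gdm = c(1, 0, 1),
                       blood_group = c("A", "A", "B"),
                       age = c(30, 25, 41),
                       label = factor(c("normal", "LBW", "normal"),
                                      levels = c("normal", "LBW"))),
            class = c("cohort_table", "data.frame"))
}

# shortest-path distances by min-plus matrix powers
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  D[A > 0] <- 1
  Ak <- A
  for (L in 2:max(2, n)) {
    Ak <- Ak %*% A
    D[D == Inf & Ak > 0] <- L
  }
  D
}

oracle_closeness <- function(A, i) {
  d <- oracle_distances(A)[i, ]
  s <- sum(d[is.finite(d) & d > 0])
  if (s == 0) 0 else 1 / s
}

# shortest-path counts: walks of minimal length are exactly the shortest
# paths, so sigma_ij = (A^d_ij)_ij
oracle_betweenness_all <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  powers <- list(diag(n), A)
  for (L in 2:max(2, n)) powers[[L + 1]] <- powers[[L]] %*% A
  sigma <- function(i, j) {
    if (!is.finite(D[i, j])) return(0)
    powers[[D[i, j] + 1]][i, j]
  }
  out <- numeric(n)
  for (v in seq_len(n)) {
    total <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (i == v || j == v || !is.finite(D[i, j])) next
      if (is.finite(D[i, v]) && is.finite(D[v, j]) &&
          D[i, v] + D[v, j] == D[i, j])
        total <- total + sigma(i, v) * sigma(v, j) / sigma(i, j)
    }
    out[v] <- total
  }
  out
}

oracle_betweenness <- function(A, v) oracle_betweenness_all(A)[v]

oracle_closeness_all <- function(A) {
  D <- oracle_distances(A)
  D[!is.finite(D)] <- 0
  s <- rowSums(D)
  ifelse(s == 0, 0, 1 / s)
}

oracle_clustering_all <- function(A) {
  d <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ifelse(d < 2, 0, tri / (d * (d - 1) / 2))
}

oracle_eigenvector <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v / sqrt(sum(v^2))
}

# dense linear solve of the PageRank fixed point (no dangling nodes assumed)
oracle_pagerank <- function(A, damping = 0.85) {
  n <- nrow(A)
  deg <- colSums(A)
  M <- A / rep(pmax(deg, 1), each = n) # M[i,j] = A[i,j]/deg(j)
  M[, deg == 0] <- 1 / n
  solve(diag(n) - damping * M, rep((1 - damping) / n, n))
}

oracle_clustering <- function(A, i) {
  d <- sum(A[i, ])
  if (d < 2) return(0)
  tri <- (A %*% A %*% A)[i, i] / 2
  tri / (d * (d - 1) / 2)
}

# all connected labeled simple graphs on n nodes, as adjacency matrices
all_connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  for (code in 0:(2^m - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    A <- matrix(0, n, n)
    for (k in seq_len(m)) if (bits[k]) {
      A[pairs[k, 1], pairs[k, 2]] <- 1
      A[pairs[k, 2], pairs[k, 1]] <- 1
    }
    R <- diag(n) + A
    for (s in seq_len(n)) R <- (R %*% (diag(n) + A)) > 0
    if (all(R)) out[[length(out) + 1]] <- A
  }
  out
}

# direct, loop-based PR-curve oracle: every distinct threshold, unit-TP
# interpolation written out longhand
oracle_auprc <- function(labels, scores, positive) {
  pos <- as.character(labels) == positive
  P <- sum(pos)
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]; s <- scores[ord]
  tp <- 0; fp <- 0
  pts <- list(c(0, 0))
  i <- 1
  while (i <= length(s)) {
    j <- i
    while (j < length(s) && s[j + 1] == s[i]) j <- j + 1
    tp <- tp + sum(pos[i:j]); fp <- fp + sum(!pos[i:j])
    pts[[length(pts) + 1]] <- c(tp, fp)
    i <- j + 1
  }
  rec <- 0; prec_first <- NULL
  area <- 0; last_r <- 0; last_p <- NULL
  for (k in 2:length(pts)) {
    a <- pts[[k - 1]]; b <- pts[[k]]
    dtp <- b[1] - a[1]
    if (dtp > 0) {
      slope <- (b[2] - a[2]) / dtp
      for (x in 1:dtp) {
        tpx <- a[1] + x
        y <- tpx / (tpx + a[2] + slope * x)
        r <- tpx / P
        if (is.null(last_p)) { last_p <- y; area <- area + (r - last_r) * y }
        else area <- area + (r - last_r) * (last_p + y) / 2
        last_r <- r; last_p <- y
      }
    } else {
      y <- b[1] / (b[1] + b[2])
      r <- b[1] / P
      if (!is.null(last_p)) area <- area + (r - last_r) * (last_p + y) / 2
      last_r <- r; last_p <- y
    }
  }
  area
}

small_walk_params <- function(...) walk_params(walk_length = 10,
                                               walks_per_node = 5, ...)
small_embed_params <- function(...) embedding_params(dimensions = 8,
                                                     window = 3, epochs = 3,
                                                     ...)
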