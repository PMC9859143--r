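path3 <- function() kg_from_edges(rbind(c("a", "b"), c("b", "c")))

test_that("degree features follow the undirected convention", {
  star <- kg_from_edges(rbind(c("c", "l1"), c("c", "l2"), c("c", "l3")),
                        n = "iso")
  expect_equal(degree_features(star, "c"),
               c(degree = 3, in_degree = 3, out_degree = 3,
                 weighted_degree = 6))
  expect_equal(degree_features(star, "iso"),
               c(degree = 0, in_degree = 0, out_degree = 0,
                 weighted_degree = 0))
  expect_error(degree_features(star, "nope"), "unknown node")
})

test_that("closeness is the reciprocal summed distance within the component", {
  g <- path3()
  expect_equal(closeness_centrality(g, "b"), 0.5)
  expect_equal(closeness_centrality(g, "a"), 1 / 3)
  iso <- kg_from_edges(rbind(c("a", "b")), n = "z")
  expect_equal(closeness_centrality(iso, "z"), 0)
})

test_that("betweenness counts shortest-path fractions, unnormalized", {
  g <- path3()
  expect_equal(betweenness_centrality(g, "b"), 1)
  expect_equal(betweenness_centrality(g, "a"), 0)
  cyc <- kg_from_edges(rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                             c("d", "a")))
  expect_equal(betweenness_centrality(cyc, "a"), 0.5)
})

test_that("eigenvector centrality matches closed forms", {
  tri <- kg_from_edges(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  v <- eigenvector_centrality(tri)
  expect_equal(unname(v), rep(1 / sqrt(3), 3), tolerance = 1e-8)
  star <- kg_from_edges(rbind(c("c", "l1"), c("c", "l2"), c("c", "l3")))
  s <- eigenvector_centrality(star)
  expect_gt(s[["c"]], s[["l1"]])
  expect_equal(s[["l1"]], s[["l2"]], tolerance = 1e-8)
  expect_equal(s[["l2"]], s[["l3"]], tolerance = 1e-8)
  disc <- kg_from_edges(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                        n = "z")
  expect_equal(eigenvector_centrality(disc)[["z"]], 0, tolerance = 1e-8)
})

test_that("HITS is symmetric on undirected graphs", {
  g <- kg_from_edges(rbind(c("a", "c"), c("b", "c")))
  h <- hits_centrality(g)
  expect_equal(h$hub, h$authority, tolerance = 1e-8)
  expect_equal(h$hub[["a"]], h$hub[["b"]], tolerance = 1e-10)
  expect_gt(h$authority[["c"]], h$authority[["a"]])
  e <- hits_centrality(kg_from_edges(rbind(c("a", "b"))))
  expect_equal(unname(c(e$hub, e$authority)), rep(0.5, 4), tolerance = 1e-10)
  star <- kg_from_edges(rbind(c("c", "l1"), c("c", "l2"), c("c", "l3")))
  hs <- hits_centrality(star)
  expect_gt(hs$authority[["c"]], hs$authority[["l1"]])
})

test_that("PageRank matches symmetry and regularity closed forms", {
  e <- pagerank_scores(kg_from_edges(rbind(c("a", "b"))))
  expect_equal(unname(e), c(0.5, 0.5), tolerance = 1e-8)
  cyc <- kg_from_edges(rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                             c("d", "a")))
  expect_equal(unname(pagerank_scores(cyc, 0.7)), rep(0.25, 4),
               tolerance = 1e-8)
  expect_error(pagerank_scores(cyc, damping = 1.5), "damping")
})

test_that("clustering coefficient is the triangle fraction of neighbor pairs", {
  tri <- kg_from_edges(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(clustering_coefficient(tri, "a"), 1)
  expect_equal(clustering_coefficient(path3(), "b"), 0)
  g <- kg_from_edges(rbind(c("x", "a"), c("x", "b"), c("x", "c"),
                           c("a", "b")))
  expect_equal(clustering_coefficient(g, "x"), 1 / 3)
})

test_that("Jaccard similarity compares neighbor sets", {
  g <- kg_from_edges(rbind(c("n1", "A"), c("n1", "B"),
                           c("n2", "B"), c("n2", "C")))
  expect_equal(jaccard_similarity(g, "n1", "n2"), 1 / 3)
  twin <- kg_from_edges(rbind(c("u", "A"), c("u", "B"),
                              c("v", "A"), c("v", "B")))
  expect_equal(jaccard_similarity(twin, "u", "v"), 1)
  expect_equal(jaccard_similarity(g, "A", "C"), 0) # disjoint neighbor sets
  iso <- kg_from_edges(rbind(c("a", "b")), n = c("y", "z"))
  expect_equal(jaccard_similarity(iso, "y", "z"), 0)
})

test_that("knn_nodes ranks by Euclidean distance with stable ties", {
  emb <- structure(matrix(c(0, 1, 5, 1), ncol = 1,
                          dimnames = list(c("a", "b", "c", "dup"), NULL)),
                   class = c("embedding_matrix", "matrix"))
  expect_equal(knn_nodes(emb, "a", 1), "b")
  expect_equal(knn_nodes(emb, "b", 1), "dup") # zero distance ranks first
  expect_equal(knn_nodes(emb, "a", 3), c("b", "dup", "c"))
  expect_error(knn_nodes(emb, "a", 4), "k must be")
  expect_error(knn_nodes(emb, "nope", 1), "unknown node")
})

test_that("Louvain separates cliques and respects modularity", {
  A <- matrix(0, 8, 8); A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  g <- kg_from_adjacency(A)
  m <- louvain_communities(g, seed = 1)
  expect_length(unique(m), 2)
  expect_length(unique(m[paste0("v", 1:4)]), 1)
  expect_length(unique(m[paste0("v", 5:8)]), 1)
  k5 <- kg_from_adjacency(matrix(1, 5, 5) - diag(5))
  expect_length(unique(louvain_communities(k5, seed = 1)), 1)
  # two 5-cliques with one bridge: the two-clique split beats one community
  B <- matrix(0, 10, 10); B[1:5, 1:5] <- 1; B[6:10, 6:10] <- 1; diag(B) <- 0
  B[5, 6] <- B[6, 5] <- 1
  gb <- kg_from_adjacency(B)
  mb <- louvain_communities(gb, seed = 1)
  expect_length(unique(mb), 2)
  expect_length(unique(mb[paste0("v", 1:5)]), 1)
  q2 <- igraph::modularity(gb, mb)
  expect_gt(q2, igraph::modularity(gb, seq_len(10)))
})

test_that("centralities agree with brute-force oracles on random graphs", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.5)
    A <- A + t(A)
    if (sum(A) == 0) next
    g <- kg_from_adjacency(A)
    verts <- paste0("v", seq_len(n))
    for (i in seq_len(n)) {
      expect_equal(closeness_centrality(g, verts[i]), oracle_closeness(A, i),
                   tolerance = 1e-8)
      expect_equal(betweenness_centrality(g, verts[i]),
                   oracle_betweenness(A, i), tolerance = 1e-8)
      expect_equal(clustering_coefficient(g, verts[i]),
                   oracle_clustering(A, i), tolerance = 1e-8)
    }
    pr <- pagerank_scores(g)
    expect_equal(unname(pr[verts]), oracle_pagerank(A), tolerance = 1e-6)
  }
})

test_that("HITS and eigenvector are permutation-equivariant", {
  set.seed(7)
  # connected graph: a disconnected one can have a degenerate leading
  # eigenvalue, where the eigenvector is not unique and the invariant is
  # ill-posed
  repeat {
    A <- matrix(0, 6, 6)
    A[upper.tri(A)] <- rbinom(15, 1, 0.5)
    A <- A + t(A)
    if (igraph::is_connected(kg_from_adjacency(A))) break
  }
  perm <- sample(6)
  Ap <- A[perm, perm]
  g <- kg_from_adjacency(A); gp <- kg_from_adjacency(Ap)
  v <- eigenvector_centrality(g); vp <- eigenvector_centrality(gp)
  expect_equal(unname(vp[paste0("v", seq_len(6))]),
               unname(v[paste0("v", perm)]), tolerance = 1e-6)
  h <- hits_centrality(g)$authority; hp <- hits_centrality(gp)$authority
  expect_equal(unname(hp[paste0("v", seq_len(6))]),
               unname(h[paste0("v", perm)]), tolerance = 1e-6)
})

test_that("the topological table has one complete row per patient", {
  co <- toy_cohort()
  g <- build_graph(co, property_columns = "age",
                   entity_columns = c("gdm", "blood_group"))
  corpus <- generate_walks(g, small_walk_params(seed = 1))
  emb <- train_embeddings(corpus, small_embed_params(seed = 1))
  topo <- compute_topo_table(g, emb, k = 2, seed = 1)
  expect_equal(nrow(topo), 3)
  expect_setequal(topo$node_id, c("p1", "p2", "p3"))
  expect_equal(ncol(topo), 15) # node_id + 13 stats + knn_ids
  expect_equal(attr(topo, "pagerank_total"), 1, tolerance = 1e-8)
  # knn ids match the one-at-a-time query path
  for (i in seq_len(3))
    expect_identical(topo$knn_ids[[i]], knn_nodes(emb, topo$node_id[i], 2))
})

test_that("isolated patients get well-defined zero features", {
  co <- toy_cohort()
  co$gdm <- c(1, 0, 1)
  co$blood_group <- NULL # p2 has no positive entity -> isolated
  g <- build_graph(co, property_columns = "age", entity_columns = "gdm")
  corpus <- generate_walks(g, small_walk_params(seed = 1))
  emb <- train_embeddings(corpus, small_embed_params(seed = 1))
  topo <- compute_topo_table(g, emb, k = 1, seed = 1)
  p2 <- topo[topo$node_id == "p2", ]
  expect_equal(p2$degree, 0)
  expect_equal(p2$closeness, 0)
  expect_equal(p2$betweenness, 0)
  expect_equal(p2$clustering, 0)
})

test_that("embedding coverage is enforced", {
  g <- build_graph(toy_cohort(), property_columns = "age",
                   entity_columns = c("gdm", "blood_group"))
  emb <- structure(matrix(0, 2, 4, dimnames = list(c("p1", "p2"), NULL)),
                   class = c("embedding_matrix", "matrix"))
  expect_error(compute_topo_table(g, emb, k = 1), "cover")
})
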