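#' Assemble a feature matrix for classification
#'
#' Builds one of the four evaluated feature sets from a cohort, the node
#' embeddings and the topological feature table:
#'
#' * `original` — the tabular risk factors: binary columns as 0/1,
#'   categorical columns one-hot encoded, continuous columns as-is (they are
#'   standardized per training fold at fit time, not here);
#' * `embedding` — each patient's node-embedding vector;
#' * `graph_combined` — embedding plus topological features (community label
#'   one-hot encoded, `knn_ids` summarized by `mean_jaccard_topk`);
#' * `all` — `original` plus `graph_combined`.
#'
#' Column names are namespaced by source (`orig_`, `emb_`, `topo_`). Labels
#' never appear among the features; rows follow cohort order.
#'
#' @param cohort A `cohort_table`.
#' @param embeddings An `embedding_matrix` (patient rows named `p<id>`);
#'   required for every set except `original`.
#' @param topo A `topo_feature_table`; required for `graph_combined` and
#'   `all`.
#' @param set_name One of `"original"`, `"embedding"`, `"graph_combined"`,
#'   `"all"`.
#' @param include_embeddings_in_combined Whether `graph_combined` contains the
#'   embedding block (default TRUE).
#' @return A `feature_matrix`: list with `x` (numeric matrix, patients x
#'   features), `y` (label factor), `patient_id`, `set_name`, and
#'   `continuous_cols` (names of columns to standardize per fold).
#' @export
assemble <- function(cohort, embeddings = NULL, topo = NULL,
                     set_name = c("original", "embedding", "graph_combined",
                                  "all"),
                     include_embeddings_in_combined = TRUE) {
  set_name <- match.arg(set_name)
  validate_cohort(cohort)
  pat_names <- paste0("p", cohort$patient_id)

  orig <- NULL
  if (set_name %in% c("original", "all")) orig <- encode_original(cohort)

  emb_block <- NULL
  if (set_name %in% c("embedding", "all") ||
      (set_name == "graph_combined" && include_embeddings_in_combined)) {
    if (is.null(embeddings)) stop("embeddings required for set '", set_name, "'")
    missing_p <- setdiff(pat_names, rownames(embeddings))
    if (length(missing_p))
      stop("patient ids absent from embeddings: ",
           paste(utils::head(missing_p, 3), collapse = ", "))
    emb_block <- unclass(embeddings)[pat_names, , drop = FALSE]
    colnames(emb_block) <- paste0("emb_", seq_len(ncol(emb_block)))
  }

  topo_block <- NULL
  if (set_name %in% c("graph_combined", "all")) {
    if (is.null(topo)) stop("topo table required for set '", set_name, "'")
    if (!setequal(topo$node_id, pat_names))
      stop("topo table patient ids do not match cohort")
    topo_block <- encode_topo(topo)[match(pat_names, topo$node_id), ,
                                    drop = FALSE]
  }

  blocks <- switch(set_name,
    original = list(orig),
    embedding = list(emb_block),
    graph_combined = if (include_embeddings_in_combined)
      list(emb_block, topo_block) else list(topo_block),
    all = if (include_embeddings_in_combined)
      list(orig, emb_block, topo_block) else list(orig, topo_block))
  x <- do.call(cbind, Filter(Negate(is.null), blocks))
  rownames(x) <- pat_names

  continuous_cols <- if (!is.null(orig)) attr(orig, "continuous_cols")
                     else character(0)
  structure(list(x = x, y = cohort$label, patient_id = cohort$patient_id,
                 set_name = set_name,
                 continuous_cols = intersect(continuous_cols, colnames(x))),
            class = "feature_matrix")
}

# 0/1 binaries kept as-is, categoricals one-hot, continuous passed through
# (fold-level standardization happens at fit time). NA values survive here
# and are imputed per training fold.
encode_original <- function(cohort) {
  fac_cols <- setdiff(names(cohort), c("patient_id", "label"))
  blocks <- list(); continuous_cols <- character(0)
  for (cn in fac_cols) {
    v <- cohort[[cn]]
    if (is_binaryish(v)) {
      m <- matrix(as.numeric(v), ncol = 1,
                  dimnames = list(NULL, paste0("orig_", cn)))
      blocks[[cn]] <- m
    } else if (is.numeric(v)) {
      nm <- paste0("orig_", cn)
      blocks[[cn]] <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
      continuous_cols <- c(continuous_cols, nm)
    } else {
      lev <- sort(unique(as.character(v[!is.na(v)])))
      m <- vapply(lev, function(l) as.numeric(as.character(v) == l),
                  numeric(length(v)))
      if (is.null(dim(m))) m <- matrix(m, nrow = length(v))
      colnames(m) <- paste0("orig_", cn, ".", lev)
      m[is.na(v), ] <- NA
      blocks[[cn]] <- m
    }
  }
  out <- do.call(cbind, blocks)
  attr(out, "continuous_cols") <- continuous_cols
  out
}

encode_topo <- function(topo) {
  num_cols <- c("degree", "in_degree", "out_degree", "weighted_degree",
                "closeness", "betweenness", "eigenvector", "hub", "authority",
                "pagerank", "clustering", "mean_jaccard_topk")
  m <- as.matrix(as.data.frame(topo)[, num_cols])
  colnames(m) <- paste0("topo_", num_cols)
  comm <- topo$community
  lev <- sort(unique(comm))
  onehot <- vapply(lev, function(l) as.numeric(comm == l),
                   numeric(length(comm)))
  if (is.null(dim(onehot))) onehot <- matrix(onehot, nrow = length(comm))
  colnames(onehot) <- paste0("topo_community.", lev)
  cbind(m, onehot)
}

#' Write a feature matrix as CSV (label column flagged in the header name)
#' @param fm A `feature_matrix`.
#' @param path File path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(patient_id = fm$patient_id, fm$x,
                   label = fm$y, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
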