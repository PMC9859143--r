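#' Configuration for a full evaluation experiment
#'
#' @param cohort A `cohort_table`.
#' @param entity_columns,property_columns Column assignment for
#'   [build_graph()]; defaults: binary and categorical factors become
#'   entities, continuous factors become patient properties.
#' @param walk A [walk_params()].
#' @param embedding An [embedding_params()].
#' @param classifiers Character vector of registry names
#'   (see [lbw_classifiers()]).
#' @param feature_sets Subset of the four feature sets.
#' @param k,repeats Cross-validation folds and repeats (default 5 x 5).
#' @param knn_k Neighbours for the node-similarity summary (default 3).
#' @param embedding_backend `"sgns"` or `"svd"`.
#' @param inductive If TRUE, the graph, embeddings and topological features
#'   are rebuilt from the training patients of every fold (test patients are
#'   attached to the training graph for feature extraction but contribute no
#'   structure); default FALSE, the transductive protocol in which graph
#'   features are computed once on the full cohort before cross-validation.
#' @param seed Master seed; all fold, walk, training and classifier seeds are
#'   derived from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cohort,
                              entity_columns = NULL, property_columns = NULL,
                              walk = walk_params(),
                              embedding = embedding_params(),
                              classifiers = names(lbw_classifiers()),
                              feature_sets = c("original", "embedding",
                                               "graph_combined", "all"),
                              k = 5, repeats = 5, knn_k = 3,
                              embedding_backend = c("sgns", "svd"),
                              inductive = FALSE, seed = 1) {
  validate_cohort(cohort)
  fac_cols <- setdiff(names(cohort), c("patient_id", "label"))
  if (is.null(entity_columns))
    entity_columns <- fac_cols[vapply(fac_cols, function(cn)
      is_binaryish(cohort[[cn]]) || !is.numeric(cohort[[cn]]), logical(1))]
  if (is.null(property_columns))
    property_columns <- setdiff(fac_cols, entity_columns)
  lbw_classifiers(classifiers) # validate names
  bad <- setdiff(feature_sets,
                 c("original", "embedding", "graph_combined", "all"))
  if (length(bad)) stop("unknown feature sets: ", paste(bad, collapse = ", "))
  structure(list(cohort = cohort, entity_columns = entity_columns,
                 property_columns = property_columns, walk = walk,
                 embedding = embedding, classifiers = classifiers,
                 feature_sets = feature_sets, k = k, repeats = repeats,
                 knn_k = knn_k,
                 embedding_backend = match.arg(embedding_backend),
                 inductive = inductive, seed = as.integer(seed)),
            class = "experiment_config")
}

# Graph -> walks -> embeddings -> topological table, one shot.
graph_feature_stack <- function(cohort, config) {
  g <- build_graph(cohort, property_columns = config$property_columns,
                   entity_columns = config$entity_columns)
  wp <- config$walk; wp$seed <- config$seed + 1000L
  corpus <- generate_walks(g, wp)
  ep <- config$embedding; ep$seed <- config$seed + 2000L
  emb <- train_embeddings(corpus, ep, backend = config$embedding_backend)
  topo <- compute_topo_table(g, emb, k = config$knn_k,
                             seed = config$seed + 3000L)
  list(graph = g, embeddings = emb, topo = topo)
}

#' Run the full cross-validated evaluation
#'
#' Builds the knowledge graph, walks, embeddings and topological features
#' (once on the full cohort under the default transductive protocol — the
#' outcome label never touches the graph), assembles each requested feature
#' set, and evaluates each classifier under repeated stratified
#' cross-validation. Continuous columns are standardized and missing values
#' imputed using training-fold statistics only.
#'
#' @param config An [experiment_config()].
#' @param keep_fold_metrics If TRUE the per-fold metric table is attached as
#'   attribute `folds`.
#' @return An `evaluation_report` tibble: one row per (classifier,
#'   feature_set) with mean and SD over all folds of weighted precision,
#'   recall, F-score, AUC-ROC, PR area of the LBW class and overall PR area.
#' @export
run_experiment <- function(config, keep_fold_metrics = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- config$cohort
  positive <- "LBW"
  splits <- stratified_repeated_cv(cohort$label, k = config$k,
                                   repeats = config$repeats,
                                   seed = config$seed)
  needs_graph <- !identical(config$feature_sets, "original")
  stack <- if (needs_graph && !config$inductive)
    graph_feature_stack(cohort, config) else NULL

  fms <- list()
  if (!config$inductive) {
    for (fs in config$feature_sets)
      fms[[fs]] <- assemble(cohort, stack$embeddings, stack$topo, fs)
  }

  registry <- lbw_classifiers(config$classifiers)
  rows <- list()
  for (fs in config$feature_sets) {
    for (cl_name in config$classifiers) {
      cl <- registry[[cl_name]]
      fold_rows <- lapply(seq_along(splits), function(si) {
        sp <- splits[[si]]
        if (config$inductive && fs != "original") {
          st <- inductive_stack(cohort, config, sp$train_ids)
          fm <- assemble(cohort, st$embeddings, st$topo, fs)
        } else {
          fm <- fms[[fs]]
        }
        fit_seed <- config$seed * 10000L + si
        evaluate_fold(fm, sp, cl, fit_seed, positive)
      })
      fold_df <- do.call(rbind, fold_rows)
      agg <- colMeans(fold_df)
      sds <- apply(fold_df, 2, stats::sd)
      rows[[length(rows) + 1]] <- tibble::tibble(
        classifier = cl_name, feature_set = fs,
        precision = agg["precision"], precision_sd = sds["precision"],
        recall = agg["recall"], recall_sd = sds["recall"],
        fscore = agg["fscore"], fscore_sd = sds["fscore"],
        auc = agg["auc"], auc_sd = sds["auc"],
        pr_lbw = agg["pr_lbw"], pr_lbw_sd = sds["pr_lbw"],
        pr_overall = agg["pr_overall"], pr_overall_sd = sds["pr_overall"],
        folds = list(if (keep_fold_metrics) fold_df else NULL))
    }
  }
  report <- do.call(rbind, rows)
  if (!keep_fold_metrics) report$folds <- NULL
  class(report) <- c("evaluation_report", class(report))
  report
}

evaluate_fold <- function(fm, sp, cl, fit_seed, positive) {
  x_tr <- fm$x[sp$train_ids, , drop = FALSE]
  x_te <- fm$x[sp$test_ids, , drop = FALSE]
  prep <- fit_preprocessor(x_tr, fm$continuous_cols)
  x_tr <- apply_preprocessor(prep, x_tr)
  x_te <- apply_preprocessor(prep, x_te)
  y_tr <- fm$y[sp$train_ids]; y_te <- fm$y[sp$test_ids]
  model <- cl$fit(x_tr, y_tr, fit_seed)
  proba <- cl$predict_proba(model, x_te)
  pred <- ifelse(proba >= 0.5, levels(fm$y)[2], levels(fm$y)[1])
  prf <- weighted_prf(y_te, pred)
  pr <- pr_value(y_te, proba, positive)
  c(precision = unname(prf["precision"]), recall = unname(prf["recall"]),
    fscore = unname(prf["fscore"]),
    auc = roc_auc(y_te, proba, positive),
    pr_lbw = unname(pr["pr_positive"]),
    pr_overall = unname(pr["pr_overall"]))
}

# Strict inductive variant: only training patients contribute edges to the
# per-fold graph. Held-out patients remain as isolated patient nodes (they
# were "not included during graph construction"), so their embeddings and
# topological features take the isolated-node values.
inductive_stack <- function(cohort, config, train_ids) {
  sub <- cohort
  test_rows <- setdiff(seq_len(nrow(sub)), train_ids)
  for (cn in config$entity_columns) {
    v <- sub[[cn]]
    if (is_binaryish(v)) v[test_rows] <- 0 else v[test_rows] <- NA
    sub[[cn]] <- v
  }
  graph_feature_stack(sub, config)
}
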