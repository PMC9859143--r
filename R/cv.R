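#' Repeated stratified k-fold cross-validation splits
#'
#' For each repeat, partitions the indices into `k` folds preserving class
#' proportions (each fold's class count differs from the exact share by at
#' most one sample). Folds within a repeat are disjoint and cover every
#' index. Deterministic given `seed`.
#'
#' @param labels Class labels (factor or character).
#' @param k Folds per repeat (default 5).
#' @param repeats Number of repeats (default 5).
#' @param seed Integer seed.
#' @return List of length `k * repeats`; each element has `train_ids`,
#'   `test_ids`, `repeat_id`, `fold_id` (indices into `labels`).
#' @export
stratified_repeated_cv <- function(labels, k = 5, repeats = 5, seed = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop("every class needs at least k = ", k, " members")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- list()
  for (r in seq_len(repeats)) {
    fold_of <- integer(n)
    for (cl in names(tab)) {
      ids <- sample(which(labels == cl))
      fold_of[ids] <- rep_len(seq_len(k), length(ids))
    }
    for (f in seq_len(k)) {
      test <- which(fold_of == f)
      out[[length(out) + 1]] <- list(train_ids = setdiff(seq_len(n), test),
                                     test_ids = test,
                                     repeat_id = r, fold_id = f)
    }
  }
  out
}

#' Classifier registry
#'
#' Returns fit/predict-probability wrappers for the evaluated classifiers,
#' with the study's hyperparameters as defaults:
#'
#' * `rf` — random forest, 100 trees, sqrt(p) features per split;
#' * `nb` — Gaussian/categorical naive Bayes, default parameters;
#' * `lr` — logistic regression with a vanishing ridge penalty (1e-8);
#' * `knn` — k-nearest-neighbour vote, K = 3, Euclidean distance;
#' * `mlp` — single-hidden-layer perceptron (16 units, weight decay 0.001,
#'   200 iterations);
#' * `xgb` — gradient-boosted trees, 100 rounds, learning rate 0.01;
#' * `gbt` — a second gradient-boosted configuration with leaf-wise
#'   (lossguide) growth, 100 rounds, learning rate 0.01.
#'
#' Every `fit(x, y, seed)` returns an opaque model; `predict_proba(model, x)`
#' returns the probability of the positive (second) level. All wrappers are
#' single-threaded and deterministic given `seed`.
#'
#' @param names Optional subset of classifier names.
#' @return Named list of `list(fit=, predict_proba=)` entries.
#' @export
lbw_classifiers <- function(names = NULL) {
  reg <- list(
    rf = list(
      fit = function(x, y, seed) {
        set.seed(seed)
        randomForest::randomForest(
          x, y, ntree = 100, mtry = max(1, floor(sqrt(ncol(x)))))
      },
      predict_proba = function(m, x)
        unname(stats::predict(m, x, type = "prob")[, 2])),
    nb = list(
      fit = function(x, y, seed) e1071::naiveBayes(x, y),
      predict_proba = function(m, x)
        unname(stats::predict(m, x, type = "raw")[, 2])),
    lr = list(
      fit = function(x, y, seed) {
        set.seed(seed)
        glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = c(1, 0.1, 0.01, 1e-3, 1e-5, 1e-8),
                       standardize = FALSE)
      },
      predict_proba = function(m, x)
        as.numeric(stats::predict(m, x, s = 1e-8, type = "response"))),
    knn = list(
      fit = function(x, y, seed) list(x = x, y = y, seed = seed),
      predict_proba = function(m, x) {
        set.seed(m$seed)
        pred <- class::knn(m$x, x, m$y, k = 3, prob = TRUE)
        pwin <- attr(pred, "prob")
        ifelse(pred == levels(m$y)[2], pwin, 1 - pwin)
      }),
    mlp = list(
      fit = function(x, y, seed) {
        set.seed(seed)
        nnet::nnet(x, stats::model.matrix(~ y - 1)[, 2], size = 16,
                   decay = 0.001, maxit = 200, trace = FALSE,
                   MaxNWts = 100000, entropy = TRUE)
      },
      predict_proba = function(m, x) as.numeric(stats::predict(m, x))),
    xgb = list(
      fit = function(x, y, seed) {
        dtr <- xgboost::xgb.DMatrix(x, label = as.numeric(y) - 1)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = 0.01,
                        nthread = 1, seed = seed),
          data = dtr, nrounds = 100, verbose = 0)
      },
      predict_proba = function(m, x)
        as.numeric(stats::predict(m, xgboost::xgb.DMatrix(x)))),
    gbt = list(
      fit = function(x, y, seed) {
        dtr <- xgboost::xgb.DMatrix(x, label = as.numeric(y) - 1)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = 0.01,
                        tree_method = "hist", grow_policy = "lossguide",
                        max_depth = 0, max_leaves = 31,
                        nthread = 1, seed = seed),
          data = dtr, nrounds = 100, verbose = 0)
      },
      predict_proba = function(m, x)
        as.numeric(stats::predict(m, xgboost::xgb.DMatrix(x)))))
  if (is.null(names)) return(reg)
  unknown <- setdiff(names, base::names(reg))
  if (length(unknown)) stop("unknown classifiers: ",
                            paste(unknown, collapse = ", "))
  reg[names]
}

# Training-fold preprocessing: impute missing values (mode for binary/one-hot,
# median for continuous) and z-score the continuous columns, using training
# statistics only.
fit_preprocessor <- function(x_train, continuous_cols) {
  med <- apply(x_train, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) 0 else stats::median(v)
  })
  mode_val <- apply(x_train, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) 0 else as.numeric(names(sort(table(v),
                                                     decreasing = TRUE))[1])
  })
  is_cont <- colnames(x_train) %in% continuous_cols
  fill <- ifelse(is_cont, med, mode_val)
  mu <- rep(0, ncol(x_train)); sdv <- rep(1, ncol(x_train))
  if (any(is_cont)) {
    mu[is_cont] <- colMeans(x_train[, is_cont, drop = FALSE], na.rm = TRUE)
    s <- apply(x_train[, is_cont, drop = FALSE], 2, stats::sd, na.rm = TRUE)
    s[!is.finite(s) | s == 0] <- 1
    sdv[is_cont] <- s
  }
  list(fill = fill, mu = mu, sd = sdv)
}

apply_preprocessor <- function(prep, x) {
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    v[is.na(v)] <- prep$fill[j]
    x[, j] <- (v - prep$mu[j]) / prep$sd[j]
  }
  x
}
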