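test_that("stratified folds preserve class balance, cover and partition", {
  y <- rep(c("normal", "LBW"), c(90, 10))
  splits <- stratified_repeated_cv(y, k = 5, repeats = 3, seed = 2)
  expect_length(splits, 15)
  for (r in 1:3) {
    these <- Filter(function(s) s$repeat_id == r, splits)
    test_sets <- lapply(these, `[[`, "test_ids")
    expect_setequal(unlist(test_sets), seq_along(y))
    for (i in seq_along(test_sets))
      for (j in seq_len(i - 1))
        expect_length(intersect(test_sets[[i]], test_sets[[j]]), 0)
    for (s in these) {
      expect_equal(sum(y[s$test_ids] == "LBW"), 2) # 10 positives over 5 folds
      expect_setequal(c(s$train_ids, s$test_ids), seq_along(y))
    }
  }
  expect_identical(stratified_repeated_cv(y, 5, 3, seed = 2), splits)
  expect_error(stratified_repeated_cv(rep(c("a", "b"), c(97, 3)), k = 5),
               "at least")
})

test_that("weighted precision/recall/F match hand computations", {
  y <- rep(c("normal", "LBW"), c(9, 1))
  pred <- rep("normal", 10)
  m <- weighted_prf(y, pred)
  expect_equal(m[["precision"]], 0.81)
  expect_equal(m[["recall"]], 0.9)
  perfect <- weighted_prf(y, y)
  expect_equal(unname(perfect), c(1, 1, 1))
})

test_that("per-class F equals 2PR/(P+R) on random confusion tables", {
  set.seed(3)
  for (i in 1:20) {
    y <- sample(c("a", "b"), 40, replace = TRUE, prob = c(0.7, 0.3))
    pred <- sample(c("a", "b"), 40, replace = TRUE)
    if (length(unique(y)) < 2) next
    for (cl in c("a", "b")) {
      cc <- confusion_counts(y, pred, cl)
      p <- if (cc[["TP"]] + cc[["FP"]] == 0) 0 else
        cc[["TP"]] / (cc[["TP"]] + cc[["FP"]])
      r <- if (cc[["TP"]] + cc[["FN"]] == 0) 0 else
        cc[["TP"]] / (cc[["TP"]] + cc[["FN"]])
      f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
      # recompute the weighted metric from per-class pieces
      w <- c(mean(y == "a"), mean(y == "b"))
      comp <- weighted_prf(y, pred)
      expect_gte(comp[["fscore"]], 0); expect_lte(comp[["fscore"]], 1)
      if (cl == "b") {
        ccA <- confusion_counts(y, pred, "a")
        pA <- if (ccA[["TP"]] + ccA[["FP"]] == 0) 0 else
          ccA[["TP"]] / (ccA[["TP"]] + ccA[["FP"]])
        rA <- if (ccA[["TP"]] + ccA[["FN"]] == 0) 0 else
          ccA[["TP"]] / (ccA[["TP"]] + ccA[["FN"]])
        fA <- if (pA + rA == 0) 0 else 2 * pA * rA / (pA + rA)
        expect_equal(comp[["fscore"]], w[1] * fA + w[2] * f, tolerance = 1e-12)
        expect_equal(comp[["precision"]], w[1] * pA + w[2] * p,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("weighted recall equals accuracy in the binary case", {
  set.seed(9)
  y <- sample(c("normal", "LBW"), 60, replace = TRUE, prob = c(0.8, 0.2))
  pred <- sample(c("normal", "LBW"), 60, replace = TRUE)
  expect_equal(weighted_prf(y, pred)[["recall"]], mean(y == pred),
               tolerance = 1e-12)
})

test_that("AUC-ROC equals the rank statistic and pROC agrees", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1), 1), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), 1), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4), 1), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.3, 0.4), 1), "both classes")
  set.seed(4)
  y <- sample(0:1, 50, replace = TRUE)
  s <- round(runif(50), 1) # ties on purpose
  skip_if_not_installed("pROC")
  ref <- suppressMessages(as.numeric(pROC::auc(y, s, direction = "<")))
  expect_equal(roc_auc(y, s, 1), ref, tolerance = 1e-12)
})

test_that("PR interpolation follows the hyperbolic formula", {
  A <- list(TP = 2, FP = 0); B <- list(TP = 4, FP = 2)
  expect_equal(pr_interpolate(A, B, 1), 0.75)
  # endpoint consistency: x = TP_B - TP_A recovers precision at B
  expect_equal(pr_interpolate(A, B, 2), 4 / 6)
  # zero-slope case is monotone in x
  Af <- list(TP = 1, FP = 3); Bf <- list(TP = 5, FP = 3)
  ys <- vapply(1:4, function(x) pr_interpolate(Af, Bf, x), numeric(1))
  expect_equal(ys, (1 + 1:4) / (1 + 1:4 + 3))
  expect_true(all(diff(ys) > 0))
  expect_error(pr_interpolate(B, A, 1), "exceed")
  expect_error(pr_interpolate(A, B, 3), "x must")
})

test_that("interpolated PR area matches the longhand oracle and is monotone-invariant", {
  expect_equal(auprc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), 1), 1)
  set.seed(6)
  for (i in 1:30) {
    n <- sample(5:30, 1)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0) y[1] <- 1
    s <- round(runif(n), 2)
    a <- auprc(y, s, 1)
    expect_equal(a, oracle_auprc(y, s, "1"), tolerance = 1e-9)
    # strictly monotone transformation leaves the area unchanged
    expect_equal(auprc(y, exp(3 * s), 1), a, tolerance = 1e-12)
    expect_gte(a, 0); expect_lte(a, 1)
  }
  expect_error(auprc(c(0, 0), c(0.1, 0.2), 1), "no positive")
})

test_that("PR area under random scores concentrates near prevalence", {
  set.seed(8)
  pi0 <- 0.2
  vals <- replicate(200, {
    y <- c(rep(1, 40), rep(0, 160))
    auprc(y, runif(200), 1)
  })
  expect_lt(abs(mean(vals) - pi0), 0.05)
})

test_that("pr_value weights per-class areas by support", {
  set.seed(10)
  y <- factor(rep(c("normal", "LBW"), c(30, 10)), levels = c("normal", "LBW"))
  s <- runif(40)
  pv <- pr_value(y, s, "LBW")
  a_pos <- auprc(y, s, "LBW")
  a_neg <- auprc(y, 1 - s, "normal")
  expect_equal(pv[["pr_positive"]], a_pos)
  expect_equal(pv[["pr_overall"]], 0.25 * a_pos + 0.75 * a_neg)
})

test_that("the experiment report has the expected shape and ranges", {
  sch <- default_lbw_schema(10)
  co <- generate_cohort(sch, 150, 0.2, seed = 4)
  cfg <- experiment_config(co, classifiers = c("lr", "nb"),
                           feature_sets = c("original", "embedding"),
                           k = 3, repeats = 2,
                           walk = small_walk_params(),
                           embedding = small_embed_params(), seed = 5)
  rep <- run_experiment(cfg)
  expect_equal(nrow(rep), 4) # 2 classifiers x 2 feature sets
  metric_cols <- c("precision", "recall", "fscore", "auc", "pr_lbw",
                   "pr_overall")
  expect_true(all(c(metric_cols, paste0(metric_cols, "_sd")) %in%
                  names(rep)))
  m <- as.matrix(rep[metric_cols])
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(as.matrix(rep[paste0(metric_cols, "_sd")]) >= 0))
})

test_that("classifier registry validates names and predicts probabilities", {
  expect_error(lbw_classifiers("svm"), "unknown")
  sch <- default_lbw_schema(10)
  co <- generate_cohort(sch, 200, 0.25, seed = 2)
  fm <- assemble(co, set_name = "original")
  prep <- lbwgraph:::fit_preprocessor(fm$x, fm$continuous_cols)
  x <- lbwgraph:::apply_preprocessor(prep, fm$x)
  for (nm in names(lbw_classifiers())) {
    cl <- lbw_classifiers(nm)[[nm]]
    m <- cl$fit(x[1:150, ], fm$y[1:150], seed = 1)
    p <- cl$predict_proba(m, x[151:200, ])
    expect_length(p, 50)
    expect_true(all(p >= 0 & p <= 1), info = nm)
  }
})

test_that("fold preprocessing imputes and standardizes from training data only", {
  x <- matrix(c(1, 2, 3, NA, 0, 1, NA, 1), ncol = 2,
              dimnames = list(NULL, c("orig_age", "orig_flag")))
  prep <- lbwgraph:::fit_preprocessor(x, "orig_age")
  out <- lbwgraph:::apply_preprocessor(prep, x)
  expect_false(anyNA(out))
  # continuous: NA -> median(1,2,3)=2 then z-scored by training stats
  expect_equal(unname(out[4, "orig_age"]), (2 - 2) / 1)
  # binary: NA -> mode (1 appears twice), left unscaled
  expect_equal(unname(out[3, "orig_flag"]), 1)
})
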