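#' Confusion counts for one class
#'
#' @param labels True labels (factor or character).
#' @param predicted Predicted labels.
#' @param class The class treated as positive.
#' @return Named counts `(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(labels, predicted, class) {
  labels <- as.character(labels); predicted <- as.character(predicted)
  c(TP = sum(labels == class & predicted == class),
    FP = sum(labels != class & predicted == class),
    FN = sum(labels == class & predicted != class),
    TN = sum(labels != class & predicted != class))
}

#' Support-weighted precision, recall and F-score
#'
#' Per-class precision TP/(TP+FP), recall TP/(TP+FN) and
#' F = 2PR/(P+R), with the 0/0 -> 0 convention, averaged across classes with
#' weights proportional to class support.
#'
#' @param labels True labels.
#' @param predicted Predicted labels.
#' @return Named vector `(precision, recall, fscore)`.
#' @export
weighted_prf <- function(labels, predicted) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  support <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  per <- vapply(classes, function(cl) {
    cc <- confusion_counts(labels, predicted, cl)
    p <- safe_div(cc["TP"], cc["TP"] + cc["FP"])
    r <- safe_div(cc["TP"], cc["TP"] + cc["FN"])
    f <- safe_div(2 * p * r, p + r)
    c(p, r, f)
  }, numeric(3))
  w <- support / sum(support)
  out <- as.numeric(per %*% w)
  names(out) <- c("precision", "recall", "fscore")
  out
}

safe_div <- function(num, den) {
  num <- unname(num); den <- unname(den)
  if (den == 0) 0 else num / den
}

#' Area under the ROC curve
#'
#' Computed as the tie-corrected Mann-Whitney rank statistic: the probability
#' that a random positive outscores a random negative, counting ties as 1/2.
#'
#' @param labels True labels.
#' @param scores Numeric scores, larger = more positive.
#' @param positive_class The class treated as positive.
#' @return Real in \[0, 1\].
#' @export
roc_auc <- function(labels, scores, positive_class) {
  pos <- as.character(labels) == as.character(positive_class)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision interpolated between two PR points
#'
#' Between achievable points A = (TP_A, FP_A) and B = (TP_B, FP_B) with
#' TP_B > TP_A, the precision at TP_A + x (1 <= x <= TP_B - TP_A) is
#' \deqn{y = \frac{TP_A + x}{TP_A + x + FP_A + \frac{FP_B - FP_A}{TP_B - TP_A} x}}
#' i.e. false positives are assumed to accrue linearly with true positives
#' between the two operating points.
#'
#' @param A,B Lists or named vectors with elements `TP` and `FP`.
#' @param x Integer offset, 1 <= x <= TP_B - TP_A.
#' @return The interpolated precision.
#' @export
pr_interpolate <- function(A, B, x) {
  tpa <- A[["TP"]]; fpa <- A[["FP"]]; tpb <- B[["TP"]]; fpb <- B[["FP"]]
  if (tpb <= tpa) stop("TP_B must exceed TP_A")
  if (x < 1 || x > tpb - tpa) stop("x must lie in [1, TP_B - TP_A]")
  slope <- (fpb - fpa) / (tpb - tpa)
  (tpa + x) / (tpa + x + fpa + slope * x)
}

# Achievable PR operating points from a threshold sweep: cumulative (TP, FP)
# at every distinct score value, scores descending, starting from (0, 0).
pr_achievable_points <- function(labels, scores, positive_class) {
  pos <- as.character(labels) == as.character(positive_class)
  o <- order(scores, decreasing = TRUE)
  pos <- pos[o]; s <- scores[o]
  keep <- which(c(diff(s) != 0, TRUE)) # last index of each tie group
  data.frame(TP = cumsum(pos)[keep], FP = cumsum(!pos)[keep])
}

#' Area under the interpolated precision-recall curve
#'
#' Builds the PR curve from a threshold sweep over the scores, inserts one
#' interpolated point per unit true-positive increment between consecutive
#' achievable points using [pr_interpolate()], and integrates precision over
#' recall by the trapezoid rule. The curve is anchored at recall 0 with the
#' precision of the first true positive.
#'
#' @inheritParams roc_auc
#' @param positive_class The class treated as positive.
#' @return Real in \[0, 1\].
#' @export
auprc <- function(labels, scores, positive_class) {
  pos <- as.character(labels) == as.character(positive_class)
  P <- sum(pos)
  if (P == 0) stop("no positive instances")
  pts <- pr_achievable_points(labels, scores, positive_class)
  tpa <- 0; fpa <- 0
  rec <- numeric(0); prec <- numeric(0)
  for (i in seq_len(nrow(pts))) {
    tpb <- pts$TP[i]; fpb <- pts$FP[i]
    if (tpb > tpa) {
      for (x in seq_len(tpb - tpa)) {
        y <- pr_interpolate(list(TP = tpa, FP = fpa),
                            list(TP = tpb, FP = fpb), x)
        rec <- c(rec, (tpa + x) / P)
        prec <- c(prec, y)
      }
    } else {
      # FP-only step: recall unchanged, precision drops to the new point
      rec <- c(rec, tpb / P)
      prec <- c(prec, tpb / (tpb + fpb))
    }
    tpa <- tpb; fpa <- fpb
  }
  rec <- c(0, rec); prec <- c(prec[1], prec)
  sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
}

#' Per-class and overall PR areas
#'
#' `pr_lbw` is the PR area for the positive (minority) class; `pr_overall`
#' is the support-weighted mean of the per-class areas, scoring each class
#' with its own predicted probability.
#'
#' @param labels True labels.
#' @param scores Probability of the positive class.
#' @param positive_class Minority class name.
#' @return Named vector `(pr_positive, pr_overall)`.
#' @export
pr_value <- function(labels, scores, positive_class) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  areas <- vapply(classes, function(cl) {
    s <- if (cl == positive_class) scores else 1 - scores
    auprc(labels, s, cl)
  }, numeric(1))
  support <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  c(pr_positive = unname(areas[positive_class]),
    pr_overall = sum(areas * support / sum(support)))
}
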