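#' Generate a synthetic maternal cohort
#'
#' Samples a patient table from a risk-factor schema. Each patient is assigned
#' a latent complication profile uniformly at random; binary complication
#' prevalences are modulated by the factor's per-profile affinity multiplier,
#' so patients in the same profile tend to share complications. The
#' low-birth-weight label is Bernoulli with logit equal to an intercept plus
#' the sum of factor effects (binary factors enter as 0/1, continuous factors
#' as z-scores against their schema mean/sd, categorical factors as an
#' indicator of their last, highest-risk category). The intercept is
#' calibrated by bisection so that the mean predicted probability over the
#' generated covariates equals `target_prevalence`.
#'
#' @param schema A [risk_factor_schema()].
#' @param n Number of patients (>= 10).
#' @param target_prevalence Desired expected LBW fraction, in (0, 1).
#' @param n_profiles Number of latent profiles (>= 1); affinity vectors in the
#'   schema are recycled or truncated to this length.
#' @param seed Integer seed; the same (schema, n, seed) always yields a
#'   bit-identical table.
#' @param missing_rate Probability that any individual factor value is masked
#'   completely at random (default 0).
#' @return A `data.frame` of class `cohort_table` with `patient_id`, one
#'   column per factor, and a `label` factor with levels `normal`, `LBW`.
#'   Attributes: `lbw_prob` (the generating per-patient probability),
#'   `profile` (latent profile index), `intercept`.
#' @export
generate_cohort <- function(schema, n, target_prevalence, n_profiles = 3,
                            seed = 1, missing_rate = 0) {
  validate_schema(schema)
  if (n < 10) stop("n must be >= 10")
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must lie in (0, 1)")
  if (n_profiles < 1) stop("n_profiles must be >= 1")
  withr_seed <- function(expr) { # local RNG scope, restore afterwards
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    expr
  }
  withr_seed({
    profile <- sample.int(n_profiles, n, replace = TRUE)
    cols <- list(patient_id = seq_len(n))
    eta <- numeric(n)
    for (f in schema$factors) {
      if (f$kind == "binary") {
        p <- rep(f$params$prevalence, n)
        if (!is.null(f$cluster_affinity) && n_profiles > 1) {
          aff <- rep_len(f$cluster_affinity, n_profiles)
          p <- pmin(p * aff[profile], 0.99)
        }
        x <- as.integer(stats::runif(n) < p)
        eta <- eta + f$effect * x
        cols[[f$name]] <- x
      } else if (f$kind == "categorical") {
        idx <- sample.int(length(f$params$labels), n, replace = TRUE,
                          prob = f$params$probs)
        eta <- eta + f$effect * (idx == length(f$params$labels))
        cols[[f$name]] <- f$params$labels[idx]
      } else {
        x <- stats::rnorm(n, f$params$mean, f$params$sd)
        eta <- eta + f$effect * (x - f$params$mean) / f$params$sd
        cols[[f$name]] <- x
      }
    }
    if (any(!is.finite(eta)))
      stop("label model cannot be calibrated: non-finite linear predictor ",
           "(infinite effects?)")
    b0 <- calibrate_intercept(eta, target_prevalence)
    prob <- stats::plogis(b0 + eta)
    label <- factor(ifelse(stats::runif(n) < prob, "LBW", "normal"),
                    levels = c("normal", "LBW"))
    df <- as.data.frame(cols, stringsAsFactors = FALSE)
    if (missing_rate > 0) {
      fac_cols <- setdiff(names(df), "patient_id")
      for (cn in fac_cols) {
        mask <- stats::runif(n) < missing_rate
        df[[cn]][mask] <- NA
      }
    }
    df$label <- label
    class(df) <- c("cohort_table", "data.frame")
    attr(df, "lbw_prob") <- prob
    attr(df, "profile") <- profile
    attr(df, "intercept") <- b0
    df
  })
}

# Bisection on the logistic intercept so mean(plogis(b0 + eta)) hits the
# target; the mean is monotone increasing in b0, so the root is unique.
calibrate_intercept <- function(eta, target, tol = 1e-10) {
  fn <- function(b0) mean(stats::plogis(b0 + eta)) - target
  lo <- -40; hi <- 40
  if (fn(lo) > 0 || fn(hi) < 0) stop("intercept calibration unsatisfiable")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (fn(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Validate a cohort table
#'
#' Checks unique patient ids, a complete label column, and an exact match
#' between the table's factor columns and the schema.
#'
#' @param cohort A `cohort_table`.
#' @param schema Optional schema to check columns against.
#' @return The cohort, invisibly.
#' @export
validate_cohort <- function(cohort, schema = NULL) {
  stopifnot(is.data.frame(cohort))
  if (!"patient_id" %in% names(cohort) || !"label" %in% names(cohort))
    stop("cohort must have patient_id and label columns")
  if (anyDuplicated(cohort$patient_id)) stop("patient_id not unique")
  if (anyNA(cohort$label)) stop("label missing for some rows")
  if (!is.null(schema)) {
    expected <- schema_factor_names(schema)
    got <- setdiff(names(cohort), c("patient_id", "label"))
    if (!setequal(expected, got))
      stop("cohort columns do not match schema: missing [",
           paste(setdiff(expected, got), collapse = ","), "] extra [",
           paste(setdiff(got, expected), collapse = ","), "]")
  }
  invisible(cohort)
}

#' Write / read a cohort table as CSV
#'
#' @param cohort A `cohort_table`.
#' @param path File path.
#' @return `read_cohort` returns a `cohort_table`; `write_cohort` the path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$label <- factor(df$label, levels = c("normal", "LBW"))
  class(df) <- c("cohort_table", "data.frame")
  df
}
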