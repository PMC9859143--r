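#' Risk-factor schema
#'
#' A schema describes the maternal risk factors a cohort table carries: binary
#' complications (gestational diabetes, previous low birth weight,
#' consanguinity, ...), categorical factors (blood group, ...) and continuous
#' measures (age, BMI, height, ...). Each factor has a marginal model, a
#' log-odds effect on the low-birth-weight outcome and, for binary factors, an
#' optional per-profile prevalence multiplier that induces complication
#' co-occurrence within latent patient profiles.
#'
#' @param factors A list of factor descriptors, each a list with elements
#'   `name`, `kind` (one of `"binary"`, `"categorical"`, `"continuous"`),
#'   `params` (for binary: `prevalence`; for categorical: `labels` and
#'   `probs`; for continuous: `mean` and `sd`), `effect` (log-odds
#'   coefficient, default 0) and optionally `cluster_affinity` (numeric vector
#'   of prevalence multipliers, one per latent profile; binary factors only).
#'
#' @return An object of class `risk_factor_schema`.
#' @export
risk_factor_schema <- function(factors) {
  stopifnot(is.list(factors), length(factors) > 0)
  factors <- lapply(factors, function(f) {
    if (is.null(f$effect)) f$effect <- 0
    f
  })
  schema <- structure(list(factors = factors), class = "risk_factor_schema")
  validate_schema(schema)
  schema
}

#' Validate a risk-factor schema
#'
#' Checks the structural invariants: unique names, known kinds, binary
#' prevalences strictly inside (0, 1), categorical probabilities summing to 1,
#' positive standard deviations, and affinity vectors that are positive.
#'
#' @param schema A `risk_factor_schema`.
#' @return The schema, invisibly. Errors on violation.
#' @export
validate_schema <- function(schema) {
  if (!inherits(schema, "risk_factor_schema")) stop("not a risk_factor_schema")
  nms <- vapply(schema$factors, function(f) f$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate factor names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  for (f in schema$factors) {
    if (!f$kind %in% c("binary", "categorical", "continuous"))
      stop("unknown factor kind '", f$kind, "' for ", f$name)
    if (f$kind == "binary") {
      p <- f$params$prevalence
      if (is.null(p) || !is.finite(p) || p <= 0 || p >= 1)
        stop("binary prevalence for ", f$name, " must lie in (0,1)")
    } else if (f$kind == "categorical") {
      pr <- f$params$probs
      if (is.null(pr) || length(pr) != length(f$params$labels))
        stop("categorical ", f$name, ": labels/probs length mismatch")
      if (abs(sum(pr) - 1) > 1e-9)
        stop("categorical probabilities for ", f$name, " must sum to 1")
      if (any(pr < 0)) stop("negative category probability for ", f$name)
    } else {
      if (is.null(f$params$sd) || f$params$sd <= 0)
        stop("continuous sd for ", f$name, " must be > 0")
    }
    if (!is.null(f$cluster_affinity)) {
      if (f$kind != "binary")
        stop("cluster_affinity is only supported on binary factors (", f$name, ")")
      if (any(f$cluster_affinity <= 0))
        stop("cluster_affinity multipliers must be positive (", f$name, ")")
    }
  }
  invisible(schema)
}

#' Default maternal risk-factor schema
#'
#' Builds a mixed-type schema of the size used throughout the package:
#' roughly 60% binary complications, 20% categorical factors and 20%
#' continuous measures. Binary complications are split into blocks, each block
#' enriched in one latent profile (multiplier `affinity_high`) and depleted in
#' the others (`affinity_low`), so that patients within a profile share
#' complications — the premise under which a patient-complication graph
#' carries signal. Effects are modest log-odds coefficients scaled by
#' `effect_scale`; `effect_scale = 0` yields a null cohort in which the label
#' is independent of every factor.
#'
#' @param n_factors Total number of risk factors (default 40).
#' @param n_profiles Number of latent complication profiles (default 3).
#' @param effect_scale Multiplier applied to every log-odds effect
#'   (default 1; 0 gives the null schema).
#' @param affinity_high,affinity_low Prevalence multipliers for a binary
#'   complication inside / outside its enriched profile.
#' @return A `risk_factor_schema`.
#' @export
default_lbw_schema <- function(n_factors = 40, n_profiles = 3, effect_scale = 1,
                               affinity_high = 3, affinity_low = 0.4) {
  stopifnot(n_factors >= 5, n_profiles >= 1)
  n_bin <- max(3, round(0.6 * n_factors))
  n_cat <- max(1, round(0.2 * n_factors))
  n_con <- n_factors - n_bin - n_cat
  if (n_con < 1) { n_con <- 1; n_bin <- n_factors - n_cat - n_con }

  factors <- vector("list", 0)
  # binary complications, block-assigned to profiles
  bin_prev <- rep(c(0.08, 0.12, 0.2, 0.3), length.out = n_bin)
  bin_eff <- rep(c(0.9, 0.6, 0.4, 0.25), length.out = n_bin) * effect_scale
  for (j in seq_len(n_bin)) {
    prof <- ((j - 1) %% n_profiles) + 1
    aff <- rep(affinity_low, n_profiles)
    aff[prof] <- affinity_high
    factors[[length(factors) + 1]] <- list(
      name = sprintf("complication_%02d", j), kind = "binary",
      params = list(prevalence = bin_prev[j]), effect = bin_eff[j],
      cluster_affinity = if (n_profiles > 1) aff else NULL)
  }
  # categorical factors (blood group first, then generic categories)
  cat_specs <- list(
    list(labels = c("O", "A", "B", "AB"), probs = c(0.44, 0.30, 0.20, 0.06)),
    list(labels = c("none", "mild", "severe"), probs = c(0.7, 0.2, 0.1)))
  for (j in seq_len(n_cat)) {
    sp <- cat_specs[[((j - 1) %% length(cat_specs)) + 1]]
    factors[[length(factors) + 1]] <- list(
      name = if (j == 1) "blood_group" else sprintf("category_%02d", j),
      kind = "categorical",
      params = list(labels = sp$labels, probs = sp$probs),
      effect = 0.35 * effect_scale)
  }
  # continuous measures
  con_specs <- list(c(31.6, 6.07), c(27, 5.5), c(158, 7), c(70, 12))
  con_names <- c("age", "bmi", "height", "weight")
  for (j in seq_len(n_con)) {
    sp <- con_specs[[((j - 1) %% length(con_specs)) + 1]]
    factors[[length(factors) + 1]] <- list(
      name = if (j <= length(con_names)) con_names[j] else sprintf("measure_%02d", j),
      kind = "continuous",
      params = list(mean = sp[1], sd = sp[2]),
      effect = 0.2 * effect_scale * (-1)^j)
  }
  risk_factor_schema(factors)
}

#' Names of schema factors by kind
#' @param schema A `risk_factor_schema`.
#' @param kind Optional kind filter.
#' @return Character vector of factor names.
#' @export
schema_factor_names <- function(schema, kind = NULL) {
  fs <- schema$factors
  if (!is.null(kind)) fs <- Filter(function(f) f$kind == kind, fs)
  vapply(fs, function(f) f$name, character(1))
}

#' Write / read a schema as a YAML config
#'
#' The on-disk form is a structured text config with one entry per factor, so
#' a schema can be versioned alongside an analysis.
#'
#' @param schema A `risk_factor_schema`.
#' @param path File path.
#' @return `read_schema` returns the schema; `write_schema` the path, invisibly.
#' @export
write_schema <- function(schema, path) {
  validate_schema(schema)
  yaml::write_yaml(list(factors = schema$factors), path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  obj <- yaml::read_yaml(path)
  risk_factor_schema(obj$factors)
}
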