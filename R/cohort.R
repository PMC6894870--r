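# Synthetic cohort generation.
#
# The generator emulates the per-class marginal distributions of the 14
# coronary-heart-disease risk factors selected from the KNHANES V-VI health
# survey (2010-2015): 7 continuous factors as per-class truncated normals
# and 7 categorical factors as per-class multinomials over their survey
# codes (including the 8/9/88 "non-applicable"/"no response" codes).
# Labels are the OR of six cardiovascular disorder flags; a configurable
# high-variance subgroup is planted in both classes so reconstruction-error
# partitioning has structure to find.

.CONT_FEATURES <- c("age", "body_mass_index", "total_cholesterol",
                    "hdl_cholesterol", "systolic_bp", "waist_circumference",
                    "neutral_fat")

.CAT_FEATURES <- c("obesity", "smoking", "diabetes", "knee_joint_pain",
                   "weight_change", "eating_out", "marital_status")

.DISORDERS <- c("hypertension", "dyslipidemia", "stroke",
                "myocardial_infarction", "angina", "hyperlipidemia")

#' Canonical risk-factor column names
#'
#' Returns the 14 feature names in canonical order (7 continuous followed by
#' 7 categorical). All feature matrices produced by [encode_features()] use
#' this column order.
#'
#' @return Character vector of length 14.
#' @export
cohort_feature_names <- function() c(.CONT_FEATURES, .CAT_FEATURES)

#' Disorder flag column names
#'
#' The six disorder indicators whose OR defines the high-risk label.
#'
#' @return Character vector of length 6.
#' @export
cohort_disorder_names <- function() .DISORDERS

# published per-class (mean, sd): low risk n = 13,075; high risk n = 12,915
.CONT_PARAMS <- list(
  age                 = list(low = c(mean = 41.54,  sd = 17.71),
                             high = c(mean = 55.96,  sd = 15.55)),
  body_mass_index     = list(low = c(mean = 22.53,  sd = 3.27),
                             high = c(mean = 24.61,  sd = 3.33)),
  total_cholesterol   = list(low = c(mean = 181.16, sd = 28.55),
                             high = c(mean = 194.17, sd = 41.91)),
  hdl_cholesterol     = list(low = c(mean = 54.53,  sd = 10.33),
                             high = c(mean = 46.23,  sd = 12.18)),
  systolic_bp         = list(low = c(mean = 113.28, sd = 14.97),
                             high = c(mean = 124.19, sd = 17.41)),
  waist_circumference = list(low = c(mean = 76.94,  sd = 9.55),
                             high = c(mean = 84.40,  sd = 9.44)),
  neutral_fat         = list(low = c(mean = 93.24,  sd = 48.54),
                             high = c(mean = 165.91, sd = 125.52))
)

# published per-class category counts, with survey codes
.CAT_TABLE <- list(
  obesity = list(
    codes  = c("Underweight" = 1, "Normal" = 2, "Obesity" = 3),
    low    = c(1176, 9258, 2641),
    high   = c(254, 7188, 5473)),
  smoking = list(
    codes  = c("Less than 5 packs" = 1, "More than 5 packs" = 2,
               "Never smoked" = 3, "Non-applicable" = 8, "No response" = 9),
    low    = c(336, 3755, 7478, 1501, 5),
    high   = c(224, 5200, 7235, 251, 5)),
  diabetes = list(
    codes  = c("Normal" = 1, "Fasting blood sugar disorder" = 2,
               "Diabetes" = 3),
    low    = c(10678, 1916, 481),
    high   = c(7427, 3262, 2226)),
  knee_joint_pain = list(
    codes  = c("Yes" = 1, "No" = 2, "Non-applicable" = 8, "No response" = 9),
    low    = c(835, 4035, 8201, 4),
    high   = c(2070, 7204, 3637, 4)),
  weight_change = list(
    codes  = c("No change" = 1, "Weight loss" = 2, "Weight gain" = 3,
               "Non-applicable" = 8, "No response" = 9),
    low    = c(7447, 1634, 2481, 1501, 12),
    high   = c(8638, 1743, 2269, 251, 14)),
  eating_out = list(
    codes  = c("More than twice a day" = 1, "Once a day" = 2,
               "5 to 6 times a week" = 3, "3 to 4 times a week" = 4,
               "1 to 2 times a week" = 5, "1 to 3 times a month" = 6,
               "Less than once a month" = 7, "No response" = 9),
    low    = c(1147, 2182, 2570, 1303, 2804, 2242, 825, 2),
    high   = c(735, 1606, 1502, 1070, 2883, 3336, 1781, 2)),
  marital_status = list(
    codes  = c("Married, living together" = 1, "Married, living separately" = 2,
               "Bereavement" = 3, "Divorced" = 4, "Response refused" = 8,
               "No response" = 9, "Non-applicable" = 88),
    low    = c(8338, 58, 566, 300, 374, 2, 3426),
    high   = c(9736, 85, 1576, 436, 165, 9, 908))
)

#' Survey code sets of the categorical risk factors
#'
#' @return Named list; one named integer vector of codes per categorical
#'   feature, names being the category labels.
#' @export
cohort_category_codes <- function() lapply(.CAT_TABLE, `[[`, "codes")

# default logistic link from standardized continuous features to the six
# disorder flags; chosen for epidemiological plausibility (hypertension
# loads on blood pressure, the lipid disorders on cholesterol/triglyceride,
# the ischemic events on age), not fitted to data
.default_disorder_link <- function() {
  coef <- matrix(0, nrow = 6, ncol = 7,
                 dimnames = list(.DISORDERS, .CONT_FEATURES))
  coef["hypertension", c("systolic_bp", "age")] <- c(1.4, 0.3)
  coef["dyslipidemia", c("total_cholesterol", "hdl_cholesterol",
                         "neutral_fat")] <- c(0.8, -0.6, 0.5)
  coef["stroke", c("age", "systolic_bp")] <- c(0.9, 0.4)
  coef["myocardial_infarction", c("age", "total_cholesterol",
                                  "waist_circumference")] <- c(0.7, 0.5, 0.3)
  coef["angina", c("age", "systolic_bp", "body_mass_index")] <- c(0.6, 0.4, 0.3)
  coef["hyperlipidemia", c("neutral_fat", "total_cholesterol")] <- c(1.0, 0.6)
  # pooled reference scale used to standardize before applying the link
  ref_mean <- vapply(.CONT_PARAMS, function(p)
    (p$low[["mean"]] + p$high[["mean"]]) / 2, numeric(1))
  ref_sd <- vapply(.CONT_PARAMS, function(p)
    (p$low[["sd"]] + p$high[["sd"]]) / 2, numeric(1))
  list(coef = coef, intercept = c(low = -6, high = -1),
       ref_mean = ref_mean, ref_sd = ref_sd)
}

#' Default synthetic-cohort specification
#'
#' Builds a [cohort_spec] whose continuous per-class means/SDs and
#' categorical per-class probabilities equal the published survey values
#' (category counts normalised to probabilities by the class column sums).
#' Default class sizes are the published 13,075 low-risk and 12,915
#' high-risk records.
#'
#' @param n_low,n_high Rows to generate per class.
#' @param anomaly_fraction Fraction of rows (within each class) whose
#'   continuous features are redrawn with inflated spread; this plants the
#'   high-variance subgroup that reconstruction-error partitioning targets.
#' @param anomaly_inflation Multiplier (>= 1) applied to the SDs of the
#'   planted subgroup.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @param min_level_count Categorical levels with a published count below
#'   this are dropped (probabilities renormalised). The default 0 keeps
#'   every level, including rare "No response" codes.
#' @return An object of class `cohort_spec`.
#' @export
default_spec <- function(n_low = 13075, n_high = 12915,
                         anomaly_fraction = 0.15, anomaly_inflation = 4,
                         seed = 20251L, min_level_count = 0) {
  cat_params <- list()
  cat_codes <- list()
  for (f in .CAT_FEATURES) {
    tab <- .CAT_TABLE[[f]]
    keep <- tab$low >= min_level_count | tab$high >= min_level_count
    codes <- tab$codes[keep]
    low <- tab$low[keep] / sum(tab$low[keep])
    high <- tab$high[keep] / sum(tab$high[keep])
    names(low) <- names(high) <- names(codes)
    cat_params[[f]] <- list(low = low, high = high)
    cat_codes[[f]] <- codes
  }
  spec <- structure(list(
    n_low = as.integer(n_low), n_high = as.integer(n_high),
    continuous_params = .CONT_PARAMS,
    categorical_params = cat_params,
    categorical_codes = cat_codes,
    disorder_link = .default_disorder_link(),
    anomaly_fraction = anomaly_fraction,
    anomaly_inflation = anomaly_inflation,
    seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks the structural invariants: probability vectors sum to 1 within
#' 1e-9 and match their code lists in length, all SDs are positive, class
#' sizes are nonnegative and the anomaly fraction lies in [0, 1).
#'
#' @param spec A `cohort_spec`.
#' @return The spec, invisibly; errors otherwise.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_low < 0 || spec$n_high < 0)
    stopf("class sizes must be nonnegative")
  if (spec$anomaly_fraction < 0 || spec$anomaly_fraction >= 1)
    stopf("anomaly_fraction must lie in [0, 1)")
  if (spec$anomaly_inflation < 1)
    stopf("anomaly_inflation must be >= 1")
  for (f in names(spec$continuous_params))
    for (cl in c("low", "high"))
      if (spec$continuous_params[[f]][[cl]][["sd"]] <= 0)
        stopf("sd of %s (%s class) must be > 0", f, cl)
  for (f in names(spec$categorical_params)) {
    codes <- spec$categorical_codes[[f]]
    for (cl in c("low", "high")) {
      p <- spec$categorical_params[[f]][[cl]]
      if (length(p) != length(codes))
        stopf("probability vector and code list of '%s' differ in length", f)
      if (abs(sum(p) - 1) > 1e-9)
        stopf("probabilities of '%s' (%s class) sum to %.12f, not 1",
              f, cl, sum(p))
    }
  }
  invisible(spec)
}

# Symmetric truncated-normal sampler: truncation to mean +/- min(4 sd, mean)
# keeps physically nonnegative quantities nonnegative while preserving the
# target mean exactly (symmetry); one-sided clipping at 0 would bias means
# upward by up to half a standard error budget for the skewest features.
.rtruncnorm_sym <- function(n, mean, sd) {
  half <- min(4 * sd, mean)
  lo <- pnorm(mean - half, mean, sd)
  hi <- pnorm(mean + half, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

.draw_class <- function(spec, class, n) {
  out <- list()
  for (f in .CONT_FEATURES) {
    p <- spec$continuous_params[[f]][[class]]
    out[[f]] <- .rtruncnorm_sym(n, p[["mean"]], p[["sd"]])
  }
  for (f in .CAT_FEATURES) {
    codes <- unname(spec$categorical_codes[[f]])
    prob <- spec$categorical_params[[f]][[class]]
    out[[f]] <- if (length(codes) == 1L) rep(codes, n)
                else sample(codes, n, replace = TRUE, prob = prob)
  }
  # plant the high-variance subgroup: redraw continuous features with
  # inflated sd for a random fraction of rows
  marked <- integer(0)
  n_anom <- floor(spec$anomaly_fraction * n)
  if (n_anom > 0) {
    marked <- sample.int(n, n_anom)
    for (f in .CONT_FEATURES) {
      p <- spec$continuous_params[[f]][[class]]
      out[[f]][marked] <- .rtruncnorm_sym(n_anom, p[["mean"]],
                                          p[["sd"]] * spec$anomaly_inflation)
    }
  }
  df <- as.data.frame(out)
  df$anomaly_marker <- 0L
  if (length(marked)) df$anomaly_marker[marked] <- 1L
  df
}

# disorder flags from the logistic link; overridden so the label always
# matches the generating class (all-zero for low risk, at least one flag for
# high risk)
.draw_flags <- function(spec, df, class) {
  link <- spec$disorder_link
  Z <- scale(as.matrix(df[, .CONT_FEATURES]),
             center = link$ref_mean[.CONT_FEATURES],
             scale = link$ref_sd[.CONT_FEATURES])
  eta <- Z %*% t(link$coef) + link$intercept[[class]]
  p <- 1 / (1 + exp(-eta))
  flags <- matrix(rbinom(length(p), 1L, as.vector(p)), nrow = nrow(p),
                  dimnames = list(NULL, .DISORDERS))
  if (class == "low") {
    flags[] <- 0L
  } else {
    none <- rowSums(flags) == 0
    if (any(none)) {
      pick <- max.col(eta[none, , drop = FALSE], ties.method = "first")
      flags[cbind(which(none), pick)] <- 1L
    }
  }
  as.data.frame(flags)
}

#' Generate a synthetic cohort
#'
#' Draws `n_low + n_high` rows per the specification: continuous features
#' from per-class symmetric truncated normals, categorical features from
#' per-class multinomials over their survey codes, disorder flags from the
#' logistic link (constrained so the label equals the generating class),
#' and a planted high-variance subgroup marked in `anomaly_marker`.
#' Byte-identical output for identical spec and seed.
#'
#' @param spec A validated [cohort_spec] (see [default_spec()]).
#' @return A `cohort_table` data.frame: 14 features, 6 disorder flags,
#'   `label`, `anomaly_marker`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    parts <- list()
    for (cl in c("low", "high")) {
      n <- if (cl == "low") spec$n_low else spec$n_high
      if (n == 0) next
      df <- .draw_class(spec, cl, n)
      flags <- .draw_flags(spec, df, cl)
      df <- cbind(df[c(.CONT_FEATURES, .CAT_FEATURES)], flags,
                  label = as.integer(rowSums(flags) > 0),
                  anomaly_marker = df$anomaly_marker)
      parts[[cl]] <- df
    }
    tab <- do.call(rbind, parts)
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    rownames(tab) <- NULL
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}

# ---- CSV round trip ---------------------------------------------------------

#' Write a cohort to CSV
#'
#' One header row; continuous columns printed with 17 significant digits so
#' that [read_cohort()] round-trips doubles exactly.
#'
#' @param table A `cohort_table`.
#' @param destination File path.
#' @return `destination`, invisibly.
#' @export
write_cohort <- function(table, destination) {
  out <- as.data.frame(table)
  for (f in intersect(.CONT_FEATURES, names(out)))
    out[[f]] <- num_to_chr(out[[f]])
  write.csv(out, destination, row.names = FALSE, quote = FALSE)
  invisible(destination)
}

#' Read a cohort from CSV
#'
#' Validates the schema: the 14 features must be present, categorical codes
#' must belong to their declared code sets, flags/label must be 0/1, and no
#' cell may be missing. When `label` is absent but the six disorder flags
#' are present, the label is derived as their OR.
#'
#' @param source CSV path.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(source) {
  df <- read.csv(source, check.names = FALSE)
  as_cohort_table(df)
}

#' Coerce and validate a data.frame as a cohort table
#'
#' @param df A data.frame with the cohort CSV schema.
#' @return A validated `cohort_table`.
#' @export
as_cohort_table <- function(df) {
  missing_cols <- setdiff(cohort_feature_names(), names(df))
  if (length(missing_cols))
    stopf("cohort is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  for (f in .CONT_FEATURES) {
    v <- df[[f]]
    if (!is.numeric(v) || anyNA(v))
      stopf("column '%s' must be numeric with no missing values (first bad row: %d)",
            f, which(!is.finite(v))[1])
  }
  codes <- cohort_category_codes()
  for (f in .CAT_FEATURES) {
    v <- df[[f]]
    bad <- which(!(v %in% codes[[f]]))
    if (length(bad))
      stopf("column '%s' contains unknown category code '%s' at row %d",
            f, v[bad[1]], bad[1])
    df[[f]] <- as.integer(v)
  }
  have_flags <- all(.DISORDERS %in% names(df))
  if (have_flags) {
    for (f in .DISORDERS) {
      if (anyNA(df[[f]]) || !is_binary(df[[f]]))
        stopf("disorder flag '%s' must be 0/1", f)
      df[[f]] <- as.integer(df[[f]])
    }
    derived <- derive_labels(df[.DISORDERS])
    if (is.null(df$label)) df$label <- derived
    else if (!identical(as.integer(df$label), derived))
      stopf("label column contradicts the OR of the disorder flags (first mismatch at row %d)",
            which(as.integer(df$label) != derived)[1])
  }
  if (is.null(df$label))
    stopf("cohort needs either a 'label' column or the 6 disorder flag columns")
  if (anyNA(df$label) || !is_binary(df$label))
    stopf("label must be 0/1 with no missing values")
  df$label <- as.integer(df$label)
  if (!is.null(df$anomaly_marker)) df$anomaly_marker <- as.integer(df$anomaly_marker)
  class(df) <- c("cohort_table", "data.frame")
  df
}
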