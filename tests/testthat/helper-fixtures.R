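# Shared fixtures: all synthetic, generated in code at test time.

small_cohort <- function(n_low = 150, n_high = 150, seed = 42,
                         anomaly_fraction = 0.15) {
  generate_cohort(default_spec(n_low = n_low, n_high = n_high,
                               anomaly_fraction = anomaly_fraction,
                               seed = seed))
}

tiny_ae <- function(epochs = 30, seed = 1) ae_spec(epochs = epochs, seed = seed)
tiny_dnn <- function(epochs = 30, seed = 1) dnn_spec(epochs = epochs, seed = seed)

# a cohort obeying the schema in which only `signal` separates the classes;
# every other column is class-independent noise
planted_cohort <- function(n = 400, signal = "age", shift = 3, seed = 1) {
  codes <- cohort_category_codes()
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    label <- rep(c(0L, 1L), length.out = n)
    df <- data.frame(row.names = seq_len(n))
    for (f in cohort_feature_names()) {
      if (f %in% names(codes)) {
        df[[f]] <- sample(unname(codes[[f]]), n, replace = TRUE)
      } else {
        df[[f]] <- rnorm(n, mean = 50, sd = 1)
      }
    }
    df[[signal]] <- df[[signal]] + shift * label
    for (fl in cohort_disorder_names()) df[[fl]] <- 0L
    df$hypertension <- label
    df$label <- label
    as_cohort_table(df)
  })
}

# fast logistic-regression trainer used to exercise trainer-agnostic
# harness code (cross_validate, ranking) without network training cost
glm_trainer <- function(features = cohort_feature_names()) {
  list(name = "glm",
       fit = function(train, seed) {
         X <- encode_features(train)[, features, drop = FALSE]
         df <- data.frame(X, .y = train$label, check.names = FALSE)
         suppressWarnings(stats::glm(.y ~ ., stats::binomial, df))
       },
       predict = function(model, table) {
         X <- encode_features(table)[, features, drop = FALSE]
         as.vector(suppressWarnings(
           stats::predict(model, data.frame(X, check.names = FALSE),
                          type = "response")))
       })
}

constant_trainer <- function(p = 0.4) {
  list(name = "constant",
       fit = function(train, seed) NULL,
       predict = function(model, table) rep(p, nrow(table)))
}
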