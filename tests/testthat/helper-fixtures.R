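# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# default synthetic study, windowed
study_table <- function() {
  if (is.null(.fixtures$table))
    .fixtures$table <- restrict_rf_window(generate_study())
  .fixtures$table
}

# coarse-grid feature matrix of the study: fast stand-in for the default
# 448-column grid wherever only structure, not resolution, matters
study_features_coarse <- function() {
  if (is.null(.fixtures$fm_coarse))
    .fixtures$fm_coarse <- assemble_features(study_table(),
                                             rf_grid(step = 0.02))
  .fixtures$fm_coarse
}

study_features_std <- function() {
  if (is.null(.fixtures$fm_std))
    .fixtures$fm_std <- standardise(study_features_coarse())
  .fixtures$fm_std
}

# plain numeric matrix wrapped for the clustering/PCA functions
fm_points <- function(x, labels = NULL) {
  colnames(x) <- sprintf("x%d", seq_len(ncol(x)))
  as_feature_matrix(x, labels = labels %||% sprintf("p%02d", seq_len(nrow(x))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny two-channel profile table with known band placement
toy_table <- function() {
  profile_table(
    labels = c("MAN", "JAR", "MAN-RIC 10%"),
    sugars = matrix(c(900, 850, 800,
                      700, 750, 650,
                      30, 25, 80,
                      0, 0, 5), 3, 4,
                    dimnames = list(NULL, c("fructose", "glucose",
                                            "maltose", "sucrose"))),
    organics = matrix(c(0.8, 0.5, 0.72,
                        0.3, 0.6, 0.27,
                        0.0, 0.4, 0.04), 3, 3),
    organic_meta = data.frame(channel = c("R254", "R366", "TW_D"),
                              rf = c(0.14, 0.41, 0.70)),
    provenance = "toy")
}
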