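#' Pipeline run configuration
#'
#' Drives [run_pipeline()]: input (a profile-table file or the synthetic
#' study design), Rf window, feature grid, augmentation, and per-analysis
#' toggles. Every stage's seed is derived deterministically from the
#' global seed.
#'
#' @param input Path to a profile table, or `NULL` to generate the
#'   synthetic default study.
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param rf_window Length-2 numeric, the retained Rf interval.
#' @param grid An [rf_grid()].
#' @param augmentation An [augmentation_config()] (its seed is overridden
#'   by the derived stage seed), or `NULL` to skip augmentation.
#' @param analyses Character subset of `c("hierarchical", "kmeans",
#'   "dbscan", "pca", "regression", "classifier")`.
#' @param kmeans_k Cluster count (`NULL` = elbow selection up to
#'   `kmeans_k_max`).
#' @param kmeans_k_max,kmeans_restarts Elbow search bound and restarts.
#' @param dbscan_eps,dbscan_min_pts DBSCAN parameters; `dbscan_eps = NULL`
#'   uses the median 4-nearest-neighbour distance heuristic.
#' @param regression_targets Sugars to regress.
#' @param max_components,cv_folds RMSECV search bound and fold count.
#' @param classifier A [classifier_config()].
#' @param feature_sets Classifier feature sets to evaluate.
#' @param figures Emit PNG figures.
#' @param write_matrices Write the raw and augmented matrices to CSV.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, out_dir = tempfile("hptlc_run_"),
                       seed = 1L,
                       rf_window = c(0.05, 0.60),
                       grid = rf_grid(),
                       augmentation = augmentation_config(),
                       analyses = c("hierarchical", "kmeans", "dbscan",
                                    "pca", "regression", "classifier"),
                       kmeans_k = NULL, kmeans_k_max = 8L,
                       kmeans_restarts = 25L,
                       dbscan_eps = NULL, dbscan_min_pts = 3L,
                       regression_targets = sugar_names(),
                       max_components = 10L, cv_folds = 10L,
                       classifier = classifier_config(),
                       feature_sets = c("sugars", "organics", "combined"),
                       figures = FALSE, write_matrices = TRUE) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Derive a stage seed from the global seed
#'
#' Deterministic, collision-resistant within a run, and kept below 2^31.
#'
#' @param seed Global seed. @param stage Stage name.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' Ingests or simulates the study, applies the Rf window, assembles and
#' standardises the feature matrix, augments it, runs the requested
#' analyses, and writes every report (JSON), matrix (CSV) and figure (PNG)
#' into `config$out_dir`. Returns (and writes) a manifest listing outputs
#' with MD5 checksums.
#'
#' Clustering and PCA run on the standardised raw-study matrix; regression
#' and the classifier run on the standardised augmented matrix (regression
#' additionally on the raw matrix). Augmentation precedes standardisation.
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  emit <- function(name, path) outputs[[name]] <<- path

  table <- if (is.null(config$input)) {
    generate_study(study_design_config(seed = derive_seed(config$seed, "simulate")))
  } else read_profile_table(config$input)
  table <- restrict_rf_window(table, config$rf_window[1], config$rf_window[2])
  raw_path <- file.path(config$out_dir, "profile_table.csv")
  write_profile_table(table, raw_path); emit("profile_table", raw_path)

  fm_raw <- assemble_features(table, config$grid)
  fm_std <- standardise(fm_raw)
  if (config$write_matrices) {
    p <- file.path(config$out_dir, "feature_matrix.csv")
    write_feature_matrix(fm_std, p); emit("feature_matrix", p)
  }

  fm_aug <- NULL
  if (!is.null(config$augmentation)) {
    aug_cfg <- config$augmentation
    aug_cfg$seed <- derive_seed(config$seed, "augment")
    fm_aug <- standardise(augment(fm_raw, aug_cfg))
    if (config$write_matrices) {
      p <- file.path(config$out_dir, "augmented_matrix.csv")
      write_feature_matrix(fm_aug, p); emit("augmented_matrix", p)
    }
  }

  report <- function(name, obj) {
    p <- file.path(config$out_dir, paste0(name, ".json"))
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
    emit(name, p)
  }

  if ("hierarchical" %in% config$analyses) {
    hc <- hierarchical_cluster(fm_std)
    report("hierarchical", list(method = hc$method, merge = hc$merge,
                                height = hc$height, labels = hc$labels,
                                cut3 = cut_clusters(hc, k = 3L)))
    if (config$figures) {
      p <- file.path(config$out_dir, "dendrogram.png")
      grDevices::png(p, 1200, 700)
      plot(hc$hclust, main = "Hierarchical clustering (average linkage)",
           xlab = "", sub = "", cex = 0.6)
      grDevices::dev.off(); emit("dendrogram", p)
    }
  }
  if ("kmeans" %in% config$analyses) {
    k <- config$kmeans_k
    elbow <- NULL
    if (is.null(k)) {
      elbow <- elbow_select_k(fm_std, config$kmeans_k_max,
                              config$kmeans_restarts,
                              derive_seed(config$seed, "elbow"))
      k <- as.integer(elbow)
    }
    km <- kmeans_cluster(fm_std, k, config$kmeans_restarts,
                         derive_seed(config$seed, "kmeans"))
    report("kmeans", list(method = km$method, k = k,
                          elbow_wss = attr(elbow, "wss"),
                          sizes = km$sizes,
                          between_total_ratio = km$between_total_ratio,
                          assignments = km$assignments))
    if (config$figures) {
      p <- file.path(config$out_dir, "kmeans_scatter.png")
      grDevices::png(p, 800, 700)
      sug <- fm_std$values[, fm_std$meta$kind == "sugar"]
      plot(sug[, "glucose"] + sug[, "fructose"],
           sug[, "sucrose"] + sug[, "maltose"],
           col = km$assignments, pch = 19,
           xlab = "Glucose + Fructose", ylab = "Sucrose + Maltose",
           main = sprintf("k-means, k = %d", k))
      grDevices::dev.off(); emit("kmeans_scatter", p)
    }
  }
  if ("dbscan" %in% config$analyses) {
    eps <- config$dbscan_eps
    if (is.null(eps)) eps <- knn_eps_heuristic(fm_std)
    db <- dbscan_cluster(fm_std, eps, config$dbscan_min_pts)
    report("dbscan", list(method = db$method, n_clusters = db$n_clusters,
                          sizes = db$sizes, noise_points = db$noise_points,
                          assignments = db$assignments))
  }
  if ("pca" %in% config$analyses) {
    pca <- pca_decompose(fm_std, n_components = min(5L, nrow(fm_std$values) - 1L))
    report("pca", list(explained_fraction = pca$explained_fraction,
                       all_fractions = pca$all_fractions,
                       scores = pca$scores))
    if (config$figures) {
      p <- file.path(config$out_dir, "scree.png")
      grDevices::png(p, 800, 600)
      plot(100 * pca$all_fractions[seq_len(min(10, length(pca$all_fractions)))],
           type = "b", xlab = "Component", ylab = "Explained variance (%)",
           main = "Scree plot")
      grDevices::dev.off(); emit("scree", p)
    }
  }
  if ("regression" %in% config$analyses) {
    reg <- list()
    for (target in config$regression_targets) {
      des <- regression_design(fm_std, target)
      mc <- min(config$max_components,
                nrow(fm_std$values) - ceiling(nrow(fm_std$values) / config$cv_folds) - 1L)
      cmp <- compare_methods(des$x, des$y, mc, config$cv_folds,
                             derive_seed(config$seed, paste0("rmsecv_", target)))
      ev <- fit_evaluate(des$x, des$y, "PLS", cmp$PLS$n_components,
                         seed = derive_seed(config$seed, paste0("fit_", target)))
      reg[[target]] <- list(
        pls_components = cmp$PLS$n_components,
        pcr_components = cmp$PCR$n_components,
        pls_rmsecv = cmp$PLS$curve, pcr_rmsecv = cmp$PCR$curve,
        rmse = ev$rmse, rmsep = ev$rmsep, r2 = ev$r2)
    }
    report("regression", reg)
  }
  if ("classifier" %in% config$analyses) {
    if (is.null(fm_aug))
      stop("classifier stage requires augmentation", call. = FALSE)
    cls <- list()
    for (fs in config$feature_sets) {
      cfg <- config$classifier
      cfg$seed <- derive_seed(config$seed, paste0("classifier_", fs))
      rep_ <- kfold_evaluate(fm_aug, cfg, fs)
      cls[[fs]] <- list(fold_accuracies = rep_$fold_accuracies,
                        mean_accuracy = rep_$mean_accuracy)
      utils::write.csv(rep_$confusion,
                       file.path(config$out_dir,
                                 sprintf("confusion_%s.csv", fs)))
      emit(paste0("confusion_", fs),
           file.path(config$out_dir, sprintf("confusion_%s.csv", fs)))
    }
    report("classifier", cls)
  }

  manifest <- list(
    seed = config$seed,
    n_samples = nrow(fm_raw$values),
    n_features = ncol(fm_raw$values),
    n_augmented = if (!is.null(fm_aug)) nrow(fm_aug$values),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# median 4-NN distance: a standard eps heuristic when none is given
knn_eps_heuristic <- function(matrix, k = 4L) {
  d <- as.matrix(stats::dist(matrix$values))
  stats::median(apply(d, 1L, function(r) sort(r)[k + 1L]))
}

#' Summarise a pipeline run
#'
#' Collates the JSON reports listed in a manifest into one human-readable
#' document: cluster sizes and quality, explained variance, chosen
#' component counts, and per-fold classifier accuracies.
#'
#' @param manifest A manifest as returned by [run_pipeline()], or the path
#'   to a `manifest.json`.
#' @return Character vector of report lines (also printed).
#' @export
summarise_run <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  if (is.null(manifest$outputs) || !length(manifest$outputs))
    stop("empty manifest", call. = FALSE)
  get_report <- function(name) {
    entry <- manifest$outputs[[name]]
    if (is.null(entry)) return(NULL)
    path <- if (is.list(entry)) entry$path else entry["path"]
    if (!file.exists(path)) stop("missing report file: ", path, call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  lines <- c(sprintf("Pipeline run (seed %s): %s samples, %s features%s",
                     manifest$seed, manifest$n_samples, manifest$n_features,
                     if (!is.null(manifest$n_augmented))
                       sprintf(", %s augmented rows", manifest$n_augmented)
                     else ""))
  km <- get_report("kmeans")
  if (!is.null(km))
    lines <- c(lines, sprintf(
      "k-means: k = %s, sizes {%s}, between_SS/total_SS = %.1f%%",
      km$k, paste(km$sizes, collapse = ", "), 100 * km$between_total_ratio))
  db <- get_report("dbscan")
  if (!is.null(db))
    lines <- c(lines, sprintf(
      "DBSCAN (eps %.3g, minPts %s): %s clusters, %s noise points",
      db$method$eps, db$method$min_pts, db$n_clusters,
      length(db$noise_points)))
  pca <- get_report("pca")
  if (!is.null(pca))
    lines <- c(lines, sprintf(
      "PCA: %s", paste(sprintf("PC%d %.1f%%", seq_along(pca$explained_fraction),
                               100 * pca$explained_fraction), collapse = ", ")))
  reg <- get_report("regression")
  if (!is.null(reg))
    for (target in names(reg))
      lines <- c(lines, sprintf(
        "%s: PLS %s / PCR %s components, RMSE %.4g, RMSEP %.4g, R^2 %.4f",
        target, reg[[target]]$pls_components, reg[[target]]$pcr_components,
        reg[[target]]$rmse, reg[[target]]$rmsep, reg[[target]]$r2))
  cls <- get_report("classifier")
  if (!is.null(cls)) {
    folds <- length(cls[[1]]$fold_accuracies)
    header <- sprintf("Fold  %s", paste(sprintf("%-10s", names(cls)),
                                        collapse = " "))
    rows <- vapply(seq_len(folds), function(f)
      sprintf("%-5d %s", f, paste(sprintf("%-10.2f",
        vapply(cls, function(r) r$fold_accuracies[f], numeric(1))),
        collapse = " ")), character(1))
    mean_row <- sprintf("Mean  %s", paste(sprintf("%-10.2f",
      vapply(cls, function(r) r$mean_accuracy, numeric(1))), collapse = " "))
    lines <- c(lines, "Classifier accuracy (%) by feature set:",
               header, rows, mean_row)
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
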