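#' Hierarchical clustering of a feature matrix
#'
#' Agglomerative clustering on Euclidean distances of the (standardised)
#' feature rows; the study convention is average linkage. Returns the full
#' merge tree; use [cut_clusters()] for flat assignments.
#'
#' @param matrix A `feature_matrix` with at least 2 samples.
#' @param linkage One of `"average"`, `"single"`, `"complete"`.
#' @param metric Distance metric; only `"euclidean"` is supported.
#' @return A `clustering_report` with fields `method`, `merge`, `height`,
#'   `order`, `labels` and the underlying `hclust` object.
#' @export
hierarchical_cluster <- function(matrix, linkage = c("average", "single", "complete"),
                                 metric = "euclidean") {
  stopifnot(inherits(matrix, "feature_matrix"))
  linkage <- match.arg(linkage)
  metric <- match.arg(metric, "euclidean")
  if (nrow(matrix$values) < 2L) stop("need at least 2 samples", call. = FALSE)
  hc <- stats::hclust(stats::dist(matrix$values, method = metric),
                      method = linkage)
  structure(list(method = list(name = "hierarchical", linkage = linkage,
                               metric = metric),
                 merge = hc$merge, height = hc$height, order = hc$order,
                 labels = matrix$labels, hclust = hc),
            class = "clustering_report")
}

#' @rdname hierarchical_cluster
#' @param report A hierarchical `clustering_report`.
#' @param k,h Number of clusters, or merge height, at which to cut.
#' @export
cut_clusters <- function(report, k = NULL, h = NULL) {
  stopifnot(inherits(report, "clustering_report"),
            !is.null(report$hclust))
  stats::cutree(report$hclust, k = k, h = h)
}

#' k-means clustering with restarts
#'
#' Lloyd iteration from `restarts` random initialisations (best solution
#' kept), reporting cluster sizes and the quality ratio
#' `between_SS / total_SS`, where `total_SS` is the sum of squares about
#' the grand centroid.
#'
#' @param matrix A `feature_matrix`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param restarts Random restarts (default 25).
#' @param seed Integer seed.
#' @return A `clustering_report` with `assignments`, `sizes`,
#'   `between_total_ratio`, `within_ss`, `total_ss` and `centers`.
#' @export
kmeans_cluster <- function(matrix, k, restarts = 25L, seed = 1L) {
  stopifnot(inherits(matrix, "feature_matrix"))
  n <- nrow(matrix$values)
  if (n == 0L) stop("empty matrix", call. = FALSE)
  if (k < 1L || k > n) stop("require 1 <= k <= n", call. = FALSE)
  if (k == n) {
    # degenerate optimum: every point its own centroid
    tot <- sum(sweep(matrix$values, 2L, colMeans(matrix$values))^2)
    return(structure(list(method = list(name = "kmeans", k = k,
                                        restarts = restarts, seed = seed),
                          assignments = stats::setNames(seq_len(n),
                                                        matrix$labels),
                          sizes = rep(1L, n),
                          between_total_ratio = if (tot > 0) 1 else 0,
                          within_ss = 0, total_ss = tot, between_ss = tot,
                          centers = matrix$values, labels = matrix$labels),
                     class = "clustering_report"))
  }
  km <- withr::with_seed(seed,
    stats::kmeans(matrix$values, centers = k, nstart = restarts,
                  iter.max = 100L))
  structure(list(method = list(name = "kmeans", k = k, restarts = restarts,
                               seed = seed),
                 assignments = stats::setNames(km$cluster, matrix$labels),
                 sizes = km$size,
                 between_total_ratio = km$betweenss / km$totss,
                 within_ss = km$tot.withinss, total_ss = km$totss,
                 between_ss = km$betweenss, centers = km$centers,
                 labels = matrix$labels),
            class = "clustering_report")
}

#' Elbow selection of the k-means cluster count
#'
#' Computes the within-cluster sum-of-squares curve for `k = 1..k_max` and
#' selects the k whose curve point is farthest (perpendicular distance)
#' from the chord joining the curve's endpoints; ties (within numerical
#' tolerance) are broken toward the smallest k, so an exactly linear curve
#' selects `k = 1`.
#'
#' @inheritParams kmeans_cluster
#' @param k_max Largest candidate k (`>= 2`, `<= n`).
#' @return The selected k; the curve and per-k distances are attached as
#'   attributes `"wss"` and `"chord_distance"`.
#' @export
elbow_select_k <- function(matrix, k_max = 10L, restarts = 25L, seed = 1L) {
  stopifnot(inherits(matrix, "feature_matrix"), k_max >= 2L)
  n <- nrow(matrix$values)
  if (k_max > n) stop("k_max exceeds sample count", call. = FALSE)
  wss <- vapply(seq_len(k_max), function(k)
    kmeans_cluster(matrix, k, restarts, seed + k)$within_ss, numeric(1L))
  d <- chord_distance(seq_len(k_max), wss)
  sel <- which(d >= max(d) - 1e-9 * max(max(d), 1))[1L]
  structure(as.integer(sel), wss = wss, chord_distance = d)
}

chord_distance <- function(x, y) {
  # perpendicular distance of each curve point from the endpoint chord
  x1 <- x[1L]; y1 <- y[1L]; x2 <- x[length(x)]; y2 <- y[length(y)]
  abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
}

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN: a point is a core point when at least `min_pts` points
#' (itself included) lie within distance `eps`; clusters are the maximal
#' density-connected sets of core points plus the border points they
#' reach; remaining points are noise (cluster id 0). To make the result
#' independent of input row order, points are processed in a canonical
#' order (lexicographic sort of the coordinate rows) and border points go
#' to the first core cluster claiming them in that order.
#'
#' @param matrix A `feature_matrix`.
#' @param eps Neighbourhood radius (Euclidean), `> 0`.
#' @param min_pts Minimum neighbourhood size of a core point, `>= 1`.
#' @return A `clustering_report` with `assignments` (0 = noise), `sizes`,
#'   `n_clusters` and `noise_points` (labels).
#' @export
dbscan_cluster <- function(matrix, eps, min_pts) {
  stopifnot(inherits(matrix, "feature_matrix"), eps > 0, min_pts >= 1)
  x <- matrix$values
  n <- nrow(x)
  if (n == 0L) stop("empty matrix", call. = FALSE)
  canon <- do.call(order, as.data.frame(x))
  rank_of <- integer(n); rank_of[canon] <- seq_len(n)
  d <- as.matrix(stats::dist(x))
  nbr <- d <= eps
  core <- rowSums(nbr) >= min_pts
  cl <- integer(n)  # 0 = unassigned/noise
  next_id <- 0L
  for (i in canon) {
    if (!core[i] || cl[i] != 0L) next
    next_id <- next_id + 1L
    # expand the density-connected component of core point i
    frontier <- i
    cl[i] <- next_id
    while (length(frontier)) {
      nb <- which(nbr[frontier[1L], ])
      frontier <- frontier[-1L]
      for (j in nb[order(rank_of[nb])]) {
        if (cl[j] == 0L) {
          cl[j] <- next_id
          if (core[j]) frontier <- c(frontier, j)
        }
      }
    }
  }
  sizes <- if (next_id > 0L) tabulate(cl[cl > 0L], next_id) else integer()
  structure(list(method = list(name = "dbscan", eps = eps, min_pts = min_pts),
                 assignments = stats::setNames(cl, matrix$labels),
                 sizes = sizes, n_clusters = next_id,
                 noise_points = matrix$labels[cl == 0L],
                 labels = matrix$labels),
            class = "clustering_report")
}

#' @export
print.clustering_report <- function(x, ...) {
  cat("clustering_report:", x$method$name, "\n")
  if (!is.null(x$sizes)) cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  if (!is.null(x$between_total_ratio))
    cat(sprintf("between_SS/total_SS = %.1f%%\n", 100 * x$between_total_ratio))
  if (!is.null(x$noise_points))
    cat("noise points:", length(x$noise_points), "\n")
  invisible(x)
}

#' Principal component analysis of a feature matrix
#'
#' PCA of the column-centred values (no rescaling: the matrix is expected
#' to be standardised already), reporting loadings, scores and the
#' fraction of total variance explained per component.
#'
#' @param matrix A `feature_matrix`.
#' @param n_components Components to keep,
#'   `<= min(samples - 1, features)`.
#' @return A `pca_result` with `loadings` (features x components), `scores`
#'   (samples x components), `explained_fraction` (kept components) and
#'   `all_fractions`.
#' @export
pca_decompose <- function(matrix, n_components = 2L) {
  stopifnot(inherits(matrix, "feature_matrix"))
  n <- nrow(matrix$values); p <- ncol(matrix$values)
  if (n_components > min(n - 1L, p))
    stop("n_components exceeds min(samples - 1, features)", call. = FALSE)
  pc <- stats::prcomp(matrix$values, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 scores = pc$x[, seq_len(n_components), drop = FALSE],
                 explained_fraction = frac[seq_len(n_components)],
                 all_fractions = frac,
                 center = pc$center, labels = matrix$labels),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", ncol(x$scores), "components;",
      sprintf("explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$explained_fraction),
                    collapse = ", ")))
  invisible(x)
}
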