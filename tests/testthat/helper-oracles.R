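# Brute-force reference implementations used as independent oracles.

# Agglomerative clustering that recomputes all pairwise group distances at
# every step from the raw point-pair distances.
oracle_agglomerate <- function(x, linkage = "average") {
  d <- as.matrix(dist(x))
  groups <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  partitions <- list()
  link <- switch(linkage,
                 average = mean, single = min, complete = max)
  while (length(groups) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(groups))
      for (j in seq_len(i - 1L)) {
        dij <- link(d[groups[[i]], groups[[j]], drop = FALSE])
        if (dij < best[1]) best <- c(dij, j, i)
      }
    heights <- c(heights, best[1])
    merged <- c(groups[[best[2]]], groups[[best[3]]])
    groups <- c(groups[-c(best[2], best[3])], list(merged))
    part <- integer(nrow(x))
    for (g in seq_along(groups)) part[groups[[g]]] <- g
    partitions[[length(partitions) + 1L]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# Exhaustive minimum within-cluster sum of squares over all assignments of
# n points to k clusters (all clusters non-empty).
oracle_kmeans_min_wss <- function(x, k) {
  n <- nrow(x)
  stopifnot(k^n <= 1e7)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      wss <- 0
      for (c in unique(assign)) {
        pts <- x[assign == c, , drop = FALSE]
        ctr <- colMeans(pts)
        wss <- wss + sum(sweep(pts, 2L, ctr)^2)
      }
      best <- min(best, wss)
    }
    i <- 1L
    while (i <= n && assign[i] == k) { assign[i] <- 1L; i <- i + 1L }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# DBSCAN by explicit reachability closure: clusters are connected
# components of the core-point graph; noise = points not within eps of any
# core point.
oracle_dbscan <- function(x, eps, min_pts) {
  d <- as.matrix(dist(x))
  nbr <- d <= eps
  core <- which(rowSums(nbr) >= min_pts)
  comp <- integer(nrow(x))
  cid <- 0L
  for (c0 in core) {
    if (comp[c0] != 0L) next
    cid <- cid + 1L
    members <- c0
    repeat {
      grow <- setdiff(core[colSums(nbr[members, core, drop = FALSE]) > 0], members)
      if (!length(grow)) break
      members <- c(members, grow)
    }
    comp[members] <- cid
  }
  border <- which(comp == 0L & rowSums(nbr[, core, drop = FALSE]) > 0)
  noise <- setdiff(which(comp == 0L), border)
  list(core_partition = comp, core = core, border = border, noise = noise,
       n_clusters = cid)
}

# Two flat clusterings are identical up to label permutation.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    nrow(unique(cbind(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
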