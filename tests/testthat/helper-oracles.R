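# Independent brute-force oracles used to cross-check the implementation.

# Connected components by boolean transitive closure of the adjacency
# matrix (repeated squaring), independent of the igraph-based path.
closureComponents <- function(ids, edges) {
  n <- length(ids)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(ids, ids)
  if (nrow(edges)) {
    adj[cbind(edges[[1]], edges[[2]])] <- TRUE
    adj[cbind(edges[[2]], edges[[1]])] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  # label each genome by the smallest id reachable from it
  apply(adj, 1, function(r) min(ids[r]))
}

# Plain agglomerative average linkage by recomputing every between-cluster
# mean distance at each step; merges only strictly below the threshold.
bruteAverageLinkage <- function(m, threshold) {
  clusters <- as.list(rownames(m))
  repeat {
    if (length(clusters) == 1) break
    best <- NULL
    bestD <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- mean(m[clusters[[i]], clusters[[j]]])
      if (d < bestD) { bestD <- d; best <- c(i, j) }
    }
    if (bestD >= threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  membership <- stats::setNames(rep(NA_character_, nrow(m)), rownames(m))
  for (cl in clusters) membership[cl] <- min(cl)
  membership
}

# Same-partition predicate up to label renaming.
samePartition <- function(a, b) {
  a <- a[sort(names(a))]
  b <- b[sort(names(b))]
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# Among/within sums of squares computed from explicit Euclidean coordinates
# (deviations from group centroids), the geometric definition that the
# distance-based decomposition must reproduce for Euclidean data.
euclideanSS <- function(points, groups) {
  centroid <- colMeans(points)
  ssTotal <- sum(sweep(points, 2, centroid)^2)
  ssWithin <- 0
  for (g in unique(groups)) {
    sub <- points[groups == g, , drop = FALSE]
    ssWithin <- ssWithin + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  c(total = ssTotal, within = ssWithin, among = ssTotal - ssWithin)
}

# A small well-separated two-group community matrix for planted-separation
# PERMANOVA checks: groups occupy disjoint species blocks.
plantedCommunity <- function(nPerGroup = 6, nSpecies = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(0, nSpecies, 2 * nPerGroup)
  rownames(m) <- sprintf("sp%02d", seq_len(nSpecies))
  colnames(m) <- sprintf("s%02d", seq_len(2 * nPerGroup))
  half <- nSpecies %/% 2
  m[seq_len(half), seq_len(nPerGroup)] <- rlnorm(half * nPerGroup)
  m[(half + 1):nSpecies, (nPerGroup + 1):(2 * nPerGroup)] <-
    rlnorm((nSpecies - half) * nPerGroup)
  list(m = m, groups = rep(c("g1", "g2"), each = nPerGroup))
}
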