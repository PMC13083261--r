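#' Filter community profiles
#'
#' Single pass, in the stated order: species detected (abundance > 0) in
#' fewer than `minSamples` samples are removed first, then samples whose
#' remaining total scaled abundance is `minTotal` or less are removed. The
#' two steps are not iterated; removing samples can in principle expose
#' species below the detection threshold, which is accepted and documented.
#'
#' @param x a [ReefProfiles-class] or a species x samples matrix.
#' @param minSamples minimum number of samples a species must be detected in.
#' @param minTotal samples with total abundance <= this are removed.
#' @return filtered object of the same type. An error of class
#'   `reefMAGs_empty_filter` is signalled if nothing survives.
#' @export
filterProfiles <- function(x, minSamples = 10, minTotal = 3) {
  m <- if (is(x, "ReefProfiles")) profileMatrix(x) else x
  if (length(m) == 0) .stopf("empty profile matrix")
  keepSpecies <- rowSums(m > 0) >= minSamples
  m2 <- m[keepSpecies, , drop = FALSE]
  keepSamples <- colSums(m2) > minTotal
  if (!any(keepSpecies) || !any(keepSamples))
    stop(structure(class = c("reefMAGs_empty_filter", "error", "condition"),
                   list(message = "profile filtering removed all species or samples",
                        call = sys.call(-1))))
  if (is(x, "ReefProfiles")) x[keepSpecies, keepSamples]
  else m2[, keepSamples, drop = FALSE]
}

#' Presence/absence Jaccard distances between samples
#'
#' Detection is strict positivity. For samples A and B the distance is
#' `1 - |A intersect B| / |A union B|`; a pair of all-absent samples has
#' distance 0 by convention.
#'
#' @param x a [ReefProfiles-class] or species x samples matrix.
#' @return a [stats::dist] over samples.
#' @export
#' @examples
#' m <- cbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1))
#' jaccardDistance(m) # 1 - 2/4 = 0.5
jaccardDistance <- function(x) {
  m <- if (is(x, "ReefProfiles")) profileMatrix(x) else x
  p <- (m > 0) * 1
  shared <- crossprod(p)                 # |A intersect B|
  sizes <- diag(shared)
  union <- outer(sizes, sizes, `+`) - shared
  d <- 1 - shared / union
  d[union == 0] <- 0
  stats::as.dist(d)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes, and returns coordinates on
#' the axes with positive eigenvalues (eigenvectors scaled by the square root
#' of their eigenvalue, sorted by decreasing eigenvalue). Negative
#' eigenvalues, which arise for non-Euclidean distance matrices, are counted
#' and reported, not corrected.
#'
#' @param d a [stats::dist] or square symmetric matrix with zero diagonal.
#' @param nAxes number of axes to return (default: all positive ones).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   decreasing) and `negativeEigenvalues` (count below `-tol`).
#' @param tol eigenvalues within `tol` of zero are treated as null.
#' @export
pcoaOrdination <- function(d, nAxes = NULL, tol = 1e-9) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    .stopf("distance matrix must be square and symmetric")
  n <- nrow(m)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (m^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  scale0 <- max(abs(e$values), 1)
  pos <- which(e$values > tol * scale0)
  if (!is.null(nAxes)) pos <- pos[seq_len(min(nAxes, length(pos)))]
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = length(pos))
  rownames(coords) <- rownames(m)
  colnames(coords) <- if (length(pos)) paste0("PCo", seq_along(pos)) else NULL
  list(coordinates = coords,
       eigenvalues = e$values,
       negativeEigenvalues = sum(e$values < -tol * scale0))
}

# among/within sum-of-squares decomposition of a squared-distance matrix
# under a grouping; Anderson's pseudo-F operates directly on distances.
.permanovaSS <- function(d2, groups) {
  n <- nrow(d2)
  ssTotal <- sum(d2[upper.tri(d2)]) / n
  ssWithin <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ssWithin <- ssWithin + sum(sub[upper.tri(sub)]) / length(idx)
  }
  c(total = ssTotal, within = ssWithin, among = ssTotal - ssWithin)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Anderson's formulation):
#' the among-group sum of squared distances is the total minus the
#' within-group sum, pseudo-F is the ratio of among/within mean squares, and
#' the p-value counts permuted statistics at least as large as the observed
#' one with the observed included: `p = (1 + #(F* >= F)) / (nPermutations + 1)`.
#'
#' @param d a [stats::dist] or square symmetric distance matrix.
#' @param groups group labels, one per sample; at least 2 groups with at
#'   least 2 samples each.
#' @param nPermutations number of label permutations.
#' @param seed optional integer seed for the permutations.
#' @return a [PermanovaResult-class].
#' @export
permanovaTest <- function(d, groups, nPermutations = 999, seed = NULL) {
  m <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) .stopf("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2) .stopf("at least two groups required")
  if (any(sizes < 2)) .stopf("every group needs at least 2 samples")
  if (!is.null(seed)) set.seed(seed)

  d2 <- m^2
  n <- nrow(m)
  a <- length(sizes)
  ss <- .permanovaSS(d2, groups)
  if (ss["total"] <= 0)
    .stopf("distance matrix has no variation; PERMANOVA undefined")
  fObs <- (ss["among"] / (a - 1)) / (ss["within"] / (n - a))
  exceed <- 0L
  for (b in seq_len(nPermutations)) {
    gp <- groups[sample.int(n)]
    ssP <- .permanovaSS(d2, gp)
    fP <- (ssP["among"] / (a - 1)) / (ssP["within"] / (n - a))
    if (fP >= fObs) exceed <- exceed + 1L
  }
  new("PermanovaResult",
      pseudoF = unname(fObs),
      R2 = unname(ss["among"] / ss["total"]),
      p = (1 + exceed) / (nPermutations + 1),
      nPermutations = as.integer(nPermutations))
}

#' PERMANOVA with balanced subsampling of unbalanced groups
#'
#' Groups larger than `subsampleSize` are subsampled to `subsampleSize`
#' without replacement in each repetition (smaller groups enter whole), the
#' PERMANOVA is run on the subsample, and the statistics are aggregated over
#' repetitions as the median p-value and mean R-squared.
#'
#' @inheritParams permanovaTest
#' @param subsampleSize target size for groups above it.
#' @param repetitions number of subsampling repetitions.
#' @param seed integer seed driving both subsampling and permutations.
#' @return list with `medianP`, `meanR2` and `repetitions` (per-repetition
#'   data.frame: pseudoF, R2, p).
#' @export
balancedPermanova <- function(d, groups, subsampleSize = 50,
                              repetitions = 100, nPermutations = 999,
                              seed = NULL) {
  m <- as.matrix(d)
  groups <- as.character(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) .stopf("every group needs at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(repetitions), function(r) {
    keep <- unlist(lapply(names(sizes), function(g) {
      idx <- which(groups == g)
      if (length(idx) > subsampleSize) sample(idx, subsampleSize) else idx
    }), use.names = FALSE)
    keep <- sort(keep)
    res <- permanovaTest(m[keep, keep, drop = FALSE], groups[keep],
                         nPermutations = nPermutations)
    data.frame(pseudoF = res@pseudoF, R2 = res@R2, p = res@p)
  })
  tab <- do.call(rbind, reps)
  list(medianP = median(tab$p), meanR2 = mean(tab$R2), repetitions = tab)
}

#' Detection decay of host-associated species across water categories
#'
#' For each water category (C coral-surrounding, R reef, O open ocean):
#' the fraction of the given host-associated species detected in at least one
#' sample of the category, and the mean per-sample summed relative abundance
#' of those species.
#'
#' @param coralSpecies character vector of host-associated species ids.
#' @param profiles a [ReefProfiles-class] containing seawater samples with
#'   `water_category` metadata.
#' @return data.frame: category, n_detected, fraction_detected,
#'   mean_rel_abundance.
#' @export
detectionDecay <- function(coralSpecies, profiles) {
  if (length(coralSpecies) == 0) .stopf("empty host species set")
  info <- sampleInfo(profiles)
  m <- profileMatrix(profiles)
  cats <- c("C", "R", "O")
  if (!any(cats %in% info$water_category))
    .stopf("no seawater samples with water_category metadata")
  sp <- intersect(coralSpecies, rownames(m))
  out <- do.call(rbind, lapply(cats, function(cc) {
    cols <- which(!is.na(info$water_category) & info$water_category == cc)
    if (!length(cols))
      return(data.frame(category = cc, n_detected = NA_integer_,
                        fraction_detected = NA_real_,
                        mean_rel_abundance = NA_real_))
    sub <- m[sp, cols, drop = FALSE]
    detected <- rowSums(sub > 0) > 0
    totals <- colSums(m[, cols, drop = FALSE])
    rel <- colSums(sub[detected, , drop = FALSE]) / ifelse(totals > 0, totals, 1)
    data.frame(category = cc,
               n_detected = sum(detected),
               fraction_detected = sum(detected) / length(coralSpecies),
               mean_rel_abundance = mean(rel),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
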