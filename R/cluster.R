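#' Cluster genomes into species at an ANI threshold
#'
#' Edges with alignment coverage below `minCoverage` are discarded; the
#' remaining edges with ANI at or above `aniThreshold` define an undirected
#' graph over the genomes and species are its connected components (single
#' linkage). Missing pairs count as below threshold; genomes without any
#' qualifying edge form singleton species. Asymmetric inputs (both (i,j) and
#' (j,i) present) are symmetrized by the arithmetic mean of ANI and coverage
#' before thresholding. Species ids are assigned deterministically in order
#' of each component's smallest member id.
#'
#' @param ani data.frame: genome_i, genome_j, ani (percent), coverage
#'   (fraction).
#' @param genomeIds character vector of all genomes to partition (vertices;
#'   includes genomes absent from the edge table).
#' @param aniThreshold percent ANI defining the species boundary.
#' @param minCoverage minimum aligned fraction of the smaller genome.
#' @return a [SpeciesClusters-class].
#' @export
#' @examples
#' ani <- data.frame(genome_i = "g1", genome_j = "g2", ani = 96, coverage = 0.5)
#' clusterSpecies(ani, c("g1", "g2", "g3"))
clusterSpecies <- function(ani, genomeIds, aniThreshold = 95,
                           minCoverage = 0.2) {
  genomeIds <- sort(unique(genomeIds))
  if (nrow(ani)) {
    unknown <- setdiff(c(ani$genome_i, ani$genome_j), genomeIds)
    if (length(unknown))
      .stopf("ANI edge references unknown genome(s): %s",
             paste(utils::head(unknown, 5), collapse = ", "))
    # canonical orientation, then symmetrize duplicates by arithmetic mean
    flip <- ani$genome_i > ani$genome_j
    tmp <- ani$genome_i[flip]
    ani$genome_i[flip] <- ani$genome_j[flip]
    ani$genome_j[flip] <- tmp
    key <- paste(ani$genome_i, ani$genome_j, sep = "\r")
    if (anyDuplicated(key)) {
      ani <- data.frame(
        genome_i = tapply(ani$genome_i, key, `[`, 1),
        genome_j = tapply(ani$genome_j, key, `[`, 1),
        ani = tapply(ani$ani, key, mean),
        coverage = tapply(ani$coverage, key, mean),
        stringsAsFactors = FALSE)
    }
    keep <- ani$coverage >= minCoverage & ani$ani >= aniThreshold &
      ani$genome_i != ani$genome_j
    edges <- ani[keep, c("genome_i", "genome_j")]
  } else {
    edges <- data.frame(genome_i = character(), genome_j = character())
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = genomeIds)
  comp <- igraph::components(g)$membership
  # deterministic ids ordered by smallest member genome id
  minMember <- tapply(names(comp), comp, min)
  ord <- rank(minMember)
  assignments <- stats::setNames(sprintf("SP%04d", ord[as.character(comp)]),
                                 names(comp))
  new("SpeciesClusters",
      assignments = assignments[genomeIds],
      representatives = character(0),
      aniThreshold = aniThreshold, minCoverage = minCoverage)
}

#' Representative-selection quality score
#'
#' \deqn{Q' = cpl - 5 \, ctn + ctn \times SH / 100 + 0.5 \log_{10}(N50)}
#' where SH is the strain heterogeneity (percent). The logarithm base is
#' fixed to 10 (configurable via `logBase`).
#'
#' @param cpl,ctn,strainHeterogeneity percents; `n50` in base pairs.
#' @param logBase base of the N50 logarithm.
#' @return numeric Q' scores.
#' @export
#' @examples
#' repScore(90, 5, 50, 1e5) # 70
repScore <- function(cpl, ctn, strainHeterogeneity, n50, logBase = 10) {
  cpl - 5 * ctn + ctn * strainHeterogeneity / 100 +
    0.5 * log(n50, base = logBase)
}

#' Select representative genomes by maximum Q'
#'
#' Within each species the member maximizing Q' is chosen; ties break to the
#' lexicographically smallest genome id.
#'
#' @param clusters a [SpeciesClusters-class].
#' @param qc data.frame with genome_id, cpl, ctn, strain_heterogeneity, n50.
#' @return the clusters with the `representatives` slot filled.
#' @export
selectRepresentatives <- function(clusters, qc) {
  scores <- stats::setNames(
    repScore(qc$cpl, qc$ctn, qc$strain_heterogeneity, qc$n50), qc$genome_id)
  missing <- setdiff(names(clusters@assignments), names(scores))
  if (length(missing))
    .stopf("no quality metrics for genome(s): %s",
           paste(utils::head(missing, 5), collapse = ", "))
  reps <- vapply(clusterMembers(clusters), function(members) {
    members <- sort(members)
    members[which.max(scores[members])]
  }, character(1))
  clusters@representatives <- reps
  validObject(clusters)
  clusters
}

#' Concordance between two partitions of the same items
#'
#' Conditional-entropy clustering comparison with `labelsA` read as the
#' clustering under evaluation and `labelsB` as the reference partition:
#' homogeneity `1 - H(B|A)/H(B)` (every A-cluster contains members of a
#' single reference class), completeness `1 - H(A|B)/H(A)` (every reference
#' class sits in a single A-cluster), each defined as 1 when the reference
#' entropy is 0, and the V-measure, their harmonic mean. All lie in
#' \[0, 1\]; identical partitions score 1 everywhere; an all-singleton
#' clustering against one reference class scores homogeneity 1,
#' completeness 0.
#'
#' @param labelsA,labelsB label vectors over the same items (same length and
#'   order).
#' @return list with `homogeneity`, `completeness`, `vMeasure`.
#' @export
#' @examples
#' partitionConcordance(c(1, 1, 2, 2), c("a", "a", "b", "b"))
partitionConcordance <- function(labelsA, labelsB) {
  if (length(labelsA) == 0) .stopf("empty label set")
  if (length(labelsA) != length(labelsB))
    .stopf("label vectors differ in length")
  tab <- table(labelsA, labelsB)
  n <- sum(tab)
  hA <- .entropy(rowSums(tab))
  hB <- .entropy(colSums(tab))
  # H(A|B): entropy of A-labels within each B-class, weighted by class mass
  hAgivenB <- sum(apply(tab, 2, function(col) sum(col) / n * .entropy(col)))
  hBgivenA <- sum(apply(tab, 1, function(row) sum(row) / n * .entropy(row)))
  h <- if (hB == 0) 1 else 1 - hBgivenA / hB
  cm <- if (hA == 0) 1 else 1 - hAgivenB / hA
  v <- if (h + cm == 0) 0 else 2 * h * cm / (h + cm)
  list(homogeneity = h, completeness = cm, vMeasure = v)
}

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Classify taxonomic novelty from a rank-prefixed assignment
#'
#' Taxonomy strings follow the GTDB convention
#' `d__...;p__...;c__...;o__...;f__...;g__...;s__...`; a rank is assigned
#' when non-empty after its prefix. Assignment must be a prefix of the rank
#' order (a gap, e.g. species present but genus absent, is a data error). A
#' full assignment is a known species; otherwise the novelty is "new (child
#' of the deepest assigned rank)", with everything above family collapsed to
#' "new order or higher" for reporting.
#'
#' @param taxonomy character vector of taxonomy strings.
#' @return factor with levels known species, new species, new genus,
#'   new family, new order or higher.
#' @export
#' @examples
#' classifyNovelty("d__Bacteria;p__X;c__Y;o__Z;f__F;g__G;s__")
classifyNovelty <- function(taxonomy) {
  prefixes <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  out <- vapply(taxonomy, function(tx) {
    parts <- trimws(strsplit(tx, ";", fixed = TRUE)[[1]])
    assigned <- rep(FALSE, 7L)
    for (k in seq_len(min(length(parts), 7L)))
      assigned[k] <- nchar(sub(prefixes[k], "", parts[k], fixed = TRUE)) > 0
    deepest <- if (any(assigned)) max(which(assigned)) else 0L
    if (deepest > 0 && any(!assigned[seq_len(deepest)]))
      .stopf("gapped taxonomy assignment: '%s'", tx)
    if (deepest == 7L) return("known species")
    child <- .RANKS[deepest + 1L]
    if (child %in% c("species", "genus", "family"))
      paste("new", child)
    else "new order or higher"
  }, character(1), USE.NAMES = FALSE)
  factor(out, levels = c("known species", "new species", "new genus",
                         "new family", "new order or higher"))
}

#' Host-sharing intersections and the unique-to-one-group fraction
#'
#' UpSet-style counts of species per nonempty host-group combination, plus
#' the fraction of detected species found in exactly one group. Species with
#' an all-false detection row go to an "undetected" bucket and are excluded
#' from the unique-fraction denominator.
#'
#' @param detection logical matrix, species as rows, host groups as columns.
#' @return list with `intersections` (data.frame combination/count, sorted by
#'   count), `undetected` (count), `uniqueFraction`.
#' @export
#' @examples
#' m <- rbind(s1 = c(TRUE, FALSE), s2 = c(FALSE, TRUE), s3 = c(TRUE, TRUE))
#' colnames(m) <- c("stony", "fire")
#' hostSharing(m)
hostSharing <- function(detection) {
  if (is.null(dim(detection)) || nrow(detection) == 0 || ncol(detection) == 0)
    .stopf("empty detection matrix")
  if (is.null(colnames(detection)))
    .stopf("detection matrix needs host-group column names")
  detection <- detection > 0
  combo <- apply(detection, 1, function(r)
    paste(colnames(detection)[r], collapse = "&"))
  undetected <- sum(combo == "")
  combo <- combo[combo != ""]
  counts <- sort(table(combo), decreasing = TRUE)
  nGroups <- rowSums(detection)
  detected <- nGroups > 0
  list(
    intersections = data.frame(combination = names(counts),
                               count = as.integer(counts),
                               row.names = NULL, stringsAsFactors = FALSE),
    undetected = undetected,
    uniqueFraction = if (any(detected)) sum(nGroups == 1) / sum(detected)
                     else NA_real_
  )
}

#' Classify 16S amplicon matches at ASV or OTU level
#'
#' Full-length alignments at 100% identity are ASV-level matches; full-length
#' alignments at >= 97% identity are OTU-level; anything else is no match.
#'
#' @param identity percent identity in \[0, 100\].
#' @param fullLength logical; alignment covers the full ASV length.
#' @return character vector: "ASV-level", "OTU-level" or "none".
#' @export
#' @examples
#' matchAsv(c(100, 98.5, 98.5), c(TRUE, TRUE, FALSE))
matchAsv <- function(identity, fullLength) {
  stopifnot(all(identity >= 0 & identity <= 100))
  ifelse(fullLength & identity == 100, "ASV-level",
  ifelse(fullLength & identity >= 97, "OTU-level", "none"))
}
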