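#' Default natural-product class map
#'
#' Maps antiSMASH-style product labels onto the BiG-SCAPE-style class groups
#' used for reporting: NRPS, RiPPs, T1PKS, T2PKS, T3PKS, terpene, others.
#' Labels absent from the map fall back to "others".
#'
#' @return named character vector, product label -> class group.
#' @export
defaultClassMap <- function() c(
  NRPS = "NRPS", "NRPS-like" = "NRPS",
  T1PKS = "T1PKS", T2PKS = "T2PKS", T3PKS = "T3PKS",
  "transAT-PKS" = "T1PKS",
  terpene = "terpene",
  "lanthipeptide-class-i" = "RiPPs", "lanthipeptide-class-ii" = "RiPPs",
  "lanthipeptide-class-iii" = "RiPPs", "lanthipeptide-class-iv" = "RiPPs",
  lassopeptide = "RiPPs", thiopeptide = "RiPPs", "RRE-containing" = "RiPPs",
  cyanobactin = "RiPPs", sactipeptide = "RiPPs", linaridin = "RiPPs",
  arylpolyene = "others", betalactone = "others", siderophore = "others",
  hserlactone = "others"
)

#' Validate and ingest BGC predictions
#'
#' Records on contigs shorter than `minContigLength` (default 5 kbp,
#' mirroring the prediction settings) are rejected.
#'
#' @param bgcs data.frame: bgc_id, genome_id, contig_id, contig_length,
#'   product_class, on_contig_edge.
#' @param minContigLength minimum contig length in bp.
#' @return the validated table.
#' @export
ingestBgcs <- function(bgcs, minContigLength = 5000) {
  need <- c("bgc_id", "genome_id", "contig_length", "product_class",
            "on_contig_edge")
  missing <- setdiff(need, colnames(bgcs))
  if (length(missing))
    .stopf("BGC table lacks column(s): %s", paste(missing, collapse = ", "))
  short <- bgcs$contig_length < minContigLength
  if (any(short))
    .stopf("%d BGC(s) on contigs shorter than %d bp (first: %s)",
           sum(short), minContigLength, bgcs$bgc_id[which(short)[1]])
  bgcs
}

#' Cluster BGCs into gene cluster families
#'
#' Average-linkage agglomerative clustering on the pairwise BGC distance
#' matrix, cut so that every merge within a family has linkage distance
#' strictly below `threshold`. Missing pairs are treated as distance 1. Input
#' rows are sorted by BGC id before clustering, making the merge order
#' deterministic.
#'
#' @param bgcDist data.frame: bgc_i, bgc_j, dist (in \[0, 1\]).
#' @param bgcIds all BGC ids to partition (singletons allowed).
#' @param threshold linkage cut (strict <).
#' @return named character vector, GCF id per BGC id (ids ordered by each
#'   family's smallest member).
#' @export
#' @examples
#' d <- data.frame(bgc_i = "b1", bgc_j = "b2", dist = 0.4)
#' clusterGcfs(d, c("b1", "b2", "b3"))
clusterGcfs <- function(bgcDist, bgcIds, threshold = 0.5) {
  bgcIds <- sort(unique(bgcIds))
  n <- length(bgcIds)
  if (n == 0) return(stats::setNames(character(0), character(0)))
  if (nrow(bgcDist)) {
    if (any(bgcDist$dist < 0 | bgcDist$dist > 1))
      .stopf("BGC distances must lie in [0, 1]")
    unknown <- setdiff(c(bgcDist$bgc_i, bgcDist$bgc_j), bgcIds)
    if (length(unknown))
      .stopf("distance references unknown BGC(s): %s",
             paste(utils::head(unknown, 5), collapse = ", "))
  }
  m <- matrix(1, n, n, dimnames = list(bgcIds, bgcIds))
  diag(m) <- 0
  if (nrow(bgcDist)) {
    i <- match(bgcDist$bgc_i, bgcIds)
    j <- match(bgcDist$bgc_j, bgcIds)
    m[cbind(i, j)] <- bgcDist$dist
    m[cbind(j, i)] <- bgcDist$dist
  }
  if (n == 1) {
    membership <- 1L
  } else {
    tree <- stats::hclust(stats::as.dist(m), method = "average")
    # strict-< cut: average linkage is monotone, so the number of merges
    # below the threshold fixes the number of clusters
    k <- n - sum(tree$height < threshold)
    membership <- stats::cutree(tree, k = k)
  }
  minMember <- tapply(bgcIds, membership, min)
  ord <- rank(minMember)
  stats::setNames(sprintf("GCF%05d", ord[as.character(membership)]), bgcIds)
}

#' Assign a natural-product class to each GCF
#'
#' Member product labels are mapped through the class map (unknown labels ->
#' "others"); the majority class wins, ties go to "others".
#'
#' @param gcfs named character, GCF id per BGC id (see [clusterGcfs()]).
#' @param productClass named character, product label per BGC id.
#' @param classMap label -> class map; see [defaultClassMap()].
#' @return named character, class per GCF id.
#' @export
assignGcfClass <- function(gcfs, productClass, classMap = defaultClassMap()) {
  mapped <- classMap[productClass[names(gcfs)]]
  mapped[is.na(mapped)] <- "others"
  vapply(split(mapped, gcfs), function(cl) {
    tab <- sort(table(cl), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) "others" else names(tab)[1]
  }, character(1))
}

#' Flag GCF novelty against reference BGC collections
#'
#' A GCF matches a reference set if any member BGC lies at distance strictly
#' below `threshold` from that set; otherwise it is new. Missing distances
#' are treated as 1 (no match) with a message.
#'
#' @param gcfs named character, GCF id per BGC id.
#' @param refDist data.frame: bgc_id, ref_set, dist — the minimum distance of
#'   each BGC to each reference collection.
#' @param threshold match cut (strict <), the GCF clustering threshold by
#'   default.
#' @return data.frame: gcf_id, ref_set, matches_reference.
#' @export
gcfNovelty <- function(gcfs, refDist, threshold = 0.5) {
  refSets <- unique(refDist$ref_set)
  if (!length(refSets)) .stopf("no reference sets supplied")
  out <- list()
  for (rs in refSets) {
    sub <- refDist[refDist$ref_set == rs, ]
    d <- stats::setNames(sub$dist, sub$bgc_id)
    dd <- d[names(gcfs)]
    if (anyNA(dd))
      message(sum(is.na(dd)), " BGC(s) without a distance to '", rs,
              "'; treated as 1 (no match)")
    dd[is.na(dd)] <- 1
    matches <- tapply(dd, gcfs, function(v) any(v < threshold))
    out[[rs]] <- data.frame(gcf_id = names(matches), ref_set = rs,
                            matches_reference = as.logical(matches),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Biosynthetic richness per group
#'
#' For each level of the grouping variable: the number of distinct GCFs whose
#' member BGCs occur in the group's genomes, the number of species and
#' genomes, and the GCF-per-species (2 decimals) and GCF-per-genome
#' (1 decimal) ratios, half-up rounded at the display precision used in
#' reporting.
#'
#' @param gcfs named character, GCF id per BGC id.
#' @param bgcs BGC table (bgc_id, genome_id).
#' @param speciesAssignments named character, species per genome.
#' @param genomes data.frame with genome_id and the grouping column.
#' @param groupVar name of the grouping column (e.g. "host_type").
#' @return data.frame: group, n_gcfs, n_species, n_genomes, gcf_per_species,
#'   gcf_per_genome plus unrounded `ratio_species`, `ratio_genome`.
#' @export
richnessMetrics <- function(gcfs, bgcs, speciesAssignments, genomes,
                            groupVar) {
  if (!groupVar %in% colnames(genomes))
    .stopf("grouping column '%s' not in genome table", groupVar)
  grp <- genomes[[groupVar]]
  out <- do.call(rbind, lapply(split(seq_len(nrow(genomes)), grp), function(i) {
    gids <- genomes$genome_id[i]
    memberBgcs <- bgcs$bgc_id[bgcs$genome_id %in% gids]
    nGcf <- length(unique(gcfs[memberBgcs]))
    nSp <- length(unique(speciesAssignments[gids]))
    nGen <- length(gids)
    data.frame(group = grp[i[1]],
               n_gcfs = nGcf, n_species = nSp, n_genomes = nGen,
               ratio_species = if (nSp) nGcf / nSp else NA_real_,
               ratio_genome = if (nGen) nGcf / nGen else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out$gcf_per_species <- roundHalfUp(out$ratio_species, 2)
  out$gcf_per_genome <- roundHalfUp(out$ratio_genome, 1)
  rownames(out) <- NULL
  out
}

#' Depth-normalized GCF richness per sample
#'
#' Divides the number of GCFs detected in a sample by the sample's total
#' mOTU count (sequencing-depth proxy).
#'
#' @param nGcfs named numeric, GCFs detected per sample.
#' @param motuTotals named numeric, total mOTU count per sample (> 0).
#' @return named numeric, normalized richness per sample.
#' @export
depthNormalizedGcfs <- function(nGcfs, motuTotals) {
  totals <- motuTotals[names(nGcfs)]
  if (anyNA(totals)) .stopf("missing mOTU total for some sample(s)")
  if (any(totals <= 0)) .stopf("non-positive mOTU total")
  nGcfs / totals
}

#' Rarefaction curve of cumulative GCF richness
#'
#' For k = 1..n sampling units (host genera, islands, ...), the mean and
#' standard deviation over iterations of the number of distinct GCFs in k
#' units sampled without replacement. Each iteration's curve is monotone
#' non-decreasing and the final point (all units) is deterministic.
#'
#' @param unitSets named list, one character vector of GCF ids per unit.
#' @param nIterations random orderings to average over.
#' @param seed optional integer seed.
#' @return data.frame: k, mean, sd.
#' @export
rarefactionCurve <- function(unitSets, nIterations = 100, seed = NULL) {
  nU <- length(unitSets)
  if (nU < 1) .stopf("at least one sampling unit required")
  if (!is.null(seed)) set.seed(seed)
  curves <- matrix(0, nIterations, nU)
  for (it in seq_len(nIterations)) {
    ord <- sample.int(nU)
    seen <- character(0)
    for (k in seq_len(nU)) {
      seen <- union(seen, unitSets[[ord[k]]])
      curves[it, k] <- length(seen)
    }
  }
  data.frame(k = seq_len(nU),
             mean = colMeans(curves),
             sd = apply(curves, 2, sd))
}

# index = log(x)/log(max) * 100 with the degenerate-case conventions:
# x = 0 -> 0; x = max (including max <= 1) -> 100.
.logIndex <- function(x, maxX, base = exp(1)) {
  ifelse(x <= 0, 0,
  ifelse(x >= maxX | maxX <= 1, 100,
         log(x, base = base) / log(maxX, base = base) * 100))
}

#' Composite BGC-richness score and candidate super-producer calls
#'
#' Within each species, three indices in \[0, 100\] are computed per genome:
#' the complete-BGC count and the N50, each normalized as
#' `log(x) / max(log(x)) * 100` (the maximum taken within the species by
#' default, globally if `normalization = "global"`), and the quality score Q
#' clamped to \[0, 100\]. Their sum is the composite index in \[0, 300\];
#' the index is invariant to the logarithm base. A species is a candidate
#' BGC-rich (super-producer) species if its highest-composite genome encodes
#' at least `minBgcs` complete BGCs. Only complete (non-contig-edge) BGCs
#' count; ties on the composite break to the lexicographically smaller
#' genome id.
#'
#' @param bgcs BGC table (bgc_id, genome_id, on_contig_edge).
#' @param qc quality table (genome_id, Q, n50).
#' @param speciesAssignments named character, species per genome.
#' @param minBgcs candidate threshold on the scoring genome's complete BGCs.
#' @param normalization "species" (default) or "global" maximum for the log
#'   normalization.
#' @param logBase logarithm base (the index is base-invariant; exposed for
#'   the numerical check).
#' @return list with `scores` (per genome: species_id, n_complete_bgcs,
#'   idx_bgc, idx_q, idx_n50, composite) and `candidates` (per species:
#'   scoring_genome, n_complete_bgcs, candidate_rich).
#' @export
bgcRichScore <- function(bgcs, qc, speciesAssignments, minBgcs = 15,
                         normalization = c("species", "global"),
                         logBase = exp(1)) {
  normalization <- match.arg(normalization)
  gid <- qc$genome_id
  complete <- bgcs[!bgcs$on_contig_edge, , drop = FALSE]
  nComplete <- stats::setNames(numeric(length(gid)), gid)
  if (nrow(complete)) {
    t1 <- table(complete$genome_id)
    nComplete[names(t1)] <- as.numeric(t1)
  }
  missing <- setdiff(gid, names(speciesAssignments))
  if (length(missing)) .stopf("genome(s) without species assignment")
  sp <- speciesAssignments[gid]

  scores <- data.frame(genome_id = gid, species_id = unname(sp),
                       n_complete_bgcs = unname(nComplete[gid]),
                       Q = qc$Q, n50 = qc$n50, stringsAsFactors = FALSE)
  globalMaxB <- max(scores$n_complete_bgcs)
  globalMaxN <- max(scores$n50)
  idx <- do.call(rbind, lapply(split(seq_len(nrow(scores)), scores$species_id),
                               function(i) {
    maxB <- if (normalization == "species") max(scores$n_complete_bgcs[i]) else globalMaxB
    maxN <- if (normalization == "species") max(scores$n50[i]) else globalMaxN
    data.frame(row = i,
               idx_bgc = .logIndex(scores$n_complete_bgcs[i], maxB, logBase),
               idx_n50 = .logIndex(scores$n50[i], maxN, logBase))
  }))
  scores$idx_bgc <- scores$idx_n50 <- NA_real_
  scores$idx_bgc[idx$row] <- idx$idx_bgc
  scores$idx_n50[idx$row] <- idx$idx_n50
  scores$idx_q <- pmin(pmax(scores$Q, 0), 100)
  scores$composite <- scores$idx_bgc + scores$idx_q + scores$idx_n50

  candidates <- do.call(rbind, lapply(split(seq_len(nrow(scores)),
                                            scores$species_id), function(i) {
    i <- i[order(-scores$composite[i], scores$genome_id[i])]
    top <- i[1]
    data.frame(species_id = scores$species_id[top],
               scoring_genome = scores$genome_id[top],
               n_complete_bgcs = scores$n_complete_bgcs[top],
               candidate_rich = scores$n_complete_bgcs[top] >= minBgcs,
               stringsAsFactors = FALSE)
  }))
  rownames(candidates) <- NULL
  list(scores = scores[, c("genome_id", "species_id", "n_complete_bgcs",
                           "idx_bgc", "idx_q", "idx_n50", "composite")],
       candidates = candidates)
}
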