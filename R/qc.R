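#' Merge dual quality assessments and apply the retention rule
#'
#' A genome is retained if either assessor reports completeness (cpl) of at
#' least 50% together with contamination (ctn) of at most 10% — the retention
#' check runs on the per-assessor values, before averaging. Merged cpl and
#' ctn are the unweighted mean of the available assessors (a genome assessed
#' by one tool keeps that tool's values exactly), and the quality score is
#' computed on the merged values as
#' \deqn{Q = cpl - 5 \times ctn.}
#'
#' @param genomes data.frame with columns `genome_id`, `cpl_a`, `ctn_a` and
#'   optionally `cpl_b`, `ctn_b` (NA where an assessor is missing).
#' @param minCpl,maxCtn retention thresholds (percent).
#' @return the input with added columns `cpl`, `ctn`, `Q`, `retained`.
#' @export
#' @examples
#' mergeQuality(data.frame(genome_id = "g1", cpl_a = 60, ctn_a = 5,
#'                         cpl_b = 40, ctn_b = 5))
mergeQuality <- function(genomes, minCpl = 50, maxCtn = 10) {
  need <- c("genome_id", "cpl_a", "ctn_a")
  missing <- setdiff(need, colnames(genomes))
  if (length(missing))
    .stopf("genome table lacks column(s): %s", paste(missing, collapse = ", "))
  if (!"cpl_b" %in% colnames(genomes)) genomes$cpl_b <- NA_real_
  if (!"ctn_b" %in% colnames(genomes)) genomes$ctn_b <- NA_real_

  hasA <- !is.na(genomes$cpl_a) & !is.na(genomes$ctn_a)
  hasB <- !is.na(genomes$cpl_b) & !is.na(genomes$ctn_b)
  if (any(!hasA & !hasB))
    .stopf("genome(s) with both assessors missing: %s",
           paste(genomes$genome_id[!hasA & !hasB], collapse = ", "))

  passA <- hasA & genomes$cpl_a >= minCpl & genomes$ctn_a <= maxCtn
  passB <- hasB & genomes$cpl_b >= minCpl & genomes$ctn_b <= maxCtn
  genomes$retained <- passA | passB
  # an assessor contributes only if it reported both values
  cplA <- ifelse(hasA, genomes$cpl_a, NA_real_)
  ctnA <- ifelse(hasA, genomes$ctn_a, NA_real_)
  cplB <- ifelse(hasB, genomes$cpl_b, NA_real_)
  ctnB <- ifelse(hasB, genomes$ctn_b, NA_real_)
  genomes$cpl <- rowMeans(cbind(cplA, cplB), na.rm = TRUE)
  genomes$ctn <- rowMeans(cbind(ctnA, ctnB), na.rm = TRUE)
  genomes$Q <- genomes$cpl - 5 * genomes$ctn
  genomes
}

#' Assign MIMAG-style quality tiers
#'
#' Tiers in decreasing order, first match wins: high (cpl >= 90, ctn <= 5),
#' good (cpl >= 70, ctn <= 10), medium (cpl >= 50, ctn <= 10), else fair.
#' Ordered matching resolves the boundary at cpl = 50 (a genome at exactly
#' 50% with ctn <= 10 is medium, not fair) and covers genomes whose merged
#' values drop below the retention line even though one assessor admitted
#' them.
#'
#' @param cpl,ctn merged completeness and contamination (percent), vectors.
#' @return factor with levels high, good, medium, fair.
#' @export
#' @examples
#' classifyTier(c(95, 75, 49.5), c(4, 8, 2))
classifyTier <- function(cpl, ctn) {
  stopifnot(length(cpl) == length(ctn))
  tier <- ifelse(cpl >= 90 & ctn <= 5, "high",
          ifelse(cpl >= 70 & ctn <= 10, "good",
          ifelse(cpl >= 50 & ctn <= 10, "medium", "fair")))
  factor(tier, levels = c("high", "good", "medium", "fair"))
}

#' Completeness-corrected genome size per species
#'
#' Within each species, only members with completeness of at least
#' `minCompleteness` qualify; the species estimate is the mean over
#' qualifying members of `size_bp * 100 / cpl`. Species with no qualifying
#' member are flagged (NA estimate).
#'
#' @param qc merged quality table (needs `genome_id`, `cpl`, `size_bp`).
#' @param speciesAssignments named character, species id per genome id.
#' @param minCompleteness qualification threshold (percent).
#' @return data.frame: species_id, est_size_bp, n_used, no_estimate.
#' @export
#' @examples
#' qc <- data.frame(genome_id = c("g1", "g2"), cpl = c(100, 90),
#'                  size_bp = c(2e6, 1.8e6))
#' estimateSpeciesGenomeSize(qc, c(g1 = "sp1", g2 = "sp1"))
estimateSpeciesGenomeSize <- function(qc, speciesAssignments,
                                      minCompleteness = 70) {
  if (!all(qc$genome_id %in% names(speciesAssignments)))
    .stopf("genome(s) without species assignment")
  sp <- speciesAssignments[qc$genome_id]
  qualifies <- qc$cpl >= minCompleteness
  corrected <- qc$size_bp * 100 / qc$cpl
  out <- do.call(rbind, lapply(split(seq_len(nrow(qc)), sp), function(i) {
    use <- i[qualifies[i]]
    data.frame(species_id = sp[i[1]],
               est_size_bp = if (length(use)) mean(corrected[use]) else NA_real_,
               n_used = length(use),
               no_estimate = length(use) == 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$species_id), , drop = FALSE]
}
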