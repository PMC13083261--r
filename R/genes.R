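#' Filter read-to-gene alignments
#'
#' Keeps alignments with percent identity of at least 95, an alignment length
#' of at least 80% of the query length, and at least 45 aligned bases.
#'
#' @param alignments data.frame: insert_id, gene_id, identity, aln_length,
#'   query_length.
#' @param minIdentity,minQueryFraction,minLength the three thresholds.
#' @return the retained rows.
#' @export
filterAlignments <- function(alignments, minIdentity = 95,
                             minQueryFraction = 0.8, minLength = 45) {
  keep <- alignments$identity >= minIdentity &
    alignments$aln_length >= minQueryFraction * alignments$query_length &
    alignments$aln_length >= minLength
  alignments[keep, , drop = FALSE]
}

#' Unique-then-fractional insert counting
#'
#' For each insert, candidate genes are first reduced to those with maximal
#' identity ("best" alignments); an insert whose reduced set has one gene is
#' unique and contributes a count of 1 to it. Each ambiguous insert (several
#' best genes) then distributes a total of 1 across its candidates in
#' proportion to the candidates' unique counts; if all its candidates have
#' zero unique count the insert is split equally. The distribution is a
#' single pass (no iteration), so the column sum equals the number of
#' retained inserts exactly.
#'
#' @param alignments filtered alignments (see [filterAlignments()]).
#' @return data.frame: gene_id, unique_count, raw_count (fractional).
#' @export
#' @examples
#' aln <- data.frame(insert_id = c("i1", "i2", "i2"),
#'                   gene_id = c("A", "A", "B"),
#'                   identity = c(99, 98, 98),
#'                   aln_length = 100, query_length = 100)
#' countInserts(aln)
countInserts <- function(alignments) {
  genes <- sort(unique(alignments$gene_id))
  if (!nrow(alignments))
    return(data.frame(gene_id = character(), unique_count = numeric(),
                      raw_count = numeric()))
  # best-identity reduction per insert
  byInsert <- split(seq_len(nrow(alignments)), alignments$insert_id)
  best <- lapply(byInsert, function(i) {
    top <- i[alignments$identity[i] == max(alignments$identity[i])]
    unique(alignments$gene_id[top])
  })
  uniqueCounts <- stats::setNames(numeric(length(genes)), genes)
  isUnique <- lengths(best) == 1L
  if (any(isUnique)) {
    t1 <- table(unlist(best[isUnique], use.names = FALSE))
    uniqueCounts[names(t1)] <- as.numeric(t1)
  }
  raw <- uniqueCounts
  for (targets in best[!isUnique]) {
    w <- uniqueCounts[targets]
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(targets), length(targets))
    raw[targets] <- raw[targets] + w
  }
  data.frame(gene_id = genes,
             unique_count = unname(uniqueCounts),
             raw_count = unname(raw),
             stringsAsFactors = FALSE)
}

#' Length- and depth-normalize gene abundances
#'
#' Per-base abundance is the raw fractional count divided by the gene length;
#' the depth-normalized abundance additionally divides by the sample's total
#' mOTU count, a proxy for the number of microbial cells sequenced.
#'
#' @param counts output of [countInserts()] (gene_id, raw_count).
#' @param geneLengths data.frame gene_id, length_bp (all > 0).
#' @param motuTotal total mOTU count of the sample (> 0).
#' @return counts with added `per_bp` and `normalized` columns.
#' @export
#' @examples
#' normalizeAbundance(data.frame(gene_id = "g", raw_count = 10),
#'                    data.frame(gene_id = "g", length_bp = 1000), 5)
normalizeAbundance <- function(counts, geneLengths, motuTotal) {
  if (motuTotal <= 0) .stopf("sample has a non-positive total mOTU count")
  len <- stats::setNames(geneLengths$length_bp, geneLengths$gene_id)
  missing <- setdiff(counts$gene_id, names(len))
  if (length(missing))
    .stopf("no length for gene(s): %s", paste(utils::head(missing, 5), collapse = ", "))
  if (any(len[counts$gene_id] <= 0)) .stopf("gene lengths must be positive")
  counts$per_bp <- counts$raw_count / len[counts$gene_id]
  counts$normalized <- counts$per_bp / motuTotal
  counts
}

#' Per-genome fraction of eukaryotic-like proteins
#'
#' A protein counts as an ELP if it carries at least one family from the
#' ELP-associated set (a protein with several ELP families counts once). The
#' fraction is ELP proteins over all predicted proteins of the genome.
#'
#' @param annotations data.frame: genome_id, protein_id, family (one row per
#'   protein-family annotation; `family = NA` rows declare unannotated
#'   proteins so every predicted protein appears at least once).
#' @param elpFamilies character vector of ELP-associated family ids.
#' @return named numeric, fraction per genome.
#' @export
elpFraction <- function(annotations, elpFamilies) {
  perGenome <- split(annotations, annotations$genome_id)
  out <- vapply(perGenome, function(a) {
    total <- length(unique(a$protein_id))
    if (total == 0) .stopf("genome with zero predicted proteins")
    hit <- unique(a$protein_id[!is.na(a$family) & a$family %in% elpFamilies])
    length(hit) / total
  }, numeric(1))
  out
}
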