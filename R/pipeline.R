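.SCHEMAS <- list(
  genomes = c("genome_id", "cpl_a", "ctn_a", "n50", "size_bp",
              "strain_heterogeneity"),
  ani = c("genome_i", "genome_j", "ani", "coverage"),
  bgcs = c("bgc_id", "genome_id", "contig_length", "product_class",
           "on_contig_edge"),
  bgc_dist = c("bgc_i", "bgc_j", "dist"),
  profiles = c("species_id", "sample_id", "abundance"),
  samples = c("sample_id", "biome", "host_genus", "island", "water_category"),
  alignments = c("insert_id", "gene_id", "identity", "aln_length",
                 "query_length"),
  gene_lengths = c("gene_id", "length_bp")
)

#' Validate a table against a named schema
#'
#' Checks that the required columns are present and that required numeric
#' columns carry no NA; violations are reported with the column name and the
#' first offending row number.
#'
#' @param x data.frame.
#' @param schema one of `names(reefMAGs:::.SCHEMAS)`.
#' @return `x`, invisibly, if valid.
#' @export
validateTable <- function(x, schema) {
  cols <- .SCHEMAS[[schema]]
  if (is.null(cols)) .stopf("unknown schema '%s'", schema)
  missing <- setdiff(cols, colnames(x))
  if (length(missing))
    .stopf("table '%s': missing required column(s): %s", schema,
           paste(missing, collapse = ", "))
  for (cc in cols) {
    bad <- which(is.na(x[[cc]]))
    if (schema == "samples" && cc %in% c("host_genus", "water_category"))
      next  # NA is meaningful (water samples have no genus and vice versa)
    if (length(bad))
      .stopf("table '%s': column '%s' has NA at row %d", schema, cc, bad[1])
  }
  invisible(x)
}

#' Read a pipeline TSV with schema validation
#'
#' @param path TSV file with a header row.
#' @param schema schema name, see [validateTable()].
#' @return data.frame.
#' @export
readPipelineTable <- function(path, schema) {
  if (!file.exists(path)) .stopf("input file not found: %s", path)
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validateTable(x, schema)
  x
}

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.logStage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Orchestrates simulate -> qc -> cluster -> community -> genes -> bgc ->
#' report in dependency order, writing every stage's TSV outputs plus a JSON
#' run manifest with per-file checksums. Deterministic: identical config and
#' seed reproduce identical checksums for every stage output.
#'
#' @param config a [SimConfig-class] (its seed drives every stage).
#' @param outDir output directory.
#' @param minSamples,minTotal community profile filters.
#' @param nPermutations,subsampleSize,repetitions PERMANOVA settings.
#' @param gcfThreshold,minBgcs BGC stage thresholds.
#' @param rarefactionIterations iterations for the host-genus rarefaction.
#' @return the manifest, invisibly (list: seed, version, configDigest,
#'   files with md5 checksums, timestamp, summary).
#' @export
runPipeline <- function(config, outDir,
                        minSamples = 10, minTotal = 3,
                        nPermutations = 199, subsampleSize = 50,
                        repetitions = 20, gcfThreshold = 0.5, minBgcs = 15,
                        rarefactionIterations = 100) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  .logStage("simulate", "generating synthetic dataset (seed ", config@seed, ")")
  sim <- simulateReefData(config)
  writeSimulation(sim, file.path(outDir, "sim"))

  .logStage("qc", "merging quality assessments")
  qc <- mergeQuality(sim@genomes)
  qc$tier <- as.character(classifyTier(qc$cpl, qc$ctn))
  .writeTsv(qc, file.path(outDir, "genome_qc.tsv"))
  retained <- qc[qc$retained, ]

  .logStage("cluster", "species clustering at ", 95, "% ANI")
  validateTable(sim@ani, "ani")
  aniRetained <- sim@ani[sim@ani$genome_i %in% retained$genome_id &
                           sim@ani$genome_j %in% retained$genome_id, ]
  clusters <- clusterSpecies(aniRetained, retained$genome_id)
  clusters <- selectRepresentatives(clusters, retained)
  assign <- speciesAssignments(clusters)
  speciesTab <- data.frame(
    genome_id = names(assign), species_id = unname(assign),
    representative = unname(representatives(clusters)[assign]),
    stringsAsFactors = FALSE)
  .writeTsv(speciesTab, file.path(outDir, "species.tsv"))
  conc <- partitionConcordance(assign, sim@truth$species[names(assign)])
  .writeTsv(data.frame(homogeneity = conc$homogeneity,
                       completeness = conc$completeness,
                       v_measure = conc$vMeasure),
            file.path(outDir, "concordance.tsv"))
  sizes <- estimateSpeciesGenomeSize(retained, assign)
  .writeTsv(sizes, file.path(outDir, "species_sizes.tsv"))

  .logStage("community", "profile filtering, ordination and PERMANOVA")
  prof <- filterProfiles(sim@profiles, minSamples = minSamples,
                         minTotal = minTotal)
  d <- jaccardDistance(prof)
  .writeTsv(as.data.frame(as.matrix(d)), file.path(outDir, "distances.tsv"))
  ord <- pcoaOrdination(d)
  .writeTsv(as.data.frame(ord$coordinates), file.path(outDir, "pcoa.tsv"))
  info <- sampleInfo(prof)
  grouping <- ifelse(info$biome == "seawater", "seawater", info$biome)
  perm <- if (length(unique(grouping)) >= 2 && all(table(grouping) >= 2)) {
    bp <- balancedPermanova(d, grouping, subsampleSize = subsampleSize,
                            repetitions = repetitions,
                            nPermutations = nPermutations,
                            seed = config@seed)
    data.frame(comparison = "biome", median_p = bp$medianP,
               mean_r2 = bp$meanR2)
  } else data.frame(comparison = character(), median_p = numeric(),
                    mean_r2 = numeric())
  .writeTsv(perm, file.path(outDir, "permanova.tsv"))
  coralSp <- rownames(sim@profiles)[
    rowSums(profileMatrix(sim@profiles)[,
      sampleInfo(sim@profiles)$biome == "coral", drop = FALSE] > 0) > 0]
  decay <- if (length(coralSp) &&
               any(!is.na(sampleInfo(sim@profiles)$water_category)))
    detectionDecay(coralSp, sim@profiles)
  else data.frame()
  .writeTsv(decay, file.path(outDir, "decay.tsv"))

  .logStage("genes", "alignment filtering and insert counting")
  validateTable(sim@alignments, "alignments")
  kept <- filterAlignments(sim@alignments)
  counts <- countInserts(kept)
  motuTotal <- sum(profileMatrix(sim@profiles))
  geneAb <- normalizeAbundance(counts, sim@geneLengths, motuTotal)
  .writeTsv(geneAb, file.path(outDir, "gene_abundance.tsv"))

  .logStage("bgc", "GCF clustering and richness scoring")
  bgcs <- ingestBgcs(sim@bgcs)
  gcfs <- clusterGcfs(sim@bgcDist, bgcs$bgc_id, threshold = gcfThreshold)
  classes <- assignGcfClass(gcfs, stats::setNames(bgcs$product_class,
                                                  bgcs$bgc_id))
  gcfTab <- data.frame(bgc_id = names(gcfs), gcf_id = unname(gcfs),
                       gcf_class = unname(classes[gcfs]),
                       stringsAsFactors = FALSE)
  .writeTsv(gcfTab, file.path(outDir, "gcfs.tsv"))
  rich <- richnessMetrics(gcfs, bgcs, assign,
                          sim@genomes[sim@genomes$genome_id %in% names(assign), ],
                          "host_type")
  .writeTsv(rich, file.path(outDir, "richness.tsv"))
  unitSets <- lapply(split(bgcs$bgc_id, sim@genomes$host_genus[
    match(bgcs$genome_id, sim@genomes$genome_id)]),
    function(ids) unique(gcfs[ids]))
  rar <- rarefactionCurve(unitSets, nIterations = rarefactionIterations,
                          seed = config@seed)
  .writeTsv(rar, file.path(outDir, "rarefaction.tsv"))
  score <- bgcRichScore(bgcs[bgcs$genome_id %in% names(assign), ],
                        qc[qc$genome_id %in% names(assign), ],
                        assign, minBgcs = minBgcs)
  .writeTsv(score$candidates, file.path(outDir, "rich_candidates.tsv"))

  .logStage("report", "writing run manifest")
  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest.json$", files)]
  sums <- tools::md5sum(files)
  cfgJson <- file.path(outDir, "sim", "config.json")
  manifest <- list(
    seed = config@seed,
    version = as.character(packageVersion("reefMAGs")),
    configDigest = unname(tools::md5sum(cfgJson)),
    files = as.list(stats::setNames(unname(sums),
                                    substring(files, nchar(outDir) + 2L))),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    summary = list(
      n_genomes = nrow(sim@genomes),
      n_retained = sum(qc$retained),
      n_species = nSpecies(clusters),
      v_measure_vs_truth = conc$vMeasure,
      n_gcfs = length(unique(gcfs)),
      n_rich_candidates = sum(score$candidates$candidate_rich)
    )
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Headline ratio report from supplied totals
#'
#' Computes ratio and percentage rows from named totals with the reporting
#' rounding conventions (half-up; ratios to the given digits, percentages to
#' whole percent by default). Zero denominators are flagged rather than
#' propagated.
#'
#' @param totals data.frame with columns `label`, `numerator`, `denominator`,
#'   `unit` ("ratio" or "percent") and optionally `digits` (default: 2 for
#'   ratios, 0 for percents).
#' @return totals with added `value` (rounded) and `undefined` flag.
#' @export
#' @examples
#' headlineReport(data.frame(label = "GCFs per species",
#'                           numerator = 6612, denominator = 4224,
#'                           unit = "ratio", digits = 2))
headlineReport <- function(totals) {
  need <- c("label", "numerator", "denominator", "unit")
  missing <- setdiff(need, colnames(totals))
  if (length(missing))
    .stopf("totals table lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(totals$numerator < 0 | totals$denominator < 0))
    .stopf("totals must be nonnegative")
  if (!"digits" %in% colnames(totals))
    totals$digits <- ifelse(totals$unit == "percent", 0, 2)
  totals$undefined <- totals$denominator == 0
  raw <- ifelse(totals$undefined, NA_real_,
                totals$numerator / totals$denominator)
  raw <- ifelse(totals$unit == "percent", raw * 100, raw)
  totals$value <- roundHalfUp(raw, totals$digits)
  totals
}

#' Bundled headline totals
#'
#' Reads the packaged table of published dataset totals (GCF counts, species
#' counts, genome counts per environment and host type) used by the worked
#' examples and the acceptance script.
#'
#' @return data.frame suitable for [headlineReport()].
#' @export
headlineTotals <- function() {
  read.delim(system.file("extdata", "headline_totals.tsv",
                         package = "reefMAGs"),
             sep = "\t", stringsAsFactors = FALSE)
}
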