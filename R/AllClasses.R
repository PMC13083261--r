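#' @import methods
#' @importFrom stats rlnorm rnorm rpois runif sd var median
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Configuration of the synthetic reef-microbiome generator
#'
#' A `SimConfig` fixes every parameter of the synthetic data: the planted
#' species structure in ANI space, the host-specific community composition
#' with seawater distance decay, the planted gene cluster family (GCF)
#' structure including BGC-rich species, and the read-to-gene alignment
#' table. Identical configurations (same seed) reproduce byte-identical
#' tables. Construct with [simConfig()].
#'
#' @slot seed integer; global seed feeding per-table substreams.
#' @slot nSpecies number of planted species.
#' @slot genomesPerSpecies length-2 integer range, genomes drawn per species.
#' @slot withinSpeciesAni percent interval for within-species ANI.
#' @slot betweenSpeciesAni percent interval for between-species ANI; must lie
#'   strictly below `withinSpeciesAni` so planted clusters are recoverable.
#' @slot aniCoverage alignment-coverage interval (fraction).
#' @slot completenessRange latent completeness interval (percent).
#' @slot contaminationScale mean of the exponential contamination draw
#'   (percent).
#' @slot qualityJitter half-width of the uniform jitter applied to each
#'   assessor's completeness/contamination around the latent truth
#'   (percentage points; 0 gives exact assessments).
#' @slot nSamplesPerGroup metagenome samples per host genus.
#' @slot nWaterSamplesPerGroup samples per water category (C/R/O); defaults
#'   to `nSamplesPerGroup`, may be 0 for a host-only design.
#' @slot nIslands islands samples are cycled over.
#' @slot hostGenera named character vector mapping host genus to host type
#'   (stony/fire/soft/sponge).
#' @slot waterRetention named numeric (C, R, O): per-sample probability that
#'   a water sample of that category retains a host-associated species.
#' @slot hostSpecificity fraction of species confined to their home genus.
#' @slot bgcRate mean complete BGCs per genome (Poisson).
#' @slot richSpeciesFraction fraction of species planted as BGC-rich;
#'   exactly `floor(fraction * nSpecies)` species (the first ids) are planted.
#' @slot contigEdgeProb probability a generated BGC is flagged contig-edge.
#' @slot gcfWithinDist interval of pairwise distances within a true GCF.
#' @slot gcfBetweenDist interval between different GCFs; must lie above
#'   `gcfWithinDist`.
#' @slot nGenes,nInserts size of the alignment simulation.
#' @slot ambiguousFraction fraction of inserts aligning to >= 2 genes;
#'   exactly `floor(fraction * nInserts)` inserts (the first ids) are made
#'   ambiguous.
#' @seealso [simConfig()], [simulateReefData()]
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nSpecies = "integer",
  genomesPerSpecies = "integer",
  withinSpeciesAni = "numeric",
  betweenSpeciesAni = "numeric",
  aniCoverage = "numeric",
  completenessRange = "numeric",
  contaminationScale = "numeric",
  qualityJitter = "numeric",
  nSamplesPerGroup = "integer",
  nWaterSamplesPerGroup = "integer",
  nIslands = "integer",
  hostGenera = "character",
  waterRetention = "numeric",
  hostSpecificity = "numeric",
  bgcRate = "numeric",
  richSpeciesFraction = "numeric",
  contigEdgeProb = "numeric",
  gcfWithinDist = "numeric",
  gcfBetweenDist = "numeric",
  nGenes = "integer",
  nInserts = "integer",
  ambiguousFraction = "numeric"
))

.validInterval <- function(x, what, lo = -Inf, hi = Inf) {
  if (length(x) != 2 || any(!is.finite(x))) return(sprintf("%s must be a finite length-2 interval", what))
  if (x[1] > x[2]) return(sprintf("%s must be ordered low <= high", what))
  if (x[1] < lo || x[2] > hi) return(sprintf("%s must lie within [%s, %s]", what, lo, hi))
  NULL
}

setValidity("SimConfig", function(object) {
  msg <- c(
    .validInterval(object@withinSpeciesAni, "withinSpeciesAni", 0, 100),
    .validInterval(object@betweenSpeciesAni, "betweenSpeciesAni", 0, 100),
    .validInterval(object@aniCoverage, "aniCoverage", 0, 1),
    .validInterval(object@completenessRange, "completenessRange", 0, 100),
    .validInterval(object@gcfWithinDist, "gcfWithinDist", 0, 1),
    .validInterval(object@gcfBetweenDist, "gcfBetweenDist", 0, 1)
  )
  if (object@nSpecies < 1L) msg <- c(msg, "nSpecies must be positive")
  if (length(object@genomesPerSpecies) != 2L || any(object@genomesPerSpecies < 1L) ||
      object@genomesPerSpecies[1] > object@genomesPerSpecies[2])
    msg <- c(msg, "genomesPerSpecies must be an ordered positive integer range")
  if (object@withinSpeciesAni[1] <= object@betweenSpeciesAni[2])
    msg <- c(msg, "withinSpeciesAni must lie strictly above betweenSpeciesAni")
  if (object@gcfBetweenDist[1] <= object@gcfWithinDist[2])
    msg <- c(msg, "gcfBetweenDist must lie strictly above gcfWithinDist")
  for (f in c("hostSpecificity", "richSpeciesFraction", "contigEdgeProb",
              "ambiguousFraction")) {
    v <- slot(object, f)
    if (length(v) != 1 || !is.finite(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a fraction in [0, 1]", f))
  }
  if (any(object@waterRetention < 0) || any(object@waterRetention > 1) ||
      !all(c("C", "R", "O") %in% names(object@waterRetention)))
    msg <- c(msg, "waterRetention must be named fractions for categories C, R, O")
  if (length(object@hostGenera) < 1 || is.null(names(object@hostGenera)) ||
      !all(object@hostGenera %in% c("stony", "fire", "soft", "sponge")))
    msg <- c(msg, "hostGenera must be a named genus -> type map (stony/fire/soft/sponge)")
  if (object@nSamplesPerGroup < 0L) msg <- c(msg, "nSamplesPerGroup must be non-negative")
  if (object@nWaterSamplesPerGroup < 0L)
    msg <- c(msg, "nWaterSamplesPerGroup must be non-negative")
  if (object@nGenes < 1L || object@nInserts < 1L)
    msg <- c(msg, "nGenes and nInserts must be positive")
  if (object@contaminationScale < 0) msg <- c(msg, "contaminationScale must be non-negative")
  if (object@qualityJitter < 0) msg <- c(msg, "qualityJitter must be non-negative")
  if (object@bgcRate < 0) msg <- c(msg, "bgcRate must be non-negative")
  if (object@richSpeciesFraction > 0 && object@bgcRate <= 0)
    msg <- c(msg, "richSpeciesFraction > 0 requires a positive bgcRate to plant rich species")
  if (object@ambiguousFraction > 0 && object@nGenes < 2L)
    msg <- c(msg, "ambiguous inserts require at least 2 genes")
  if (length(msg)) msg else TRUE
})

#' Sample-by-species community profiles with sample metadata
#'
#' `ReefProfiles` is a thin [SummarizedExperiment::SummarizedExperiment]
#' whose single assay `"abundance"` holds nonnegative scaled counts (species
#' as rows, samples as columns) and whose `colData` carries the required
#' sample metadata: `biome` (coral/sponge/seawater), `host_genus`, `island`
#' and `water_category` (C/R/O, `NA` for host samples).
#'
#' @seealso [reefProfiles()], [filterProfiles()], [jaccardDistance()]
#' @export
setClass("ReefProfiles", contains = "SummarizedExperiment")

setValidity("ReefProfiles", function(object) {
  msg <- NULL
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else if (any(SummarizedExperiment::assay(object, "abundance") < 0))
    msg <- c(msg, "abundances must be nonnegative")
  need <- c("biome", "host_genus", "island", "water_category")
  missing <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(missing))
    msg <- c(msg, paste0("missing sample metadata column(s): ",
                         paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Species-level clustering of a genome collection
#'
#' Result of [clusterSpecies()]: a partition of the retained genomes into
#' species at an average-nucleotide-identity threshold, optionally carrying
#' per-species representative genomes selected by Q' (see
#' [selectRepresentatives()]).
#'
#' @slot assignments named character; species id per genome id.
#' @slot representatives named character; representative genome per species
#'   (empty until [selectRepresentatives()] is applied).
#' @slot aniThreshold,minCoverage the thresholds used.
#' @export
setClass("SpeciesClusters", representation(
  assignments = "character",
  representatives = "character",
  aniThreshold = "numeric",
  minCoverage = "numeric"
))

setValidity("SpeciesClusters", function(object) {
  msg <- NULL
  if (is.null(names(object@assignments)) && length(object@assignments))
    msg <- c(msg, "assignments must be named by genome id")
  if (length(object@representatives)) {
    bad <- !mapply(function(sp, rep) {
      rep %in% names(object@assignments)[object@assignments == sp]
    }, names(object@representatives), object@representatives)
    if (any(bad)) msg <- c(msg, "each representative must be a member of its species")
  }
  if (length(msg)) msg else TRUE
})

#' PERMANOVA test result
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (Anderson's pseudo-F formulation). See [permanovaTest()].
#'
#' @slot pseudoF observed pseudo-F statistic.
#' @slot R2 fraction of the total sum of squared distances explained by the
#'   grouping; at most 1, and marginally negative values can arise for
#'   non-Euclidean distance matrices (e.g. Jaccard) under the null because
#'   the within-group sum of squared distances may exceed the total.
#' @slot p permutation p-value, `>= 1/(nPermutations + 1)`.
#' @slot nPermutations number of label permutations.
#' @export
setClass("PermanovaResult", representation(
  pseudoF = "numeric", R2 = "numeric", p = "numeric", nPermutations = "integer"
))

setValidity("PermanovaResult", function(object) {
  msg <- NULL
  if (object@R2 > 1) msg <- c(msg, "R2 cannot exceed 1")
  if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must be in (0, 1]")
  if (object@p < 1 / (object@nPermutations + 1) - 1e-12)
    msg <- c(msg, "p cannot be below 1/(nPermutations + 1)")
  if (length(msg)) msg else TRUE
})

#' Bundle of synthetic reef-microbiome tables
#'
#' Everything [simulateReefData()] generates: the genome table with dual
#' quality assessments, the pairwise ANI table, the BGC table with pairwise
#' BGC distances, the community profiles, the read-to-gene alignment table
#' with gene lengths, and the truth tables for the planted structure.
#'
#' @slot config the [SimConfig-class] used.
#' @slot genomes,ani,bgcs,bgcDist,alignments,geneLengths data.frames (see
#'   [simulateReefData()] for column contracts).
#' @slot profiles a [ReefProfiles-class].
#' @slot truth list: `species` (true species per genome), `genomeSize`
#'   (true size per genome), `homeGenus` (per species), `gcf` (true family
#'   per BGC), `richSpecies` (planted BGC-rich species ids), `geneAbundance`
#'   (true insert count per gene).
#' @export
setClass("ReefSim", representation(
  config = "SimConfig",
  genomes = "data.frame",
  ani = "data.frame",
  bgcs = "data.frame",
  bgcDist = "data.frame",
  profiles = "ReefProfiles",
  alignments = "data.frame",
  geneLengths = "data.frame",
  truth = "list"
))

#' @describeIn SimConfig compact parameter display
#' @param object a `SimConfig`
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSpecies, "species, genomes/species in [",
      object@genomesPerSpecies[1], ",", object@genomesPerSpecies[2],
      "], seed", object@seed, "\n")
  cat("  ANI within [", object@withinSpeciesAni[1], ",",
      object@withinSpeciesAni[2], "] vs between [",
      object@betweenSpeciesAni[1], ",", object@betweenSpeciesAni[2], "]\n")
  cat("  hosts:", paste(names(object@hostGenera), collapse = ", "),
      "| samples/group:", object@nSamplesPerGroup, "\n")
  invisible(object)
})

#' @describeIn SpeciesClusters summary display
#' @param object a `SpeciesClusters`
#' @export
setMethod("show", "SpeciesClusters", function(object) {
  cat("SpeciesClusters:", length(unique(object@assignments)), "species over",
      length(object@assignments), "genomes (ANI >=", object@aniThreshold,
      "%, coverage >=", object@minCoverage, ")\n")
  if (length(object@representatives))
    cat("  representatives selected for", length(object@representatives),
        "species\n")
  invisible(object)
})

#' @describeIn PermanovaResult summary display
#' @param object a `PermanovaResult`
#' @export
setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              object@pseudoF, object@R2, object@p, object@nPermutations))
  invisible(object)
})

#' @describeIn ReefSim summary display
#' @param object a `ReefSim`
#' @export
setMethod("show", "ReefSim", function(object) {
  cat("ReefSim:", nrow(object@genomes), "genomes /",
      length(unique(object@truth$species)), "species,",
      nrow(object@bgcs), "BGCs,", ncol(object@profiles), "samples,",
      nrow(object@alignments), "alignments\n")
  invisible(object)
})

#' Accessors for species clusterings
#'
#' @param x a [SpeciesClusters-class]
#' @return `speciesAssignments()` returns the named character vector of
#'   species ids per genome; `clusterMembers()` a list of member genome ids
#'   per species; `representatives()` the named representative vector.
#' @export
speciesAssignments <- function(x) x@assignments

#' @rdname speciesAssignments
#' @export
clusterMembers <- function(x) split(names(x@assignments), x@assignments)

#' @rdname speciesAssignments
#' @export
representatives <- function(x) x@representatives

#' @rdname speciesAssignments
#' @export
nSpecies <- function(x) length(unique(x@assignments))
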