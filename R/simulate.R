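#' Construct a synthetic-data configuration
#'
#' Defaults plant a recoverable species structure (within-species ANI
#' strictly above between-species ANI), a host-specific community with
#' seawater distance decay (retention factors C 0.2 > R 0.1 > O 0.02), and a
#' two-block GCF distance structure separated around the 0.5 clustering
#' threshold. See [SimConfig-class] for the meaning of every field.
#'
#' @param seed integer seed; one global seed feeds per-table substreams so
#'   adding a table does not perturb the others.
#' @param nSpecies,genomesPerSpecies planted species count and per-species
#'   genome range.
#' @param withinSpeciesAni,betweenSpeciesAni,aniCoverage ANI intervals
#'   (percent) and alignment-coverage interval (fraction).
#' @param completenessRange,contaminationScale,qualityJitter latent quality
#'   parameters (percent); assessors report truth +/- uniform jitter.
#' @param nSamplesPerGroup,nWaterSamplesPerGroup,nIslands,hostGenera,waterRetention,hostSpecificity
#'   community design.
#' @param bgcRate,richSpeciesFraction,contigEdgeProb,gcfWithinDist,gcfBetweenDist
#'   biosynthetic design.
#' @param nGenes,nInserts,ambiguousFraction alignment-table design.
#' @return a validated [SimConfig-class].
#' @export
#' @examples
#' cfg <- simConfig(seed = 1, nSpecies = 5, genomesPerSpecies = c(2, 2))
#' cfg
simConfig <- function(seed,
                      nSpecies = 20L,
                      genomesPerSpecies = c(1L, 6L),
                      withinSpeciesAni = c(95.5, 100),
                      betweenSpeciesAni = c(80, 92),
                      aniCoverage = c(0.3, 1.0),
                      completenessRange = c(50, 100),
                      contaminationScale = 2,
                      qualityJitter = 3,
                      nSamplesPerGroup = 10L,
                      nWaterSamplesPerGroup = nSamplesPerGroup,
                      nIslands = 4L,
                      hostGenera = c(Pocillopora = "stony", Porites = "stony",
                                     Millepora = "fire", Aplysina = "sponge"),
                      waterRetention = c(C = 0.2, R = 0.1, O = 0.02),
                      hostSpecificity = 0.95,
                      bgcRate = 2,
                      richSpeciesFraction = 0.1,
                      contigEdgeProb = 0.3,
                      gcfWithinDist = c(0, 0.3),
                      gcfBetweenDist = c(0.6, 1.0),
                      nGenes = 50L,
                      nInserts = 500L,
                      ambiguousFraction = 0.1) {
  if (missing(seed) || length(seed) != 1 || !is.finite(seed))
    .stopf("a single integer seed is required")
  new("SimConfig",
      seed = as.integer(seed),
      nSpecies = as.integer(nSpecies),
      genomesPerSpecies = as.integer(genomesPerSpecies),
      withinSpeciesAni = as.numeric(withinSpeciesAni),
      betweenSpeciesAni = as.numeric(betweenSpeciesAni),
      aniCoverage = as.numeric(aniCoverage),
      completenessRange = as.numeric(completenessRange),
      contaminationScale = as.numeric(contaminationScale),
      qualityJitter = as.numeric(qualityJitter),
      nSamplesPerGroup = as.integer(nSamplesPerGroup),
      nWaterSamplesPerGroup = as.integer(nWaterSamplesPerGroup),
      nIslands = as.integer(nIslands),
      hostGenera = hostGenera,
      waterRetention = waterRetention,
      hostSpecificity = as.numeric(hostSpecificity),
      bgcRate = as.numeric(bgcRate),
      richSpeciesFraction = as.numeric(richSpeciesFraction),
      contigEdgeProb = as.numeric(contigEdgeProb),
      gcfWithinDist = as.numeric(gcfWithinDist),
      gcfBetweenDist = as.numeric(gcfBetweenDist),
      nGenes = as.integer(nGenes),
      nInserts = as.integer(nInserts),
      ambiguousFraction = as.numeric(ambiguousFraction))
}

.speciesIds <- function(n) sprintf("SP%04d", seq_len(n))

# Per-sample detection probability of a species in samples of its home genus.
.P_DETECT_HOME <- 0.9
# Per-sample detection probability in a secondary genus for species not
# confined to their home genus.
.P_DETECT_AWAY <- 0.3

.sampleFrame <- function(config) {
  genera <- names(config@hostGenera)
  n <- config@nSamplesPerGroup
  host <- data.frame(
    sample_id = unlist(lapply(genera, function(g) sprintf("%s_h%02d", g, seq_len(n))),
                       use.names = FALSE),
    biome = rep(ifelse(config@hostGenera == "sponge", "sponge", "coral"),
                each = n),
    host_genus = rep(genera, each = n),
    water_category = NA_character_,
    stringsAsFactors = FALSE
  )
  nw <- config@nWaterSamplesPerGroup
  water <- data.frame(
    sample_id = unlist(lapply(c("C", "R", "O"),
                              function(w) sprintf("water_%s%02d", w, seq_len(nw))),
                       use.names = FALSE),
    biome = rep("seawater", 3L * nw),
    host_genus = rep(NA_character_, 3L * nw),
    water_category = rep(c("C", "R", "O"), each = nw),
    stringsAsFactors = FALSE
  )
  all <- rbind(host, water)
  all$island <- sprintf("ISL%02d", (seq_len(nrow(all)) - 1L) %% config@nIslands + 1L)
  all
}

#' Generate the synthetic genome table
#'
#' Each genome carries two quality assessments (assessor A and B values drawn
#' as a shared latent truth plus independent uniform jitter, clipped to
#' \[0, 100\] for completeness and to nonnegative for contamination), an N50,
#' a strain heterogeneity, an observed assembly size equal to
#' `true size * completeness / 100`, and a host/sample assignment in its
#' species' home genus.
#'
#' @param config a [SimConfig-class].
#' @return list with `genomes` (data.frame: genome_id, cpl_a, ctn_a, cpl_b,
#'   ctn_b, n50, size_bp, strain_heterogeneity, host_genus, host_type,
#'   sample_id) and `truth` (list: species, genomeSize, completeness,
#'   contamination, homeGenus).
#' @export
simulateGenomes <- function(config) {
  validObject(config)
  .withSubstream(config@seed, "genomes", {
    sp <- .speciesIds(config@nSpecies)
    genera <- names(config@hostGenera)
    homeGenus <- stats::setNames(
      genera[(seq_along(sp) - 1L) %% length(genera) + 1L], sp)
    nPer <- if (config@genomesPerSpecies[1] == config@genomesPerSpecies[2])
      rep(config@genomesPerSpecies[1], config@nSpecies)
    else
      sample(seq(config@genomesPerSpecies[1], config@genomesPerSpecies[2]),
             config@nSpecies, replace = TRUE)
    trueSpecies <- rep(sp, times = nPer)
    nG <- length(trueSpecies)
    gid <- sprintf("G%05d", seq_len(nG))
    names(trueSpecies) <- gid

    # one latent size per species, shared by its genomes
    spSize <- stats::setNames(round(runif(config@nSpecies, 2e6, 8e6)), sp)
    trueSize <- spSize[trueSpecies]
    names(trueSize) <- gid

    cplTrue <- runif(nG, config@completenessRange[1], config@completenessRange[2])
    ctnTrue <- pmin(stats::rexp(nG, rate = 1 / max(config@contaminationScale, 1e-9)), 10)
    if (config@contaminationScale == 0) ctnTrue <- rep(0, nG)
    n50 <- round(10^runif(nG, 4, 5.7))

    # planted BGC-rich species: their designated (highest-completeness)
    # genome is made the species' best assembly outright — species-max
    # completeness and N50, species-min contamination — so the 15-BGC
    # planting lands on the genome that also wins representative scoring
    nRich <- floor(config@richSpeciesFraction * config@nSpecies)
    for (s in sp[seq_len(nRich)]) {
      i <- which(trueSpecies == s)
      if (length(i) < 2) next
      top <- i[which.max(cplTrue[i])]
      swap <- function(v, from, to) { tmp <- v[from]; v[from] <- v[to]; v[to] <- tmp; v }
      ctnTrue <- swap(ctnTrue, i[which.min(ctnTrue[i])], top)
      n50 <- swap(n50, i[which.max(n50[i])], top)
    }
    j <- config@qualityJitter
    jit <- function(x, lo, hi) pmin(pmax(x + runif(nG, -j, j), lo), hi)
    genomes <- data.frame(
      genome_id = gid,
      cpl_a = jit(cplTrue, 0, 100), ctn_a = jit(ctnTrue, 0, Inf),
      cpl_b = jit(cplTrue, 0, 100), ctn_b = jit(ctnTrue, 0, Inf),
      n50 = n50,
      # exact product, so completeness correction recovers true size exactly
      size_bp = unname(trueSize * cplTrue / 100),
      strain_heterogeneity = runif(nG, 0, 100),
      host_genus = unname(homeGenus[trueSpecies]),
      stringsAsFactors = FALSE
    )
    genomes$host_type <- unname(config@hostGenera[genomes$host_genus])
    genomes$sample_id <- sprintf("%s_h%02d", genomes$host_genus,
                                 sample.int(max(config@nSamplesPerGroup, 1L),
                                            nG, replace = TRUE))
    rownames(genomes) <- NULL
    list(genomes = genomes,
         truth = list(species = trueSpecies,
                      genomeSize = trueSize,
                      completeness = stats::setNames(cplTrue, gid),
                      contamination = stats::setNames(ctnTrue, gid),
                      homeGenus = homeGenus))
  })
}

#' Generate the pairwise ANI table
#'
#' Within-species pairs draw ANI from the within interval, between-species
#' pairs from the between interval; coverage is uniform on the configured
#' interval. The table stores each unordered pair once (`genome_i <
#' genome_j`) and is symmetric by construction.
#'
#' @param genomes genome table from [simulateGenomes()].
#' @param truth matching truth list.
#' @param config a [SimConfig-class].
#' @return data.frame: genome_i, genome_j, ani (percent), coverage (fraction).
#' @export
simulateAni <- function(genomes, truth, config) {
  if (!all(genomes$genome_id %in% names(truth$species)))
    .stopf("genome without a true species label")
  .withSubstream(config@seed, "ani", {
    gid <- genomes$genome_id
    if (length(gid) < 2)
      return(data.frame(genome_i = character(), genome_j = character(),
                        ani = numeric(), coverage = numeric()))
    pairs <- t(utils::combn(gid, 2))
    same <- truth$species[pairs[, 1]] == truth$species[pairs[, 2]]
    n <- nrow(pairs)
    ani <- numeric(n)
    ani[same] <- runif(sum(same), config@withinSpeciesAni[1], config@withinSpeciesAni[2])
    ani[!same] <- runif(sum(!same), config@betweenSpeciesAni[1], config@betweenSpeciesAni[2])
    data.frame(genome_i = pairs[, 1], genome_j = pairs[, 2],
               ani = ani,
               coverage = runif(n, config@aniCoverage[1], config@aniCoverage[2]),
               stringsAsFactors = FALSE)
  })
}

.BGC_CLASSES <- c("T1PKS", "T2PKS", "T3PKS", "NRPS", "terpene",
                  "lanthipeptide-class-iii", "lanthipeptide-class-ii",
                  "thiopeptide", "arylpolyene", "betalactone")

#' Generate BGC predictions and pairwise BGC distances
#'
#' Genomes carry `Poisson(bgcRate)` complete BGCs (plus contig-edge BGCs at
#' rate `contigEdgeProb`); for each planted BGC-rich species (exactly
#' `floor(richSpeciesFraction * nSpecies)` species, the first ids) the
#' highest-completeness genome is topped up to at least 15 complete BGCs.
#' BGCs of the same genome slot across genomes of one species share a true
#' GCF, so within-family distances fall in `gcfWithinDist` and between-family
#' distances in `gcfBetweenDist`.
#'
#' @inheritParams simulateAni
#' @return list with `bgcs` (bgc_id, genome_id, contig_id, contig_length,
#'   product_class, on_contig_edge), `bgcDist` (bgc_i, bgc_j, dist) and
#'   `truth` additions (`gcf`, `richSpecies`).
#' @export
simulateBgcs <- function(genomes, truth, config) {
  if (config@richSpeciesFraction > 0 && config@bgcRate <= 0)
    .stopf("cannot plant BGC-rich species with bgcRate <= 0")
  .withSubstream(config@seed, "bgcs", {
    sp <- .speciesIds(config@nSpecies)
    nRich <- floor(config@richSpeciesFraction * config@nSpecies)
    richSpecies <- sp[seq_len(nRich)]

    gid <- genomes$genome_id
    gSpecies <- truth$species[gid]
    nComplete <- rpois(length(gid), config@bgcRate)
    # plant: within each rich species, top the best (highest latent
    # completeness) genome up to >= 15 complete BGCs
    for (s in richSpecies) {
      memb <- gid[gSpecies == s]
      best <- memb[which.max(truth$completeness[memb])]
      i <- match(best, gid)
      nComplete[i] <- max(nComplete[i], 15L)
    }
    p <- config@contigEdgeProb
    nEdge <- if (p > 0) rpois(length(gid), config@bgcRate * p / (1 - p)) else
      rep(0L, length(gid))

    rows <- list()
    classPool <- function(s, slot) {
      # class is a deterministic function of (species, slot) so all members
      # of a true GCF share one product class
      .BGC_CLASSES[(sum(utf8ToInt(s)) + slot) %% length(.BGC_CLASSES) + 1L]
    }
    for (i in seq_along(gid)) {
      nTot <- nComplete[i] + nEdge[i]
      if (nTot == 0) next
      slot <- seq_len(nTot)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gid[i],
        species = unname(gSpecies[i]),
        slot = slot,
        on_contig_edge = c(rep(FALSE, nComplete[i]), rep(TRUE, nEdge[i])),
        stringsAsFactors = FALSE
      )
    }
    if (!length(rows)) {
      return(list(bgcs = data.frame(bgc_id = character(), genome_id = character(),
                                    contig_id = character(), contig_length = integer(),
                                    product_class = character(), on_contig_edge = logical()),
                  bgcDist = data.frame(bgc_i = character(), bgc_j = character(),
                                       dist = numeric()),
                  truth = list(gcf = character(0), richSpecies = richSpecies)))
    }
    b <- do.call(rbind, rows)
    b$bgc_id <- sprintf("BGC%05d", seq_len(nrow(b)))
    b$contig_id <- sprintf("%s_c%03d", b$genome_id, b$slot)
    b$contig_length <- round(runif(nrow(b), 5000, 200000))
    trueGcf <- sprintf("%s_F%03d", b$species, b$slot)
    b$product_class <- mapply(classPool, b$species, b$slot)
    names(trueGcf) <- b$bgc_id

    bgcs <- b[, c("bgc_id", "genome_id", "contig_id", "contig_length",
                  "product_class", "on_contig_edge")]
    rownames(bgcs) <- NULL

    if (nrow(bgcs) >= 2) {
      pairs <- t(utils::combn(bgcs$bgc_id, 2))
      sameF <- trueGcf[pairs[, 1]] == trueGcf[pairs[, 2]]
      d <- numeric(nrow(pairs))
      d[sameF] <- runif(sum(sameF), config@gcfWithinDist[1], config@gcfWithinDist[2])
      d[!sameF] <- runif(sum(!sameF), config@gcfBetweenDist[1], config@gcfBetweenDist[2])
      bgcDist <- data.frame(bgc_i = pairs[, 1], bgc_j = pairs[, 2], dist = d,
                            stringsAsFactors = FALSE)
    } else {
      bgcDist <- data.frame(bgc_i = character(), bgc_j = character(),
                            dist = numeric())
    }
    list(bgcs = bgcs, bgcDist = bgcDist,
         truth = list(gcf = trueGcf, richSpecies = richSpecies))
  })
}

#' Generate community profiles and sample metadata
#'
#' Species are detected in their home genus samples with high probability
#' (and always in at least one, so no species is orphaned); exactly
#' `floor(hostSpecificity * nSpecies)` species are confined to their home
#' genus, the rest may also appear in one secondary genus. Water samples
#' retain each host-associated species with the category retention factor
#' (C > R > O), producing the distance-decay signal. Detected abundances are
#' log-normal.
#'
#' @inheritParams simulateAni
#' @return a [ReefProfiles-class] (species x samples).
#' @export
simulateCommunity <- function(genomes, truth, config) {
  if (length(config@hostGenera) == 0) .stopf("empty host genus list")
  .withSubstream(config@seed, "community", {
    sp <- .speciesIds(config@nSpecies)
    samples <- .sampleFrame(config)
    genera <- names(config@hostGenera)

    nConf <- floor(config@hostSpecificity * config@nSpecies)
    confined <- stats::setNames(rep(FALSE, config@nSpecies), sp)
    confined[seq_len(nConf)] <- TRUE
    secondary <- stats::setNames(rep(NA_character_, config@nSpecies), sp)
    if (length(genera) > 1) {
      for (s in sp[!confined]) {
        secondary[s] <- sample(setdiff(genera, truth$homeGenus[s]), 1)
      }
    }

    m <- matrix(0, nrow = config@nSpecies, ncol = nrow(samples),
                dimnames = list(sp, samples$sample_id))
    for (i in seq_len(nrow(samples))) {
      smp <- samples[i, ]
      if (smp$biome == "seawater") {
        pDet <- config@waterRetention[[smp$water_category]]
        det <- runif(config@nSpecies) < pDet
      } else {
        home <- truth$homeGenus[sp] == smp$host_genus
        away <- !is.na(secondary[sp]) & secondary[sp] == smp$host_genus
        det <- (home & runif(config@nSpecies) < .P_DETECT_HOME) |
               (away & runif(config@nSpecies) < .P_DETECT_AWAY)
      }
      m[det, i] <- rlnorm(sum(det), meanlog = 1, sdlog = 1)
    }
    # conservation: force every species into the first sample of its home
    # genus so no species has zero host abundance
    if (config@nSamplesPerGroup >= 1L) {
      for (s in sp) {
        hostCols <- samples$sample_id[!is.na(samples$host_genus) &
                                        samples$host_genus == truth$homeGenus[s]]
        if (length(hostCols) && sum(m[s, hostCols]) == 0)
          m[s, hostCols[1]] <- rlnorm(1, meanlog = 1, sdlog = 1)
      }
    }
    reefProfiles(m, samples)
  })
}

#' Generate a read-to-gene alignment table with planted gene abundances
#'
#' Every insert gets one primary alignment that passes the downstream filters
#' (identity >= 95, full query coverage, length >= 45). Exactly
#' `floor(ambiguousFraction * nInserts)` inserts (the first ids) get a second
#' passing alignment of equal identity to a different gene, making them
#' ambiguous. Additional decoy alignments straddle the filter thresholds
#' (sub-95 identity, sub-45 length, or sub-80% coverage) and are always
#' removed by [filterAlignments()], so with `ambiguousFraction = 0` the
#' counting stage recovers the planted abundances exactly.
#'
#' @param config a [SimConfig-class].
#' @return list with `alignments` (insert_id, gene_id, identity, aln_length,
#'   query_length), `geneLengths` (gene_id, length_bp) and `truth`
#'   (named true insert count per gene).
#' @export
simulateAlignments <- function(config) {
  if (config@ambiguousFraction > 0 && config@nGenes < 2)
    .stopf("ambiguous inserts require at least 2 genes")
  .withSubstream(config@seed, "alignments", {
    genes <- sprintf("gene%04d", seq_len(config@nGenes))
    w <- rlnorm(config@nGenes, 0, 1)
    target <- sample(genes, config@nInserts, replace = TRUE, prob = w)
    inserts <- sprintf("ins%06d", seq_len(config@nInserts))
    qlen <- sample(100:300, config@nInserts, replace = TRUE)

    primary <- data.frame(
      insert_id = inserts, gene_id = target,
      identity = runif(config@nInserts, 95, 100),
      aln_length = qlen, query_length = qlen,
      stringsAsFactors = FALSE
    )
    nAmb <- floor(config@ambiguousFraction * config@nInserts)
    amb <- NULL
    if (nAmb > 0) {
      idx <- seq_len(nAmb)
      alt <- vapply(target[idx], function(g) sample(setdiff(genes, g), 1), "")
      amb <- data.frame(
        insert_id = inserts[idx], gene_id = alt,
        identity = primary$identity[idx],   # ties the best-identity reduction
        aln_length = qlen[idx], query_length = qlen[idx],
        stringsAsFactors = FALSE
      )
    }
    # decoys straddling each filter threshold; all fail at least one filter
    nDecoy <- max(1L, round(config@nInserts * 0.2))
    di <- sample.int(config@nInserts, nDecoy, replace = TRUE)
    kind <- sample(1:3, nDecoy, replace = TRUE)
    dq <- qlen[di]
    decoy <- data.frame(
      insert_id = inserts[di],
      gene_id = sample(genes, nDecoy, replace = TRUE),
      identity = ifelse(kind == 1, runif(nDecoy, 80, 94.99), runif(nDecoy, 95, 100)),
      aln_length = ifelse(kind == 2, pmin(sample(20:44, nDecoy, replace = TRUE), dq),
                          ifelse(kind == 3, pmax(40L, floor(dq * 0.79)), dq)),
      query_length = dq,
      stringsAsFactors = FALSE
    )
    # kind 3 decoys must fail the 80% coverage rule but keep >= 45 bases
    # whenever possible; if the floor pushed below 45 they fail the length
    # rule instead, which is also sub-threshold.
    aln <- rbind(primary, amb, decoy)
    rownames(aln) <- NULL
    truthCounts <- table(factor(target, levels = genes))
    list(alignments = aln,
         geneLengths = data.frame(gene_id = genes,
                                  length_bp = sample(300:3000, config@nGenes,
                                                     replace = TRUE),
                                  stringsAsFactors = FALSE),
         truth = stats::setNames(as.numeric(truthCounts), genes))
  })
}

#' Generate the full synthetic dataset
#'
#' Runs all generators under per-table substreams of the configured seed and
#' bundles the tables with their truth into a [ReefSim-class].
#'
#' @param config a [SimConfig-class].
#' @return a [ReefSim-class].
#' @export
#' @examples
#' sim <- simulateReefData(simConfig(seed = 1, nSpecies = 5,
#'                                   genomesPerSpecies = c(2, 2)))
#' sim
simulateReefData <- function(config) {
  validObject(config)
  g <- simulateGenomes(config)
  ani <- simulateAni(g$genomes, g$truth, config)
  b <- simulateBgcs(g$genomes, g$truth, config)
  profiles <- simulateCommunity(g$genomes, g$truth, config)
  a <- simulateAlignments(config)
  new("ReefSim",
      config = config,
      genomes = g$genomes,
      ani = ani,
      bgcs = b$bgcs,
      bgcDist = b$bgcDist,
      profiles = profiles,
      alignments = a$alignments,
      geneLengths = a$geneLengths,
      truth = c(g$truth, b$truth, list(geneAbundance = a$truth)))
}

#' Write a synthetic dataset as TSV tables
#'
#' Writes genomes.tsv, ani.tsv, bgcs.tsv, bgc_dist.tsv, profiles.tsv,
#' samples.tsv, alignments.tsv, gene_lengths.tsv, a truth/ directory and a
#' config.json recording the full configuration.
#'
#' @param sim a [ReefSim-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  wt <- function(x, name) {
    p <- file.path(dir, name)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  m <- SummarizedExperiment::assay(sim@profiles, "abundance")
  profLong <- data.frame(species_id = rownames(m)[row(m)[m > 0]],
                         sample_id = colnames(m)[col(m)[m > 0]],
                         abundance = m[m > 0])
  paths <- c(
    wt(sim@genomes, "genomes.tsv"),
    wt(sim@ani, "ani.tsv"),
    wt(sim@bgcs, "bgcs.tsv"),
    wt(sim@bgcDist, "bgc_dist.tsv"),
    wt(profLong, "profiles.tsv"),
    wt(as.data.frame(SummarizedExperiment::colData(sim@profiles)), "samples.tsv"),
    wt(sim@alignments, "alignments.tsv"),
    wt(sim@geneLengths, "gene_lengths.tsv"),
    wt(data.frame(genome_id = names(sim@truth$species),
                  species_id = unname(sim@truth$species),
                  true_size_bp = unname(sim@truth$genomeSize[names(sim@truth$species)])),
       file.path("truth", "genomes.tsv")),
    wt(data.frame(bgc_id = names(sim@truth$gcf), gcf_id = unname(sim@truth$gcf)),
       file.path("truth", "gcfs.tsv")),
    wt(data.frame(gene_id = names(sim@truth$geneAbundance),
                  inserts = unname(sim@truth$geneAbundance)),
       file.path("truth", "gene_abundance.tsv"))
  )
  cfgList <- lapply(slotNames(sim@config), function(s) slot(sim@config, s))
  names(cfgList) <- slotNames(sim@config)
  jsonlite::write_json(cfgList, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, file.path(dir, "config.json")))
}

#' Construct a ReefProfiles object
#'
#' @param abundance numeric matrix, species as rows, samples as columns.
#' @param sampleData data.frame with columns sample_id, biome, host_genus,
#'   island, water_category (rows matching the columns of `abundance`).
#' @return a [ReefProfiles-class].
#' @export
reefProfiles <- function(abundance, sampleData) {
  stopifnot(ncol(abundance) == nrow(sampleData))
  cd <- S4Vectors::DataFrame(sampleData)
  rownames(cd) <- sampleData$sample_id
  new("ReefProfiles", SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance), colData = cd))
}

#' @rdname reefProfiles
#' @param x a `ReefProfiles`
#' @return `profileMatrix()` returns the species x samples abundance matrix;
#'   `sampleInfo()` the sample metadata as a data.frame.
#' @export
profileMatrix <- function(x) SummarizedExperiment::assay(x, "abundance")

#' @rdname reefProfiles
#' @export
sampleInfo <- function(x) as.data.frame(SummarizedExperiment::colData(x))
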