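test_that("GCF clustering cuts strictly below the threshold", {
  expect_equal(length(unique(
    clusterGcfs(data.frame(bgc_i = "b1", bgc_j = "b2", dist = 0.4),
                c("b1", "b2")))), 1)
  expect_equal(length(unique(
    clusterGcfs(data.frame(bgc_i = "b1", bgc_j = "b2", dist = 0.6),
                c("b1", "b2")))), 2)
  # exactly at the threshold: not merged (strict <)
  expect_equal(length(unique(
    clusterGcfs(data.frame(bgc_i = "b1", bgc_j = "b2", dist = 0.5),
                c("b1", "b2")))), 2)
  # missing pairs default to distance 1; singletons allowed
  g <- clusterGcfs(data.frame(bgc_i = "b1", bgc_j = "b2", dist = 0.1),
                   c("b1", "b2", "b3"))
  expect_equal(length(unique(g)), 2)
  expect_error(clusterGcfs(data.frame(bgc_i = "a", bgc_j = "b", dist = 1.2),
                           c("a", "b")), "\\[0, 1\\]")
})

test_that("planted two-block structure is recovered exactly", {
  set.seed(401)
  ids <- paste0("b", 1:6)
  block <- rep(c("X", "Y"), each = 3)
  pairs <- t(combn(ids, 2))
  same <- block[match(pairs[, 1], ids)] == block[match(pairs[, 2], ids)]
  d <- data.frame(bgc_i = pairs[, 1], bgc_j = pairs[, 2],
                  dist = ifelse(same, runif(nrow(pairs), 0, 0.3),
                                runif(nrow(pairs), 0.6, 1)))
  gcfs <- clusterGcfs(d, ids)
  expect_equal(length(unique(gcfs)), 2)
  expect_true(samePartition(gcfs, stats::setNames(block, ids)))
})

test_that("average-linkage clustering matches a brute-force oracle", {
  set.seed(402)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    ids <- sprintf("b%02d", seq_len(n))
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    v <- runif(n * (n - 1) / 2)
    m[lower.tri(m)] <- v
    m <- m + t(m)
    pairs <- which(lower.tri(m), arr.ind = TRUE)
    d <- data.frame(bgc_i = ids[pairs[, 2]], bgc_j = ids[pairs[, 1]],
                    dist = m[pairs])
    for (thr in c(0.3, 0.5, 0.7)) {
      got <- clusterGcfs(d, ids, threshold = thr)
      want <- bruteAverageLinkage(m, thr)
      expect_true(samePartition(got, want),
                  label = sprintf("rep %d thr %.1f", rep, thr))
    }
  }
})

test_that("threshold extremes give all singletons and one family", {
  set.seed(403)
  ids <- paste0("b", 1:6)
  pairs <- t(combn(ids, 2))
  d <- data.frame(bgc_i = pairs[, 1], bgc_j = pairs[, 2],
                  dist = runif(nrow(pairs), 0.05, 0.95))
  tiny <- clusterGcfs(d, ids, threshold = 1e-12)
  expect_equal(length(unique(tiny)), length(ids))
  all1 <- clusterGcfs(d, ids, threshold = 1 + 1e-9)
  expect_equal(length(unique(all1)), 1)
})

test_that("GCF class assignment maps labels and resolves ties to others", {
  gcfs <- stats::setNames(c("F1", "F1", "F2", "F3", "F3"),
                          paste0("b", 1:5))
  pc <- stats::setNames(c("T1PKS", "T1PKS", "lanthipeptide-class-iii",
                          "NRPS", "terpene"), paste0("b", 1:5))
  cl <- assignGcfClass(gcfs, pc)
  expect_equal(unname(cl["F1"]), "T1PKS")
  expect_equal(unname(cl["F2"]), "RiPPs")
  expect_equal(unname(cl["F3"]), "others") # NRPS vs terpene tie
  unk <- assignGcfClass(stats::setNames("F", "b"),
                        stats::setNames("mystery-label", "b"))
  expect_equal(unname(unk), "others")
})

test_that("GCF novelty is strict-below-threshold against each reference", {
  gcfs <- stats::setNames(c("F1", "F1", "F2"), c("b1", "b2", "b3"))
  refDist <- data.frame(
    bgc_id = c("b1", "b2", "b3", "b1", "b2", "b3"),
    ref_set = rep(c("predicted", "characterized"), each = 3),
    dist = c(0, 1, 1, 0.5, 0.7, 0.49))
  nov <- gcfNovelty(gcfs, refDist)
  getRow <- function(g, r)
    nov$matches_reference[nov$gcf_id == g & nov$ref_set == r]
  expect_true(getRow("F1", "predicted"))     # member at distance 0
  expect_false(getRow("F2", "predicted"))    # all members at 1
  expect_false(getRow("F1", "characterized")) # 0.5 is not < 0.5
  expect_true(getRow("F2", "characterized")) # 0.49 < 0.5
  # missing distances are treated as 1, with a message
  expect_message(nov2 <- gcfNovelty(gcfs, refDist[-3, ]), "treated as 1")
  expect_false(nov2$matches_reference[nov2$gcf_id == "F2" &
                                        nov2$ref_set == "predicted"])
})

test_that("richness ratios reproduce the published worked examples", {
  # 6,612 GCFs over 4,224 species -> 1.57; 5,877 over 8,304 -> 0.71
  rep <- headlineReport(data.frame(
    label = c("reef", "ocean"),
    numerator = c(6612, 5877), denominator = c(4224, 8304),
    unit = "ratio", digits = 2))
  expect_equal(rep$value, c(1.57, 0.71))
  # zero GCFs give ratio 0; zero denominators are flagged
  z <- headlineReport(data.frame(label = c("a", "b"),
                                 numerator = c(0, 5),
                                 denominator = c(10, 0),
                                 unit = "ratio"))
  expect_equal(z$value[1], 0)
  expect_true(z$undefined[2])
  expect_true(is.na(z$value[2]))
})

test_that("per-group richness counts GCFs, species and genomes", {
  genomes <- data.frame(genome_id = c("g1", "g2", "g3"),
                        host_type = c("fire", "fire", "stony"))
  bgcs <- data.frame(bgc_id = paste0("b", 1:4),
                     genome_id = c("g1", "g1", "g2", "g3"))
  gcfs <- stats::setNames(c("F1", "F2", "F1", "F3"), paste0("b", 1:4))
  sp <- c(g1 = "s1", g2 = "s2", g3 = "s3")
  r <- richnessMetrics(gcfs, bgcs, sp, genomes, "host_type")
  fire <- r[r$group == "fire", ]
  expect_equal(fire$n_gcfs, 2)
  expect_equal(fire$n_species, 2)
  expect_equal(fire$gcf_per_species, 1.00)
  expect_equal(fire$gcf_per_genome, 1.0)
  expect_equal(r$n_gcfs[r$group == "stony"], 1)
})

test_that("depth-normalized GCF richness divides by the mOTU total", {
  got <- depthNormalizedGcfs(c(s1 = 10, s2 = 0), c(s1 = 100, s2 = 50))
  expect_equal(unname(got), c(0.1, 0))
  expect_equal(depthNormalizedGcfs(c(s = 20), c(s = 200)),
               depthNormalizedGcfs(c(s = 10), c(s = 100)))
  expect_error(depthNormalizedGcfs(c(s = 1), c(s = 0)), "non-positive")
})

test_that("rarefaction means match exhaustive enumeration on a 3-unit toy", {
  sets <- list(u1 = c("a", "b"), u2 = c("b", "c"), u3 = c("c", "d", "e"))
  r <- rarefactionCurve(sets, nIterations = 3000, seed = 1)
  # k = 1: mean over units of |set| = (2 + 2 + 3) / 3
  expect_equal(r$mean[1], 7 / 3, tolerance = 0.05)
  # k = 2: average union size over the 3 unordered pairs = (3 + 5 + 4) / 3
  expect_equal(r$mean[2], 4, tolerance = 0.05)
  # endpoint is deterministic: all 5 distinct GCFs, zero variance
  expect_equal(r$mean[3], 5)
  expect_equal(r$sd[3], 0)
  expect_true(all(diff(r$mean) >= 0))
  # identical sets give a flat curve
  flat <- rarefactionCurve(list(a = c("x", "y"), b = c("x", "y")),
                           nIterations = 10, seed = 2)
  expect_equal(flat$mean, c(2, 2))
})

test_that("composite scoring follows the log-normalized index rules", {
  bgcs <- data.frame(
    bgc_id = paste0("b", 1:20),
    genome_id = c(rep("g1", 16), rep("g2", 4)),
    on_contig_edge = FALSE)
  qc <- data.frame(genome_id = c("g1", "g2"), Q = c(80, 80),
                   n50 = c(1e5, 1e5))
  sp <- c(g1 = "s1", g2 = "s1")
  res <- bgcRichScore(bgcs, qc, sp)
  s <- res$scores
  expect_equal(s$idx_bgc[s$genome_id == "g1"], 100)
  expect_equal(s$idx_bgc[s$genome_id == "g2"],
               log(4) / log(16) * 100) # = 50
  expect_equal(res$candidates$scoring_genome, "g1")
  expect_true(res$candidates$candidate_rich) # 16 >= 15

  # single-genome species: 14 complete BGCs is not a candidate, 15 is
  one <- function(n) bgcRichScore(
    data.frame(bgc_id = paste0("x", seq_len(n)), genome_id = "g",
               on_contig_edge = FALSE),
    data.frame(genome_id = "g", Q = 90, n50 = 1e5), c(g = "s"))
  expect_false(one(14)$candidates$candidate_rich)
  expect_true(one(15)$candidates$candidate_rich)

  # contig-edge BGCs cluster but do not count toward the rule
  edge <- bgcRichScore(
    data.frame(bgc_id = paste0("e", 1:20), genome_id = "g",
               on_contig_edge = c(rep(FALSE, 10), rep(TRUE, 10))),
    data.frame(genome_id = "g", Q = 90, n50 = 1e5), c(g = "s"))
  expect_equal(edge$candidates$n_complete_bgcs, 10)
  expect_false(edge$candidates$candidate_rich)
})

test_that("composite index is log-base invariant and bounded", {
  set.seed(404)
  bgcs <- data.frame(
    bgc_id = sprintf("b%03d", 1:60),
    genome_id = rep(sprintf("g%02d", 1:12), each = 5),
    on_contig_edge = sample(c(TRUE, FALSE), 60, replace = TRUE))
  qc <- data.frame(genome_id = sprintf("g%02d", 1:12),
                   Q = runif(12, -20, 110), n50 = 10^runif(12, 4, 6))
  sp <- stats::setNames(rep(c("sA", "sB", "sC"), each = 4),
                        sprintf("g%02d", 1:12))
  base <- lapply(c(exp(1), 2, 10), function(bb)
    bgcRichScore(bgcs, qc, sp, logBase = bb)$scores)
  expect_equal(base[[1]]$composite, base[[2]]$composite, tolerance = 1e-12)
  expect_equal(base[[1]]$composite, base[[3]]$composite, tolerance = 1e-12)
  s <- base[[1]]
  expect_true(all(s$idx_bgc >= 0 & s$idx_bgc <= 100))
  expect_true(all(s$idx_q >= 0 & s$idx_q <= 100))
  expect_true(all(s$idx_n50 >= 0 & s$idx_n50 <= 100))
  expect_true(all(s$composite >= 0 & s$composite <= 300))
})

test_that("BGC ingest rejects short contigs", {
  ok <- data.frame(bgc_id = "b", genome_id = "g", contig_id = "c",
                   contig_length = 5000, product_class = "NRPS",
                   on_contig_edge = FALSE)
  expect_silent(ingestBgcs(ok))
  bad <- transform(ok, contig_length = 4999)
  expect_error(ingestBgcs(bad), "shorter than")
})
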