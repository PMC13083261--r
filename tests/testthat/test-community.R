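test_that("profile filtering applies species-then-sample thresholds once", {
  m <- matrix(0, nrow = 3, ncol = 12,
              dimnames = list(paste0("sp", 1:3), paste0("s", 1:12)))
  m["sp1", 1:10] <- 10         # detected in exactly 10 samples: kept
  m["sp2", 1:9] <- 5           # detected in 9 samples: removed first
  m["sp3", 1:12] <- 0.3        # detected everywhere, low abundance: kept
  f <- filterProfiles(m, minSamples = 10, minTotal = 3)
  expect_setequal(rownames(f), c("sp1", "sp3"))
  # samples 11, 12 hold only sp3 at 0.3 after the species filter: removed;
  # note sp2's abundance no longer counts toward sample totals
  expect_equal(colnames(f), paste0("s", 1:10))
})

test_that("sample totals at exactly the threshold are removed", {
  m <- matrix(c(3, 3.01), nrow = 1,
              dimnames = list("sp1", c("at", "above")))
  f <- filterProfiles(m, minSamples = 1, minTotal = 3)
  expect_equal(colnames(f), "above")
  expect_error(filterProfiles(m, minSamples = 3, minTotal = 3),
               class = "reefMAGs_empty_filter")
})

test_that("jaccard distance follows the set formula with conventions", {
  m <- cbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1))
  expect_equal(as.numeric(jaccardDistance(m)), 0.5) # 1 - 2/4
  same <- cbind(x = c(1, 0, 2), y = c(3, 0, 1))
  expect_equal(as.numeric(jaccardDistance(same)), 0)
  disjoint <- cbind(x = c(1, 0), y = c(0, 1))
  expect_equal(as.numeric(jaccardDistance(disjoint)), 1)
  # all-absent pair: distance 0 by convention
  empty <- cbind(x = c(0, 0), y = c(0, 0))
  expect_equal(as.numeric(jaccardDistance(empty)), 0)
})

test_that("jaccard agrees with vegan and satisfies the triangle inequality", {
  skip_if_not_installed("vegan")
  set.seed(201)
  for (rep in 1:5) {
    m <- matrix(rbinom(60, 1, 0.5) * runif(60), nrow = 6) # species x samples
    colnames(m) <- paste0("s", 1:10)
    if (any(colSums(m > 0) == 0)) next # vegan's convention differs there
    got <- as.matrix(jaccardDistance(m))
    ref <- as.matrix(vegan::vegdist(t(m > 0), method = "jaccard",
                                    binary = TRUE))
    expect_equal(got, ref, ignore_attr = TRUE, tolerance = 1e-12)
    # metric property on detection vectors
    n <- ncol(m)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(got[i, j], got[i, k] + got[k, j] + 1e-12)
  }
})

test_that("PCoA reproduces Euclidean distances and flags negative eigenvalues", {
  # planted points in the plane: self-consistency to 1e-9
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4), c(3, 4))
  d <- dist(pts)
  ord <- pcoaOrdination(d)
  rec <- dist(ord$coordinates)
  expect_lt(max(abs(as.numeric(rec) - as.numeric(d))), 1e-9)
  expect_equal(ord$negativeEigenvalues, 0)
  # sum of positive eigenvalues equals total squared coordinate mass
  expect_equal(sum(ord$eigenvalues[ord$eigenvalues > 1e-9]),
               sum(ord$coordinates^2), tolerance = 1e-9)
  # two samples at distance 1: single axis at +/- 0.5
  ord2 <- pcoaOrdination(matrix(c(0, 1, 1, 0), 2))
  expect_equal(sort(as.numeric(ord2$coordinates)), c(-0.5, 0.5))
  expect_equal(ncol(ord2$coordinates), 1)
  # all-zero distances: no positive axes
  ord0 <- pcoaOrdination(matrix(0, 3, 3))
  expect_equal(ncol(ord0$coordinates), 0)
  expect_error(pcoaOrdination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA matches the ape implementation on a non-Euclidean matrix", {
  skip_if_not_installed("ape")
  set.seed(202)
  m <- matrix(rbinom(80, 1, 0.4), nrow = 8)
  colnames(m) <- paste0("s", 1:10)
  d <- jaccardDistance(m)
  got <- pcoaOrdination(d)
  ref <- ape::pcoa(d)
  nAx <- min(ncol(got$coordinates), ncol(ref$vectors))
  for (k in seq_len(nAx)) {
    expect_equal(abs(got$coordinates[, k]), abs(ref$vectors[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("PERMANOVA decomposition matches the Euclidean centroid oracle", {
  set.seed(203)
  pts <- rbind(matrix(rnorm(6, 0), ncol = 2),
               matrix(rnorm(6, 3), ncol = 2))
  groups <- rep(c("a", "b"), each = 3)
  d <- dist(pts)
  res <- permanovaTest(d, groups, nPermutations = 99, seed = 1)
  ss <- euclideanSS(pts, groups)
  expect_equal(res@R2, unname(ss["among"] / ss["total"]), tolerance = 1e-12)
  fOracle <- (ss["among"] / 1) / (ss["within"] / 4)
  expect_equal(res@pseudoF, unname(fOracle), tolerance = 1e-12)
})

test_that("PERMANOVA agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(204)
  pc <- plantedCommunity(nPerGroup = 5, nSpecies = 16, seed = 3)
  # sparse presence noise so groups overlap without collapsing the
  # presence/absence structure
  noise <- matrix(rbinom(length(pc$m), 1, 0.3), nrow = nrow(pc$m))
  pc$m <- pc$m + noise * runif(length(pc$m), 0.5, 2)
  d <- jaccardDistance(pc$m)
  res <- permanovaTest(d, pc$groups, nPermutations = 199, seed = 9)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = pc$groups),
                        permutations = 199)
  expect_equal(res@pseudoF, ref$F[1], tolerance = 1e-10)
  expect_equal(res@R2, ref$R2[1], tolerance = 1e-10)
})

test_that("planted separation forces the minimal p-value", {
  pc <- plantedCommunity(nPerGroup = 6, nSpecies = 20, seed = 5)
  d <- jaccardDistance(pc$m)
  res <- permanovaTest(d, pc$groups, nPermutations = 99, seed = 2)
  expect_equal(res@p, 1 / 100)
  expect_gt(res@R2, 0.5)
  expect_error(permanovaTest(d, c("a", rep("b", 11)), 99), "at least 2")
  expect_error(permanovaTest(d, rep("a", 12), 99), "two groups")
})

test_that("balanced subsampling reproduces with a seed and aggregates", {
  pc <- plantedCommunity(nPerGroup = 10, nSpecies = 20, seed = 6)
  d <- jaccardDistance(pc$m)
  # unbalanced: drop half of group 2
  keep <- c(1:10, 11:14)
  dSub <- as.matrix(d)[keep, keep]
  gSub <- pc$groups[keep]
  r1 <- balancedPermanova(dSub, gSub, subsampleSize = 4, repetitions = 3,
                          nPermutations = 49, seed = 7)
  r2 <- balancedPermanova(dSub, gSub, subsampleSize = 4, repetitions = 3,
                          nPermutations = 49, seed = 7)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$repetitions), 3)
  # balanced groups below the subsample size: every repetition identical
  rBal <- balancedPermanova(dSub, gSub, subsampleSize = 50, repetitions = 3,
                            nPermutations = 49, seed = 8)
  expect_equal(length(unique(rBal$repetitions$p)), 1)
  expect_equal(length(unique(rBal$repetitions$R2)), 1)
  # strong planted effect: small median p at modest settings
  expect_lte(r1$medianP, 0.05)
})

test_that("detection decay reports per-category fractions and abundance", {
  m <- matrix(0, 3, 5,
              dimnames = list(paste0("sp", 1:3),
                              c("h1", "wC1", "wC2", "wR1", "wO1")))
  m[, "h1"] <- 1
  m["sp1", "wC1"] <- 2; m["sp2", "wC2"] <- 1
  m["sp1", "wR1"] <- 1
  info <- data.frame(sample_id = colnames(m),
                     biome = c("coral", rep("seawater", 4)),
                     host_genus = c("Porites", rep(NA, 4)),
                     island = "I1",
                     water_category = c(NA, "C", "C", "R", "O"))
  prof <- reefProfiles(m, info)
  dec <- detectionDecay(paste0("sp", 1:3), prof)
  expect_equal(dec$fraction_detected[dec$category == "C"], 2 / 3)
  expect_equal(dec$fraction_detected[dec$category == "R"], 1 / 3)
  expect_equal(dec$fraction_detected[dec$category == "O"], 0)
  expect_error(detectionDecay(character(0), prof), "empty")
})
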