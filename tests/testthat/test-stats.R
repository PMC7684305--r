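# Community-comparison statistics.

test_that("WARM aggregation sums the listed columns and conserves totals", {
  m <- matrix(c(3, 4, 10, 1, 2, 20), nrow = 2,
              dimnames = list(c("s1", "s2"),
                              c("Globorotalia_hirsuta",
                                "Globigerinella_calida",
                                "Neogloboquadrina_pachyderma")))
  out <- aggregate_warm(m)
  expect_equal(unname(out["s1", "WARM"]), 3 + 10)
  expect_equal(rowSums(out), rowSums(m))
  # empty warm list is the identity
  expect_identical(aggregate_warm(m, character(0)), m)
  # all taxa warm collapses to one column of row sums
  all_warm <- aggregate_warm(m, colnames(m))
  expect_equal(ncol(all_warm), 1)
  expect_equal(unname(all_warm[, "WARM"]), unname(rowSums(m)))
})

test_that("CSS factors match hand-computed values and are scale invariant", {
  # sample {10,10,10,10}: median of nonzero counts 10, factor 40
  m <- matrix(c(10, 10, 10, 10,
                1, 2, 3, 100), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), NULL))
  res <- css_normalize(m, percentile = 0.5)
  expect_equal(unname(res$factors["s1"]), 40)
  expect_equal(unname(res$normalized["s1", ]), rep(250, 4))
  # s2: nonzero quantile(0.5, type 7) of {1,2,3,100} = 2.5 -> factor 1+2 = 3
  expect_equal(unname(res$factors["s2"]), 3)

  # per-sample scale invariance on randomized tables
  set.seed(13)
  for (rep in 1:5) {
    counts <- matrix(rpois(60, 15), nrow = 6)
    rownames(counts) <- sprintf("s%d", 1:6)
    scaled <- counts; scaled[3, ] <- scaled[3, ] * 7
    a <- css_normalize(counts)$normalized
    b <- css_normalize(scaled)$normalized
    expect_equal(a, b, tolerance = 1e-12)
  }

  # all-zero samples are excluded with a warning
  z <- rbind(m, s3 = c(0, 0, 0, 0))
  expect_warning(res2 <- css_normalize(z), "all-zero")
  expect_equal(rownames(res2$normalized), c("s1", "s2"))
})

test_that("Bray-Curtis satisfies the distance axioms and the worked example", {
  m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(as.numeric(bray_curtis(m)), 4 / 12)
  ident <- rbind(a = c(2, 5), b = c(2, 5))
  expect_equal(as.numeric(bray_curtis(ident)), 0)
  disj <- rbind(a = c(5, 0), b = c(0, 7))
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  # axioms on randomized tables
  set.seed(19)
  counts <- matrix(rpois(50, 8), nrow = 5)
  d <- as.matrix(bray_curtis(counts))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PCoA reproduces Euclidean configurations and flags corrections", {
  # collinear points with distances 1, 1, 2 embed exactly in 1-D
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  ord <- pcoa_ord(d)
  expect_false(ord$corrected)
  got <- dist(ord$coordinates[, 1])
  expect_equal(as.numeric(got), c(1, 2, 1), tolerance = 1e-10)

  # distances from a known Euclidean configuration are recovered
  set.seed(23)
  X <- matrix(rnorm(8 * 3), 8, 3)
  dE <- dist(X)
  ordE <- pcoa_ord(dE)
  expect_equal(as.numeric(dist(ordE$coordinates[, 1:3])), as.numeric(dE),
               tolerance = 1e-10)
  expect_true(all(diff(ordE$eigenvalues) <= 1e-9))

  # duplicate samples land on coincident coordinates
  Y <- rbind(X[1, ], X)
  ordD <- pcoa_ord(dist(Y))
  expect_equal(ordD$coordinates[1, ], ordD$coordinates[2, ],
               tolerance = 1e-8)

  # non-Euclidean input triggers the recorded additive correction
  set.seed(29)
  counts <- matrix(rpois(60, 5), nrow = 10)
  ordB <- pcoa_ord(bray_curtis(counts))
  expect_true(ordB$corrected)
  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("dispersion distances agree with vegan::betadisper on Euclidean input", {
  set.seed(31)
  X <- matrix(rnorm(16 * 4), 16, 4)
  d <- dist(X)
  g <- rep(c("a", "b"), each = 8)
  ours <- dispersion_test(d, g, n_perm = 99, seed = 1)
  ref <- vegan::betadisper(d, g, type = "centroid")
  expect_equal(unname(ours$distances), unname(ref$distances),
               tolerance = 1e-8)
})

test_that("dispersion test separates unequal spreads and respects the p floor", {
  set.seed(37)
  X <- rbind(matrix(rnorm(10 * 3, sd = 1), 10),
             matrix(rnorm(10 * 3, sd = 10), 10))
  g <- rep(c("tight", "wide"), each = 10)
  res <- dispersion_test(dist(X), g, n_perm = 999, seed = 2)
  expect_lte(res$p_value, 0.01)
  # p >= 1/(n_perm+1) by construction
  expect_gte(res$p_value, 1 / 1000)
  # singleton groups are excluded with a warning
  expect_warning(
    dispersion_test(dist(X), c(rep("a", 10), rep("b", 9), "c"),
                    n_perm = 49, seed = 1), "singleton")
  # pairwise mode returns one row per pair
  res3 <- dispersion_test(dist(X), rep(c("a", "b", "c"), length.out = 20),
                          n_perm = 99, seed = 3, pairwise = TRUE)
  expect_equal(nrow(res3$pairwise), 3)
})

test_that("permanova matches vegan::adonis2 and detects separated clouds", {
  set.seed(41)
  counts <- matrix(rpois(14 * 6, 10), 14, 6)
  g <- rep(c("a", "b"), each = 7)
  d <- bray_curtis(counts)
  ours <- permanova_test(d, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(ours$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$R2, ref$R2[1], tolerance = 1e-10)

  # permuting sample order leaves the pseudo-F unchanged
  p <- sample(14)
  m <- as.matrix(d)
  ours_p <- permanova_test(m[p, p], g[p], n_perm = 99, seed = 1)
  expect_equal(ours_p$statistic, ours$statistic, tolerance = 1e-12)

  # disjoint clouds are strongly significant
  X <- rbind(matrix(rnorm(8 * 3), 8), matrix(rnorm(8 * 3, mean = 30), 8))
  res <- permanova_test(dist(X), rep(c("a", "b"), each = 8),
                        n_perm = 999, seed = 2)
  expect_lte(res$p_value, 0.01)
})

test_that("Mantel statistic matches vegan and is 1 for identical tables", {
  set.seed(43)
  c1 <- matrix(rpois(60, 10), 10, 6)
  c2 <- c1 + matrix(rpois(60, 2), 10, 6)
  d1 <- bray_curtis(c1); d2 <- bray_curtis(c2)
  ours <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  ref <- vegan::mantel(d1, d2, permutations = 99)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$statistic, 1)
})

test_that("planktonic fraction profiles conserve reads and bin by midpoint", {
  counts <- matrix(c(1L, 99L, 50L, 50L, 90L, 10L), nrow = 2,
                   dimnames = list(c("OTU_0001", "OTU_0002"),
                                   c("s_top", "s_mid", "s_deep")))
  ann <- data.frame(taxonomy = c("p", "b"),
                    habitat = c("planktonic", "benthic"),
                    row.names = rownames(counts))
  md <- data.frame(sample = c("s_top", "s_mid", "s_deep"),
                   depth_cm_top = c(0, 12, 24),
                   depth_cm_bottom = c(2, 14, 26))
  prof <- planktonic_fraction_profile(list(counts = counts,
                                           annotation = ann), md)
  ord <- match(c("s_top", "s_mid", "s_deep"), prof$samples$sample)
  expect_equal(prof$samples$fraction[ord], c(0.01, 0.5, 0.9))
  expect_equal(prof$samples$planktonic + prof$samples$benthic,
               colSums(counts)[prof$samples$sample], ignore_attr = TRUE)
  expect_equal(prof$bins$mean_fraction, c(0.01, 0.5, 0.9))

  # replicates are summed before fractions
  counts2 <- matrix(c(10L, 0L, 0L, 10L), nrow = 2,
                    dimnames = list(rownames(counts)[1:2],
                                    c("s1.rep1", "s1.rep2")))
  prof2 <- planktonic_fraction_profile(
    list(counts = counts2, annotation = ann),
    data.frame(sample = "s1", depth_cm_top = 0, depth_cm_bottom = 2))
  expect_equal(prof2$samples$fraction, 0.5)
})

test_that("congruence report: identical tables give Mantel 1, zone contrast detected", {
  set.seed(47)
  md <- data.frame(sample = sprintf("s%02d", 1:12),
                   site = rep(c("S01", "S02", "S03", "S04"), each = 3),
                   zone = rep(c("LC", "NAC"), each = 6))
  base <- matrix(rpois(12 * 5, 30), 12, 5,
                 dimnames = list(md$sample, sprintf("t%d", 1:5)))
  shift <- base
  shift[md$zone == "NAC", 1] <- shift[md$zone == "NAC", 1] + 200
  rep1 <- congruence_report(shift, shift, md, n_perm = 99, seed = 1)
  expect_equal(rep1$mantel$statistic, 1)
  expect_lte(rep1$fossil$by_zone$permanova$p_value, 0.05)
  expect_equal(rep1$fossil$by_zone$permanova$statistic,
               rep1$molecular$by_zone$permanova$statistic)

  # spinose taxa are removed from the fossil side before comparison
  fossil <- cbind(base, Globigerina_bulloides = rpois(12, 50))
  rep2 <- congruence_report(fossil, base, md,
                            spinose_taxa = "Globigerina_bulloides",
                            n_perm = 99, seed = 1)
  expect_equal(rep2$mantel$statistic, 1, tolerance = 1e-12)

  expect_error(congruence_report(base[1:2, ], base[1:2, ], md),
               "shared samples")
})
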