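# Community statistics: rarefaction, absolute abundance, R_i, niche
# classification, clades, SIMPER, PCA.

test_that("rarefaction: threshold behaviour and reproducibility", {
  counts <- cbind(deep = c(6000L, 2500L, 500L),
                  exact = c(5000L, 3000L, 1000L),
                  shallow = c(5000L, 3000L, 999L))
  rownames(counts) <- paste0("OTU", 1:3)
  meta <- data.frame(sample_id = colnames(counts), line = "D",
                     replicate = "A", cycle = 1:3, substrate = "soil")
  x <- otuExperiment(counts, meta)

  expect_message(r <- rarefySamples(x, depth = 9000, seed = 1), "shallow")
  expect_identical(attr(r, "dropped"), "shallow")
  expect_identical(ncol(r), 2L)
  # a sample at exactly the target depth is returned unchanged
  expect_identical(SummarizedExperiment::assay(r, "counts")[, "exact"],
                   counts[, "exact"])
  expect_equal(unname(colSums(SummarizedExperiment::assay(r, "counts"))),
               c(9000, 9000))
  # seeded: same seed, same draw
  r2 <- rarefySamples(x, depth = 9000, seed = 1)
  expect_identical(SummarizedExperiment::assay(r, "counts"),
                   SummarizedExperiment::assay(r2, "counts"))
})

test_that("rarefaction preserves hypergeometric expectations", {
  counts <- matrix(c(6000L, 2500L, 400L, 100L), ncol = 1,
                   dimnames = list(paste0("OTU", 1:4), "s1"))
  meta <- data.frame(sample_id = "s1", line = "D", replicate = "A",
                     cycle = 1L, substrate = "soil")
  x <- otuExperiment(counts, meta)
  depth <- 4500
  total <- sum(counts)

  draws <- vapply(1:1000, function(i) {
    SummarizedExperiment::assay(rarefySamples(x, depth = depth, seed = i),
                                "counts")[, 1]
  }, numeric(4))
  m <- rowMeans(draws)
  expected <- depth * counts[, 1] / total
  # hypergeometric variance, standard error of the mean over 1000 draws
  vhyp <- depth * (counts[, 1] / total) * (1 - counts[, 1] / total) *
    (total - depth) / (total - 1)
  se <- sqrt(vhyp / 1000)
  expect_true(all(abs(m - expected) <= 3 * se + 1e-9))
})

test_that("absolute abundances scale relative abundances to ddPCR totals", {
  counts <- cbind(a = c(4500L, 4500L, 0L), b = c(100L, 800L, 100L))
  rownames(counts) <- paste0("OTU", 1:3)
  meta <- data.frame(sample_id = c("a", "b"), line = "D", replicate = "A",
                     cycle = 1:2, substrate = c("soil", "digestate"))
  totals <- c(a = 1e10, b = 2e9)
  x <- otuExperiment(counts, meta, total_copies = totals)

  ab <- absoluteAbundance(x)
  expect_equal(ab["OTU1", "a"], 5e9)     # relative abundance 0.5 of 1e10
  expect_equal(ab["OTU3", "a"], 0)       # absent OTU stays 0
  expect_equal(colSums(ab), totals)      # exact normalization identity

  set.seed(11)
  for (i in 1:3) {
    cts <- matrix(rpois(40, 50), nrow = 8,
                  dimnames = list(paste0("O", 1:8), paste0("s", 1:5)))
    tot <- setNames(10^runif(5, 8, 11), colnames(cts))
    expect_equal(colSums(sweep(sweep(cts, 2, colSums(cts), "/"), 2, tot, "*")),
                 tot)
  }
  expect_error(absoluteAbundance(x, totals = c(a = 1e10)), "missing")
})

test_that("R_i identities: dilution, ln 10, and the inverse growth check", {
  expect_equal(enrichmentRatio(0.1 * 5e8, 5e8, f = 0.1), 0,
               ignore_attr = TRUE)
  expect_equal(enrichmentRatio(5e8, 5e8, f = 0.1), log(10),
               ignore_attr = TRUE)
  # abundance ratio 0.1 * e^3.40 corresponds to R = 3.40
  expect_equal(enrichmentRatio(0.1 * exp(3.40) * 2e9, 2e9, f = 0.1), 3.40,
               ignore_attr = TRUE)

  r <- enrichmentRatio(c(0, 1e6, 0), c(1e6, 0, 0), f = 0.1, pseudo = 0.5)
  expect_true(is.na(r[3]))
  expect_identical(attr(r, "flagged"), c(TRUE, TRUE, TRUE))

  # pure dilution series through the table-level interface
  x <- dilutionExperiment(n_cycles = 3L)
  rt <- enrichmentRatios(x, f = 0.1)
  w <- subset(rt, otu_id == "W" & !flagged)
  expect_true(nrow(w) >= 3)
  expect_equal(w$R, rep(0, nrow(w)), tolerance = 1e-9)
})

test_that("doublings convert summed R to cell divisions", {
  expect_equal(doublings(log(2)), 1)
  expect_equal(doublings(0), 0)
  expect_equal(doublings(5 * log(2)), 5)
})

test_that("niche classification thresholds", {
  mk <- function(rs, rd) {
    data.frame(otu_id = "x", line = "D", replicate = "A", cycle = c(1L, 2L),
               substrate = c("soil", "digestate"), R = c(rs, rd),
               flagged = FALSE)
  }
  expect_identical(classifyNiche(mk(3, 3))$category, "generalist")
  expect_identical(classifyNiche(mk(3, -1))$category, "soil_specialist")
  expect_identical(classifyNiche(mk(-1, 3))$category, "digestate_specialist")
  expect_identical(classifyNiche(mk(-1, -1))$category, "washout")
  # the gap between thresholds is washout, not specialist
  expect_identical(classifyNiche(mk(3, 1))$category, "washout")
})

test_that("Ward clustering recovers planted clades and has monotone heights", {
  set.seed(5)
  # two planted profile groups, between-group distance >> within-group
  g1 <- matrix(rep(c(0.8, 0.1, 0.1), each = 10), nrow = 10) +
    matrix(rnorm(30, 0, 0.01), nrow = 10)
  g2 <- matrix(rep(c(0.05, 0.15, 0.8), each = 10), nrow = 10) +
    matrix(rnorm(30, 0, 0.01), nrow = 10)
  prof <- rbind(g1, g2)
  rownames(prof) <- paste0("OTU", 1:20)
  colnames(prof) <- paste0("s", 1:3)

  cm <- clusterClades(abs(prof), top_n = 20, n_clades = 2)
  cl <- cladeAssignments(cm)
  g1_cl <- cl[paste0("OTU", 1:10)]
  g2_cl <- cl[paste0("OTU", 11:20)]
  expect_identical(length(unique(g1_cl)), 1L)
  expect_identical(length(unique(g2_cl)), 1L)
  expect_false(g1_cl[[1]] == g2_cl[[1]])
  expect_true(all(diff(linkageTree(cm)$height) >= -1e-12))

  # identical profiles: all merge heights zero
  same <- matrix(0.5, nrow = 6, ncol = 3,
                 dimnames = list(paste0("O", 1:6), paste0("s", 1:3)))
  cm0 <- clusterClades(same, top_n = 6, n_clades = 1)
  expect_true(all(linkageTree(cm0)$height == 0))

  expect_error(clusterClades(same, top_n = 6, n_clades = 10), "n_clades")
})

test_that("SIMPER contributions match symmetry, brute force and vegan", {
  # two single-sample groups with disjoint OTUs: 50% each, dissimilarity 1
  rel <- cbind(a = c(1, 0), b = c(0, 1))
  rownames(rel) <- c("OTU1", "OTU2")
  sc <- simperContributions(rel, "a", "b")
  expect_equal(sort(sc$contribution_pct), c(50, 50))
  expect_equal(attr(sc, "overall_dissimilarity"), 1)

  # random toy table vs vegan's SIMPER (independent implementation)
  set.seed(9)
  cts <- matrix(rpois(24, 20) + 1, nrow = 6,
                dimnames = list(paste0("O", 1:6), paste0("s", 1:4)))
  rel <- sweep(cts, 2, colSums(cts), "/")
  ga <- c("s1", "s2"); gb <- c("s3", "s4")
  sc <- simperContributions(rel, ga, gb)
  expect_equal(sum(sc$contribution_pct), 100, tolerance = 1e-9)

  veg <- vegan::simper(t(rel), group = c("A", "A", "B", "B"))
  veg_sm <- summary(veg)$A_B
  veg_avg <- setNames(veg_sm$average, rownames(veg_sm))
  ours <- setNames(sc$mean_delta, sc$otu_id)[names(veg_avg)]
  expect_equal(unname(ours), unname(veg_avg), tolerance = 1e-10)

  # identical groups: flagged as undefined
  rel_same <- cbind(a = c(0.5, 0.5), b = c(0.5, 0.5))
  rownames(rel_same) <- c("OTU1", "OTU2")
  expect_warning(sc0 <- simperContributions(rel_same, "a", "b"), "identical")
  expect_true(all(is.na(sc0$contribution_pct)))

  expect_error(simperContributions(rel, character(0), gb), "non-empty")
})

test_that("PCA projects duplicates identically and preserves variance", {
  set.seed(3)
  rel <- matrix(runif(40), nrow = 8,
                dimnames = list(paste0("O", 1:8), paste0("s", 1:5)))
  rel <- sweep(rel, 2, colSums(rel), "/")
  dup <- cbind(rel, dup_of_s1 = rel[, "s1"])
  p <- communityPCA(dup)
  expect_equal(p$x["s1", ], p$x["dup_of_s1", ], tolerance = 1e-10)
  # total variance preserved across components
  expect_equal(sum(p$sdev^2), sum(apply(t(dup), 2, var)), tolerance = 1e-10)
})
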