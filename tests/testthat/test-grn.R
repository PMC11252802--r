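test_that("adjusted Rand index matches hand values and is label-invariant", {
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjustedRandIndex(1:3, 1:4), "equal length")
})

test_that("ARI equals brute-force pair counting on 200 random pairs", {
  set.seed(7)
  checkedAgainstMclust <- requireNamespace("mclust", quietly = TRUE)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b), ariPairOracle(a, b),
                 info = paste("instance", i))
    if (checkedAgainstMclust) {
      mARI <- mclust::adjustedRandIndex(a, b)
      # mclust yields NaN in the degenerate max == expected case, where the
      # pair-counting convention defines agreement as 1 (or 0)
      if (is.finite(mARI)) expect_equal(adjustedRandIndex(a, b), mARI)
    }
  }
})

test_that("dendrogram merges coincident points first, heights monotone", {
  x <- cbind(c1 = c(1, 1), c2 = c(1, 1), c3 = c(9, 9))
  dend <- clusterDendrogram(x)
  hc <- dend@hc
  expect_equal(hc$height[1], 0)
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))

  r <- matrix(rnorm(60), 4, 15, dimnames = list(NULL, paste0("c", 1:15)))
  expect_false(is.unsorted(clusterDendrogram(r)@hc$height))
  r[1, 1] <- NA
  expect_error(clusterDendrogram(r), "non-finite")
})

test_that("three well-separated blocks are recovered exactly at k = 3", {
  set.seed(12)
  centers <- diag(3) * 10
  x <- t(centers[rep(1:3, each = 20), ] + rnorm(180, sd = 0.2))
  colnames(x) <- paste0("c", 1:60)
  dend <- clusterDendrogram(x)
  labels <- cutree(dend@hc, k = 3)
  expect_equal(adjustedRandIndex(labels, rep(1:3, each = 20)), 1)
})

test_that("ARI-guided cut recovers the planted state count", {
  co <- plantedCohort(seed = 11)
  am <- cohortActivity(co)
  dend <- clusterDendrogram(am)
  p <- selectCutByARI(dend, am, kRange = 2:10, nResamples = 15, seed = 3)
  expect_identical(nGrns(p), 5L)
  expect_gt(adjustedRandIndex(grnLabels(p),
                              co$truth$stateOfCell[names(grnLabels(p))]),
            0.9)
  expect_identical(nrow(ariProfile(p)), 9L)
  expect_true(all(abs(ariProfile(p)$meanARI) <= 1))
  # cut height realizes the chosen k
  expect_identical(length(unique(cutree(p@dendrogram@hc,
                                        h = p@dendrogram@cutHeight))), 5L)

  # determinism under a fixed seed
  p2 <- selectCutByARI(dend, am, kRange = 2:10, nResamples = 15, seed = 3)
  expect_identical(ariProfile(p), ariProfile(p2))
  expect_identical(grnLabels(p), grnLabels(p2))
})

test_that("degenerate all-identical activity collapses to one GRN", {
  auc <- matrix(0.3, 4, 20, dimnames = list(paste0("r", 1:4),
                                            paste0("c", 1:20)))
  am <- new("ActivityMatrix",
            SummarizedExperiment(assays = list(auc = auc)))
  am <- zscaleClip(am)
  dend <- clusterDendrogram(am)
  expect_warning(p <- selectCutByARI(dend, am, kRange = 2:5), "degenerate")
  expect_identical(nGrns(p), 1L)
  expect_identical(nrow(ariProfile(p)), 0L)
})

test_that("RSS boundary cases and the numeric JSD oracle agree", {
  cells <- paste0("c", 1:8)
  labels <- setNames(rep(1:2, each = 4), cells)
  # activity exactly the uniform indicator of GRN 1 -> RSS 1 there, 0 on 2
  auc <- rbind(ind = c(rep(0.25, 4), rep(0, 4)))
  colnames(auc) <- cells
  rss <- regulonSpecificity(auc, labels)
  expect_equal(rss$rss[rss$grn == "1"], 1)
  expect_equal(rss$rss[rss$grn == "2"], 0)

  # uniform activity over all cells vs a half-support cluster
  aucU <- rbind(u = rep(1 / 8, 8)); colnames(aucU) <- cells
  rssU <- regulonSpecificity(aucU, labels)
  q <- c(rep(1 / 4, 4), rep(0, 4))
  expect_equal(rssU$rss[rssU$grn == "1"],
               1 - sqrt(jsdOracle(rep(1 / 8, 8), q)))

  # invariance to positive rescaling of the activity vector
  rssS <- regulonSpecificity(aucU * 37, labels)
  expect_equal(rssS$rss, rssU$rss)

  # all-zero regulon is NA with warning
  aucZ <- rbind(z = rep(0, 8), u = rep(1, 8)); colnames(aucZ) <- cells
  expect_warning(rssZ <- regulonSpecificity(aucZ, labels), "NA RSS")
  expect_true(all(is.na(rssZ$rss[rssZ$regulon == "z"])))
  expect_true(all(rssZ$rss >= 0 & rssZ$rss <= 1, na.rm = TRUE))
})

test_that("planted TF regulons rank first in their own GRN", {
  co <- plantedCohort(seed = 19)
  am <- cohortActivity(co)
  dend <- clusterDendrogram(am)
  p <- selectCutByARI(dend, am, kRange = 2:8, nResamples = 15, seed = 5)
  tab <- assignRegulons(am, p, nPerm = 200, seed = 4)
  expect_true(all(tab$p_adj >= tab$p, na.rm = TRUE))
  # map each GRN to its majority truth state; that state's regulon is rank 1
  labels <- grnLabels(p)
  for (g in unique(tab$grn)) {
    cells <- names(labels)[labels == as.integer(g)]
    state <- names(which.max(table(co$truth$stateOfCell[cells])))
    top <- tab$regulon[tab$grn == g & tab$rank == 1]
    expect_identical(top, state)
    expect_lt(tab$p_adj[tab$grn == g & tab$rank == 1], 0.05)
  }
})

test_that("permutation significance is calibrated under a null activity", {
  set.seed(77)
  cells <- sprintf("c%03d", 1:120)
  labels <- setNames(rep(1:3, each = 40), cells)
  auc <- matrix(runif(40 * 120), 40, 120,
                dimnames = list(sprintf("r%02d", 1:40), cells))
  tab <- assignRegulons(auc, labels, nPerm = 400, seed = 11)
  frac <- mean(tab$p_adj < 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / nrow(tab))
  expect_lte(frac, 0.05 + 2 * se)
})

test_that("patient hold-out leaves multi-patient GRNs intact", {
  co <- plantedCohort(seed = 23)  # alpha = 5: every state spans patients
  am <- cohortActivity(co)
  dend <- clusterDendrogram(am)
  p <- selectCutByARI(dend, am, kRange = 2:8, nResamples = 10, seed = 2)
  rob <- holdoutRobustness(am, p, co$truth$patientOfCell)
  expect_true(all(rob$ari > 0.8))
  expect_identical(nrow(rob), length(unique(co$truth$patientOfCell)))
})

test_that("GRN marker summary scales per gene and recovers couplings", {
  cells <- paste0("c", 1:30)
  labels <- setNames(rep(1:3, each = 10), cells)
  m <- matrix(0.5, 5, 30, dimnames = list(paste0("g", 1:5), cells))
  m["g1", labels == 2] <- 3  # expressed in exactly one GRN
  m["g2", ] <- 1             # constant
  sce <- sceFromLognorm(m)
  expect_warning(gs <- grnMarkerSummary(sce, labels, c("g1", "g2")),
                 "constant")
  s1 <- gs$summary[gs$summary$gene == "g1", ]
  expect_equal(s1$scaled[order(s1$grn)], c(0, 1, 0))
  s2 <- gs$summary[gs$summary$gene == "g2", ]
  expect_equal(s2$scaled, rep(0, 3))
  expect_error(grnMarkerSummary(sce, labels, "absent"), "absent")
})
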