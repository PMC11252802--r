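test_that("Lin's CCC matches hand computations and its CI behaves", {
  expect_equal(linCCC(c(1, 5, 9), c(1, 5, 9))$estimate, 1)
  expect_equal(linCCC(1:3, 2:4)$estimate, 4 / 7)
  expect_equal(linCCC(1:3, 3:1)$estimate, -1)
  set.seed(1)
  x <- rnorm(200); y <- 0.8 * x + rnorm(200, sd = 0.4)
  cc <- linCCC(x, y)
  expect_true(cc$ci_low <= cc$estimate && cc$estimate <= cc$ci_high)
  expect_error(linCCC(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("|CCC| <= |r|, with equality at matched moments", {
  set.seed(6)
  for (i in 1:100) {
    x <- rnorm(20); y <- rnorm(20) + runif(1, -2, 2)
    expect_lte(abs(linCCC(x, y)$estimate),
               abs(cor(x, y)) + 1e-12)
  }
  # equal means and variances: CCC == r exactly
  x <- rnorm(50)
  y <- sample(x)  # same marginal moments by construction
  expect_equal(linCCC(x, y)$estimate, cor(x, y))
})

test_that("Pearson wrapper handles exact fits and rejects constants", {
  x <- 1:10
  expect_equal(pearsonCorr(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearsonCorr(x, -x)$estimate, -1)
  expect_error(pearsonCorr(rep(1, 5), 1:5), "constant")
})

test_that("exact Wilcoxon matches the enumeration distribution", {
  # the worked example: complete separation of 3 vs 3
  res <- wilcoxonTest(1:3, 4:6)
  expect_equal(res$p, 0.1)
  expect_identical(res$method, "exact rank-sum")

  # against wilcox.test's exact p on tie-free random cases, n_x+n_y <= 8
  set.seed(12)
  for (i in 1:40) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    x <- sample(100, nx); y <- sample(100, ny) + 0.5
    expect_equal(wilcoxonTest(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 info = paste("instance", i))
  }

  # paired with all-zero differences is untestable, p = 1
  resP <- wilcoxonTest(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(resP$p, 1)
  expect_true(resP$untestable)

  # paired exact path agrees with wilcox.test on tie-free differences
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(8); y <- x + rnorm(8)
    expect_equal(wilcoxonTest(x, y, paired = TRUE)$p,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  }
  expect_identical(significanceTier(3e-5), "****")
  expect_error(wilcoxonTest(1:3, 1:4, paired = TRUE), "equal lengths")
})

test_that("Benjamini-Hochberg step-up closed forms hold", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjaminiHochberg(0.2), 0.2)
  set.seed(4)
  p <- runif(50)
  expect_true(all(benjaminiHochberg(p) >= p))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hurdle DE recovers planted shifts and keeps detection-only genes", {
  set.seed(21)
  nA <- 200; nB <- 200
  counts <- rbind(
    shifted = c(rnbinom(nA, mu = 8, size = 10), rnbinom(nB, mu = 2, size = 10)),
    detOnly = c(rnbinom(nA, mu = 2, size = 10), rep(0, nB)),
    flat = rnbinom(nA + nB, mu = 3, size = 10),
    dead = rep(0, nA + nB))
  colnames(counts) <- sprintf("c%03d", seq_len(nA + nB))
  # equal library sizes: keep the counts scale by skipping depth effects
  sce <- sceFromLognorm(log1p(counts))
  de <- hurdleDE(sce, colnames(counts)[1:nA], colnames(counts)[-(1:nA)])
  expect_false("dead" %in% de$gene)
  expect_identical(attr(de, "excluded"), "dead")

  row <- de[de$gene == "shifted", ]
  expect_lt(row$p_adj, 0.01)
  expect_lt(abs(row$log2FC - 2), 0.5)  # planted 4-fold on the mean

  rowD <- de[de$gene == "detOnly", ]
  expect_lt(rowD$p, 1e-6)          # detection part drives significance
  expect_true(is.finite(rowD$log2FC))
  expect_equal(rowD$det_frac_B, 0)

  rowF <- de[de$gene == "flat", ]
  expect_gt(rowF$p, 0.001)
  expect_lt(abs(rowF$log2FC), 0.5)
})

test_that("hurdle DE type-I error is nominal under the null", {
  co <- simulateCohort(cohortSimSpec(nStates = 2, cellsPerState = 200,
                                     genesPerRegulon = 2,
                                     nBackgroundGenes = 996,
                                     regulonEffect = 1, seed = 9))
  sce <- logNormalize(co$expr)
  cells <- colnames(sce)
  de <- hurdleDE(sce, cells[1:200], cells[201:400])
  for (alpha in c(0.01, 0.05)) {
    frac <- mean(de$p < alpha, na.rm = TRUE)
    se <- sqrt(alpha * (1 - alpha) / sum(!is.na(de$p)))
    expect_lt(abs(frac - alpha), 2 * se + 1e-9)
  }
  expect_lt(abs(median(de$log2FC)), 0.1)
})

test_that("Fisher overlap equals exhaustive enumeration for small universes", {
  u <- letters[1:20]
  res <- overlapFisher(letters[1:5], letters[1:5], u)
  expect_equal(res$p, 1 / choose(20, 5))
  expect_equal(res$nOverlap, 5)

  # disjoint small sets in a large universe: p near 1
  res0 <- overlapFisher(letters[1:3], letters[4:6], letters[1:26])
  expect_gt(res0$p, 0.5)

  # exhaustive oracle over all placements of B, |U| <= 12
  set.seed(8)
  for (i in 1:15) {
    U <- seq_len(sample(6:12, 1))
    A <- sample(U, sample(2:4, 1))
    B <- sample(U, sample(2:4, 1))
    k <- length(intersect(A, B))
    combos <- combn(length(U), length(B))
    exceed <- mean(apply(combos, 2, function(idx)
      length(intersect(U[idx], A)) >= k))
    expect_equal(overlapFisher(A, B, U)$p, exceed,
                 info = paste("instance", i))
  }
  expect_error(overlapFisher(c("a", "zz"), "a", letters[1:5]), "zz")
})

test_that("cross-cohort comparison recovers shared planted programs", {
  mkSpec <- function(states, seed)
    cohortSimSpec(nStates = 3, cellsPerState = 100, genesPerRegulon = 25,
                  nBackgroundGenes = 300, regulonEffect = 8,
                  stateNames = states, seed = seed)
  two <- simulateTwoCohorts(mkSpec(c("NE", "A1", "A2"), 31),
                            mkSpec(c("NE", "B1", "B2"), 32),
                            sharedStates = "NE")
  deOf <- function(co) {
    sce <- logNormalize(co$expr)
    inNE <- names(co$truth$stateOfCell)[co$truth$stateOfCell == "NE"]
    hurdleDE(sce, inNE, setdiff(colnames(sce), inNE))
  }
  de1 <- deOf(two$A); de2 <- deOf(two$B)
  cc <- crossCohortCompare(de1, de2, fcThreshold = 0.4, fdr = 0.05)
  sharedTargets <- two$A$regulons[["NE"]]
  expect_gte(length(intersect(cc$shared, sharedTargets)),
             0.8 * length(sharedTargets))
  expect_lt(cc$overlap$p, 1e-4)

  # private-state contrast as negative control
  privDE <- function(co, state) {
    sce <- logNormalize(co$expr)
    own <- names(co$truth$stateOfCell)[co$truth$stateOfCell == state]
    hurdleDE(sce, own, setdiff(colnames(sce), own))
  }
  ccPriv <- crossCohortCompare(privDE(two$A, "A1"), privDE(two$B, "B1"),
                               fcThreshold = 0.4, fdr = 0.05)
  expect_gt(ccPriv$overlap$p, 0.05)

  # infinite threshold empties both sets, p = 1
  ccInf <- crossCohortCompare(de1, de2, fcThreshold = Inf)
  expect_length(ccInf$shared, 0)
  expect_equal(ccInf$overlap$p, 1)
})
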