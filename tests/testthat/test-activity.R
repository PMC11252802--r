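test_that("AUCell hits its closed-form boundary and toy values", {
  # regulon occupying the very top of the ranking scores exactly 1
  x <- matrix(10:1, ncol = 1, dimnames = list(paste0("g", 1:10), "c1"))
  sce <- sceFromLognorm(x)
  top3 <- RegulonSet(list(R = c("g1", "g2", "g3")))
  am <- aucellScore(sce, top3, topFraction = 0.5)
  expect_equal(assay(am, "auc")["R", "c1"], 1)

  # regulon entirely below rank T scores 0
  bottom <- RegulonSet(list(R = c("g9", "g10")))
  am0 <- aucellScore(sce, bottom, topFraction = 0.5)
  expect_equal(assay(am0, "auc")["R", "c1"], 0)

  # hand-enumerated toy: T = 5, regulon genes at ranks 1 and 3 -> 8/9
  toy <- RegulonSet(list(R = c("g1", "g3")))
  amT <- aucellScore(sce, toy, topFraction = 0.5)
  expect_equal(assay(amT, "auc")["R", "c1"], 8 / 9)

  # regulon with no gene present is NA with warning, not 0
  expect_warning(
    amN <- aucellScore(sce, RegulonSet(list(R = "g1", Z = "absent"))),
    "NA")
  expect_true(is.na(assay(amN, "auc")["Z", "c1"]))
})

test_that("AUCell equals the brute-force recovery-curve oracle", {
  set.seed(42)
  for (i in 1:100) {
    nGenes <- sample(8:40, 1)
    nCells <- sample(1:4, 1)
    m <- matrix(sample(0:5, nGenes * nCells, replace = TRUE) +
                  round(runif(nGenes * nCells), 2),
                nGenes, nCells,
                dimnames = list(sprintf("g%02d", 1:nGenes),
                                sprintf("c%d", 1:nCells)))
    reg <- sample(rownames(m), sample(2:5, 1))
    tf <- runif(1, 0.2, 1)
    am <- aucellScore(sceFromLognorm(m), RegulonSet(list(R = reg)),
                      topFraction = tf, tieMethod = "stable")
    for (j in seq_len(nCells)) {
      expect_equal(assay(am, "auc")["R", j],
                   aucellOracle(m[, j], reg, tf),
                   info = sprintf("instance %d cell %d", i, j))
    }
  }
})

test_that("AUCell is invariant to monotone transforms of a cell", {
  m <- randomLognorm(50, 8, seed = 5)
  reg <- RegulonSet(list(R = rownames(m)[c(3, 11, 27)]))
  a1 <- assay(aucellScore(sceFromLognorm(m), reg, tieSeed = 2), "auc")
  a2 <- assay(aucellScore(sceFromLognorm(exp(m) + 5), reg, tieSeed = 2),
              "auc")
  expect_equal(a1, a2)
})

test_that("z-scaling centres, clips, and zeroes constant regulons", {
  auc <- rbind(const = rep(0.4, 10),
               spread = c(rep(0.1, 9), 0.9),
               normal = seq(0.1, 0.55, length.out = 10))
  colnames(auc) <- paste0("c", 1:10)
  am <- new("ActivityMatrix",
            SummarizedExperiment(assays = list(auc = auc)))
  sc <- scaledActivity(zscaleClip(am, zclip = 2))
  expect_equal(unname(sc["const", ]), rep(0, 10))
  expect_equal(unname(sc["spread", 10]), 2)  # outlier lands on the clip
  z <- sc["normal", ]
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-6)
  # single cell: sd undefined
  am1 <- new("ActivityMatrix",
             SummarizedExperiment(assays = list(auc = auc[, 1, drop = FALSE])))
  expect_error(zscaleClip(am1), "2 cells")
})

test_that("module score is 0 under exchangeability and positive for top genes", {
  m <- matrix(3, 40, 6, dimnames = list(sprintf("g%02d", 1:40),
                                        paste0("c", 1:6)))
  s <- moduleScore(sceFromLognorm(m), c("g01", "g05"), nBins = 5)
  expect_equal(unname(s), rep(0, 6))

  m2 <- randomLognorm(50, 6, seed = 8)
  m2["g001", ] <- m2["g001", ] + 10  # dominant gene
  s2 <- moduleScore(sceFromLognorm(m2), "g001", nBins = 10, seed = 1)
  expect_true(all(s2 > 0))
  expect_error(moduleScore(sceFromLognorm(m2), c("nope1", "nope2")),
               "nope1")
})

test_that("module score is stable across control-sampling seeds", {
  m <- randomLognorm(200, 40, seed = 9)
  set <- rownames(m)[1:10]
  m[set, 1:20] <- m[set, 1:20] + 1.5
  s1 <- moduleScore(sceFromLognorm(m), set, seed = 1)
  s2 <- moduleScore(sceFromLognorm(m), set, seed = 2)
  expect_gt(cor(s1, s2), 0.9)
})

test_that("diffusion imputation: identity at t=0 and fixed point on clones", {
  m <- randomLognorm(20, 12, seed = 2)
  sce <- sceFromLognorm(m)
  out0 <- assay(diffuseImpute(sce, k = 3, t = 0), "imputed")
  expect_identical(out0, m)

  clones <- matrix(rep(m[, 1], 8), ncol = 8,
                   dimnames = list(rownames(m), paste0("c", 1:8)))
  outC <- assay(diffuseImpute(sceFromLognorm(clones), k = 3, t = 1),
                "imputed")
  expect_equal(outC, clones)

  expect_error(diffuseImpute(sce, k = 12), "smaller")
})

test_that("two-cell diffusion matches the hand-derived Markov matrix", {
  # distinct cells, k = 1: bandwidth is the neighbour distance, so the
  # kernel gives self weight 1 and neighbour weight exp(-1); the
  # row-normalized Markov rows are (1, e^-1)/(1 + e^-1)
  m <- matrix(c(0, 0, 2, 2), nrow = 2,
              dimnames = list(c("gA", "gB"), c("c1", "c2")))
  out <- assay(diffuseImpute(sceFromLognorm(m), k = 1, t = 1, nPcs = 2),
               "imputed")
  w <- exp(-1) / (1 + exp(-1))
  expected <- cbind(c1 = m[, 1] * (1 - w) + m[, 2] * w,
                    c2 = m[, 1] * w + m[, 2] * (1 - w))
  expect_equal(out, expected)
})

test_that("diffusion preserves ranges and denoises toward planted means", {
  set.seed(31)
  # two blobs with distinct means plus heavy noise/dropout
  meanA <- rep(c(4, 0.2), each = 15)
  meanB <- rep(c(0.2, 4), each = 15)
  mu <- cbind(matrix(meanA, 30, 40), matrix(meanB, 30, 40))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 0.8), 30, 80,
                   dimnames = list(sprintf("g%02d", 1:30),
                                   sprintf("c%02d", 1:80)))
  sce <- logNormalize(sceFromCounts(counts))
  imp <- assay(diffuseImpute(sce, k = 10, t = 1, nPcs = 10), "imputed")
  raw <- assay(sce, "lognorm")
  expect_true(all(imp >= apply(raw, 1, min) - 1e-9))
  expect_true(all(imp <= apply(raw, 1, max) + 1e-9))
  # truth on the lognorm scale: the noiseless per-blob mean profile
  target <- cbind(matrix(rowMeans(raw[, 1:40]), 30, 40),
                  matrix(rowMeans(raw[, 41:80]), 30, 40))
  mse <- function(x) mean((x - target)^2)
  expect_lt(mse(imp), mse(raw))
})
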