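# Shared in-code fixtures; everything is generated at test time.

suppressPackageStartupMessages({
  library(SingleCellExperiment)
  library(SummarizedExperiment)
})

# Expression container straight from a lognorm matrix.
sceFromLognorm <- function(m) {
  SingleCellExperiment(assays = list(lognorm = m))
}

sceFromCounts <- function(m) {
  SingleCellExperiment(assays = list(counts = m))
}

# Small deterministic lognorm matrix (genes x cells).
randomLognorm <- function(nGenes, nCells, seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(nGenes * nCells)), nGenes, nCells,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("c%03d", seq_len(nCells))))
  m
}

# The standard planted five-state cohort used across the discovery tests:
# defaults of cohortSimSpec() (600 cells, 590 genes, effect 8).
plantedCohort <- function(seed = 11) simulateCohort(cohortSimSpec(seed = seed))

# Run simulate -> lognorm -> aucell -> scale for a cohort.
cohortActivity <- function(cohort, topFraction = 0.05, tieSeed = 7) {
  sce <- logNormalize(cohort$expr)
  zscaleClip(aucellScore(sce, cohort$regulons, topFraction = topFraction,
                         tieSeed = tieSeed))
}

# Independent recovery-curve oracle for AUCell: walks the full ranking and
# sums the hit curve explicitly.
aucellOracle <- function(x, regulonGenes, topFraction) {
  n <- length(x)
  Ttop <- ceiling(topFraction * n)
  ord <- order(-x, seq_len(n))  # stable tie-break, matches tieMethod="stable"
  isHit <- names(x)[ord] %in% regulonGenes
  hits <- cumsum(isHit)
  m <- sum(names(x) %in% regulonGenes)
  sum(hits[seq_len(Ttop)]) / sum(pmin(seq_len(Ttop), m))
}

# Brute-force pair-counting ARI oracle.
ariPairOracle <- function(a, b) {
  n <- length(a)
  agree <- disagree <- 0
  sameA <- outer(a, a, "==")
  sameB <- outer(b, b, "==")
  upper <- upper.tri(sameA)
  concord <- sum((sameA == sameB)[upper])
  # ARI from pair counts: (observed concordant - expected) / (max - expected)
  n11 <- sum((sameA & sameB)[upper])
  n00 <- sum((!sameA & !sameB)[upper])
  n10 <- sum((sameA & !sameB)[upper])
  n01 <- sum((!sameA & sameB)[upper])
  total <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / total
  maxIdx <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxIdx == expected) return(ifelse(n11 == expected, 1, 0))
  (n11 - expected) / (maxIdx - expected)
}

# Direct Jensen-Shannon divergence (base-2) summation oracle.
jsdOracle <- function(p, q) {
  m <- (p + q) / 2
  term <- function(a) sum(ifelse(a > 0, a * log2(a / m), 0))
  (term(p) + term(q)) / 2
}
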