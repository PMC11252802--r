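#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement from the contingency table:
#' `ARI = (Index - E[Index]) / (Max - E[Index])`. Equals 1 exactly when the
#' partitions are identical up to relabeling, and is invariant to any
#' bijective relabeling of either side.
#'
#' @param a,b label vectors of equal length >= 2 (any atomic type).
#' @return numeric ARI in [-1, 1].
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (length(a) < 2L) stop("need at least 2 observations")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(ch2(tab))
  sumA <- sum(ch2(rowSums(tab)))
  sumB <- sum(ch2(colSums(tab)))
  nPairs <- ch2(length(a))
  expected <- sumA * sumB / nPairs
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(ifelse(sumIJ == expected, 1, 0))
  (sumIJ - expected) / (maxIdx - expected)
}

#' Hierarchical clustering of cells on scaled regulon activity
#'
#' Ward linkage on Euclidean distances over the z-scaled, clipped activity
#' view; deterministic given the input. The merge record is returned as a
#' [DendrogramModel-class] ready for cut selection.
#'
#' @param am an [ActivityMatrix-class] with a `"scaled"` assay (or a plain
#'   cells-in-columns matrix).
#' @param metric distance metric (only `"euclidean"` is offered).
#' @param linkage an `hclust` method (default `"ward.D2"`).
#' @return a [DendrogramModel-class].
#' @export
clusterDendrogram <- function(am, metric = "euclidean",
                              linkage = "ward.D2") {
  x <- if (is(am, "ActivityMatrix")) scaledActivity(am) else as.matrix(am)
  if (!all(is.finite(x))) stop("non-finite values in activity matrix")
  hc <- stats::hclust(stats::dist(t(x), method = metric), method = linkage)
  new("DendrogramModel", hc = hc, metric = metric, linkage = linkage,
      cutHeight = NA_real_, nClusters = NA_integer_)
}

# Subsampling-stability reclustering for one candidate k.
.resampleARI <- function(x, full, k, nResamples, subsampleFrac, linkage) {
  n <- nrow(x)
  vapply(seq_len(nResamples), function(r) {
    idx <- sample.int(n, max(2L, floor(subsampleFrac * n)))
    hcSub <- stats::hclust(stats::dist(x[idx, , drop = FALSE]),
                           method = linkage)
    adjustedRandIndex(full[idx], stats::cutree(hcSub, k = k))
  }, numeric(1))
}

#' Select the dendrogram cut by resampling-stability ARI
#'
#' For each candidate number of clusters k, the full-dendrogram partition
#' is compared (adjusted Rand index) against reclusterings of random
#' `subsampleFrac` subsets, restricted to the subset. The chosen k
#' maximizes the mean ARI, ties broken toward smaller k, and the cut height
#' realizing k is recorded. Degenerate inputs (all cells identical)
#' return a single GRN with an empty profile and a warning.
#'
#' @param dend a [DendrogramModel-class] from [clusterDendrogram()].
#' @param am the [ActivityMatrix-class] (with `"scaled"` assay) or matrix
#'   the dendrogram was built on.
#' @param kRange candidate cluster numbers (default 2:15).
#' @param nResamples reclustered subsets per candidate (default 20).
#' @param subsampleFrac fraction of cells per subset (default 0.8).
#' @param seed seed for the resampling.
#' @return a [GRNPartition-class].
#' @export
selectCutByARI <- function(dend, am, kRange = 2:15, nResamples = 20L,
                           subsampleFrac = 0.8, seed = 1L) {
  stopifnot(is(dend, "DendrogramModel"))
  x <- if (is(am, "ActivityMatrix")) t(scaledActivity(am)) else t(as.matrix(am))
  hc <- dend@hc
  n <- nrow(x)
  if (any(kRange < 2L) || any(kRange > n - 1L))
    stop("kRange must lie within [2, nCells - 1]")
  cellIds <- if (!is.null(rownames(x))) rownames(x) else hc$labels
  if (all(stats::dist(x) == 0)) {
    warning("degenerate activity (all cells identical): single GRN")
    labels <- rep(1L, n); names(labels) <- cellIds
    return(new("GRNPartition", labels = labels, nGrns = 1L,
               dendrogram = dend,
               ariProfile = data.frame(k = integer(), meanARI = numeric(),
                                       sdARI = numeric())))
  }
  set.seed(seed)
  prof <- lapply(kRange, function(k) {
    full <- stats::cutree(hc, k = k)
    ari <- .resampleARI(x, full, k, nResamples, subsampleFrac,
                        dend@linkage)
    c(meanARI = mean(ari), sdARI = stats::sd(ari))
  })
  prof <- data.frame(k = kRange, do.call(rbind, prof))
  best <- prof$k[which.max(prof$meanARI)]  # which.max takes first = smallest k
  labels <- stats::cutree(hc, k = best)
  names(labels) <- cellIds
  # k clusters are realized for any cut height in (h[n-k], h[n-k+1])
  heights <- sort(hc$height)
  dend@cutHeight <- (heights[n - best] + heights[n - best + 1L]) / 2
  dend@nClusters <- as.integer(best)
  labels <- stats::setNames(as.integer(labels), cellIds)
  new("GRNPartition", labels = labels, nGrns = as.integer(best),
      dendrogram = dend, ariProfile = prof)
}

# Jensen-Shannon divergence with base-2 logs; p, q sum to 1. Bounded [0,1].
.jsd2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / m[nz]))
  }
  (kl(p) + kl(q)) / 2
}

# RSS as a regulons x GRNs matrix; rows with no usable activity are NA.
# Vectorized over regulons for the permutation test.
.rssMatrix <- function(auc, labels) {
  rs <- rowSums(auc, na.rm = TRUE)
  dead <- rs == 0 | rowSums(is.na(auc)) > 0
  P <- auc / ifelse(rs > 0, rs, 1)
  grns <- sort(unique(labels))
  out <- matrix(NA_real_, nrow(auc), length(grns),
                dimnames = list(rownames(auc), as.character(grns)))
  for (gi in seq_along(grns)) {
    inC <- labels == grns[gi]
    q <- as.numeric(inC) / sum(inC)
    Q <- matrix(q, nrow(auc), ncol(auc), byrow = TRUE)
    M <- (P + Q) / 2
    T1 <- P * log2(P / M); T1[P == 0] <- 0
    T2 <- Q * log2(Q / M); T2[Q == 0] <- 0
    jsd <- (rowSums(T1) + rowSums(T2)) / 2
    out[, gi] <- 1 - sqrt(pmax(jsd, 0))
  }
  out[dead, ] <- NA_real_
  out
}

#' Regulon specificity score (RSS) per regulon and GRN
#'
#' For regulon R and GRN C, the regulon's raw (non-negative) activity over
#' cells is normalized to a distribution p_R, compared with the uniform
#' indicator distribution of C via the Jensen-Shannon divergence with
#' base-2 logarithms (so JSD is in [0, 1]), and
#' `RSS = 1 - sqrt(JSD)` in [0, 1]: 1 for a regulon active uniformly on
#' exactly C, 0 for activity supported entirely outside C. RSS is invariant
#' to positive rescaling of a regulon's activity vector. All-zero regulons
#' are reported `NA` with a warning.
#'
#' @param am an [ActivityMatrix-class] (raw `"auc"` assay is used).
#' @param partition a [GRNPartition-class] (or named label vector) covering
#'   the scored cells.
#' @return data.frame with columns `regulon`, `grn`, `rss`.
#' @export
regulonSpecificity <- function(am, partition) {
  auc <- if (is(am, "ActivityMatrix"))
    SummarizedExperiment::assay(am, "auc") else as.matrix(am)
  labels <- if (is(partition, "GRNPartition")) grnLabels(partition)
            else partition
  if (!all(colnames(auc) %in% names(labels)))
    stop("partition does not cover all scored cells")
  labels <- labels[colnames(auc)]
  if (any(auc < 0, na.rm = TRUE)) stop("RSS requires non-negative activity")
  dead <- rowSums(auc, na.rm = TRUE) == 0 | rowSums(is.na(auc)) > 0
  if (any(dead))
    warning("regulon(s) with no usable activity get NA RSS: ",
            paste(rownames(auc)[dead], collapse = ", "))
  rssM <- .rssMatrix(auc, labels)
  grns <- colnames(rssM)
  data.frame(regulon = rep(rownames(rssM), times = length(grns)),
             grn = rep(grns, each = nrow(rssM)),
             rss = as.vector(rssM), stringsAsFactors = FALSE)
}

#' Rank regulons within GRNs with permutation significance
#'
#' Empirical p-values per (regulon, GRN) from label permutations of the
#' partition (`p = (1 + #{perm RSS >= observed}) / (nPerm + 1)`),
#' Benjamini-Hochberg adjusted across regulons within each GRN; regulons
#' ranked by RSS within GRN and the top `topN` flagged.
#'
#' @param am an [ActivityMatrix-class].
#' @param partition a [GRNPartition-class] or named label vector.
#' @param nPerm label permutations (default 1000; below 100 a warning about
#'   the 1/nPerm resolution limit is issued).
#' @param topN regulons reported as leading per GRN (default 10).
#' @param seed permutation seed.
#' @return data.frame with columns `regulon`, `grn`, `rss`, `rank`, `p`,
#'   `p_adj`, `top`.
#' @export
assignRegulons <- function(am, partition, nPerm = 1000L, topN = 10L,
                           seed = 1L) {
  if (nPerm < 100L)
    warning("nPerm < 100: empirical p resolution limited to 1/",
            nPerm)
  auc <- if (is(am, "ActivityMatrix"))
    SummarizedExperiment::assay(am, "auc") else as.matrix(am)
  labels <- if (is(partition, "GRNPartition")) grnLabels(partition)
            else partition
  labels <- labels[colnames(auc)]
  obs <- regulonSpecificity(auc, labels)
  obsM <- .rssMatrix(auc, labels)
  set.seed(seed)
  exceed <- matrix(0, nrow(obsM), ncol(obsM))
  for (b in seq_len(nPerm)) {
    permM <- .rssMatrix(auc, sample(as.vector(labels)))
    exceed <- exceed + (!is.na(permM) & !is.na(obsM) & permM >= obsM)
  }
  pM <- (1 + exceed) / (nPerm + 1)
  pM[is.na(obsM)] <- NA_real_
  obs$p <- as.vector(pM)
  obs$p_adj <- NA_real_
  obs$rank <- NA_integer_
  for (g in unique(obs$grn)) {
    sel <- obs$grn == g
    obs$p_adj[sel] <- stats::p.adjust(obs$p[sel], method = "BH")
    obs$rank[sel] <- rank(-obs$rss[sel], ties.method = "first",
                          na.last = "keep")
  }
  obs$top <- !is.na(obs$rank) & obs$rank <= topN
  obs[order(obs$grn, obs$rank), ]
}

#' Leave-one-unit-out robustness of a GRN partition
#'
#' For each unit (cell group, e.g. patient): cells of the unit are removed,
#' the remaining cells are reclustered at the original number of GRNs, and
#' the adjusted Rand index against the original partition restricted to the
#' retained cells is reported.
#'
#' @param am the [ActivityMatrix-class] (with `"scaled"` assay) the
#'   partition was built on.
#' @param partition a [GRNPartition-class].
#' @param unitLabels named vector, cell id -> unit.
#' @return data.frame with columns `unit`, `nRemoved`, `ari`.
#' @export
holdoutRobustness <- function(am, partition, unitLabels) {
  x <- t(scaledActivity(am))
  labels <- grnLabels(partition)
  units <- unique(unitLabels[rownames(x)])
  if (length(units) < 2L) stop("need at least 2 units")
  res <- lapply(units, function(u) {
    keep <- rownames(x)[unitLabels[rownames(x)] != u]
    if (!length(keep)) stop("unit ", u, " contains all cells")
    if (length(keep) == nrow(x)) {
      warning("unit ", u, " has zero cells; skipped")
      return(NULL)
    }
    hc <- stats::hclust(stats::dist(x[keep, , drop = FALSE]),
                        method = partition@dendrogram@linkage)
    k <- min(nGrns(partition), length(keep) - 1L)
    re <- stats::cutree(hc, k = k)
    data.frame(unit = u, nRemoved = nrow(x) - length(keep),
               ari = adjustedRandIndex(labels[keep], re))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-GRN marker and module-score summary
#'
#' Computes per-GRN mean log-normalized expression of the requested genes,
#' min-max scales each gene across GRNs to [0, 1] (constant genes are
#' reported all-0 with a warning), per-GRN mean module scores for each gene
#' set, and the Pearson r and Lin's concordance correlation between each
#' gene's scaled per-GRN expression and each module score over the
#' GRN-level points.
#'
#' @param sce expression object with a `"lognorm"` assay.
#' @param partition a [GRNPartition-class] or named label vector.
#' @param genes character vector of genes to summarize (must be present).
#' @param moduleSets named list of gene sets for [moduleScore()].
#' @param seed seed for module-score control sampling.
#' @return list with `summary` (long data.frame grn x gene: `mean`,
#'   `scaled`), `moduleScores` (data.frame grn x set means), and
#'   `correlations` (gene x set: `pearson`, `ccc`).
#' @export
grnMarkerSummary <- function(sce, partition, genes,
                             moduleSets = list(), seed = 1L) {
  expr <- .getLayer(sce, "lognorm")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("genes absent from expression: ", paste(missing, collapse = ", "))
  labels <- if (is(partition, "GRNPartition")) grnLabels(partition)
            else partition
  labels <- labels[colnames(expr)]
  grns <- sort(unique(labels))
  if (any(vapply(grns, function(g) sum(labels == g), integer(1)) == 0L))
    stop("GRN with zero cells")
  meanExpr <- vapply(grns, function(g)
    rowMeans(expr[genes, labels == g, drop = FALSE]), numeric(length(genes)))
  meanExpr <- matrix(meanExpr, nrow = length(genes),
                     dimnames = list(genes, grns))
  scaled <- t(apply(meanExpr, 1, function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0, length(v)))
    (v - rng[1]) / diff(rng)
  }))
  if (any(apply(meanExpr, 1, function(v) diff(range(v)) == 0)))
    warning("constant gene(s) across GRNs reported as all-0 scaled values")
  dimnames(scaled) <- dimnames(meanExpr)

  msGrn <- NULL
  if (length(moduleSets)) {
    ms <- vapply(names(moduleSets), function(nm)
      moduleScore(sce, moduleSets[[nm]],
                  seed = stageSeed(seed, paste0("module.", nm))),
      numeric(ncol(expr)))
    msGrn <- vapply(grns, function(g)
      colMeans(ms[labels == g, , drop = FALSE]),
      numeric(length(moduleSets)))
    msGrn <- matrix(msGrn, nrow = length(moduleSets),
                    dimnames = list(names(moduleSets), grns))
  }
  correlations <- NULL
  if (!is.null(msGrn)) {
    correlations <- do.call(rbind, lapply(genes, function(g)
      do.call(rbind, lapply(rownames(msGrn), function(s) {
        x <- msGrn[s, ]; y <- scaled[g, ]
        pear <- if (stats::sd(x) > 0 && stats::sd(y) > 0)
          stats::cor(x, y) else NA_real_
        ccc <- tryCatch(linCCC(x, y)$estimate, error = function(e) NA_real_)
        data.frame(gene = g, set = s, pearson = pear, ccc = ccc)
      }))))
  }
  summary <- data.frame(
    grn = rep(grns, each = length(genes)),
    gene = rep(genes, times = length(grns)),
    mean = as.vector(meanExpr), scaled = as.vector(scaled))
  list(summary = summary, moduleScores = msGrn,
       correlations = correlations)
}
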