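#' Graph-based clustering of cells (PhenoGraph-style)
#'
#' PCA over the log-normalized expression (or any cells-in-columns matrix),
#' shared-nearest-neighbour graph with Jaccard edge weights, and seeded
#' Louvain modularity optimization.
#'
#' @param sce expression object with a `"lognorm"` assay, or a matrix.
#' @param k neighbours (default 30); must be < number of cells.
#' @param nPcs principal components (default 30).
#' @param resolution Louvain resolution (default 1).
#' @param seed seed for the community detection.
#' @return named integer vector, cell id -> cluster.
#' @export
knnGraphCluster <- function(sce, k = 30L, nPcs = 30L, resolution = 1.0,
                            seed = 1L) {
  x <- if (is.matrix(sce)) sce else .getLayer(sce, "lognorm")
  if (k >= ncol(x)) stop("k must be smaller than the number of cells")
  pcs <- .pcaScores(x, nPcs)
  g <- scran::buildSNNGraph(pcs, k = k, transposed = TRUE,
                            type = "jaccard")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  stats::setNames(as.integer(igraph::membership(cl)), colnames(x))
}

#' Shannon entropy of a frequency vector
#'
#' `H = -sum(p * ln p)` with `0 * ln 0 = 0`, natural logarithm. Frequencies
#' off unit sum by more than 1e-6 are renormalized with a warning.
#'
#' @param p non-negative frequencies.
#' @return entropy in nats, in `[0, ln(length(p))]`.
#' @examples
#' shannonEntropy(c(0.5, 0.5))  # ln 2
#' @export
shannonEntropy <- function(p) {
  if (any(p < 0)) stop("negative frequency")
  s <- sum(p)
  if (s == 0) stop("frequencies sum to zero")
  if (abs(s - 1) > 1e-6) {
    warning("frequencies renormalized (sum was ", format(s), ")")
  }
  p <- p / s
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Cluster-balanced resampled patient entropy
#'
#' For each cluster, `nReps` subsamples of `nPerCluster` cells are drawn
#' with replacement (so clusters smaller than `nPerCluster` are still
#' resampled) and the Shannon entropy of the patient frequencies of each
#' subsample is recorded — controlling for unequal cluster sizes when
#' comparing patient diversity across cell phenotypes. Low entropy means a
#' patient-specific cluster; entropy near `ln(nPatients)` means a shared,
#' multi-patient phenotype.
#'
#' @param clusters named vector, cell id -> cluster.
#' @param patients named vector, cell id -> patient.
#' @param nPerCluster cells per draw (default 100).
#' @param nReps draws per cluster (default 100).
#' @param seed resampling seed.
#' @return list with `reps` (data.frame `cluster`, `rep`, `entropy`) and
#'   `summary` (data.frame `cluster`, `n`, `mean`, `sd`).
#' @export
subsampledEntropy <- function(clusters, patients, nPerCluster = 100L,
                              nReps = 100L, seed = 1L) {
  if (!length(clusters)) stop("empty clustering")
  common <- intersect(names(clusters), names(patients))
  if (!length(common)) stop("clusters and patients share no cell ids")
  clusters <- clusters[common]; patients <- patients[common]
  set.seed(seed)
  reps <- lapply(sort(unique(clusters)), function(cl) {
    cells <- names(clusters)[clusters == cl]
    if (!length(cells)) {
      warning("cluster ", cl, " has zero cells; skipped")
      return(NULL)
    }
    ent <- vapply(seq_len(nReps), function(r) {
      draw <- sample(patients[cells], nPerCluster, replace = TRUE)
      shannonEntropy(table(draw) / nPerCluster)
    }, numeric(1))
    data.frame(cluster = cl, rep = seq_len(nReps), entropy = ent)
  })
  reps <- do.call(rbind, reps)
  summary <- do.call(rbind, lapply(split(reps, reps$cluster), function(d)
    data.frame(cluster = d$cluster[1],
               n = sum(clusters == d$cluster[1]),
               mean = mean(d$entropy), sd = stats::sd(d$entropy))))
  rownames(summary) <- NULL
  list(reps = reps, summary = summary)
}

#' Compare resampled entropy between cluster groups
#'
#' Pairwise two-sided Wilcoxon rank-based tests on the per-cluster mean
#' entropies of each group (rank-sum for the unpaired cluster sets;
#' exact for small samples via [wilcoxonTest()]), with the conventional
#' significance tier labels.
#'
#' @param entropyResult a [subsampledEntropy()] result.
#' @param grouping named vector, cluster -> group (e.g. disease category).
#' @return data.frame: `groupA`, `groupB`, medians, `statistic`, `p`,
#'   `tier` (`"untestable"` when a group has a single cluster and no test
#'   is possible).
#' @export
compareEntropy <- function(entropyResult, grouping) {
  s <- entropyResult$summary
  s$group <- grouping[as.character(s$cluster)]
  if (anyNA(s$group)) stop("grouping does not cover all clusters")
  groups <- sort(unique(s$group))
  if (length(groups) < 2L) stop("need at least 2 groups")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    x <- s$mean[s$group == pr[1]]
    y <- s$mean[s$group == pr[2]]
    res <- tryCatch(wilcoxonTest(x, y, paired = FALSE),
                    error = function(e) NULL)
    data.frame(groupA = pr[1], groupB = pr[2],
               medianA = stats::median(x), medianB = stats::median(y),
               statistic = if (is.null(res)) NA_real_ else res$statistic,
               p = if (is.null(res)) NA_real_ else res$p,
               tier = if (is.null(res)) "untestable" else res$tier)
  })
  do.call(rbind, out)
}
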