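#' AUCell-style regulon activity scoring
#'
#' Per cell, genes are ranked by descending expression (ties broken by a
#' seeded random permutation, or by stable gene order for exact
#' reproducibility) and the regulon's recovery curve is integrated over the
#' top `topFraction` of the ranking: with `T = ceiling(topFraction *
#' nGenes)` and `hits(r)` the number of regulon genes at rank <= r, the raw
#' AUC is `sum_{r=1..T} hits(r)`, normalized by its maximum
#' `sum_{r=1..T} min(r, m)` where `m` is the number of regulon genes present
#' in the matrix. Activities lie in [0, 1]; being rank-based they are
#' invariant to any monotone transform of a cell's expression values.
#' Regulons with no genes present are reported as `NA` with a warning,
#' never as 0.
#'
#' @param sce expression object with a `"lognorm"` assay.
#' @param regulons a [RegulonSet-class].
#' @param topFraction fraction of the ranking scanned, in (0, 1].
#' @param tieMethod `"random"` (seeded permutation) or `"stable"`
#'   (deterministic by gene order).
#' @param tieSeed seed for the tie-breaking permutation.
#' @return an [ActivityMatrix-class] (regulons x cells, assay `"auc"`).
#' @export
aucellScore <- function(sce, regulons, topFraction = 0.05,
                        tieMethod = c("random", "stable"), tieSeed = 1L) {
  tieMethod <- match.arg(tieMethod)
  stopifnot(topFraction > 0, topFraction <= 1)
  expr <- .getLayer(sce, "lognorm")
  nGenes <- nrow(expr); nCells <- ncol(expr)
  Ttop <- as.integer(ceiling(topFraction * nGenes))

  present <- lapply(regulonTargets(regulons),
                    function(g) which(rownames(expr) %in% g))
  m <- lengths(present)
  if (all(m == 0)) stop("no regulon gene present in the expression matrix")
  if (any(m == 0))
    warning("regulon(s) with no genes present scored as NA: ",
            paste(names(regulons)[m == 0], collapse = ", "))

  tb <- if (tieMethod == "random") {
    set.seed(tieSeed)
    sample.int(nGenes)
  } else seq_len(nGenes)

  maxAuc <- vapply(m, function(mi)
    sum(pmin(seq_len(Ttop), mi)), numeric(1))

  auc <- matrix(NA_real_, nrow = length(regulons), ncol = nCells,
                dimnames = list(names(regulons), colnames(expr)))
  ranks <- integer(nGenes)
  for (j in seq_len(nCells)) {
    ord <- order(-expr[, j], tb)
    ranks[ord] <- seq_len(nGenes)
    for (i in seq_along(present)) {
      if (m[i] == 0) next
      r <- ranks[present[[i]]]
      r <- r[r <= Ttop]
      # a regulon gene at rank r contributes to hits(r..T)
      auc[i, j] <- sum(Ttop - r + 1) / maxAuc[i]
    }
  }
  am <- new("ActivityMatrix", SummarizedExperiment::SummarizedExperiment(
    assays = list(auc = auc)))
  S4Vectors::metadata(am) <- list(topFraction = topFraction,
                                  tieMethod = tieMethod, tieSeed = tieSeed)
  am
}

#' Per-regulon z-scaling with clipping
#'
#' Each regulon's activities are centred and scaled across cells, then
#' clipped to `[-zclip, zclip]` — the view used for heatmaps and for
#' clustering cells into GRNs. Constant regulons map to all zeros.
#'
#' @param am an [ActivityMatrix-class].
#' @param zclip clipping bound (default 2).
#' @return `am` with an added `"scaled"` assay.
#' @export
zscaleClip <- function(am, zclip = 2.0) {
  auc <- SummarizedExperiment::assay(am, "auc")
  if (ncol(auc) < 2L)
    stop("z-scaling needs at least 2 cells (sd undefined)")
  mu <- rowMeans(auc, na.rm = TRUE)
  sd <- apply(auc, 1, stats::sd, na.rm = TRUE)
  z <- (auc - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0 | !is.finite(sd), ] <- 0
  z <- pmin(pmax(z, -zclip), zclip)
  SummarizedExperiment::assay(am, "scaled") <- z
  S4Vectors::metadata(am)$zclip <- zclip
  am
}

#' Scaled activity view of an ActivityMatrix
#' @param am an [ActivityMatrix-class] that has been through [zscaleClip()].
#' @return matrix of z-scaled, clipped activities.
#' @export
scaledActivity <- function(am) {
  if (!"scaled" %in% SummarizedExperiment::assayNames(am))
    stop("no scaled view; run zscaleClip() first")
  SummarizedExperiment::assay(am, "scaled")
}

#' Binned-control module score
#'
#' Per-cell mean expression of a gene set minus the mean of control genes
#' drawn, for each set gene, from the same average-expression bin — centred
#' near zero under exchangeability. The construction used for AR-style
#' module scores.
#'
#' @param sce expression object with a `"lognorm"` assay.
#' @param geneSet character vector of gene ids.
#' @param nBins number of average-expression bins (default 24).
#' @param nCtrl control genes sampled per set gene (default 100).
#' @param seed seed for control sampling.
#' @return named numeric vector, one score per cell.
#' @export
moduleScore <- function(sce, geneSet, nBins = 24L, nCtrl = 100L,
                        seed = 1L) {
  expr <- .getLayer(sce, "lognorm")
  setGenes <- intersect(geneSet, rownames(expr))
  if (!length(setGenes))
    stop("no gene of the set is present; missing: ",
         paste(utils::head(geneSet, 10), collapse = ", "))
  nBins <- min(as.integer(nBins), nrow(expr))
  avg <- rowMeans(expr)
  # equal-occupancy bins over the average-expression ranking
  bins <- ceiling(rank(avg, ties.method = "first") * nBins / nrow(expr))
  set.seed(seed)
  ctrl <- unique(unlist(lapply(setGenes, function(g) {
    pool <- which(bins == bins[[g]])
    rownames(expr)[sample(pool, min(nCtrl, length(pool)))]
  })))
  colMeans(expr[setGenes, , drop = FALSE]) -
    colMeans(expr[ctrl, , drop = FALSE])
}

#' Diffusion (kNN Markov) imputation of expression
#'
#' Builds a k-nearest-neighbour graph over cells (Euclidean distance over
#' the top principal components), applies an adaptive Gaussian kernel whose
#' per-cell bandwidth is the distance to the `ceiling(k/3)`-th neighbour,
#' symmetrizes the affinities by their mean, and row-normalizes to a Markov
#' matrix M. Imputed expression mixes each cell's profile with its
#' neighbours' through `t` diffusion steps; `t = 0` returns the input
#' unchanged. Row-stochastic averaging keeps every gene's imputed values
#' inside the gene's observed range.
#'
#' @param sce expression object with a `"lognorm"` assay.
#' @param k neighbours per cell (must be < number of cells; default 20).
#' @param t diffusion steps (default 1).
#' @param nPcs principal components for the distance space (default 20).
#' @return `sce` with an added `"imputed"` assay.
#' @export
diffuseImpute <- function(sce, k = 20L, t = 1L, nPcs = 20L) {
  expr <- .getLayer(sce, "lognorm")
  n <- ncol(expr)
  if (k >= n) stop("k must be smaller than the number of cells")
  if (t < 0) stop("t must be >= 0")
  if (t == 0) {
    SummarizedExperiment::assay(sce, "imputed") <- expr
    return(sce)
  }
  pcs <- .pcaScores(expr, nPcs)
  d <- as.matrix(stats::dist(pcs))
  A <- matrix(0, n, n)
  bw <- as.integer(ceiling(k / 3))
  for (i in seq_len(n)) {
    nb <- order(d[i, -i])  # indices into the vector without i
    nb <- seq_len(n)[-i][nb[seq_len(k)]]
    sigma <- d[i, nb[bw]]
    if (sigma > 0) {
      A[i, nb] <- exp(-(d[i, nb] / sigma)^2)
      A[i, i] <- 1
    } else {
      # coincident neighbourhood: uniform over zero-distance cells
      A[i, c(i, nb[d[i, nb] == 0])] <- 1
    }
  }
  W <- (A + t(A)) / 2
  M <- W / rowSums(W)
  Mt <- M
  if (t > 1) for (s in seq_len(t - 1)) Mt <- Mt %*% M
  imputed <- tcrossprod(expr, Mt)  # column j becomes sum_i Mt[j,i] x_i
  dimnames(imputed) <- dimnames(expr)
  SummarizedExperiment::assay(sce, "imputed") <- imputed
  sce
}
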