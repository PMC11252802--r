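#' Lin's concordance correlation coefficient
#'
#' Agreement with the identity line:
#' `CCC = 2*s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` using
#' population (1/n) moments, so CCC penalizes location and scale shifts
#' that Pearson's r ignores (`|CCC| <= |r|`, with equality when means and
#' variances agree). The 95% CI uses Lin's Fisher z-transform with the
#' original asymptotic variance.
#'
#' @param x,y equal-length finite numeric vectors, n >= 3.
#' @return list: `statistic = "lin_ccc"`, `estimate`, `ci_low`, `ci_high`,
#'   `n`.
#' @examples
#' linCCC(c(1, 2, 3), c(2, 3, 4))$estimate  # 4/7
#' @export
linCCC <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite input")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0)
    stop("both inputs have zero variance; CCC undefined")
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  # Lin (1989) asymptotic variance of the z-transformed CCC
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else NA_real_
  ciLow <- ciHigh <- NA_real_
  if (!is.na(r) && abs(r) > 0 && abs(ccc) < 1) {
    u <- (mx - my) / (sx2 * sy2)^(1 / 4)
    sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    if (is.finite(sz2) && sz2 >= 0) {
      z <- atanh(ccc)
      ciLow <- tanh(z - 1.959964 * sqrt(sz2))
      ciHigh <- tanh(z + 1.959964 * sqrt(sz2))
    }
  } else if (abs(ccc) == 1) {
    ciLow <- ciHigh <- ccc
  }
  list(statistic = "lin_ccc", estimate = ccc, ci_low = ciLow,
       ci_high = ciHigh, n = n)
}

#' Pearson correlation with Fisher-z 95% CI
#'
#' @param x,y equal-length numeric vectors, n >= 3, both non-constant.
#' @return list: `statistic = "pearson"`, `estimate`, `ci_low`, `ci_high`,
#'   `n`.
#' @export
pearsonCorr <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; Pearson correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(statistic = "pearson", estimate = unname(ct$estimate),
       ci_low = ct$conf.int[1], ci_high = ct$conf.int[2], n = n)
}

# Exact two-sided rank-sum p by enumeration of group assignments;
# tie-safe (works on midranks).
.exactRankSumP <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(n, nx)
  sums <- colSums(matrix(r[combos], nrow = nx))
  mu <- nx * (n + 1) / 2
  stat <- mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
  list(statistic = obs - nx * (nx + 1) / 2, p = stat)  # W statistic
}

# Exact two-sided signed-rank p by enumeration of sign patterns.
.exactSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  total <- 2^n
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- as.matrix(signs) %*% r
  p <- mean(abs(vs - mu) >= abs(obs - mu) - 1e-9)
  list(statistic = obs, p = p)
}

#' Wilcoxon rank test with exact small-sample p and tier label
#'
#' Unpaired (rank-sum) or paired (signed-rank), two-sided. Small samples
#' (unpaired `n_x + n_y <= 12`, paired `n <= 15`) use exact enumeration of
#' the permutation distribution, which remains exact under ties; larger
#' samples use the normal approximation with tie correction. Zero paired
#' differences are dropped; if all differences are zero the comparison is
#' flagged untestable with p = 1.
#'
#' @param x,y numeric samples (equal length when `paired`).
#' @param paired logical.
#' @return list: `statistic`, `p`, `tier` (see [significanceTier()]),
#'   `method`, and `untestable` flag.
#' @export
wilcoxonTest <- function(x, y, paired = FALSE) {
  if (paired && length(x) != length(y))
    stop("paired test requires equal lengths")
  if (!length(x) || !length(y)) stop("empty sample")
  if (paired) {
    d <- x - y
    if (all(d == 0))
      return(list(statistic = 0, p = 1, tier = "ns",
                  method = "signed-rank (all differences zero)",
                  untestable = TRUE))
    if (sum(d != 0) <= 15L) {
      res <- .exactSignedRankP(d)
      method <- "exact signed-rank"
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                exact = FALSE,
                                                correct = TRUE))
      res <- list(statistic = unname(wt$statistic), p = wt$p.value)
      method <- "signed-rank, normal approximation"
    }
  } else {
    if (length(x) + length(y) <= 12L) {
      res <- .exactRankSumP(x, y)
      method <- "exact rank-sum"
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))
      res <- list(statistic = unname(wt$statistic), p = wt$p.value)
      method <- "rank-sum, normal approximation"
    }
  }
  list(statistic = res$statistic, p = res$p,
       tier = significanceTier(res$p), method = method,
       untestable = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotone enforcement;
#' order-preserving wrapper over [stats::p.adjust()] with input
#' validation.
#' @param p p-values in [0, 1].
#' @return adjusted p-values (elementwise >= input).
#' @export
benjaminiHochberg <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Closed-form likelihood-ratio chi-squares used by the hurdle model.
# Detection part: 2x2 binomial LRT (G-statistic) for detection ~ group.
.detectionLRT <- function(det, grp) {
  tab <- table(factor(det, levels = c(FALSE, TRUE)), grp)
  if (any(rowSums(tab) == 0)) return(NULL)  # detection does not vary
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  keep <- tab > 0
  list(chisq = 2 * sum(tab[keep] * log(tab[keep] / e[keep])), df = 1L)
}

# Continuous part: Gaussian LRT (n*log(RSS0/RSS1)) for expression ~ group
# among detected cells; needs detected cells in both groups.
.continuousLRT <- function(v, grp) {
  if (length(unique(grp)) < 2L || length(v) < 3L) return(NULL)
  n <- length(v)
  rss0 <- sum((v - mean(v))^2)
  gm <- tapply(v, grp, mean)
  rss1 <- sum((v - gm[as.character(grp)])^2)
  if (rss1 <= 0) rss1 <- .Machine$double.eps * rss0
  if (rss0 <= 0) return(NULL)
  list(chisq = n * log(rss0 / rss1), df = 1L)
}

#' Two-part hurdle differential expression
#'
#' Per gene, a detection component (likelihood-ratio test of the group
#' effect on the detected/undetected indicator) and a continuous component
#' (likelihood-ratio test of the group effect on log-normalized expression
#' among detected cells) are combined by summing the two chi-square
#' statistics and their degrees of freedom; a component that is
#' inestimable (detection constant, or detected cells confined to one
#' group) is dropped. The fold change is
#' `log2((mean_A + eps) / (mean_B + eps))` on the normalized (de-logged)
#' expression scale. P-values are Benjamini-Hochberg adjusted across
#' genes. Genes undetected everywhere are excluded (reported in the
#' `excluded` attribute).
#'
#' @param sce expression object with a `"lognorm"` assay.
#' @param cellsA,cellsB cell ids of the two groups (each >= 3 cells).
#' @param pseudocount `eps` for the fold change (default 1).
#' @return data.frame: `gene`, `log2FC`, `mean_A`, `mean_B`, `det_frac_A`,
#'   `det_frac_B`, `p`, `p_adj`.
#' @export
hurdleDE <- function(sce, cellsA, cellsB, pseudocount = 1) {
  expr <- .getLayer(sce, "lognorm")
  stopifnot(all(cellsA %in% colnames(expr)),
            all(cellsB %in% colnames(expr)))
  if (length(cellsA) < 3L || length(cellsB) < 3L)
    stop("both groups need at least 3 cells")
  A <- expr[, cellsA, drop = FALSE]
  B <- expr[, cellsB, drop = FALSE]
  # normalized (de-logged) means for the fold change
  normA <- rowMeans(expm1(A)); normB <- rowMeans(expm1(B))
  detA <- rowMeans(A > 0); detB <- rowMeans(B > 0)
  excluded <- rownames(expr)[detA == 0 & detB == 0]
  genes <- setdiff(rownames(expr), excluded)
  grp <- factor(c(rep("A", ncol(A)), rep("B", ncol(B))))
  res <- lapply(genes, function(g) {
    v <- c(A[g, ], B[g, ])
    det <- v > 0
    chisq <- 0; df <- 0L
    dpart <- .detectionLRT(det, grp)
    if (!is.null(dpart)) { chisq <- chisq + dpart$chisq; df <- df + dpart$df }
    cpart <- .continuousLRT(v[det], grp[det])
    if (!is.null(cpart)) { chisq <- chisq + cpart$chisq; df <- df + cpart$df }
    p <- if (df > 0) stats::pchisq(chisq, df = df, lower.tail = FALSE)
         else NA_real_
    data.frame(gene = g,
               log2FC = log2((normA[g] + pseudocount) /
                               (normB[g] + pseudocount)),
               mean_A = normA[g], mean_B = normB[g],
               det_frac_A = detA[g], det_frac_B = detB[g], p = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- benjaminiHochberg(out$p)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' One-sided Fisher enrichment test of a set overlap
#'
#' `p = P(X >= |A intersect B|)` under the hypergeometric null of drawing
#' `|B|` genes from the universe, with the sample odds ratio from the 2x2
#' table.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe the common gene universe.
#' @return list: `nA`, `nB`, `nOverlap`, `nUniverse`, `oddsRatio`, `p`,
#'   `overlap` (the shared elements).
#' @export
overlapFisher <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  offA <- setdiff(setA, universe); offB <- setdiff(setB, universe)
  if (length(offA) || length(offB))
    stop("sets not contained in universe: ",
         paste(utils::head(c(offA, offB), 10), collapse = ", "))
  ov <- intersect(setA, setB)
  k <- length(ov); a <- length(setA); b <- length(setB)
  u <- length(universe)
  p <- stats::phyper(k - 1, a, u - a, b, lower.tail = FALSE)
  orNum <- k * (u - a - b + k)
  orDen <- (a - k) * (b - k)
  oddsRatio <- if (orDen == 0) Inf else orNum / orDen
  list(nA = a, nB = b, nOverlap = k, nUniverse = u,
       oddsRatio = oddsRatio, p = p, overlap = ov)
}

#' Cross-cohort shared differential-expression comparison
#'
#' Thresholds each cohort's hurdle-DE table (`log2FC > fcThreshold` in the
#' contrast direction and `p_adj < fdr`), intersects the significant sets,
#' and tests the overlap with [overlapFisher()] over the common gene
#' universe; a per-gene fold-change scatter table over the common universe
#' is included.
#'
#' @param de1,de2 [hurdleDE()] results from the two cohorts.
#' @param fcThreshold log2 fold-change cutoff (default 0.4).
#' @param fdr adjusted-p cutoff (default 0.05).
#' @param universe gene universe; default the intersection of the two DE
#'   tables' genes.
#' @param direction `"up"` (positive log2FC) or `"down"`.
#' @return list: `sig1`, `sig2`, `shared`, `overlap` (the
#'   [overlapFisher()] result), `scatter` (gene, log2FC.1, log2FC.2),
#'   `thresholds`.
#' @export
crossCohortCompare <- function(de1, de2, fcThreshold = 0.4, fdr = 0.05,
                               universe = NULL,
                               direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (is.null(universe)) universe <- intersect(de1$gene, de2$gene)
  if (!length(universe)) stop("empty common gene universe")
  sig <- function(de) {
    fc <- if (direction == "up") de$log2FC else -de$log2FC
    de$gene[!is.na(de$p_adj) & de$p_adj < fdr & fc > fcThreshold]
  }
  sig1 <- intersect(sig(de1), universe)
  sig2 <- intersect(sig(de2), universe)
  shared <- intersect(sig1, sig2)
  ov <- overlapFisher(sig1, sig2, universe)
  scatter <- data.frame(gene = universe,
                        log2FC.1 = de1$log2FC[match(universe, de1$gene)],
                        log2FC.2 = de2$log2FC[match(universe, de2$gene)])
  list(sig1 = sig1, sig2 = sig2, shared = shared, overlap = ov,
       scatter = scatter,
       thresholds = c(fc = fcThreshold, fdr = fdr))
}
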