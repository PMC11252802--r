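#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames colData colData<-
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' RegulonSet: transcription factor to target-gene set mapping
#'
#' Ordered collection of regulons, each a transcription factor (TF) name
#' plus a non-empty set of target genes, as parsed from a GMT file or
#' planted by the cohort simulator. The reported regulon size is the number
#' of targets, plus one when the TF itself is counted as a member
#' (`includeTF`), matching the "TF(n g)" labelling convention used on
#' regulon-activity heatmaps.
#'
#' @slot entries named list; each element a character vector of target genes,
#'   names are unique TF names.
#' @slot includeTF named logical vector parallel to `entries`; whether the TF
#'   itself counts towards the reported regulon size.
#' @export
setClass("RegulonSet",
  representation(entries = "list", includeTF = "logical"))

setValidity("RegulonSet", function(object) {
  e <- object@entries
  msgs <- character()
  if (is.null(names(e)) || anyNA(names(e)) || any(names(e) == ""))
    msgs <- c(msgs, "all regulons must be named")
  if (anyDuplicated(names(e)))
    msgs <- c(msgs, paste0("duplicate TF names: ",
      paste(unique(names(e)[duplicated(names(e))]), collapse = ", ")))
  if (any(lengths(e) == 0))
    msgs <- c(msgs, paste0("empty target set for: ",
      paste(names(e)[lengths(e) == 0], collapse = ", ")))
  if (length(object@includeTF) != length(e))
    msgs <- c(msgs, "includeTF must parallel entries")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RegulonSet
#'
#' @param targets named list of character vectors (TF name -> target genes).
#' @param includeTF logical scalar or vector: count the TF itself in the
#'   reported regulon size.
#' @return A [RegulonSet-class] object.
#' @examples
#' rs <- RegulonSet(list(ASCL1 = c("DLL3", "INSM1")))
#' regulonSizes(rs)
#' @export
RegulonSet <- function(targets, includeTF = FALSE) {
  includeTF <- rep_len(as.logical(includeTF), length(targets))
  names(includeTF) <- names(targets)
  new("RegulonSet", entries = lapply(targets, as.character),
      includeTF = includeTF)
}

#' @describeIn RegulonSet-class number of regulons
#' @param x,object a `RegulonSet`
#' @export
setMethod("length", "RegulonSet", function(x) length(x@entries))

#' @describeIn RegulonSet-class TF names
#' @export
setMethod("names", "RegulonSet", function(x) names(x@entries))

#' @describeIn RegulonSet-class extract one regulon's target genes
#' @param i index or TF name
#' @export
setMethod("[[", "RegulonSet", function(x, i) x@entries[[i]])

setMethod("show", "RegulonSet", function(object) {
  cat("RegulonSet with", length(object), "regulons\n")
  lab <- regulonLabels(object)
  n <- min(5L, length(lab))
  if (n > 0) cat(" ", paste(lab[seq_len(n)], collapse = ", "),
                 if (length(lab) > n) "..." else "", "\n")
})

#' ActivityMatrix: per-cell regulon activities
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' regulons x cells AUC activity matrix in assay `"auc"` (values in [0,1],
#' `NA` for regulons with no scoreable genes) and, after [zscaleClip()], a
#' per-regulon z-scored and clipped view in assay `"scaled"`. Scoring
#' parameters (top fraction, tie handling) live in `metadata()`.
#'
#' @export
setClass("ActivityMatrix", contains = "SummarizedExperiment")

setValidity("ActivityMatrix", function(object) {
  if (!"auc" %in% SummarizedExperiment::assayNames(object))
    return("assay 'auc' is required")
  a <- SummarizedExperiment::assay(object, "auc")
  v <- a[!is.na(a)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    return("auc values must lie in [0, 1]")
  TRUE
})

#' DendrogramModel: an agglomerative merge record with an optional cut
#'
#' Wraps the `hclust` merge record (heights, merge pairs) together with the
#' metric/linkage used and, once a cut has been selected, the cut height and
#' resulting number of clusters.
#'
#' @slot hc an [stats::hclust] object over cells.
#' @slot metric,linkage character; distance metric and linkage names.
#' @slot cutHeight numeric; height realizing the selected cut (NA before
#'   selection).
#' @slot nClusters integer; clusters at the cut (NA before selection).
#' @export
setClass("DendrogramModel",
  representation(hc = "ANY", metric = "character", linkage = "character",
                 cutHeight = "numeric", nClusters = "integer"))

setValidity("DendrogramModel", function(object) {
  if (!inherits(object@hc, "hclust")) return("hc must be an hclust object")
  if (is.unsorted(object@hc$height, strictly = FALSE))
    return("merge heights must be non-decreasing")
  TRUE
})

setMethod("show", "DendrogramModel", function(object) {
  cat("DendrogramModel:", length(object@hc$order), "leaves,",
      object@linkage, "linkage on", object@metric, "distance\n")
  if (!is.na(object@nClusters))
    cat("  cut at height", format(object@cutHeight, digits = 4),
        "->", object@nClusters, "clusters\n")
})

#' GRNPartition: cell-to-GRN assignment with its selection trace
#'
#' Holds the cell -> GRN labels chosen by [selectCutByARI()], the dendrogram
#' they were cut from, and the resampling-stability profile (mean and sd of
#' the adjusted Rand index per candidate cluster number) that justified the
#' cut.
#'
#' @slot labels named integer vector, cell id -> GRN label.
#' @slot nGrns integer, number of GRN states.
#' @slot dendrogram the [DendrogramModel-class] the cut was taken from.
#' @slot ariProfile data.frame with columns `k`, `meanARI`, `sdARI`.
#' @export
setClass("GRNPartition",
  representation(labels = "integer", nGrns = "integer",
                 dendrogram = "DendrogramModel", ariProfile = "data.frame"))

setValidity("GRNPartition", function(object) {
  msgs <- character()
  if (is.null(names(object@labels)))
    msgs <- c(msgs, "labels must be named by cell id")
  if (object@nGrns < 1L) msgs <- c(msgs, "nGrns must be >= 1")
  if (nrow(object@ariProfile) &&
      any(abs(object@ariProfile$meanARI) > 1 + 1e-9))
    msgs <- c(msgs, "ARI values must lie in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GRNPartition", function(object) {
  cat("GRNPartition:", length(object@labels), "cells in",
      object@nGrns, "GRNs\n")
  print(table(GRN = object@labels))
})
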