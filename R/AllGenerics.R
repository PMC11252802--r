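#' Target-gene sets of a RegulonSet
#' @param x a [RegulonSet-class]
#' @return named list of character vectors.
#' @export
setGeneric("regulonTargets", function(x) standardGeneric("regulonTargets"))

#' @rdname regulonTargets
#' @export
setMethod("regulonTargets", "RegulonSet", function(x) x@entries)

#' Reported regulon sizes
#'
#' Number of target genes, plus one where the TF itself is counted.
#' @param x a [RegulonSet-class]
#' @return named integer vector.
#' @export
setGeneric("regulonSizes", function(x) standardGeneric("regulonSizes"))

#' @rdname regulonSizes
#' @export
setMethod("regulonSizes", "RegulonSet", function(x)
  lengths(x@entries) + as.integer(x@includeTF))

#' Heatmap-style regulon labels, e.g. "ASCL1(34 g)"
#' @param x a [RegulonSet-class]
#' @return character vector of labels.
#' @export
setGeneric("regulonLabels", function(x) standardGeneric("regulonLabels"))

#' @rdname regulonLabels
#' @export
setMethod("regulonLabels", "RegulonSet", function(x)
  sprintf("%s(%d g)", names(x@entries), regulonSizes(x)))

#' GRN labels of a partition
#' @param x a [GRNPartition-class]
#' @return named integer vector, cell id -> GRN label.
#' @export
setGeneric("grnLabels", function(x) standardGeneric("grnLabels"))

#' @rdname grnLabels
#' @export
setMethod("grnLabels", "GRNPartition", function(x) x@labels)

#' Number of GRN states in a partition
#' @param x a [GRNPartition-class]
#' @export
setGeneric("nGrns", function(x) standardGeneric("nGrns"))

#' @rdname nGrns
#' @export
setMethod("nGrns", "GRNPartition", function(x) x@nGrns)

#' ARI stability profile that selected the cut
#' @param x a [GRNPartition-class]
#' @return data.frame with columns `k`, `meanARI`, `sdARI`.
#' @export
setGeneric("ariProfile", function(x) standardGeneric("ariProfile"))

#' @rdname ariProfile
#' @export
setMethod("ariProfile", "GRNPartition", function(x) x@ariProfile)

#' Dendrogram a partition was cut from
#' @param x a [GRNPartition-class]
#' @export
setGeneric("dendrogram", function(x) standardGeneric("dendrogram"))

#' @rdname dendrogram
#' @export
setMethod("dendrogram", "GRNPartition", function(x) x@dendrogram)
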