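#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline with their defaults:
#' AUCell top fraction (0.05), kNN graph neighbours (30), diffusion
#' imputation k/t (20/1), entropy subsampling (100 cells x 100 reps),
#' z-score clipping (2), and the differential-expression thresholds
#' (|log2FC| > 0.4, FDR < 0.05).
#'
#' @param seed integer master seed fanned out to every stage.
#' @param aucellTopFraction fraction of the per-cell expression ranking
#'   scanned by the recovery curve; in (0, 1].
#' @param knnK neighbours for graph clustering.
#' @param magicK,magicT diffusion-imputation neighbourhood size and number
#'   of diffusion steps.
#' @param subsampleN,subsampleReps cells drawn per cluster and repetitions
#'   for the resampled entropy.
#' @param zclip absolute bound for the z-scaled activity view.
#' @param fcThreshold,fdrThreshold log2 fold-change and adjusted-p cutoffs
#'   for differential-expression calls.
#' @param nPcs principal components used before kNN graphs.
#' @return a validated list of class `AnalysisConfig`.
#' @examples
#' cfg <- analysisConfig(seed = 1)
#' cfg$aucellTopFraction
#' @export
analysisConfig <- function(seed = 1L,
                           aucellTopFraction = 0.05,
                           knnK = 30L,
                           magicK = 20L,
                           magicT = 1L,
                           subsampleN = 100L,
                           subsampleReps = 100L,
                           zclip = 2.0,
                           fcThreshold = 0.4,
                           fdrThreshold = 0.05,
                           nPcs = 20L) {
  cfg <- list(seed = as.integer(seed),
              aucellTopFraction = aucellTopFraction,
              knnK = as.integer(knnK), magicK = as.integer(magicK),
              magicT = as.integer(magicT),
              subsampleN = as.integer(subsampleN),
              subsampleReps = as.integer(subsampleReps),
              zclip = zclip, fcThreshold = fcThreshold,
              fdrThreshold = fdrThreshold, nPcs = as.integer(nPcs))
  stopifnot(aucellTopFraction > 0, aucellTopFraction <= 1)
  pos <- c("knnK", "magicK", "subsampleN", "subsampleReps", "zclip",
           "fcThreshold", "fdrThreshold", "nPcs")
  bad <- pos[vapply(cfg[pos], function(v) !is.finite(v) || v <= 0, logical(1))]
  if (length(bad))
    stop("configuration values must be strictly positive: ",
         paste(bad, collapse = ", "))
  if (cfg$magicT < 0) stop("magicT must be >= 0")
  class(cfg) <- "AnalysisConfig"
  cfg
}

#' Read an analysis configuration from YAML
#'
#' Unrecognized keys are rejected; missing keys fall back to defaults.
#' @param path YAML file whose keys mirror [analysisConfig()] arguments.
#' @return an `AnalysisConfig` list.
#' @export
readAnalysisConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysisConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(analysisConfig, vals)
}

#' Derive a stage-specific seed from the master seed
#'
#' Stable string hash of the stage name combined with the master seed, so
#' adding a stage never perturbs the randomness of existing stages.
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return integer in [1, 2^31 - 2].
#' @export
stageSeed <- function(seed, stage) {
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 31 + v) %% 2147483647
  as.integer((h + as.numeric(seed) %% 2147483647) %% 2147483646 + 1)
}

.logLevelRank <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Package log messages
#'
#' Timestamped, level-filtered logging; the threshold is the
#' `grnstates.log_level` option (default `"info"`).
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param ... message parts pasted together.
#' @return invisibly, the formatted line (or NULL when filtered).
#' @export
logMsg <- function(level = "info", ...) {
  threshold <- getOption("grnstates.log_level", "info")
  if (.logLevelRank[[level]] < .logLevelRank[[threshold]])
    return(invisible(NULL))
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), paste0(...))
  message(line)
  invisible(line)
}

# Pull an assay ("layer") from an expression container, with a clear error
# when the requested layer has not been computed yet.
.getLayer <- function(sce, layer) {
  if (!layer %in% SummarizedExperiment::assayNames(sce))
    stop("expression object has no '", layer, "' layer; available: ",
         paste(SummarizedExperiment::assayNames(sce), collapse = ", "))
  as.matrix(SummarizedExperiment::assay(sce, layer))
}

# PCA scores (cells x components) over a genes x cells matrix. Components
# are capped by the data rank; centring only, no scaling of constant genes.
.pcaScores <- function(x, nPcs) {
  xt <- t(x)
  nPcs <- min(nPcs, nrow(xt) - 1L, ncol(xt))
  p <- stats::prcomp(xt, center = TRUE, scale. = FALSE, rank. = nPcs)
  p$x
}

#' Significance tier label for a p-value
#'
#' Maps p to the conventional annotation tiers: `****` below 1e-4, `***`
#' below 1e-3, `**` below 0.01, `*` below 0.05, otherwise `ns`.
#' @param p numeric p-value(s).
#' @return character vector of tiers.
#' @examples
#' significanceTier(c(0.03, 5e-5, 0.5))
#' @export
significanceTier <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***"
    else if (pi < 0.01) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}
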