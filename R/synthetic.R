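#' Specification for a synthetic single-cell cohort
#'
#' Describes a negative-binomial count cohort with planted TF-regulon-defined
#' cell states: each state owns a block of `genesPerRegulon` genes whose mean
#' is multiplied by `regulonEffect` in cells of that state; the remaining
#' `nBackgroundGenes` genes are state-independent. Patients are drawn per
#' state from Dirichlet(alpha)-distributed frequencies: a small alpha (0.05)
#' makes the state patient-specific, a large alpha (50) spreads it evenly
#' across patients. Optional antigen genes have their mean multiplied by a
#' fold in a chosen state, emulating cell-surface-antigen/state coupling
#' (e.g. a PSMA-like gene up in the AR-like state, a DLL3-like gene up in an
#' ASCL1-like state).
#'
#' @param nStates number of planted states (>= 2).
#' @param cellsPerState cells simulated per state.
#' @param nPatients number of patients in the cohort.
#' @param patientAlpha Dirichlet concentration per state (scalar recycled or
#'   vector of length `nStates`).
#' @param genesPerRegulon target genes per planted regulon.
#' @param nBackgroundGenes state-independent genes.
#' @param regulonEffect fold-increase of a regulon gene's mean in its own
#'   state.
#' @param baselineMean negative-binomial baseline mean per gene.
#' @param dispersion negative-binomial size parameter.
#' @param antigenCoupling NULL or data.frame with columns `gene`, `state`,
#'   `fold`: extra antigen genes appended to the matrix.
#' @param stateNames names of the states (default S1..Sk).
#' @param stateCategory disease category per state, from
#'   {naive_CSPC, CRPC_adeno, NEPC} (recycled).
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return a validated list of class `CohortSimSpec`.
#' @export
cohortSimSpec <- function(nStates = 5L, cellsPerState = 120L,
                          nPatients = 8L, patientAlpha = 5,
                          genesPerRegulon = 30L, nBackgroundGenes = 440L,
                          regulonEffect = 8, baselineMean = 0.5,
                          dispersion = 10, antigenCoupling = NULL,
                          stateNames = NULL,
                          stateCategory = "CRPC_adeno", seed = 1L) {
  nStates <- as.integer(nStates)
  if (nStates < 2L) stop("nStates must be >= 2")
  if (is.null(stateNames)) stateNames <- paste0("S", seq_len(nStates))
  if (length(stateNames) != nStates) stop("stateNames length != nStates")
  patientAlpha <- rep_len(patientAlpha, nStates)
  stateCategory <- rep_len(stateCategory, nStates)
  if (any(patientAlpha <= 0)) stop("patientAlpha must be > 0")
  if (regulonEffect <= 0 || baselineMean <= 0 || dispersion <= 0)
    stop("regulonEffect, baselineMean and dispersion must be > 0")
  if (cellsPerState < 1L || nPatients < 1L || genesPerRegulon < 1L ||
      nBackgroundGenes < 0L)
    stop("cellsPerState, nPatients, genesPerRegulon must be positive")
  if (!is.null(antigenCoupling)) {
    stopifnot(is.data.frame(antigenCoupling),
              all(c("gene", "state", "fold") %in% names(antigenCoupling)))
    if (!all(antigenCoupling$state %in% stateNames))
      stop("antigenCoupling refers to unknown states")
    if (any(antigenCoupling$fold <= 0)) stop("antigen folds must be > 0")
  }
  spec <- list(nStates = nStates, cellsPerState = as.integer(cellsPerState),
               nPatients = as.integer(nPatients),
               patientAlpha = patientAlpha,
               genesPerRegulon = as.integer(genesPerRegulon),
               nBackgroundGenes = as.integer(nBackgroundGenes),
               regulonEffect = regulonEffect, baselineMean = baselineMean,
               dispersion = dispersion, antigenCoupling = antigenCoupling,
               stateNames = stateNames, stateCategory = stateCategory,
               seed = as.integer(seed))
  class(spec) <- "CohortSimSpec"
  spec
}

# Gene name layout for one cohort; regulon gene names may be overridden to
# share sets across cohorts.
.cohortGeneNames <- function(spec, regulonGeneNames = NULL) {
  if (is.null(regulonGeneNames))
    regulonGeneNames <- lapply(spec$stateNames, function(s)
      sprintf("%s_G%03d", s, seq_len(spec$genesPerRegulon)))
  names(regulonGeneNames) <- spec$stateNames
  bg <- if (spec$nBackgroundGenes > 0)
    sprintf("BG_%04d", seq_len(spec$nBackgroundGenes)) else character()
  antigen <- if (!is.null(spec$antigenCoupling))
    as.character(spec$antigenCoupling$gene) else character()
  all <- c(unlist(regulonGeneNames, use.names = FALSE), bg, antigen)
  if (anyDuplicated(all))
    stop("gene name collision in simulation spec: ",
         paste(unique(all[duplicated(all)]), collapse = ", "))
  list(regulon = regulonGeneNames, background = bg, antigen = antigen,
       all = all)
}

#' Simulate a ground-truthed single-cell cohort
#'
#' Draws counts gene-by-gene from a negative binomial whose mean is
#' `baselineMean`, multiplied by `regulonEffect` for a state's regulon genes
#' in cells of that state, and by the antigen fold where an antigen coupling
#' applies. Patient assignments per state follow Dirichlet-distributed
#' frequencies. Bit-identical output for a fixed spec (including its seed).
#'
#' @param spec a [cohortSimSpec()].
#' @param regulonGeneNames internal override used by [simulateTwoCohorts()]
#'   to share regulon gene sets across cohorts.
#' @return list with elements `expr` (a `SingleCellExperiment`, counts assay,
#'   annotated `colData`), `regulons` (a [RegulonSet-class], one regulon per
#'   state, named by state), and `truth` (list: `stateOfCell`,
#'   `patientOfCell` named vectors, `regulons`, `antigenMap`).
#' @examples
#' cohort <- simulateCohort(cohortSimSpec(nStates = 3, cellsPerState = 20,
#'   genesPerRegulon = 5, nBackgroundGenes = 30, seed = 7))
#' dim(cohort$expr)
#' @export
simulateCohort <- function(spec, regulonGeneNames = NULL) {
  stopifnot(inherits(spec, "CohortSimSpec"))
  layout <- .cohortGeneNames(spec, regulonGeneNames)
  set.seed(spec$seed)
  nCells <- spec$nStates * spec$cellsPerState
  stateOfCell <- rep(spec$stateNames, each = spec$cellsPerState)
  cellIds <- sprintf("cell_%04d", seq_len(nCells))
  names(stateOfCell) <- cellIds

  # per-state Dirichlet patient frequencies, then patients per cell
  patients <- paste0("P", seq_len(spec$nPatients))
  patientOfCell <- character(nCells)
  for (s in seq_len(spec$nStates)) {
    g <- stats::rgamma(spec$nPatients, shape = spec$patientAlpha[s])
    if (sum(g) == 0) g[which.max(g)] <- 1  # guard against underflow
    w <- g / sum(g)
    idx <- which(stateOfCell == spec$stateNames[s])
    patientOfCell[idx] <- sample(patients, length(idx), replace = TRUE,
                                 prob = w)
  }
  names(patientOfCell) <- cellIds

  nGenes <- length(layout$all)
  mu <- matrix(spec$baselineMean, nrow = nGenes, ncol = nCells,
               dimnames = list(layout$all, cellIds))
  for (s in spec$stateNames) {
    own <- stateOfCell == s
    mu[layout$regulon[[s]], own] <- mu[layout$regulon[[s]], own] *
      spec$regulonEffect
  }
  antigenMap <- NULL
  if (!is.null(spec$antigenCoupling)) {
    for (r in seq_len(nrow(spec$antigenCoupling))) {
      ac <- spec$antigenCoupling[r, ]
      own <- stateOfCell == ac$state
      mu[as.character(ac$gene), own] <- mu[as.character(ac$gene), own] *
        ac$fold
    }
    antigenMap <- spec$antigenCoupling
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = spec$dispersion),
                   nrow = nGenes, dimnames = dimnames(mu))

  regulons <- RegulonSet(layout$regulon)
  category <- spec$stateCategory[match(stateOfCell, spec$stateNames)]
  annot <- data.frame(cell_id = cellIds, patient_id = patientOfCell,
                      category = category, site = "synthetic",
                      state = stateOfCell, stringsAsFactors = FALSE)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts))
  sce <- annotateCells(sce, annot)
  list(expr = sce, regulons = regulons,
       truth = list(stateOfCell = stateOfCell,
                    patientOfCell = patientOfCell,
                    regulons = regulons, antigenMap = antigenMap))
}

#' Simulate two cohorts with shared and private planted states
#'
#' States named in `sharedStates` use identical regulon gene sets in both
#' cohorts (same gene names); cohort-private states use disjoint,
#' cohort-prefixed gene sets. Background gene names are common to both
#' cohorts, so the two gene universes overlap on background plus shared
#' regulon genes — the fixture for cross-cohort differential-expression
#' overlap tests.
#'
#' @param specA,specB [cohortSimSpec()] objects; `stateNames` must contain
#'   `sharedStates` in both.
#' @param sharedStates character vector of state names shared across
#'   cohorts.
#' @return list with elements `A` and `B`, each a [simulateCohort()] result.
#' @export
simulateTwoCohorts <- function(specA, specB, sharedStates) {
  stopifnot(inherits(specA, "CohortSimSpec"),
            inherits(specB, "CohortSimSpec"))
  if (!all(sharedStates %in% specA$stateNames) ||
      !all(sharedStates %in% specB$stateNames))
    stop("sharedStates must exist in both specs")
  if (specA$genesPerRegulon != specB$genesPerRegulon)
    stop("shared regulons require equal genesPerRegulon")
  privA <- setdiff(specA$stateNames, sharedStates)
  privB <- setdiff(specB$stateNames, sharedStates)
  clash <- intersect(privA, privB)
  if (length(clash))
    stop("private regulon name collision between cohorts: ",
         paste(clash, collapse = ", "))
  mkNames <- function(spec, tag) {
    out <- lapply(spec$stateNames, function(s) {
      if (s %in% sharedStates)
        sprintf("SH_%s_G%03d", s, seq_len(spec$genesPerRegulon))
      else sprintf("%s_%s_G%03d", tag, s, seq_len(spec$genesPerRegulon))
    })
    names(out) <- spec$stateNames
    out
  }
  list(A = simulateCohort(specA, regulonGeneNames = mkNames(specA, "A")),
       B = simulateCohort(specB, regulonGeneNames = mkNames(specB, "B")))
}

#' Specification for a synthetic TMA H-score table
#'
#' Each marker pair is generated from a shared latent plus independent
#' noise, calibrated in closed form so the *population* concordance
#' correlation between the pair equals `ccc`: with noise variance
#' `noiseSd^2`, the latent variance is `|ccc| * noiseSd^2 / (1 - |ccc|)`,
#' giving equal means and variances and hence CCC = Pearson = ccc. Pairs
#' that re-use an already generated marker are extended conditionally at
#' the same population correlation. Scores are clipped to the marker scale
#' ([0, 200]; [0, 100] for Ki-67-type markers, drawn at half scale), which
#' can slightly shrink the realized CCC.
#'
#' @param nCores number of TMA cores (>= 10).
#' @param markerPairs data.frame with columns `markerA`, `markerB`, `ccc`
#'   (each |ccc| <= 1). Defaults to the panel design points used throughout
#'   the package: INSM1~ASCL1 at 0.86, SYP~ASCL1 at 0.52, EZH2~KI67 at
#'   0.73.
#' @param nPatients patients the cores are spread over.
#' @param histologyEffects optional named list histology -> named numeric
#'   marker mean shifts (applied after calibration; shifts distort CCC and
#'   are off by default).
#' @param noiseSd independent noise standard deviation per marker.
#' @param seed integer seed.
#' @return a validated list of class `HScoreSimSpec`.
#' @export
hscoreSimSpec <- function(nCores = 131L,
                          markerPairs = data.frame(
                            markerA = c("INSM1", "SYP", "EZH2"),
                            markerB = c("ASCL1", "ASCL1", "KI67"),
                            ccc = c(0.86, 0.52, 0.73)),
                          nPatients = 16L, histologyEffects = NULL,
                          noiseSd = 15, seed = 1L) {
  nCores <- as.integer(nCores)
  if (nCores < 10L) stop("nCores must be >= 10")
  stopifnot(is.data.frame(markerPairs),
            all(c("markerA", "markerB", "ccc") %in% names(markerPairs)))
  if (any(abs(markerPairs$ccc) > 1)) stop("|ccc| must be <= 1")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  bad <- abs(markerPairs$ccc) == 1 & noiseSd > 0
  if (any(bad))
    stop("target ccc of +-1 is infeasible with noiseSd > 0: the ",
         "shared-latent construction bounds |CCC| by ",
         "latentVar / (latentVar + noiseSd^2) < 1")
  spec <- list(nCores = nCores, markerPairs = markerPairs,
               nPatients = as.integer(nPatients),
               histologyEffects = histologyEffects, noiseSd = noiseSd,
               seed = as.integer(seed))
  class(spec) <- "HScoreSimSpec"
  spec
}

.isKiMarker <- function(marker) tolower(marker) %in% c("ki67", "ki-67")

#' Simulate a TMA H-score table with planted concordance structure
#'
#' @param spec an [hscoreSimSpec()].
#' @return list with `hscores` (long-format table as from [readHScores()])
#'   and `truth` (the pair table with the population design values plus the
#'   per-marker scale used).
#' @examples
#' sim <- simulateHScores(hscoreSimSpec(nCores = 50, seed = 3))
#' head(sim$hscores)
#' @export
simulateHScores <- function(spec) {
  stopifnot(inherits(spec, "HScoreSimSpec"))
  set.seed(spec$seed)
  n <- spec$nCores
  coreIds <- sprintf("core%03d", seq_len(n))
  histology <- sample(c("PRAD", "HGC", "NEPC"), n, replace = TRUE)
  patient <- paste0("P", 1L + (seq_len(n) - 1L) %% spec$nPatients)
  site <- sample(c("bone", "liver", "lymph_node", "prostate"), n,
                 replace = TRUE)

  # standardized marker values; built pairwise at the target correlation
  std <- list()
  for (r in seq_len(nrow(spec$markerPairs))) {
    a <- as.character(spec$markerPairs$markerA[r])
    b <- as.character(spec$markerPairs$markerB[r])
    rho <- spec$markerPairs$ccc[r]
    s <- if (rho < 0) -1 else 1
    ar <- abs(rho)
    if (is.null(std[[a]]) && is.null(std[[b]])) {
      latent <- stats::rnorm(n)
      mix <- sqrt(ar)
      std[[a]] <- mix * latent + sqrt(1 - ar) * stats::rnorm(n)
      std[[b]] <- s * (mix * latent) + sqrt(1 - ar) * stats::rnorm(n)
    } else {
      if (is.null(std[[a]])) { tmp <- a; a <- b; b <- tmp }
      if (!is.null(std[[b]]))
        stop("marker pair (", a, ", ", b, ") already fully generated; ",
             "reorder markerPairs so each pair introduces a new marker")
      std[[b]] <- s * ar * std[[a]] + sqrt(1 - ar^2) * stats::rnorm(n)
    }
  }

  # One common scale for every H-score marker: CCC equals the planted
  # correlation only when a pair shares mean and variance, so the total sd
  # comes from the latent calibration of the strongest pair. Ki-type
  # markers sit at half scale on [0, 100]; Pearson is unaffected, CCC
  # against a full-scale marker is not calibrated across scales.
  arMax <- max(abs(spec$markerPairs$ccc))
  noise <- spec$noiseSd
  commonSd <- if (arMax >= 1) max(noise, 1) else
    sqrt(arMax * noise^2 / (1 - arMax) + noise^2)
  rows <- lapply(names(std), function(mk) {
    totalSd <- commonSd
    mu <- 100; hi <- 200
    if (.isKiMarker(mk)) { mu <- 50; hi <- 100; totalSd <- totalSd / 2 }
    sc <- mu + totalSd * std[[mk]]
    if (!is.null(spec$histologyEffects)) {
      for (h in names(spec$histologyEffects)) {
        shift <- spec$histologyEffects[[h]]
        if (mk %in% names(shift)) sc[histology == h] <-
            sc[histology == h] + shift[[mk]]
      }
    }
    data.frame(core_id = coreIds, patient_id = patient, site = site,
               histology = histology, marker = mk,
               score = pmin(pmax(sc, 0), hi), stringsAsFactors = FALSE)
  })
  hs <- do.call(rbind, rows)
  rownames(hs) <- NULL
  truth <- spec$markerPairs
  list(hscores = validateHScores(hs), truth = truth)
}
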