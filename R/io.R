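#' Read a single-cell expression matrix
#'
#' Reads either a 10x-style Matrix Market triplet (`matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`, gzip-tolerant) or a dense CSV with genes
#' in rows. The result is a [SingleCellExperiment::SingleCellExperiment]
#' with the raw values in assay `"counts"`; genes are rows, cells are
#' columns throughout the package.
#'
#' @param path directory containing the MTX triplet, or a CSV file.
#' @param format `"mtx"` or `"csv"`.
#' @param genesInRows for CSV input: whether rows are genes (default TRUE);
#'   set FALSE for a cells x genes sheet, which is transposed on read.
#' @return a `SingleCellExperiment` with assay `"counts"`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(matrix(1:6, 3, dimnames = list(paste0("g", 1:3), NULL)),
#'           tf, row.names = TRUE)
#' sce <- readExpression(tf, format = "csv")
#' dim(sce)
#' @export
readExpression <- function(path, format = c("mtx", "csv"),
                           genesInRows = TRUE) {
  format <- match.arg(format)
  if (format == "mtx") {
    find1 <- function(stem) {
      cand <- file.path(path, c(stem, paste0(stem, ".gz")))
      hit <- cand[file.exists(cand)]
      if (!length(hit)) stop("missing ", stem, " in ", path)
      hit[[1]]
    }
    m <- Matrix::readMM(find1("matrix.mtx"))
    feats <- utils::read.delim(find1("features.tsv"), header = FALSE,
                               stringsAsFactors = FALSE)
    bars <- utils::read.delim(find1("barcodes.tsv"), header = FALSE,
                              stringsAsFactors = FALSE)
    if (nrow(feats) != nrow(m) || nrow(bars) != ncol(m))
      stop(sprintf(paste0("dimension mismatch: matrix is %d x %d but ",
                          "features has %d rows and barcodes %d"),
                   nrow(m), ncol(m), nrow(feats), nrow(bars)))
    geneIds <- as.character(feats[[1]])
    cellIds <- as.character(bars[[1]])
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    ids <- as.character(df[[1]])
    .checkUniqueIds(ids, if (genesInRows) "gene" else "cell")
    m <- as.matrix(df[-1])
    rownames(m) <- ids
    if (!genesInRows) m <- t(m)
    geneIds <- rownames(m)
    cellIds <- colnames(m)
  }
  .checkUniqueIds(geneIds, "gene")
  .checkUniqueIds(cellIds, "cell")
  m <- as.matrix(m)
  if (any(m < 0) || any(m != floor(m)))
    stop("counts layer must contain non-negative integers")
  dimnames(m) <- list(geneIds, cellIds)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

.checkUniqueIds <- function(ids, what) {
  if (anyNA(ids) || any(ids == ""))
    stop("missing ", what, " ids")
  if (anyDuplicated(ids))
    stop("duplicate ", what, " ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  invisible(TRUE)
}

#' Attach a cell annotation table
#'
#' Validates and stores per-cell annotation (patient, disease category,
#' site) in the `colData` of an expression object. Every cell must be
#' annotated exactly once and the category must come from the closed set
#' `naive_CSPC`, `CRPC_adeno`, `NEPC`.
#'
#' @param sce a `SingleCellExperiment`.
#' @param annot data.frame with columns `cell_id`, `patient_id`,
#'   `category`, and optionally `site` plus free extra columns.
#' @return `sce` with populated `colData`.
#' @export
annotateCells <- function(sce, annot) {
  req <- c("cell_id", "patient_id", "category")
  miss <- setdiff(req, names(annot))
  if (length(miss))
    stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(annot$cell_id))
    stop("duplicate cell_id in annotation: ",
         paste(unique(annot$cell_id[duplicated(annot$cell_id)]),
               collapse = ", "))
  allowed <- c("naive_CSPC", "CRPC_adeno", "NEPC")
  bad <- setdiff(unique(annot$category), allowed)
  if (length(bad))
    stop("category outside {", paste(allowed, collapse = ", "), "}: ",
         paste(bad, collapse = ", "))
  idx <- match(colnames(sce), annot$cell_id)
  if (anyNA(idx))
    stop("cells without annotation: ",
         paste(utils::head(colnames(sce)[is.na(idx)], 5), collapse = ", "))
  cd <- annot[idx, setdiff(names(annot), "cell_id"), drop = FALSE]
  rownames(cd) <- colnames(sce)
  SummarizedExperiment::colData(sce) <- S4Vectors::DataFrame(cd)
  sce
}

#' Read regulons from a GMT file
#'
#' One regulon per line: TF name, description, then target genes, all
#' tab-separated. Lines with an empty gene list are rejected.
#'
#' @param path GMT file.
#' @param includeTF whether the TF itself counts in reported sizes.
#' @return a [RegulonSet-class] in file order.
#' @export
readRegulons <- function(path, includeTF = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line(s) without target genes: ",
         paste(short, collapse = ", "))
  targets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(targets) <- vapply(parts, `[[`, character(1), 1L)
  RegulonSet(targets, includeTF = includeTF)
}

#' Write a RegulonSet to GMT
#' @param regulons a [RegulonSet-class]
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeRegulons <- function(regulons, path) {
  lines <- vapply(names(regulons), function(nm)
    paste(c(nm, "na", regulons[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TMA H-score table
#'
#' Accepts a long CSV/TSV (columns `core_id`, `patient_id`, `site`,
#' `histology`, `marker`, `score`) or a wide sheet (one row per core, one
#' column per marker) which is reshaped to long form; missing stains are
#' absent rows, never zeros. H-scores must lie in [0, 200]; markers listed
#' in `kiMarkers` (proliferation index) in [0, 100].
#'
#' @param path CSV or TSV file.
#' @param kiMarkers marker names held to the 0-100 scale
#'   (case-insensitive).
#' @return a validated long-format data.frame.
#' @export
readHScores <- function(path, kiMarkers = c("KI67", "Ki-67")) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  idCols <- c("core_id", "patient_id", "site", "histology")
  if (!"marker" %in% names(df)) {
    miss <- setdiff(idCols, names(df))
    if (length(miss))
      stop("H-score table lacks columns: ", paste(miss, collapse = ", "))
    markers <- setdiff(names(df), idCols)
    long <- do.call(rbind, lapply(markers, function(mk)
      data.frame(df[idCols], marker = mk, score = df[[mk]],
                 stringsAsFactors = FALSE)))
    df <- long[!is.na(long$score), , drop = FALSE]
    rownames(df) <- NULL
  }
  validateHScores(df, kiMarkers = kiMarkers)
}

#' Validate a long-format H-score table
#'
#' Enforces the container invariants: required columns, histology from
#' {PRAD, HGC, NEPC}, unique (core, marker) pairs, scores within the
#' marker's scale.
#' @inheritParams readHScores
#' @param df long-format data.frame.
#' @return `df`, invisibly validated.
#' @export
validateHScores <- function(df, kiMarkers = c("KI67", "Ki-67")) {
  req <- c("core_id", "patient_id", "site", "histology", "marker", "score")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("H-score table lacks columns: ", paste(miss, collapse = ", "))
  badHist <- setdiff(unique(df$histology), c("PRAD", "HGC", "NEPC"))
  if (length(badHist))
    stop("histology outside {PRAD, HGC, NEPC}: ",
         paste(badHist, collapse = ", "))
  dup <- duplicated(df[c("core_id", "marker")])
  if (any(dup))
    stop("duplicate (core_id, marker) rows at indices: ",
         paste(which(dup), collapse = ", "))
  isKi <- tolower(df$marker) %in% tolower(kiMarkers)
  upper <- ifelse(isKi, 100, 200)
  bad <- which(!is.finite(df$score) | df$score < 0 | df$score > upper)
  if (length(bad))
    stop("score out of range at row(s): ", paste(bad, collapse = ", "),
         " (H-scores 0-200; ", paste(kiMarkers, collapse = "/"),
         " 0-100)")
  df
}

#' Log-normalize a counts layer
#'
#' Per cell: `log(1 + scaleFactor * count / total)`, natural log. Cells
#' with zero total are kept (all-zero profile) with a warning. Depth
#' scaling a cell leaves its profile unchanged.
#'
#' @param sce expression object with a `"counts"` assay.
#' @param scaleFactor library-size target (default 1e4).
#' @return `sce` with an added `"lognorm"` assay.
#' @export
logNormalize <- function(sce, scaleFactor = 1e4) {
  counts <- .getLayer(sce, "counts")
  if (any(counts < 0)) stop("negative values in counts layer")
  totals <- colSums(counts)
  if (any(totals == 0))
    warning("all-zero cells kept as all-zero lognorm profiles: ",
            paste(utils::head(colnames(counts)[totals == 0], 5),
                  collapse = ", "))
  scale <- ifelse(totals > 0, scaleFactor / totals, 0)
  ln <- log1p(sweep(counts, 2, scale, `*`))
  SummarizedExperiment::assay(sce, "lognorm") <- ln
  sce
}

#' Write a tabular result (or matrix) to CSV/TSV
#'
#' Full double precision (round-trips to at least 1e-12); header row always
#' present; matrices are written with their row names in the first column.
#'
#' @param x data.frame or matrix.
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @return invisibly, `path`.
#' @export
writeTable <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  ok <- tryCatch({
    utils::write.table(x, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, qmethod = "double")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Write an expression object as a 10x-style MTX triplet
#' @param sce expression object; the `"counts"` assay is written.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeExpression <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(.getLayer(sce, "counts"), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(rownames(sce)),
                     file.path(dir, "features.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(colnames(sce)),
                     file.path(dir, "barcodes.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(dir)
}
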