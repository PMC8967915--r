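#' Central QC data container
#'
#' `QCExperiment()` builds a [SingleCellExperiment::SingleCellExperiment]
#' holding one gene-by-barcode count matrix together with the matrix *level*
#' ("Droplet", "Cell" or "FilteredCell"), a mandatory per-barcode `sample`
#' annotation, and a provenance log of every QC operation applied (operation
#' name, parameters, seed, timestamp, package version).
#'
#' Levels encode how far filtering has progressed: a Droplet matrix still
#' contains empty droplets, a Cell matrix keeps only barcodes called as real
#' cells, and a FilteredCell matrix additionally drops poor-quality cells.
#' A Cell matrix may only be derived from a Droplet matrix by column
#' subsetting, and FilteredCell only from Cell.
#'
#' @param counts sparse or dense non-negative integer matrix, genes in rows,
#'   barcodes in columns. Dimnames are taken as gene/barcode identifiers when
#'   `gene_ids`/`barcode_ids` are not given.
#' @param level one of `"Droplet"`, `"Cell"`, `"FilteredCell"`.
#' @param sample character scalar or per-barcode vector of sample labels.
#' @param gene_ids,barcode_ids optional identifier vectors overriding the
#'   dimnames; must be unique within their axis.
#' @return A `SingleCellExperiment` with `counts` assay, `sample` column in
#'   `colData`, and `metadata(x)$level` / `metadata(x)$provenance` set.
#' @examples
#' m <- Matrix::rsparsematrix(10, 4, 0.5)
#' m@x <- abs(round(m@x * 10))
#' exp <- QCExperiment(m, level = "Droplet", sample = "s1")
#' matrixLevel(exp)
#' @export
QCExperiment <- function(counts, level = c("Droplet", "Cell", "FilteredCell"),
                         sample = "sample1", gene_ids = NULL,
                         barcode_ids = NULL) {
  level <- match.arg(level)
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (any(counts@x < 0)) stopf("count matrix has negative entries")
  if (any(counts@x != round(counts@x)))
    stopf("count matrix has non-integer entries; values must be counts")
  gene_ids <- gene_ids %||% rownames(counts) %||%
    sprintf("gene%d", seq_len(nrow(counts)))
  barcode_ids <- barcode_ids %||% colnames(counts) %||%
    sprintf("barcode%d", seq_len(ncol(counts)))
  if (length(gene_ids) != nrow(counts))
    stopf("gene_ids length (%d) != number of rows (%d)",
          length(gene_ids), nrow(counts))
  if (length(barcode_ids) != ncol(counts))
    stopf("barcode_ids length (%d) != number of columns (%d)",
          length(barcode_ids), ncol(counts))
  if (anyDuplicated(gene_ids))
    stopf("duplicate gene identifiers (e.g. '%s')",
          gene_ids[duplicated(gene_ids)][1])
  if (anyDuplicated(barcode_ids))
    stopf("duplicate barcode identifiers (e.g. '%s')",
          barcode_ids[duplicated(barcode_ids)][1])
  dimnames(counts) <- list(gene_ids, barcode_ids)
  sample <- as.character(sample)
  if (length(sample) == 1L) sample <- rep(sample, ncol(counts))
  if (length(sample) != ncol(counts))
    stopf("'sample' must be scalar or one label per barcode")
  if (any(is.na(sample) | sample == ""))
    stopf("'sample' labels must be non-empty for every barcode")
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sample = sample, row.names = barcode_ids))
  S4Vectors::metadata(sce)$level <- level
  S4Vectors::metadata(sce)$provenance <- list()
  sce
}

#' Matrix level of a QC experiment
#' @param exp a `QCExperiment`.
#' @return `"Droplet"`, `"Cell"` or `"FilteredCell"`.
#' @export
matrixLevel <- function(exp) {
  lv <- S4Vectors::metadata(exp)$level
  if (is.null(lv)) stopf("experiment carries no matrix level")
  lv
}

#' Provenance log of a QC experiment
#' @param exp a `QCExperiment`.
#' @return List of provenance entries (operation, parameters, seed,
#'   timestamp, version), in execution order.
#' @export
provenance <- function(exp) S4Vectors::metadata(exp)$provenance %||% list()

#' Append a provenance entry
#'
#' Every QC operation records exactly one entry; re-running a pipeline from
#' the recorded parameters and seeds reproduces identical stochastic output.
#'
#' @param exp a `QCExperiment`.
#' @param operation operation name.
#' @param parameters named list of parameters as actually used.
#' @param seed integer seed used, or `NA` for deterministic operations.
#' @return The experiment with the entry appended.
#' @export
logProvenance <- function(exp, operation, parameters = list(), seed = NA) {
  entry <- list(operation = operation, parameters = parameters,
                seed = if (is.na(seed[1])) NA_integer_ else as.integer(seed),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                version = as.character(packageVersion("scqckit")))
  S4Vectors::metadata(exp)$provenance <-
    c(provenance(exp), list(entry))
  exp
}

#' Attach a per-barcode metric column
#'
#' @param exp a `QCExperiment`.
#' @param name column name.
#' @param values vector with one entry per barcode.
#' @param overwrite allow replacing an existing column.
#' @return The experiment with the column appended; everything else
#'   unchanged.
#' @export
attachCellMetric <- function(exp, name, values, overwrite = FALSE) {
  if (length(values) != ncol(exp))
    stopf("metric '%s' has %d values for %d barcodes",
          name, length(values), ncol(exp))
  if (name %in% colnames(SummarizedExperiment::colData(exp)) && !overwrite)
    stopf("cell annotation '%s' already present (use overwrite = TRUE)", name)
  SummarizedExperiment::colData(exp)[[name]] <- values
  exp
}

levelRank <- c(Droplet = 1L, Cell = 2L, FilteredCell = 3L)

#' Subset barcodes, optionally advancing the matrix level
#'
#' Legal level transitions are Droplet to Cell, Cell to FilteredCell, or
#' staying at the same level; skipping a level is an error. All assays,
#' annotations and reduced dimensions are subset to the kept columns in their
#' original order and retained entries are untouched.
#'
#' @param exp a `QCExperiment`.
#' @param keep logical vector, one per barcode.
#' @param new_level target level (default: unchanged).
#' @return The subset experiment with a provenance entry appended.
#' @export
subsetCells <- function(exp, keep, new_level = matrixLevel(exp)) {
  if (length(keep) != ncol(exp) || !is.logical(keep))
    stopf("'keep' must be a logical vector with one entry per barcode")
  keep[is.na(keep)] <- FALSE
  old <- matrixLevel(exp)
  if (!new_level %in% names(levelRank)) stopf("unknown level '%s'", new_level)
  if (levelRank[[new_level]] - levelRank[[old]] > 1L ||
      levelRank[[new_level]] < levelRank[[old]])
    stopf("illegal level transition %s -> %s", old, new_level)
  out <- exp[, keep]
  S4Vectors::metadata(out)$level <- new_level
  logProvenance(out, "subsetCells",
                list(kept = sum(keep), removed = sum(!keep),
                     from_level = old, to_level = new_level))
}

#' Combine per-sample experiments into one
#'
#' Columns are concatenated; the `sample` column distinguishes origin.
#' Barcodes shared between samples are disambiguated by
#' `<sample>_<barcode>` prefixing, which is deterministic and reversible.
#'
#' @param exps list of `QCExperiment`s sharing an identical gene universe and
#'   matrix level.
#' @return A single combined `QCExperiment`.
#' @export
combineSamples <- function(exps) {
  stopifnot(is.list(exps), length(exps) >= 1L)
  if (length(exps) == 1L) return(exps[[1]])
  genes <- rownames(exps[[1]])
  lv <- matrixLevel(exps[[1]])
  for (e in exps[-1]) {
    if (!identical(rownames(e), genes))
      stopf("experiments do not share an identical gene universe")
    if (!identical(matrixLevel(e), lv))
      stopf("experiments are at different matrix levels")
  }
  bcs <- lapply(exps, colnames)
  if (anyDuplicated(unlist(bcs))) {
    exps <- lapply(exps, function(e) {
      colnames(e) <- paste(e$sample, colnames(e), sep = "_")
      e
    })
  }
  common <- Reduce(intersect, lapply(exps, function(e)
    colnames(SummarizedExperiment::colData(e))))
  exps <- lapply(exps, function(e) {
    SummarizedExperiment::colData(e) <-
      SummarizedExperiment::colData(e)[, common, drop = FALSE]
    e
  })
  out <- do.call(SingleCellExperiment::cbind, exps)
  S4Vectors::metadata(out) <- list(
    level = lv, provenance = do.call(c, lapply(exps, provenance)))
  logProvenance(out, "combineSamples",
                list(n_samples = length(exps),
                     n_barcodes = ncol(out)))
}

# Apply `fun(exp_subset, ...)` to each sample's columns independently and
# stitch per-barcode results back in input column order. `fun` must return a
# list of named per-barcode vectors (metrics for that sample).
perSampleMetrics <- function(exp, fun, ...) {
  smp <- exp$sample
  out <- NULL
  for (s in unique(smp)) {
    idx <- which(smp == s)
    res <- fun(exp[, idx], ...)
    if (is.null(out))
      out <- lapply(res, function(v) {
        full <- rep(if (is.numeric(v)) NA_real_ else NA, ncol(exp))
        full
      })
    for (nm in names(res)) out[[nm]][idx] <- res[[nm]]
  }
  out
}
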