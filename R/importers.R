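#' Read a MatrixMarket (MEX) triple into a count matrix
#'
#' Reads `matrix.mtx(.gz)` together with its barcode and feature sidecar
#' files. Orientation on disk is decided by matching matrix dimensions
#' against the sidecar lengths (never by which dimension is larger); the
#' returned matrix is always genes x barcodes with counts preserved exactly.
#'
#' @param matrix_path MatrixMarket coordinate file, optionally gzipped.
#' @param barcodes_path,features_path one-record-per-line text files,
#'   optionally gzipped. Feature files may carry 1-3 tab-separated columns
#'   (id, symbol, feature type).
#' @param keep_feature_types feature-type values retained when the feature
#'   file has a third column (CellRanger v3 semantics).
#' @return A sparse `dgCMatrix`, genes x barcodes, with a `features`
#'   attribute holding the full feature table.
#' @export
importMEX <- function(matrix_path, barcodes_path, features_path,
                      keep_feature_types = "Gene Expression") {
  for (p in c(matrix_path, barcodes_path, features_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  con <- openText(matrix_path)
  m <- Matrix::readMM(con)
  try(close(con), silent = TRUE)
  m <- as(as(m, "CsparseMatrix"), "dMatrix")
  if (any(m@x != round(m@x)))
    stopf("matrix '%s' has non-integer entries; values must be counts",
          matrix_path)
  if (any(m@x < 0)) stopf("matrix '%s' has negative entries", matrix_path)
  bc <- readSidecar(barcodes_path)
  ft <- readSidecar(features_path)
  n_b <- nrow(bc); n_f <- nrow(ft)
  if (nrow(m) == n_f && ncol(m) == n_b) {
    # genes in rows already
  } else if (nrow(m) == n_b && ncol(m) == n_f) {
    m <- Matrix::t(m)
  } else {
    stopf("matrix is %d x %d but sidecars list %d features / %d barcodes",
          nrow(m), ncol(m), n_f, n_b)
  }
  gene_ids <- ft[[1]]
  if (anyDuplicated(gene_ids))
    stopf("duplicate gene identifiers in '%s' (e.g. '%s')", features_path,
          gene_ids[duplicated(gene_ids)][1])
  dimnames(m) <- list(gene_ids, bc[[1]])
  if (ncol(ft) >= 3L) {
    keep <- ft[[3]] %in% keep_feature_types
    m <- m[keep, , drop = FALSE]
    ft <- ft[keep, , drop = FALSE]
  }
  attr(m, "features") <- ft
  m
}

readSidecar <- function(path) {
  con <- openText(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) stopf("sidecar '%s' is empty", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- max(lengths(parts))
  df <- as.data.frame(do.call(rbind, lapply(parts, function(p)
    c(p, rep(NA_character_, ncols - length(p))))),
    stringsAsFactors = FALSE)
  names(df) <- c("id", "symbol", "type")[seq_len(ncols)]
  df
}

# Build a QCExperiment from an importMEX result.
mexToExperiment <- function(m, level, sample_name) {
  ft <- attr(m, "features")
  attr(m, "features") <- NULL
  exp <- QCExperiment(m, level = level, sample = sample_name)
  if (!is.null(ft) && ncol(ft) >= 2L) {
    rd <- S4Vectors::DataFrame(ft[-1], row.names = rownames(exp))
    SummarizedExperiment::rowData(exp) <- rd
  }
  exp
}

#' Import one or more samples from a preprocessing-tool output layout
#'
#' Reads the Droplet ("raw") and/or Cell ("filtered") matrices for each
#' sample directory according to the tool's on-disk dialect, then combines
#' samples with [combineSamples()]. Supported dialects: `cellranger_v2`,
#' `cellranger_v3`, `starsolo`, `bustools`, `dropest`, `mex`.
#'
#' @param sample_dirs character vector of top-level sample directories.
#' @param sample_names sample labels, one per directory.
#' @param tool dialect name.
#' @param data_type which matrices to read: `"Droplet"`, `"Cell"` or
#'   `"Both"`. `"Both"` requires a dialect that emits both matrices.
#' @return A list with elements `droplet` and `cell`, each a `QCExperiment`
#'   or `NULL`.
#' @export
importSamples <- function(sample_dirs, sample_names = basename(sample_dirs),
                          tool = "cellranger_v3",
                          data_type = c("Both", "Droplet", "Cell")) {
  data_type <- match.arg(data_type)
  if (length(sample_dirs) != length(sample_names))
    stopf("sample_dirs and sample_names differ in length")
  man <- mexDialects()
  if (!tool %in% names(man)) stopf("unknown preprocessing tool '%s'", tool)
  if (data_type %in% c("Cell", "Both") && is.null(man[[tool]]$filtered))
    stopf("tool '%s' emits no Cell (filtered) matrix; use data_type='Droplet'",
          tool)
  readOne <- function(dir, name, which, level) {
    paths <- resolveDialectPaths(tool, dir, which)
    miss <- paths[!file.exists(paths)]
    if (length(miss))
      stopf("sample '%s': expected %s-layout file(s) missing: %s",
            name, tool, paste(miss, collapse = ", "))
    m <- importMEX(paths[["matrix"]], paths[["barcodes"]],
                   paths[["features"]])
    mexToExperiment(m, level, name)
  }
  droplet <- cell <- NULL
  if (data_type %in% c("Droplet", "Both"))
    droplet <- combineSamples(mapply(readOne, sample_dirs, sample_names,
                                     MoreArgs = list(which = "raw",
                                                     level = "Droplet"),
                                     SIMPLIFY = FALSE))
  if (data_type %in% c("Cell", "Both"))
    cell <- combineSamples(mapply(readOne, sample_dirs, sample_names,
                                  MoreArgs = list(which = "filtered",
                                                  level = "Cell"),
                                  SIMPLIFY = FALSE))
  list(droplet = droplet, cell = cell)
}

#' Import CellRanger v2/v3 sample directories
#'
#' Thin wrappers around [importSamples()] for the two CellRanger layouts
#' (v2: `raw_gene_bc_matrices/<genome>/genes.tsv`, uncompressed; v3:
#' `raw_feature_bc_matrix/features.tsv.gz`, gzipped).
#'
#' @inheritParams importSamples
#' @return As [importSamples()].
#' @export
importCellRangerV2 <- function(sample_dirs,
                               sample_names = basename(sample_dirs),
                               data_type = c("Both", "Droplet", "Cell")) {
  importSamples(sample_dirs, sample_names, "cellranger_v2",
                match.arg(data_type))
}

#' @rdname importCellRangerV2
#' @export
importCellRangerV3 <- function(sample_dirs,
                               sample_names = basename(sample_dirs),
                               data_type = c("Both", "Droplet", "Cell")) {
  importSamples(sample_dirs, sample_names, "cellranger_v3",
                match.arg(data_type))
}

#' Import a delimited text count matrix
#'
#' @param path delimited file, optionally gzipped; header row of barcodes,
#'   first column of gene ids (or the transpose with
#'   `genes_in_rows = FALSE`).
#' @param delimiter field separator.
#' @param genes_in_rows orientation flag.
#' @return A sparse genes x barcodes `dgCMatrix`.
#' @export
importDelimited <- function(path, delimiter = ",", genes_in_rows = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(
    readTSVGz(path, sep = delimiter, header = TRUE,
              row.names = 1L, check.names = FALSE, fill = FALSE),
    error = function(e) stopf("malformed delimited matrix '%s': %s",
                              path, conditionMessage(e)))
  m <- as.matrix(df)
  if (!is.numeric(m)) stopf("non-numeric entries in '%s'", path)
  if (any(m < 0)) stopf("negative entries in '%s'", path)
  if (any(m != round(m)))
    stopf("non-integer entries in '%s'; values must be counts", path)
  if (!genes_in_rows) m <- t(m)
  if (anyDuplicated(rownames(m)))
    stopf("duplicate gene identifiers in '%s'", path)
  as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}
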