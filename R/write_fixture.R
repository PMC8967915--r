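#' Write an experiment to disk in a supported importer dialect
#'
#' Emits the on-disk layout of each supported preprocessing tool
#' (`cellranger_v2`, `cellranger_v3`, `starsolo`, `bustools`, `dropest`,
#' `mex`) plus `csv` and `h5ad`, faithful to the dialect manifest used by
#' the importers, so every layout can be round-tripped in tests without
#' downloads.
#'
#' @param exp a `QCExperiment` (the Droplet matrix for raw layouts).
#' @param dialect layout name.
#' @param out_dir sample directory to create.
#' @param cell_barcodes optional character vector (or logical per barcode)
#'   naming the barcodes written to the "filtered" matrix for dialects that
#'   carry one; defaults to all barcodes.
#' @return `out_dir`, invisibly.
#' @export
writeFixture <- function(exp, dialect, out_dir, cell_barcodes = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- SummarizedExperiment::assay(exp, "counts")
  if (dialect == "csv") {
    path <- file.path(out_dir, "counts.csv")
    df <- as.data.frame(as.matrix(counts), check.names = FALSE)
    write.table(cbind(gene = rownames(counts), df), path, sep = ",",
                quote = FALSE, row.names = FALSE)
    return(invisible(out_dir))
  }
  if (dialect == "h5ad") {
    exportAnnData(exp, file.path(out_dir, "sample.h5ad"),
                  compression = "gzip")
    return(invisible(out_dir))
  }
  man <- mexDialects()
  if (!dialect %in% names(man)) stopf("unknown dialect '%s'", dialect)
  d <- man[[dialect]]
  writeTriple <- function(rel, m) {
    if (d$genome_subdir) rel <- vapply(rel, sprintf, character(1), "genome")
    paths <- setNames(file.path(out_dir, rel), names(rel))
    for (p in unique(dirname(paths)))
      dir.create(p, recursive = TRUE, showWarnings = FALSE)
    writeMEXTriple(m, paths[["matrix"]], paths[["barcodes"]],
                   paths[["features"]], feature_cols = d$feature_cols,
                   gzipped = d$gzipped,
                   feature_table = as.data.frame(
                     SummarizedExperiment::rowData(exp)))
  }
  writeTriple(d$raw, counts)
  if (!is.null(d$filtered)) {
    keep <- cell_barcodes %||% colnames(counts)
    if (is.logical(keep)) keep <- colnames(counts)[keep]
    writeTriple(d$filtered, counts[, keep, drop = FALSE])
  }
  invisible(out_dir)
}

# Write one MEX triple; paths include any .gz suffix desired by the dialect.
writeMEXTriple <- function(m, matrix_path, barcodes_path, features_path,
                           feature_cols = 2L, gzipped = FALSE,
                           feature_table = NULL) {
  writeLinesMaybeGz <- function(lines, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    writeLines(lines, con)
    close(con)
  }
  tmp <- sub("\\.gz$", "", matrix_path)
  Matrix::writeMM(as(m, "CsparseMatrix"), tmp)
  if (grepl("\\.gz$", matrix_path)) gzipFile(tmp)
  writeLinesMaybeGz(colnames(m), barcodes_path)
  ids <- rownames(m)
  sym <- if (!is.null(feature_table$symbol))
    as.character(feature_table$symbol) else ids
  feat <- switch(as.character(feature_cols),
                 "1" = ids,
                 "2" = paste(ids, sym, sep = "\t"),
                 paste(ids, sym, "Gene Expression", sep = "\t"))
  writeLinesMaybeGz(feat, features_path)
  invisible(NULL)
}
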