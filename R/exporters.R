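#' Export an experiment to flat files
#'
#' Writes every assay as a MatrixMarket MEX triple
#' (`<assay>_matrix.mtx`, shared `barcodes.tsv` / `features.tsv`), the cell
#' and gene annotations and every reduced dimension as tab-delimited files,
#' and the provenance log as human-auditable YAML. All files are optionally
#' gzipped. A `manifest.json` lists every written file with its MD5
#' checksum.
#'
#' @param exp a `QCExperiment`.
#' @param out_dir output directory (created if needed).
#' @param gzip gzip all text outputs.
#' @return Named character vector of written paths (the manifest),
#'   invisibly.
#' @export
exportFlatFiles <- function(exp, out_dir, gzip = TRUE) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'",
                                  out_dir)
  written <- character(0)
  finish <- function(path) {
    if (gzip) path <- gzipFile(path)
    written <<- c(written, path)
    path
  }
  writeTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    finish(path)
  }

  assays <- SummarizedExperiment::assays(exp)
  for (nm in names(assays)) {
    mpath <- file.path(out_dir, sprintf("%s_matrix.mtx", nm))
    Matrix::writeMM(as(assays[[nm]], "CsparseMatrix"), mpath)
    finish(mpath)
  }
  bpath <- file.path(out_dir, "barcodes.tsv")
  writeLines(colnames(exp), bpath); finish(bpath)
  fpath <- file.path(out_dir, "features.tsv")
  rd <- as.data.frame(SummarizedExperiment::rowData(exp))
  feat <- if (ncol(rd)) do.call(paste, c(list(rownames(exp)),
                                         lapply(rd, as.character),
                                         sep = "\t")) else rownames(exp)
  writeLines(feat, fpath); finish(fpath)

  cd <- as.data.frame(SummarizedExperiment::colData(exp))
  writeTSV(cbind(barcode = colnames(exp), cd),
           file.path(out_dir, "colData.tsv"))
  writeTSV(cbind(gene = rownames(exp), rd),
           file.path(out_dir, "rowData.tsv"))

  for (nm in names(SingleCellExperiment::reducedDims(exp))) {
    rdm <- as.data.frame(SingleCellExperiment::reducedDim(exp, nm))
    writeTSV(cbind(barcode = colnames(exp), rdm),
             file.path(out_dir, sprintf("reducedDim_%s.tsv", nm)))
  }

  meta_path <- file.path(out_dir, "metadata.yaml")
  yaml::write_yaml(list(level = matrixLevel(exp),
                        provenance = provenance(exp)), meta_path)
  written <- c(written, meta_path)  # metadata stays uncompressed

  manifest <- lapply(written, function(p)
    list(file = basename(p), md5 = digest::digest(file = p, algo = "md5")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  names(written) <- basename(written)
  invisible(written)
}

#' Re-import a flat-file export
#'
#' Inverse of [exportFlatFiles()]: reconstructs the experiment (counts,
#' extra assays, annotations, reduced dimensions, provenance) from an
#' export directory.
#'
#' @param dir directory written by [exportFlatFiles()].
#' @return A `QCExperiment`.
#' @export
importFlatFiles <- function(dir) {
  find <- function(base) {
    for (p in file.path(dir, c(base, paste0(base, ".gz"))))
      if (file.exists(p)) return(p)
    stopf("missing '%s' in flat-file export '%s'", base, dir)
  }
  readMMGz <- function(path) {
    con <- openText(path)
    on.exit(try(close(con), silent = TRUE))
    Matrix::readMM(con)
  }
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  m <- readMMGz(find("counts_matrix.mtx"))
  barcodes <- readLinesGz(find("barcodes.tsv"))
  features <- readLinesGz(find("features.tsv"))
  gene_ids <- vapply(strsplit(features, "\t"), `[`, "", 1L)
  dimnames(m) <- list(gene_ids, barcodes)
  cd <- readTSVGz(find("colData.tsv"), check.names = FALSE)
  exp <- QCExperiment(as(m, "CsparseMatrix"), level = meta$level %||% "Cell",
                      sample = as.character(cd$sample))
  for (cc in setdiff(colnames(cd), c("barcode", "sample")))
    exp <- attachCellMetric(exp, cc, cd[[cc]])
  rdf <- readTSVGz(find("rowData.tsv"), check.names = FALSE)
  if (ncol(rdf) > 1L)
    SummarizedExperiment::rowData(exp) <-
      S4Vectors::DataFrame(rdf[-1], row.names = rownames(exp))
  mats <- list.files(dir, pattern = "_matrix\\.mtx(\\.gz)?$")
  for (f in mats) {
    nm <- sub("_matrix\\.mtx(\\.gz)?$", "", f)
    if (nm == "counts") next
    a <- readMMGz(file.path(dir, f))
    dimnames(a) <- dimnames(m)
    SummarizedExperiment::assay(exp, nm) <- as(a, "CsparseMatrix")
  }
  reds <- list.files(dir, pattern = "^reducedDim_.*\\.tsv(\\.gz)?$")
  for (f in reds) {
    nm <- sub("^reducedDim_(.*)\\.tsv(\\.gz)?$", "\\1", f)
    rdm <- readTSVGz(file.path(dir, f), check.names = FALSE)
    SingleCellExperiment::reducedDim(exp, nm) <-
      as.matrix(rdm[, -1, drop = FALSE])
  }
  S4Vectors::metadata(exp)$provenance <- meta$provenance %||% list()
  exp
}
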