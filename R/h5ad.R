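# Native h5ad (AnnData-on-disk) reading and writing via rhdf5, following
# the anndata 0.8+ on-disk encoding: X as dense array or csr/csc group,
# obs/var as "dataframe" groups with an "_index" dataset, obsm as a dict of
# arrays, uns for unstructured metadata. Note rhdf5 presents datasets to R
# column-major, so a dataset h5py sees as (n_obs, n_var) reads into R as
# var x obs.

h5attrString <- function(file, path, name, value) {
  fid <- rhdf5::H5Fopen(file)
  obj <- rhdf5::H5Oopen(fid, path)
  on.exit({ rhdf5::H5Oclose(obj); rhdf5::H5Fclose(fid) })
  rhdf5::h5writeAttribute(value, obj, name, variableLengthString = TRUE,
                          asScalar = length(value) == 1L)
}

h5attrPlain <- function(file, path, name, value) {
  fid <- rhdf5::H5Fopen(file)
  obj <- rhdf5::H5Oopen(fid, path)
  on.exit({ rhdf5::H5Oclose(obj); rhdf5::H5Fclose(fid) })
  rhdf5::h5writeAttribute(value, obj, name)
}

h5writeEncoded <- function(x, file, path) {
  if (is.factor(x)) x <- as.character(x)
  bool <- is.logical(x)
  if (bool) x <- as.integer(x)
  if (is.character(x)) {
    rhdf5::h5write(x, file, path, variableLengthString = TRUE)
    h5attrString(file, path, "encoding-type", "string-array")
  } else {
    rhdf5::h5write(x, file, path)
    h5attrString(file, path, "encoding-type", "array")
  }
  h5attrString(file, path, "encoding-version", "0.2.0")
  if (bool) h5attrPlain(file, path, "is_boolean", 1L)
}

h5writeDataFrame <- function(df, index, file, group) {
  rhdf5::h5createGroup(file, group)
  h5attrString(file, group, "encoding-type", "dataframe")
  h5attrString(file, group, "encoding-version", "0.2.0")
  h5attrString(file, group, "_index", "_index")
  cols <- colnames(df) %||% character(0)
  # column-order must exist even when empty (empty numeric array, as the
  # reference writer emits)
  if (length(cols))
    h5attrString(file, group, "column-order", cols)
  else
    h5attrPlain(file, group, "column-order", numeric(0))
  rhdf5::h5write(index, file, paste0(group, "/_index"),
                 variableLengthString = TRUE)
  h5attrString(file, paste0(group, "/_index"), "encoding-type",
               "string-array")
  h5attrString(file, paste0(group, "/_index"), "encoding-version", "0.2.0")
  for (cc in cols)
    h5writeEncoded(df[[cc]], file, paste0(group, "/", cc))
}

#' Export an experiment to an h5ad (AnnData) file
#'
#' Writes the primary count assay as `X` (cells x genes, CSR), extra assays
#' into `layers`, cell annotations to `obs`, gene annotations to `var`,
#' reduced dimensions to `obsm`, and the provenance log as YAML text under
#' `uns/provenance`. The result is readable by Python AnnData and by
#' [importH5AD()].
#'
#' @param exp a `QCExperiment`.
#' @param out_path output file path.
#' @param compression `"gzip"` or `"none"` (the lzf filter is not available
#'   in this HDF5 stack and raises a parameter error).
#' @return `out_path`, invisibly.
#' @export
exportAnnData <- function(exp, out_path, compression = "gzip") {
  if (!compression %in% c("gzip", "none"))
    stopf("unsupported compression '%s' (supported: gzip, none)",
          compression)
  level <- if (compression == "gzip") 6L else 0L
  if (file.exists(out_path)) unlink(out_path)
  rhdf5::h5createFile(out_path)
  h5attrString(out_path, "/", "encoding-type", "anndata")
  h5attrString(out_path, "/", "encoding-version", "0.1.0")

  writeCSR <- function(m, group) {
    # genes x barcodes CSC == cells x genes CSR
    m <- as(m, "CsparseMatrix")
    rhdf5::h5createGroup(out_path, group)
    writeDS <- function(v, nm, mode) {
      p <- paste0(group, "/", nm)
      rhdf5::h5createDataset(out_path, p, dims = length(v),
                             storage.mode = mode, level = level,
                             chunk = min(length(v), 65536L))
      rhdf5::h5write(v, out_path, p)
    }
    writeDS(m@x, "data", "double")
    writeDS(m@i, "indices", "integer")
    writeDS(m@p, "indptr", "integer")
    h5attrString(out_path, group, "encoding-type", "csr_matrix")
    h5attrString(out_path, group, "encoding-version", "0.1.0")
    h5attrPlain(out_path, group, "shape", c(ncol(m), nrow(m)))
  }

  assays <- SummarizedExperiment::assays(exp)
  writeCSR(assays[[1]], "X")
  if (length(assays) > 1L) {
    rhdf5::h5createGroup(out_path, "layers")
    h5attrString(out_path, "layers", "encoding-type", "dict")
    h5attrString(out_path, "layers", "encoding-version", "0.1.0")
    for (nm in names(assays)[-1])
      writeCSR(assays[[nm]], paste0("layers/", nm))
  }

  cd <- as.data.frame(SummarizedExperiment::colData(exp))
  h5writeDataFrame(cd, colnames(exp), out_path, "obs")
  rd <- as.data.frame(SummarizedExperiment::rowData(exp))
  h5writeDataFrame(rd, rownames(exp), out_path, "var")

  rdims <- SingleCellExperiment::reducedDims(exp)
  if (length(rdims)) {
    rhdf5::h5createGroup(out_path, "obsm")
    h5attrString(out_path, "obsm", "encoding-type", "dict")
    h5attrString(out_path, "obsm", "encoding-version", "0.1.0")
    for (nm in names(rdims)) {
      p <- paste0("obsm/", nm)
      rhdf5::h5write(t(unname(as.matrix(rdims[[nm]]))), out_path, p)
      h5attrString(out_path, p, "encoding-type", "array")
      h5attrString(out_path, p, "encoding-version", "0.2.0")
    }
  }

  rhdf5::h5createGroup(out_path, "uns")
  h5attrString(out_path, "uns", "encoding-type", "dict")
  h5attrString(out_path, "uns", "encoding-version", "0.1.0")
  meta <- list(level = matrixLevel(exp), provenance = provenance(exp))
  h5writeEncoded(yaml::as.yaml(meta), out_path, "uns/provenance")
  invisible(out_path)
}

h5ReadAttr <- function(path, obj, name) {
  att <- tryCatch(rhdf5::h5readAttributes(path, obj), error = function(e)
    list())
  att[[name]]
}

#' Import an h5ad (AnnData) file
#'
#' Reads `X` (dense, CSR or CSC), `obs`/`var` dataframes (including
#' categorical columns), `obsm` embeddings and, when present, the
#' provenance log written by [exportAnnData()]. When `obs` carries no
#' `sample` column the file stem is used as the sample label.
#'
#' @param path h5ad file.
#' @param level matrix level to assign when the file does not record one.
#' @return A `QCExperiment`.
#' @export
importH5AD <- function(path, level = "Cell") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ls <- rhdf5::h5ls(path)
  top <- ls$name[ls$group == "/"]
  if (!all(c("X", "obs", "var") %in% top))
    stopf("'%s' lacks X/obs/var groups; not an AnnData container", path)

  readMatrix <- function(group) {
    enc <- h5ReadAttr(path, group, "encoding-type")
    entries <- ls$name[ls$group == paste0("/", sub("^/", "", group))]
    if (!is.null(enc) && enc %in% c("csr_matrix", "csc_matrix") ||
        all(c("data", "indices", "indptr") %in% entries)) {
      data <- as.numeric(rhdf5::h5read(path, paste0(group, "/data")))
      indices <- as.integer(rhdf5::h5read(path, paste0(group, "/indices")))
      indptr <- as.integer(rhdf5::h5read(path, paste0(group, "/indptr")))
      shape <- as.integer(h5ReadAttr(path, group, "shape"))  # (obs, var)
      if (identical(enc, "csc_matrix"))
        m <- Matrix::t(new("dgCMatrix", x = data, i = indices, p = indptr,
                           Dim = c(shape[1], shape[2])))
      else
        m <- new("dgCMatrix", x = data, i = indices, p = indptr,
                 Dim = c(shape[2], shape[1]))  # genes x cells
      m
    } else {
      m <- rhdf5::h5read(path, group)  # R sees var x obs
      as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    }
  }

  readDF <- function(group) {
    entries <- ls[ls$group == paste0("/", group), , drop = FALSE]
    idx_name <- h5ReadAttr(path, group, "_index") %||% "_index"
    index <- as.character(rhdf5::h5read(path, paste0(group, "/", idx_name)))
    cols <- h5ReadAttr(path, group, "column-order")
    if (is.null(cols))
      cols <- setdiff(entries$name, idx_name)
    df <- data.frame(row.names = index)
    for (cc in cols) {
      p <- paste0(group, "/", cc)
      sub <- entries[entries$name == cc, , drop = FALSE]
      if (nrow(sub) && sub$otype[1] == "H5I_GROUP") {
        cats <- rhdf5::h5read(path, paste0(p, "/categories"))
        codes <- as.integer(rhdf5::h5read(path, paste0(p, "/codes")))
        v <- as.character(cats)[ifelse(codes < 0L, NA_integer_,
                                       codes + 1L)]
      } else {
        v <- rhdf5::h5read(path, p)
        if (is.raw(v)) v <- as.integer(v)
        if (!is.null(h5ReadAttr(path, p, "is_boolean"))) v <- as.logical(v)
        if (is.array(v)) v <- as.vector(v)
        if (is.character(v)) v <- as.character(v)
      }
      df[[cc]] <- v
    }
    df
  }

  m <- readMatrix("X")
  if (any(m@x < 0) || any(m@x != round(m@x)))
    warnf("X of '%s' does not look like raw counts", path)
  obs <- readDF("obs")
  var <- readDF("var")
  if (nrow(obs) != ncol(m) || nrow(var) != nrow(m))
    stopf("dimension mismatch between X (%d x %d) and var/obs (%d / %d)",
          nrow(m), ncol(m), nrow(var), nrow(obs))
  dimnames(m) <- list(rownames(var), rownames(obs))

  meta_level <- level
  prov <- list()
  if ("uns" %in% top) {
    uns <- ls$name[ls$group == "/uns"]
    if ("provenance" %in% uns) {
      meta <- yaml::yaml.load(as.character(
        rhdf5::h5read(path, "uns/provenance")))
      meta_level <- meta$level %||% level
      prov <- meta$provenance %||% list()
    }
  }
  if (!"sample" %in% colnames(obs))
    obs$sample <- sub("\\.h5ad$", "", basename(path))

  exp <- QCExperiment(m, level = meta_level, sample = obs$sample)
  for (cc in setdiff(colnames(obs), "sample"))
    exp <- attachCellMetric(exp, cc, obs[[cc]])
  if (ncol(var))
    SummarizedExperiment::rowData(exp) <-
      S4Vectors::DataFrame(var, row.names = rownames(exp))
  S4Vectors::metadata(exp)$provenance <- prov

  if ("layers" %in% top) {
    for (nm in ls$name[ls$group == "/layers"])
      SummarizedExperiment::assay(exp, nm, withDimnames = FALSE) <-
        readMatrix(paste0("layers/", nm))
  }
  if ("obsm" %in% top) {
    for (nm in ls$name[ls$group == "/obsm"]) {
      v <- rhdf5::h5read(path, paste0("obsm/", nm))  # R sees k x obs
      SingleCellExperiment::reducedDim(exp, nm) <- t(v)
    }
  }
  rhdf5::h5closeAll()
  exp
}
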