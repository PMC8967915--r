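library(Matrix)
suppressPackageStartupMessages(library(SummarizedExperiment))

annotatedExp <- function() {
  cached("annotated_exp", {
    exp <- fxSmall()$experiment
    exp <- quietly(runPerCellQC(exp, gene_sets = geneSet(
      "set1", rownames(exp)[1:10])))
    exp <- quietly(runCxds(exp))
    runDecontXUMAP(exp, seed = 4)
  })
}

test_that("flat-file export round-trips losslessly and checksums verify", {
  exp <- annotatedExp()
  d <- tempfile()
  man <- exportFlatFiles(exp, d)
  back <- importFlatFiles(d)
  expect_identical(as.matrix(assay(exp)), as.matrix(assay(back)))
  expect_equal(as.data.frame(colData(exp)), as.data.frame(colData(back)))
  expect_equal(unname(as.matrix(SingleCellExperiment::reducedDim(
    exp, "decontX_UMAP"))),
    unname(as.matrix(SingleCellExperiment::reducedDim(back,
                                                      "decontX_UMAP"))))
  expect_identical(length(provenance(back)), length(provenance(exp)))
  # manifest checks out
  mf <- jsonlite::read_json(file.path(d, "manifest.json"),
                            simplifyVector = TRUE)
  expect_true(all(file.exists(file.path(d, mf$file))))
  for (i in seq_len(nrow(mf)))
    expect_identical(digest::digest(file = file.path(d, mf$file[i]),
                                    algo = "md5"), mf$md5[i])
})

test_that("gzip and plain flat files decompress to identical bytes", {
  exp <- fxSmall()$experiment
  d1 <- tempfile(); d2 <- tempfile()
  exportFlatFiles(exp, d1, gzip = TRUE)
  exportFlatFiles(exp, d2, gzip = FALSE)
  gz <- readLines(gzfile(file.path(d1, "colData.tsv.gz")))
  plain <- readLines(file.path(d2, "colData.tsv"))
  expect_identical(gz, plain)
  m1 <- as.matrix(readMM(gzfile(file.path(d1, "counts_matrix.mtx.gz"))))
  m2 <- as.matrix(readMM(file.path(d2, "counts_matrix.mtx")))
  expect_identical(m1, m2)
})

test_that("h5ad export/import round-trips counts, annotations, embeddings", {
  exp <- annotatedExp()
  f <- tempfile(fileext = ".h5ad")
  exportAnnData(exp, f)
  back <- importH5AD(f)
  expect_identical(as.matrix(assay(exp)), as.matrix(assay(back)))
  expect_equal(as.data.frame(colData(exp)), as.data.frame(colData(back)))
  expect_equal(unname(as.matrix(SingleCellExperiment::reducedDim(
    exp, "decontX_UMAP"))),
    unname(as.matrix(SingleCellExperiment::reducedDim(back,
                                                      "decontX_UMAP"))))
  expect_identical(matrixLevel(back), matrixLevel(exp))
  expect_identical(length(provenance(back)), length(provenance(exp)))
})

test_that("gzip-compressed and uncompressed h5ad hold identical content", {
  exp <- fxSmall()$experiment
  f1 <- tempfile(fileext = ".h5ad"); f2 <- tempfile(fileext = ".h5ad")
  exportAnnData(exp, f1, compression = "gzip")
  exportAnnData(exp, f2, compression = "none")
  b1 <- importH5AD(f1); b2 <- importH5AD(f2)
  expect_identical(as.matrix(assay(b1)), as.matrix(assay(b2)))
  expect_error(exportAnnData(exp, tempfile(), compression = "lzf"),
               "unsupported compression")
})

test_that("extra assays travel through the h5ad layers group", {
  exp <- fxSmall()$experiment[, 1:80]
  exp <- runDecontX(exp, seed = 1)
  f <- tempfile(fileext = ".h5ad")
  exportAnnData(exp, f)
  back <- importH5AD(f)
  expect_true("decontX_counts" %in% assayNames(back))
  expect_equal(as.matrix(assay(exp, "decontX_counts")),
               as.matrix(assay(back, "decontX_counts")),
               tolerance = 1e-12)
})

test_that("exported h5ad is readable by the Python AnnData stack", {
  exp <- annotatedExp()
  f <- tempfile(fileext = ".h5ad")
  exportAnnData(exp, f)
  out <- tempfile()
  script <- sprintf(paste0(
    "import anndata\nad = anndata.read_h5ad('%s')\n",
    "print(int(ad.X.sum())); print(ad.shape[0]); print(ad.shape[1])\n",
    "print(','.join(list(ad.obs.columns)[:2]))"), f)
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  res <- system2("python", sf, stdout = TRUE)
  expect_identical(res[1], as.character(sum(assay(exp))))
  expect_identical(as.integer(res[2]), ncol(exp))
  expect_identical(as.integer(res[3]), nrow(exp))
  expect_identical(res[4], "sample,total")
})

test_that("h5ad files written by Python AnnData import cleanly", {
  f <- tempfile(fileext = ".h5ad")
  script <- sprintf(paste0(
    "import anndata, numpy as np, pandas as pd, scipy.sparse as sp\n",
    "np.random.seed(0)\n",
    "X = sp.random(30, 20, 0.4, format='csr')\n",
    "X.data = np.round(X.data * 10)\n",
    "ad = anndata.AnnData(X=X,\n",
    "  obs=pd.DataFrame({'sample': pd.Categorical(['a']*15 + ['b']*15),\n",
    "                    'val': np.arange(30.0)},\n",
    "                   index=['c%%d' %% i for i in range(30)]),\n",
    "  var=pd.DataFrame(index=['g%%d' %% i for i in range(20)]))\n",
    "ad.obsm['X_pca'] = np.random.rand(30, 3)\n",
    "ad.write_h5ad('%s')\nprint(int(ad.X.sum()))"), f)
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  total <- as.numeric(system2("python", sf, stdout = TRUE))
  got <- importH5AD(f)
  expect_identical(dim(got), c(20L, 30L))
  expect_identical(sum(assay(got)), total)
  expect_identical(got$sample, rep(c("a", "b"), each = 15))
  expect_equal(got$val, 0:29)
  expect_identical(dim(SingleCellExperiment::reducedDim(got, "X_pca")),
                   c(30L, 3L))
})
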