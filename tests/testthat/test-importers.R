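library(Matrix)
suppressPackageStartupMessages(library(SummarizedExperiment))

writeTriple <- function(dir, m, barcodes, features, gz = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  suf <- if (gz) ".gz" else ""
  mp <- file.path(dir, paste0("matrix.mtx", suf))
  bp <- file.path(dir, paste0("barcodes.tsv", suf))
  fp <- file.path(dir, paste0("features.tsv", suf))
  tmp <- file.path(dir, "matrix.mtx")
  writeMM(m, tmp)
  if (gz) {
    con <- gzfile(mp, "wb"); writeBin(readBin(tmp, "raw", 1e6), con)
    close(con); unlink(tmp)
  }
  wl <- function(x, p) {
    con <- if (gz) gzfile(p, "wt") else file(p, "wt")
    writeLines(x, con); close(con)
  }
  wl(barcodes, bp); wl(features, fp)
  c(matrix = mp, barcodes = bp, features = fp)
}

test_that("MEX triples read exactly, gzipped or not", {
  m <- sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(4, 1), dims = c(3, 2))
  for (gz in c(FALSE, TRUE)) {
    p <- writeTriple(tempfile(), m, c("AAA", "CCC"),
                     paste0("g", 1:3, "\tsym", 1:3), gz = gz)
    got <- importMEX(p["matrix"], p["barcodes"], p["features"])
    expect_identical(sum(got), 5)
    expect_identical(unname(as.matrix(got)), as.matrix(m))
    expect_identical(rownames(got), paste0("g", 1:3))
  }
})

test_that("orientation is decided by sidecar lengths, not size", {
  m <- sparseMatrix(i = 1:2, j = c(1, 3), x = c(7, 2), dims = c(2, 3))
  # on disk: barcodes x genes (transposed); 2 barcodes, 3 genes
  p <- writeTriple(tempfile(), m, c("b1", "b2"), paste0("g", 1:3))
  got <- importMEX(p["matrix"], p["barcodes"], p["features"])
  expect_identical(dim(got), c(3L, 2L))
  expect_identical(unname(as.matrix(got)), t(as.matrix(m)))
})

test_that("MEX errors: sidecar mismatch, non-integers, duplicate genes", {
  m <- sparseMatrix(i = 1, j = 1, x = 1, dims = c(3, 2))
  p <- writeTriple(tempfile(), m, c("b1", "b2"), paste0("g", 1:4))
  expect_error(importMEX(p["matrix"], p["barcodes"], p["features"]),
               "sidecars")
  p <- writeTriple(tempfile(), m * 1.5, c("b1", "b2"), paste0("g", 1:3))
  expect_error(importMEX(p["matrix"], p["barcodes"], p["features"]),
               "non-integer")
  p <- writeTriple(tempfile(), m, c("b1", "b2"), c("g1", "g1", "g3"))
  expect_error(importMEX(p["matrix"], p["barcodes"], p["features"]),
               "duplicate gene")
})

test_that("delimited matrices import exactly in either orientation", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("gene,b1,b2", "g1,0,1", "g2,2,3"), f)
  m <- importDelimited(f)
  expect_identical(sum(m), 6)
  expect_identical(dim(m), c(2L, 2L))
  ft <- tempfile(fileext = ".csv")
  writeLines(c("bc,g1,g2", "b1,0,2", "b2,1,3"), ft)
  mt <- importDelimited(ft, genes_in_rows = FALSE)
  expect_identical(as.matrix(m), as.matrix(mt))
  fbad <- tempfile(fileext = ".csv")
  writeLines(c("gene,b1", "g1,1.5"), fbad)
  expect_error(importDelimited(fbad), "non-integer")
  fneg <- tempfile(fileext = ".csv")
  writeLines(c("gene,b1", "g1,-2"), fneg)
  expect_error(importDelimited(fneg), "negative")
})

test_that("every fixture dialect round-trips to the original counts", {
  sim <- fxSmall()
  exp <- sim$experiment
  orig <- as.matrix(assay(exp))
  for (dialect in c("cellranger_v2", "cellranger_v3", "starsolo",
                    "bustools", "dropest", "mex")) {
    dir <- tempfile(paste0("fx_", dialect))
    writeFixture(exp, dialect, dir)
    got <- importSamples(dir, "s1", dialect, data_type = "Droplet")$droplet
    expect_identical(unname(as.matrix(assay(got))), unname(orig),
                     label = dialect)
    expect_identical(rownames(got), rownames(exp), label = dialect)
  }
  # csv and h5ad round trips
  dir <- tempfile("fx_csv")
  writeFixture(exp, "csv", dir)
  got <- importDelimited(file.path(dir, "counts.csv"))
  expect_identical(unname(as.matrix(got)), unname(orig))
  dir <- tempfile("fx_h5ad")
  writeFixture(exp, "h5ad", dir)
  got <- importH5AD(file.path(dir, "sample.h5ad"))
  expect_identical(unname(as.matrix(assay(got))), unname(orig))
})

test_that("dialect layouts conform to the manifest", {
  exp <- fxSmall()$experiment
  d2 <- tempfile(); writeFixture(exp, "cellranger_v2", d2)
  expect_true(file.exists(file.path(
    d2, "raw_gene_bc_matrices", "genome", "genes.tsv")))
  d3 <- tempfile(); writeFixture(exp, "cellranger_v3", d3)
  expect_true(file.exists(file.path(
    d3, "raw_feature_bc_matrix", "features.tsv.gz")))
  expect_error(writeFixture(exp, "nonsense", tempfile()),
               "unknown dialect")
})

test_that("cellranger import respects data_type and reports missing layout", {
  exp <- fxSmall()$experiment
  tot <- Matrix::colSums(assay(exp))
  dir <- tempfile()
  writeFixture(exp, "cellranger_v3", dir, cell_barcodes = tot > 1000)
  both <- importCellRangerV3(dir, "s1", data_type = "Both")
  expect_identical(matrixLevel(both$droplet), "Droplet")
  expect_identical(matrixLevel(both$cell), "Cell")
  expect_identical(ncol(both$cell), sum(tot > 1000))
  cellonly <- importCellRangerV3(dir, "s1", data_type = "Cell")
  expect_null(cellonly$droplet)
  expect_error(importCellRangerV2(dir, "s1", data_type = "Droplet"),
               "missing")
})

test_that("v3 feature types other than Gene Expression are dropped", {
  m <- sparseMatrix(i = 1:3, j = c(1, 2, 2), x = c(1, 2, 3), dims = c(3, 2))
  p <- writeTriple(tempfile(), m, c("b1", "b2"),
                   c("g1\ts1\tGene Expression", "g2\ts2\tAntibody Capture",
                     "g3\ts3\tGene Expression"))
  got <- importMEX(p["matrix"], p["barcodes"], p["features"])
  expect_identical(rownames(got), c("g1", "g3"))
  expect_identical(attr(got, "features")$type,
                   rep("Gene Expression", 2))
})

test_that("h5ad import fills a missing sample column from the file stem", {
  exp <- fxSmall()$experiment
  f <- file.path(tempdir(), "mystem.h5ad")
  # strip the sample column before export
  SummarizedExperiment::colData(exp)$sample <- NULL
  colData(exp)$dummy <- seq_len(ncol(exp))
  expect_error(exportAnnData(exp, f), NA)
  got <- importH5AD(f)
  expect_identical(unique(got$sample), "mystem")
})
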