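library(Matrix)
suppressPackageStartupMessages(library(SummarizedExperiment))

toyExp <- function(n_genes = 4, n_cells = 3, level = "Droplet",
                   sample = "s1", seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 3), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("b", seq_len(n_cells))))
  QCExperiment(Matrix(m, sparse = TRUE), level = level, sample = sample)
}

test_that("construction validates counts and identifiers", {
  m <- Matrix(matrix(c(1, 0, 2, 3), 2), sparse = TRUE)
  expect_error(QCExperiment(m * 0.5, "Cell"), "non-integer")
  expect_error(QCExperiment(-m, "Cell"), "negative")
  expect_error(QCExperiment(m, "Cell", gene_ids = c("a", "a"),
                            barcode_ids = c("x", "y")), "duplicate gene")
  expect_error(QCExperiment(m, "Cell", gene_ids = c("a", "b"),
                            barcode_ids = c("x", "x")), "duplicate barcode")
  exp <- QCExperiment(m, "Cell", sample = "s",
                      gene_ids = c("a", "b"), barcode_ids = c("x", "y"))
  expect_identical(matrixLevel(exp), "Cell")
  expect_identical(exp$sample, c("s", "s"))
})

test_that("attachCellMetric validates length and name, and round-trips", {
  exp <- toyExp(n_cells = 3)
  exp <- attachCellMetric(exp, "total", c(5, 0, 9))
  expect_identical(colData(exp)$total, c(5, 0, 9))
  expect_error(attachCellMetric(exp, "bad", c(1, 2)), "2 values for 3")
  expect_error(attachCellMetric(exp, "total", c(1, 2, 3)),
               "already present")
  exp <- attachCellMetric(exp, "total", c(1, 2, 3), overwrite = TRUE)
  expect_identical(colData(exp)$total, c(1, 2, 3))
})

test_that("subsetCells keeps columns in order and enforces level rules", {
  exp <- toyExp(n_cells = 3, level = "Droplet")
  sub <- subsetCells(exp, c(TRUE, FALSE, TRUE), "Cell")
  expect_identical(colnames(sub), c("b1", "b3"))
  expect_identical(as.matrix(assay(sub)), as.matrix(assay(exp))[, c(1, 3)])
  expect_identical(matrixLevel(sub), "Cell")
  same <- subsetCells(exp, rep(TRUE, 3))
  expect_identical(as.matrix(assay(same)), as.matrix(assay(exp)))
  expect_error(subsetCells(exp, rep(TRUE, 3), "FilteredCell"),
               "illegal level transition")
  expect_error(subsetCells(sub, rep(TRUE, 2), "Droplet"),
               "illegal level transition")
  expect_length(provenance(sub), 1L)
})

test_that("combineSamples concatenates, labels and conserves counts", {
  e1 <- toyExp(n_genes = 5, n_cells = 2, sample = "s1", seed = 1)
  e2 <- toyExp(n_genes = 5, n_cells = 3, sample = "s2", seed = 2)
  comb <- combineSamples(list(e1, e2))
  expect_identical(ncol(comb), 5L)
  expect_identical(comb$sample, c("s1", "s1", "s2", "s2", "s2"))
  expect_identical(sum(assay(comb)), sum(assay(e1)) + sum(assay(e2)))
  # shared barcodes get sample-prefixed
  expect_identical(colnames(comb),
                   c("s1_b1", "s1_b2", "s2_b1", "s2_b2", "s2_b3"))
  e3 <- toyExp(n_genes = 4, n_cells = 2, sample = "s3")
  expect_error(combineSamples(list(e1, e3)), "gene universe")
})

test_that("provenance accumulates one entry per operation", {
  exp <- toyExp(n_genes = 30, n_cells = 120, level = "Cell")
  exp <- quietly(runPerCellQC(exp))
  exp <- quietly(runCxds(exp))
  exp <- filterCellsByThresholds(exp, list(list(column = "total", min = 0)))
  # perCellQC + cxds + subsetCells + filter log
  expect_identical(vapply(provenance(exp), `[[`, "", "operation"),
                   c("runPerCellQC", "runDoublet_cxds", "subsetCells",
                     "filterCellsByThresholds"))
  expect_true(all(vapply(provenance(exp), function(e)
    !is.null(e$timestamp) && !is.null(e$version), logical(1))))
})

test_that("per-sample isolation: combined equals per-sample concatenation", {
  e1 <- toyExp(n_genes = 40, n_cells = 80, sample = "s1", seed = 3,
               level = "Cell")
  e2 <- toyExp(n_genes = 40, n_cells = 60, sample = "s2", seed = 4,
               level = "Cell")
  comb <- quietly(runPerCellQC(combineSamples(list(e1, e2))))
  solo <- lapply(list(e1, e2), function(e) quietly(runPerCellQC(e)))
  for (col in c("total", "detected", "percent_top_50")) {
    expect_identical(colData(comb)[[col]],
                     c(colData(solo[[1]])[[col]],
                       colData(solo[[2]])[[col]]))
  }
})
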