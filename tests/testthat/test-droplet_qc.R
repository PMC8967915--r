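library(Matrix)
suppressPackageStartupMessages(library(SummarizedExperiment))

test_that("ambient profile follows the pseudo-count rule and is symmetric", {
  m <- sparseMatrix(i = c(1, 2, 1), j = c(1, 1, 2), x = c(8, 2, 500),
                    dims = c(3, 2),
                    dimnames = list(paste0("g", 1:3), c("low", "high")))
  exp <- QCExperiment(m, "Droplet")
  p <- ambientProfile(exp, lower = 100)
  expect_equal(unname(p), c(8.5, 2.5, 0.5) / 11.5, tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  perm <- QCExperiment(m[, 2:1], "Droplet")
  expect_equal(ambientProfile(perm, lower = 100), p)
  expect_error(ambientProfile(exp, lower = 1), "ambient pool")
})

test_that("barcode ranks: sorted totals are monotone and flat curves are degenerate", {
  set.seed(1)
  m <- rsparsematrix(50, 300, 0.3)
  m@x <- abs(round(m@x * 100)) + 1
  exp <- QCExperiment(m, "Droplet")
  br <- barcodeRanks(exp, lower = 0)
  ord <- order(br$rank)
  expect_true(all(diff(br$total[ord]) <= 0))
  expect_gte(br$knee_total, br$inflection_total)
  # flat curve: every barcode the same total
  flat <- QCExperiment(Matrix(matrix(10, 1, 200), sparse = TRUE), "Droplet")
  bf <- barcodeRanks(flat, lower = 1)
  expect_identical(bf$knee_total, 10)
  expect_identical(bf$inflection_total, 10)
  expect_error(barcodeRanks(exp, lower = 1e6), "too few")
})

test_that("knee and inflection land between the plateaus of a two-plateau curve", {
  # ~1,000 barcodes around 5,000 counts over ~100,000 around 10 counts
  spec <- simulationSpec(n_cell_types = 1, cells_per_type = 1000,
                         n_empty_droplets = 100000, doublet_fraction = 0,
                         seed = 99)
  sim <- simulateDropletData(spec)
  br <- barcodeRanks(sim$experiment, lower = 1)
  gm <- sqrt(5000 * 10)
  for (v in c(br$knee_total, br$inflection_total)) {
    expect_gt(v, 10); expect_lt(v, 5000)
    expect_gte(v, gm / 3); expect_lte(v, gm * 3)
  }
})

test_that("Monte-Carlo p-values match exhaustive enumeration on a tiny model", {
  # 3 genes; ambient pool barcodes with totals <= 2, tested totals 3..6
  set.seed(10)
  pool <- t(rmultinom(300, 2, c(0.5, 0.3, 0.2)))
  tested <- do.call(cbind, lapply(3:6, function(t)
    rmultinom(8, t, c(1 / 3, 1 / 3, 1 / 3))))  # off-model draws too
  m <- as(Matrix(cbind(t(pool), tested), sparse = TRUE), "CsparseMatrix")
  dimnames(m) <- list(paste0("g", 1:3), paste0("b", seq_len(ncol(m))))
  exp <- QCExperiment(m, "Droplet")
  ambient <- ambientProfile(exp, lower = 2)
  keep <- Matrix::colSums(m) > 2
  td <- emptyDropsTest(m[, keep], ambient, niters = 10000, seed = 11)
  p_exact <- enumeratePValues(as.matrix(m[, keep]), ambient)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_true(all(abs(td$pvalue - p_exact) <= 3 * se + 2 / 10000))
  # the barcode at exactly total x ambient proportions has ~the top p-value
  exp_prop <- round(6 * ambient)
  mm <- cbind(m[, keep], Matrix(exp_prop, 3, 1, sparse = TRUE,
                                dimnames = list(paste0("g", 1:3), "best")))
  tb <- emptyDropsTest(mm, ambient, niters = 10000, seed = 11)
  at6 <- tb$pvalue[tb$total == 6]
  expect_gte(tb["best", "pvalue"], max(at6) * 0.95)
})

test_that("empty-droplet results are deterministic under a fixed seed", {
  d <- fxSmall()$experiment
  t1 <- emptyDropsTest(assay(d)[, 1:50], rep(1 / 500, 500),
                       niters = 500, seed = 3)
  t2 <- emptyDropsTest(assay(d)[, 1:50], rep(1 / 500, 500),
                       niters = 500, seed = 3)
  expect_identical(t1, t2)
  expect_error(emptyDropsTest(assay(d)[, 1:5], rep(1 / 500, 500),
                              niters = 50, seed = 1), "at least 100")
})

test_that("log-probability decreases when counts move to low-ambient genes", {
  ambient <- c(0.7, 0.2, 0.1)
  base <- matrix(c(7, 2, 1), 3)
  shifted <- matrix(c(6, 2, 2), 3)  # one count moved to the rarest gene
  m <- Matrix(cbind(base, shifted), sparse = TRUE)
  ll <- emptyDropsTest(m, ambient, niters = 100, seed = 1)$logprob
  expect_lt(ll[2], ll[1])
})

test_that("p-values are super-uniform under the ambient null", {
  set.seed(21)
  ambient <- rexp(100); ambient <- ambient / sum(ambient)
  totals <- sample(150:400, 600, replace = TRUE)
  m <- Matrix(vapply(totals, function(t)
    rmultinom(1, t, ambient)[, 1], numeric(100)), sparse = TRUE)
  td <- emptyDropsTest(m, ambient, niters = 10000, seed = 4)
  ks <- suppressWarnings(stats::ks.test(td$pvalue, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("filtering to cells honours the chosen method and is idempotent", {
  sim <- fxDroplet()
  d <- runBarcodeRanks(sim$experiment)
  d <- runEmptyDrops(d, niters = 1000, seed = 5)
  cell <- filterToCells(d, "emptydrops")
  expect_identical(matrixLevel(cell), "Cell")
  again <- filterToCells(cell, "emptydrops")
  expect_identical(colnames(again), colnames(cell))
  knee <- filterToCells(d, "barcoderanks_knee")
  cd <- colData(d)
  expect_identical(
    colnames(knee),
    colnames(d)[cd$dropletUtils_barcodeRank_total >
                  cd$dropletUtils_barcodeRank_knee])
  expect_error(filterToCells(sim$experiment, "emptydrops"), "missing")
})
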