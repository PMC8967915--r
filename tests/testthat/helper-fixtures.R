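# Shared fixtures, built once per test session and cached. All statistical
# tests consume the package's own synthetic-data generator; nothing is
# downloaded or stored on disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# standard droplet-level fixture (default simulation settings)
fxDroplet <- function() cached("droplet", simulateDropletData(simulationSpec()))

# standard cell-level doublet fixture: 2,000 cells, 3 types, 10% heterotypic
# doublets
fxCell <- function() cached("cell", simulateCellData(
  simulationSpec(cells_per_type = 600L, doublet_fraction = 0.10,
                 n_empty_droplets = 0L)))

# small cell-level fixture for cheap structural tests
fxSmall <- function() cached("small", simulateCellData(
  simulationSpec(cells_per_type = 60L, doublet_fraction = 0.08,
                 n_empty_droplets = 0L, seed = 42L)))

# doublet scorer results on the standard fixture (shared between the unit
# and acceptance suites to avoid recomputation)
fxDoubletResults <- function() cached("doublet_results", {
  exp <- fxCell()$experiment
  list(knn = doubletKnn(exp, seed = 101L),
       cxds = doubletCxds(exp),
       bcds = doubletBcds(exp, seed = 101L))
})

fxDecont <- function() cached("decont", {
  sim <- fxCell()
  list(sim = sim, res = decontX(sim$experiment, seed = 7L))
})

# rank-based AUROC, implemented independently of any scoring code
aucScore <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# brute-force multinomial enumeration: exact lower-tail probability of the
# conditional log-likelihood for every column of `counts` under `ambient`
enumeratePValues <- function(counts, ambient) {
  G <- length(ambient)
  stopifnot(G == 3L)  # enumeration oracle is for tiny instances
  logp <- log(ambient / sum(ambient))
  ll <- function(x) lgamma(sum(x) + 1) - sum(lgamma(x + 1)) + sum(x * logp)
  vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    t <- sum(x)
    obs <- ll(x)
    acc <- 0
    for (a in 0:t) for (b in 0:(t - a)) {
      y <- c(a, b, t - a - b)
      if (ll(y) <= obs + 1e-8) acc <- acc + exp(ll(y))
    }
    min(acc, 1)
  }, numeric(1))
}

quietly <- function(expr) suppressWarnings(suppressMessages(expr))

miniFixtureDir <- function() {
  cached("mini_fixture_dir", {
    spec <- simulationSpec(n_genes = 300L, cells_per_type = 80L,
                           n_empty_droplets = 4000L,
                           doublet_fraction = 0.08, seed = 11L)
    sim <- simulateDropletData(spec)
    dir <- file.path(tempdir(), "pipeline_fixture", "s1")
    tot <- Matrix::colSums(SummarizedExperiment::assay(sim$experiment))
    writeFixture(sim$experiment, "cellranger_v3", dir,
                 cell_barcodes = tot > 500)
    dir
  })
}

miniConfig <- function(out_dir, ...) {
  pipelineConfig(preproc = "cellranger_v3", base_paths = miniFixtureDir(),
                 samples = "s1", data_type = "Both",
                 mito_gene_set = "human-symbol", out_dir = out_dir,
                 seed = 777L,
                 params = list(runEmptyDrops = list(niters = 500)), ...)
}

pipelineRun1 <- function() {
  cached("pipeline_run1", {
    out <- file.path(tempdir(), "pipe_out1")
    res <- quietly(runPipeline(miniConfig(out)))
    list(out = out, res = res)
  })
}

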