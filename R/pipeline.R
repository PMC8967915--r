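#' Pipeline configuration
#'
#' Normalized configuration for [runPipeline()]: preprocessing tool,
#' per-sample inputs, which matrices to process, the mitochondrial gene set,
#' output formats, output directory, the global seed (from which every
#' operation derives its own seed by name hashing) and per-operation
#' parameter overrides.
#'
#' @param preproc importer dialect (`cellranger_v2`, `cellranger_v3`,
#'   `starsolo`, `bustools`, `dropest`, `mex`, `csv`, `h5ad`).
#' @param base_paths sample directories (or files for csv/h5ad).
#' @param samples sample names, one per path.
#' @param data_type `"Droplet"`, `"Cell"` or `"Both"`.
#' @param mito_gene_set built-in set token (e.g. `"human-symbol"`), custom
#'   file path, or `NULL` to skip.
#' @param output_formats subset of `c("FlatFile", "AnnData")`.
#' @param out_dir output directory.
#' @param seed global pipeline seed.
#' @param algorithms cell-QC algorithm roster.
#' @param params named list of per-operation parameter overrides, e.g.
#'   `list(runEmptyDrops = list(niters = 1000))`.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(preproc = "cellranger_v3", base_paths = character(),
                           samples = NULL, data_type = "Both",
                           mito_gene_set = NULL,
                           output_formats = c("FlatFile", "AnnData"),
                           out_dir = "scqc_out", seed = 12345L,
                           algorithms = c("percell", "knn", "cxds", "bcds",
                                          "hybrid", "decontx"),
                           params = list()) {
  cfg <- list(preproc = preproc,
              base_paths = as.character(base_paths),
              samples = as.character(samples %||% basename(base_paths)),
              data_type = data_type, mito_gene_set = mito_gene_set,
              output_formats = output_formats, out_dir = out_dir,
              seed = as.integer(seed), algorithms = algorithms,
              params = params)
  validatePipelineConfig(cfg)
}

validatePipelineConfig <- function(cfg) {
  if (!cfg$data_type %in% c("Droplet", "Cell", "Both"))
    stopf("invalid data_type '%s'", cfg$data_type)
  if (!length(cfg$base_paths)) stopf("no input paths configured")
  if (length(cfg$base_paths) != length(cfg$samples))
    stopf("number of samples does not match number of input paths")
  known <- c("cellranger_v2", "cellranger_v3", "starsolo", "bustools",
             "dropest", "mex", "csv", "h5ad")
  if (!cfg$preproc %in% known)
    stopf("unknown preprocessing tool '%s'", cfg$preproc)
  bad <- setdiff(cfg$output_formats, c("FlatFile", "AnnData"))
  if (length(bad)) stopf("unknown output format(s): %s",
                         paste(bad, collapse = ", "))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y[intersect(names(y),
                                      names(formals(pipelineConfig)))])
}

#' Parse command-line arguments into a pipeline configuration
#'
#' Supports `-b`/`--basePath`/`--cellRangerDirs`, `-P`/`--preproc`,
#' `-s`/`--sample`, `-d`/`--dataType`, `-M`/`--mitoGeneSet`,
#' `-F`/`--outputFormat` (repeatable), `-o`/`--outDir`, `-S`/`--seed` and
#' `-y`/`--yamlFile`. Command-line values override YAML values.
#'
#' @param argv character vector of arguments.
#' @return A `PipelineConfig`.
#' @export
parseCLI <- function(argv) {
  vals <- list(output_formats = character(0), base_paths = character(0),
               samples = character(0))
  yaml_file <- NULL
  i <- 1L
  need <- function(flag) {
    if (i + 1L > length(argv)) stopf("flag %s needs a value", flag)
    argv[i + 1L]
  }
  while (i <= length(argv)) {
    a <- argv[i]
    switch(a,
      "-b" = , "--basePath" = , "--cellRangerDirs" = {
        vals$base_paths <- c(vals$base_paths,
                             strsplit(need(a), ",")[[1]]); i <- i + 2L },
      "-P" = , "--preproc" = { vals$preproc <- need(a); i <- i + 2L },
      "-s" = , "--sample" = {
        vals$samples <- c(vals$samples, strsplit(need(a), ",")[[1]])
        i <- i + 2L },
      "-d" = , "--dataType" = { vals$data_type <- need(a); i <- i + 2L },
      "-M" = , "--mitoGeneSet" = { vals$mito_gene_set <- need(a)
        i <- i + 2L },
      "-F" = , "--outputFormat" = {
        vals$output_formats <- c(vals$output_formats, need(a)); i <- i + 2L },
      "-o" = , "--outDir" = { vals$out_dir <- need(a); i <- i + 2L },
      "-S" = , "--seed" = { vals$seed <- as.integer(need(a)); i <- i + 2L },
      "-y" = , "--yamlFile" = { yaml_file <- need(a); i <- i + 2L },
      stopf("unknown flag '%s'", a))
  }
  base <- if (!is.null(yaml_file)) {
    y <- yaml::read_yaml(yaml_file)
    y[intersect(names(y), names(formals(pipelineConfig)))]
  } else list()
  # CLI wins over YAML
  for (nm in names(vals))
    if (length(vals[[nm]])) base[[nm]] <- vals[[nm]]
  if (!length(base$samples %||% character(0)) &&
      length(base$base_paths %||% character(0)))
    base$samples <- basename(base$base_paths)
  do.call(pipelineConfig, base)
}

pipelineLog <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full QC pipeline
#'
#' Executes import, droplet QC (Droplet matrix), per-cell QC + doublet
#' detection + decontamination (Cell matrix), HTML reports, the per-sample
#' summary TSV, and data export, according to the configuration. Stages are
#' isolated: a failing stage is logged and later stages still run on
#' whatever results exist, so completed results are never lost.
#'
#' @param config a `PipelineConfig`.
#' @return A list with `status` (0 success, 1 runtime error, 2 validation
#'   error) and `artifacts` (named paths of generated outputs), invisibly.
#' @export
runPipeline <- function(config) {
  config <- tryCatch(validatePipelineConfig(unclass(config)),
                     error = function(e) e)
  if (inherits(config, "error")) {
    message("configuration error: ", conditionMessage(config))
    return(invisible(list(status = 2L, artifacts = character(0))))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(config$out_dir, "run.log"), "wt")
  on.exit(close(logcon))
  artifacts <- character(0)
  status <- 0L
  seed <- config$seed
  pp <- function(op, defaults = list()) {
    ov <- config$params[[op]] %||% list()
    utils::modifyList(defaults, ov)
  }
  fail <- function(stage, e) {
    status <<- 1L
    pipelineLog(logcon, stage, paste("ERROR:", conditionMessage(e)))
    NULL
  }

  # stage 1: import
  pipelineLog(logcon, "import", sprintf("tool=%s, %d sample(s), type=%s",
                                        config$preproc,
                                        length(config$base_paths),
                                        config$data_type))
  imported <- tryCatch({
    if (config$preproc == "csv") {
      exps <- mapply(function(p, s) {
        if (dir.exists(p)) p <- file.path(p, "counts.csv")
        QCExperiment(importDelimited(p), level = "Cell", sample = s)
      }, config$base_paths, config$samples, SIMPLIFY = FALSE)
      list(droplet = NULL, cell = combineSamples(exps))
    } else if (config$preproc == "h5ad") {
      exps <- mapply(function(p, s) {
        if (dir.exists(p)) p <- file.path(p, "sample.h5ad")
        e <- importH5AD(p)
        e$sample <- rep(s, ncol(e))
        e
      }, config$base_paths, config$samples, SIMPLIFY = FALSE)
      list(droplet = NULL, cell = combineSamples(exps))
    } else {
      dt <- config$data_type
      tool <- config$preproc
      if (dt %in% c("Cell", "Both") &&
          is.null(mexDialects()[[tool]]$filtered))
        dt <- "Droplet"
      importSamples(config$base_paths, config$samples, tool, dt)
    }
  }, error = function(e) fail("import", e))
  if (is.null(imported)) {
    pipelineLog(logcon, "pipeline", "import failed; aborting")
    return(invisible(list(status = 1L, artifacts = artifacts)))
  }
  droplet <- imported$droplet
  cell <- imported$cell

  # stage 2: droplet QC
  if (!is.null(droplet)) {
    droplet <- tryCatch({
      d <- do.call(runBarcodeRanks,
                   c(list(droplet), pp("runBarcodeRanks")))
      do.call(runEmptyDrops,
              c(list(d), pp("runEmptyDrops",
                            list(seed = deriveSeed(seed, "runEmptyDrops")))))
    }, error = function(e) { fail("dropletQC", e); droplet })
    if (is.null(cell) &&
        "dropletUtils_emptyDrops_is_cell" %in%
          colnames(SummarizedExperiment::colData(droplet))) {
      cell <- tryCatch(filterToCells(droplet, "emptydrops"),
                       error = function(e) fail("filterToCells", e))
      pipelineLog(logcon, "dropletQC",
                  sprintf("filtered to %d cells", ncol(cell %||% droplet)))
    }
  }

  # stage 3: cell QC
  if (!is.null(cell)) {
    gene_sets <- list()
    if (!is.null(config$mito_gene_set))
      gene_sets <- tryCatch(list(mitoGeneSet(config$mito_gene_set)),
                            error = function(e) { fail("geneSet", e)
                              list() })
    if ("percell" %in% config$algorithms)
      cell <- tryCatch(do.call(runPerCellQC,
                               c(list(cell, gene_sets = gene_sets),
                                 pp("runPerCellQC"))),
                       error = function(e) { fail("perCellQC", e); cell })
    if ("knn" %in% config$algorithms)
      cell <- tryCatch(do.call(runDoubletKNN,
                               c(list(cell),
                                 pp("runDoubletKNN",
                                    list(seed = deriveSeed(seed, "knn"))))),
                       error = function(e) { fail("doubletKNN", e); cell })
    if ("cxds" %in% config$algorithms)
      cell <- tryCatch(do.call(runCxds, c(list(cell), pp("runCxds"))),
                       error = function(e) { fail("cxds", e); cell })
    if ("bcds" %in% config$algorithms)
      cell <- tryCatch(do.call(runBcds,
                               c(list(cell),
                                 pp("runBcds",
                                    list(seed = deriveSeed(seed, "bcds"))))),
                       error = function(e) { fail("bcds", e); cell })
    if ("hybrid" %in% config$algorithms)
      cell <- tryCatch(runCxdsBcdsHybrid(cell),
                       error = function(e) { fail("hybrid", e); cell })
    votes <- intersect(c("knn", "cxds", "bcds"), config$algorithms)
    if (length(votes) >= 2L)
      cell <- tryCatch(runDoubletConsensus(cell, votes),
                       error = function(e) { fail("consensus", e); cell })
    if ("decontx" %in% config$algorithms) {
      cell <- tryCatch(do.call(runDecontX,
                               c(list(cell),
                                 pp("runDecontX",
                                    list(seed = deriveSeed(seed,
                                                           "decontx"))))),
                       error = function(e) { fail("decontX", e); cell })
      cell <- tryCatch(runDecontXUMAP(cell,
                                      seed = deriveSeed(seed, "umap")),
                       error = function(e) { fail("umap", e); cell })
    }
  }

  # stage 4: reports and summary
  if (!is.null(droplet) &&
      "dropletUtils_emptyDrops_is_cell" %in%
        colnames(SummarizedExperiment::colData(droplet))) {
    p <- file.path(config$out_dir, "dropletQC.html")
    r <- tryCatch({ reportDropletQC(droplet, p); p },
                  error = function(e) fail("dropletReport", e))
    if (!is.null(r)) artifacts["droplet_report"] <- r
  }
  if (!is.null(cell) &&
      "total" %in% colnames(SummarizedExperiment::colData(cell))) {
    p <- file.path(config$out_dir, "cellQC.html")
    r <- tryCatch({ reportCellQC(cell, p, droplet); p },
                  error = function(e) fail("cellReport", e))
    if (!is.null(r)) artifacts["cell_report"] <- r
    p <- file.path(config$out_dir, "summary.tsv")
    r <- tryCatch({ writeSummaryTSV(summarizeQC(cell, droplet), p); p },
                  error = function(e) fail("summary", e))
    if (!is.null(r)) artifacts["summary"] <- r
  }

  # stage 5: export
  exportOne <- function(exp, tag) {
    if ("FlatFile" %in% config$output_formats) {
      d <- file.path(config$out_dir, paste0(tag, "_flatfiles"))
      r <- tryCatch({ exportFlatFiles(exp, d); d },
                    error = function(e) fail("exportFlatFiles", e))
      if (!is.null(r)) artifacts[paste0(tag, "_flatfiles")] <<- r
    }
    if ("AnnData" %in% config$output_formats) {
      f <- file.path(config$out_dir, paste0(tag, ".h5ad"))
      r <- tryCatch({ exportAnnData(exp, f); f },
                    error = function(e) fail("exportAnnData", e))
      if (!is.null(r)) artifacts[paste0(tag, "_h5ad")] <<- r
    }
  }
  if (!is.null(cell)) exportOne(cell, "cell")
  if (!is.null(droplet) && config$data_type %in% c("Droplet", "Both"))
    exportOne(droplet, "droplet")

  pipelineLog(logcon, "pipeline",
              sprintf("finished with status %d (%d artifacts)", status,
                      length(artifacts)))
  invisible(list(status = status, artifacts = artifacts))
}
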