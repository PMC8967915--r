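#' Built-in mitochondrial gene sets
#'
#' Plain-text gene sets shipped with the package: the 13 mitochondrially
#' encoded protein-coding genes for human and mouse, in gene-symbol,
#' Ensembl and Entrez identifier formats.
#'
#' @param name one of `"human-symbol"`, `"human-ensembl"`, `"human-entrez"`,
#'   `"mouse-symbol"`, `"mouse-ensembl"`, `"mouse-entrez"`, or a path to a
#'   custom one-id-per-line file.
#' @return A list of class `GeneSet` with `name`, `ids` and `id_type`.
#' @export
mitoGeneSet <- function(name = "human-symbol") {
  builtin <- c("human-symbol", "human-ensembl", "human-entrez",
               "mouse-symbol", "mouse-ensembl", "mouse-entrez")
  if (name %in% builtin) {
    parts <- strsplit(name, "-")[[1]]
    path <- system.file("extdata",
                        sprintf("%s_mito_%s.txt", parts[1], parts[2]),
                        package = "scqckit", mustWork = TRUE)
    id_type <- parts[2]
  } else {
    path <- name
    if (!file.exists(path)) stopf("gene-set file not found: %s", path)
    id_type <- "symbol"
  }
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  geneSet(paste0("mito"), ids, id_type)
}

#' Construct a gene set
#' @param name set name (used in metric column names).
#' @param ids unique, non-empty identifier vector.
#' @param id_type `"symbol"`, `"ensembl"` or `"entrez"`.
#' @return A list of class `GeneSet`.
#' @export
geneSet <- function(name, ids, id_type = c("symbol", "ensembl", "entrez")) {
  id_type <- match.arg(id_type)
  ids <- unique(as.character(ids))
  if (!length(ids)) stopf("gene set '%s' is empty", name)
  structure(list(name = name, ids = ids, id_type = id_type),
            class = "GeneSet")
}

matchGeneSet <- function(set, gene_ids) {
  universe <- gene_ids
  ids <- set$ids
  if (identical(set$id_type, "ensembl")) {
    universe <- sub("\\.\\d+$", "", universe)
    ids <- sub("\\.\\d+$", "", ids)
  }
  which(universe %in% ids)
}

#' Per-cell QC metrics
#'
#' Computes, for each cell, the total UMI count, the number of genes
#' detected, the percentage of the library occupied by the top N expressed
#' genes (N in `top_ns`), and the percentage of counts falling in each
#' supplied gene set (for example the mitochondrial percentage). Metric
#' computation is delegated to the scater package and applied per sample.
#' Cells with zero counts get 0 for gene-set percentages and 100 for
#' top-N percentages (0 genes detected is at most any N).
#'
#' @param exp Cell- or FilteredCell-level `QCExperiment`.
#' @param gene_sets list of [geneSet()] objects (optionally one, unwrapped).
#' @param top_ns integer vector of N values for the top-N percentage.
#' @return The experiment with columns `total`, `detected`,
#'   `percent_top_<N>` and `<set>_percent` appended, plus provenance noting
#'   unmatched gene-set identifiers.
#' @export
runPerCellQC <- function(exp, gene_sets = list(),
                         top_ns = c(50, 100, 200, 500)) {
  if (!matrixLevel(exp) %in% c("Cell", "FilteredCell"))
    stopf("per-cell QC runs on the Cell or FilteredCell matrix")
  if (inherits(gene_sets, "GeneSet")) gene_sets <- list(gene_sets)
  subsets <- list()
  unmatched <- list()
  for (gs in gene_sets) {
    idx <- matchGeneSet(gs, rownames(exp))
    unmatched[[gs$name]] <- length(gs$ids) - length(idx)
    if (!length(idx))
      warnf("gene set '%s' matched no genes; emitting zeros", gs$name)
    subsets[[gs$name]] <- idx
  }
  res <- perSampleMetrics(exp, function(sub) {
    counts <- SummarizedExperiment::assay(sub, "counts")
    pct_top <- pmin(top_ns, nrow(counts))
    qc <- scater::perCellQCMetrics(
      counts,
      subsets = subsets[lengths(subsets) > 0],
      percent.top = sort(unique(pct_top)))
    out <- list(total = qc$sum, detected = qc$detected)
    for (i in seq_along(top_ns)) {
      v <- qc[[sprintf("percent.top_%d", pct_top[i])]]
      v[qc$sum == 0] <- 100
      out[[sprintf("percent_top_%d", top_ns[i])]] <- v
    }
    for (gs in gene_sets) {
      nm <- sprintf("%s_percent", gs$name)
      if (length(subsets[[gs$name]])) {
        v <- qc[[sprintf("subsets_%s_percent", gs$name)]]
        v[qc$sum == 0] <- 0
      } else v <- numeric(ncol(counts))
      out[[nm]] <- v
    }
    out
  })
  for (nm in names(res))
    exp <- attachCellMetric(exp, nm, res[[nm]], overwrite = TRUE)
  logProvenance(exp, "runPerCellQC",
                list(top_ns = top_ns,
                     gene_sets = vapply(gene_sets, `[[`, "", "name"),
                     unmatched_ids = unmatched))
}

#' Median-absolute-deviation outlier detection
#'
#' Flags values deviating from the (per-sample) median by more than `nmads`
#' median absolute deviations (scaled by 1.4826 for consistency with the
#' normal standard deviation), optionally on the log2(x + 1) scale. A zero
#' MAD (degenerate spread) flags nothing, with a warning.
#'
#' @param values finite numeric vector (at least 3 values per sample).
#' @param nmads threshold in MADs.
#' @param on_log compute on log2(value + 1).
#' @param direction flag `"lower"`, `"higher"` or `"both"` tails.
#' @param sample optional per-value sample labels; outliers are assessed
#'   within each sample.
#' @return Logical vector, `TRUE` for outliers.
#' @export
detectCellOutlier <- function(values, nmads = 3, on_log = TRUE,
                              direction = c("both", "lower", "higher"),
                              sample = NULL) {
  direction <- match.arg(direction)
  if (!all(is.finite(values))) stopf("values must be finite")
  if (is.null(sample)) sample <- rep("all", length(values))
  out <- logical(length(values))
  for (s in unique(sample)) {
    idx <- which(sample == s)
    v <- values[idx]
    if (length(v) < 3L) stopf("need at least 3 values per sample")
    if (on_log) v <- log2(v + 1)
    med <- median(v)
    dev <- mad(v, constant = 1.4826)
    if (dev == 0) {
      warnf("MAD is zero in sample '%s'; no outliers flagged", s)
      next
    }
    lo <- v < med - nmads * dev
    hi <- v > med + nmads * dev
    out[idx] <- switch(direction, lower = lo, higher = hi, both = lo | hi)
  }
  out
}

#' Threshold-based cell filtering
#'
#' Applies a conjunction of simple min/max rules on cell-annotation columns
#' and returns the FilteredCell matrix. Per-rule removal counts are logged
#' in provenance.
#'
#' @param exp Cell-level `QCExperiment`.
#' @param rules list of rules, each `list(column =, min =, max =)` (either
#'   bound optional).
#' @return FilteredCell-level `QCExperiment`.
#' @export
filterCellsByThresholds <- function(exp, rules = list()) {
  cd <- SummarizedExperiment::colData(exp)
  keep <- rep(TRUE, ncol(exp))
  removed <- list()
  for (r in rules) {
    if (!r$column %in% colnames(cd))
      stopf("unknown cell annotation column '%s'", r$column)
    v <- cd[[r$column]]
    ok <- rep(TRUE, length(v))
    if (!is.null(r$min)) ok <- ok & v >= r$min
    if (!is.null(r$max)) ok <- ok & v <= r$max
    ok[is.na(ok)] <- FALSE
    removed[[r$column]] <- sum(keep & !ok)
    keep <- keep & ok
  }
  out <- subsetCells(exp, keep, "FilteredCell")
  logProvenance(out, "filterCellsByThresholds",
                list(rules = rules, removed_per_rule = removed,
                     kept = sum(keep)))
}
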