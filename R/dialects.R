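# On-disk layout manifest for MEX-style preprocessing-tool outputs.
# Each dialect names, relative to a sample directory, the matrix and sidecar
# files for the Droplet ("raw") and Cell ("filtered") matrices, plus how many
# columns the feature sidecar carries. Keeping this as data keeps the
# importers and the fixture writer in lockstep.
mexDialects <- function() {
  list(
    cellranger_v2 = list(
      raw = c(matrix = "raw_gene_bc_matrices/%s/matrix.mtx",
              features = "raw_gene_bc_matrices/%s/genes.tsv",
              barcodes = "raw_gene_bc_matrices/%s/barcodes.tsv"),
      filtered = c(matrix = "filtered_gene_bc_matrices/%s/matrix.mtx",
                   features = "filtered_gene_bc_matrices/%s/genes.tsv",
                   barcodes = "filtered_gene_bc_matrices/%s/barcodes.tsv"),
      genome_subdir = TRUE, gzipped = FALSE, feature_cols = 2L),
    cellranger_v3 = list(
      raw = c(matrix = "raw_feature_bc_matrix/matrix.mtx.gz",
              features = "raw_feature_bc_matrix/features.tsv.gz",
              barcodes = "raw_feature_bc_matrix/barcodes.tsv.gz"),
      filtered = c(matrix = "filtered_feature_bc_matrix/matrix.mtx.gz",
                   features = "filtered_feature_bc_matrix/features.tsv.gz",
                   barcodes = "filtered_feature_bc_matrix/barcodes.tsv.gz"),
      genome_subdir = FALSE, gzipped = TRUE, feature_cols = 3L),
    starsolo = list(
      raw = c(matrix = "Gene/raw/matrix.mtx",
              features = "Gene/raw/features.tsv",
              barcodes = "Gene/raw/barcodes.tsv"),
      filtered = c(matrix = "Gene/filtered/matrix.mtx",
                   features = "Gene/filtered/features.tsv",
                   barcodes = "Gene/filtered/barcodes.tsv"),
      genome_subdir = FALSE, gzipped = FALSE, feature_cols = 2L),
    bustools = list(
      raw = c(matrix = "output.mtx",
              features = "output.genes.txt",
              barcodes = "output.barcodes.txt"),
      filtered = NULL,
      genome_subdir = FALSE, gzipped = FALSE, feature_cols = 1L),
    dropest = list(
      raw = c(matrix = "matrix.mtx",
              features = "genes.tsv",
              barcodes = "barcodes.tsv"),
      filtered = NULL,
      genome_subdir = FALSE, gzipped = FALSE, feature_cols = 1L),
    mex = list(
      raw = c(matrix = "matrix.mtx",
              features = "features.tsv",
              barcodes = "barcodes.tsv"),
      filtered = NULL,
      genome_subdir = FALSE, gzipped = FALSE, feature_cols = 2L)
  )
}

resolveDialectPaths <- function(dialect, dir, which = "raw",
                                genome = "genome") {
  man <- mexDialects()
  if (!dialect %in% names(man)) stopf("unknown dialect '%s'", dialect)
  d <- man[[dialect]]
  rel <- d[[which]]
  if (is.null(rel))
    stopf("dialect '%s' has no %s matrix layout", dialect, which)
  if (d$genome_subdir) {
    # discover the genome subdirectory if present
    top <- file.path(dir, dirname(dirname(sprintf(rel[["matrix"]], "x"))))
    if (dir.exists(top)) {
      subs <- list.dirs(top, recursive = FALSE, full.names = FALSE)
      if (length(subs) >= 1L) genome <- subs[1]
    }
    rel <- vapply(rel, sprintf, character(1), genome)
  }
  setNames(file.path(dir, rel), names(rel))
}
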