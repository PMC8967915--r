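#' Barcode-rank knee and inflection points
#'
#' Ranks all barcodes of a Droplet matrix by total UMI count and locates the
#' knee and inflection points of the log-log rank versus total-count curve.
#' A cubic smoothing spline is fitted to the unique (log10 rank, log10
#' total) points above `lower`; the knee is the fitted count value at the
#' steepest-descent point of the smoothed curve (the middle of the
#' transition out of the cell plateau), and the inflection is the count at
#' the lower end of the steepest raw segment at or beyond that point (the
#' foot of the transition). Barcodes with total counts under these points
#' are candidates for empty droplets.
#'
#' @param exp Droplet-level `QCExperiment`.
#' @param lower totals at or below this value are excluded from the curve
#'   fit (they form the ambient pool elsewhere).
#' @param df degrees of freedom of the smoothing spline.
#' @return A list of class `BarcodeRankResult` with per-barcode `rank`
#'   (average rank for ties) and `total`, plus `knee_total` and
#'   `inflection_total` count values.
#' @export
barcodeRanks <- function(exp, lower = 100, df = 10) {
  if (matrixLevel(exp) != "Droplet")
    stopf("barcode ranks are computed on the Droplet matrix")
  total <- Matrix::colSums(SummarizedExperiment::assay(exp, "counts"))
  rk <- rank(-total, ties.method = "average")
  keep <- total > lower
  if (sum(keep) < 100)
    stopf("only %d barcodes above lower=%g; too few for rank-curve fitting",
          sum(keep), lower)
  ut <- sort(unique(total[keep]), decreasing = TRUE)
  ur <- vapply(split(rk[keep], total[keep]), mean, numeric(1))
  ur <- ur[order(as.numeric(names(ur)), decreasing = TRUE)]
  x <- log10(ur); y <- log10(ut)
  if (length(ut) < 5L) {
    knee <- inflection <- ut[which.max(x)]  # degenerate (e.g. flat) curve
  } else {
    dfree <- max(4, min(df, length(ut) - 1))
    fit <- smooth.spline(x, y, df = dfree)
    d1 <- predict(fit, x, deriv = 1)$y
    steepest <- which.min(d1)
    # transition region: slope within 3/4 of the steepest descent
    region <- which(d1 <= 0.75 * d1[steepest])
    top <- 10^predict(fit, x[min(region)])$y  # shoulder of the transition
    bot <- 10^predict(fit, x[max(region)])$y  # foot of the transition
    knee <- sqrt(top * bot)                   # log-space midpoint
    inflection <- bot
  }
  inflection <- min(inflection, knee)
  knee <- max(knee, inflection)
  structure(list(rank = rk, total = total, knee_total = knee,
                 inflection_total = inflection, lower = lower, df = df),
            class = "BarcodeRankResult")
}

#' @rdname barcodeRanks
#' @param seed unused (deterministic); kept for uniform provenance.
#' @return `runBarcodeRanks` returns the experiment with per-barcode columns
#'   `dropletUtils_barcodeRank_rank`/`_total` and per-sample constant
#'   columns `_knee`/`_inflection` appended, plus a provenance entry.
#' @export
runBarcodeRanks <- function(exp, lower = 100, df = 10, seed = NA) {
  res <- perSampleMetrics(exp, function(sub) {
    br <- barcodeRanks(sub, lower = lower, df = df)
    list(dropletUtils_barcodeRank_rank = br$rank,
         dropletUtils_barcodeRank_total = br$total,
         dropletUtils_barcodeRank_knee = rep(br$knee_total, ncol(sub)),
         dropletUtils_barcodeRank_inflection =
           rep(br$inflection_total, ncol(sub)))
  })
  for (nm in names(res))
    exp <- attachCellMetric(exp, nm, res[[nm]], overwrite = TRUE)
  logProvenance(exp, "runBarcodeRanks", list(lower = lower, df = df))
}

#' Ambient RNA profile from low-count barcodes
#'
#' Sums counts over all barcodes with totals at or below `lower` (the
#' ambient pool), adds a pseudo-count to every gene and normalizes to a
#' probability vector.
#'
#' @param exp Droplet-level `QCExperiment`.
#' @param lower ambient-pool threshold on barcode totals.
#' @param alpha per-gene pseudo-count.
#' @return Named per-gene probability vector summing to 1.
#' @export
ambientProfile <- function(exp, lower = 100, alpha = 0.5) {
  if (matrixLevel(exp) != "Droplet")
    stopf("the ambient pool is defined on the Droplet matrix")
  counts <- SummarizedExperiment::assay(exp, "counts")
  total <- Matrix::colSums(counts)
  pool <- total <= lower
  if (!any(pool))
    stopf("no barcodes with total <= %g to form the ambient pool", lower)
  pooled <- Matrix::rowSums(counts[, pool, drop = FALSE]) + alpha
  pooled / sum(pooled)
}

# Conditional multinomial log-likelihood of each column of a sparse counts
# matrix under the ambient profile, given its total.
ambientLogProb <- function(counts, ambient) {
  counts <- as(counts, "CsparseMatrix")
  total <- Matrix::colSums(counts)
  xlogp <- as.vector(Matrix::crossprod(counts, log(ambient)))
  jj <- rep.int(seq_len(ncol(counts)), diff(counts@p))
  lgsum <- numeric(ncol(counts))
  if (length(jj)) {
    agg <- rowsum(lgamma(counts@x + 1), jj)
    lgsum[as.integer(rownames(agg))] <- agg[, 1]
  }
  lgamma(total + 1) - lgsum + xlogp
}

#' Monte-Carlo ambient-pool test for a set of barcodes
#'
#' Core of the empty-droplet test: for each barcode, the conditional
#' multinomial log-likelihood of its counts under the ambient profile is
#' compared against `niters` simulated draws at the same total; the
#' Monte-Carlo p-value uses the add-one estimator `(1 + b) / (1 + niters)`.
#' Simulated likelihood distributions are shared across barcodes with the
#' same total.
#'
#' @param counts sparse genes x barcodes matrix of the tested barcodes.
#' @param ambient per-gene ambient probability vector.
#' @param niters Monte-Carlo iterations (at least 100).
#' @param seed integer seed.
#' @return A data.frame with `total`, `logprob`, `pvalue` and `limited`
#'   (TRUE when no simulated draw reached the observed likelihood, i.e.
#'   more iterations could lower the p-value).
#' @export
emptyDropsTest <- function(counts, ambient, niters = 10000, seed = 1L) {
  if (niters < 100) stopf("niters must be at least 100")
  counts <- as(counts, "CsparseMatrix")
  stopifnot(length(ambient) == nrow(counts))
  total <- Matrix::colSums(counts)
  obs_ll <- ambientLogProb(counts, ambient)
  ut <- sort(unique(as.integer(total)))
  grp <- match(as.integer(total), ut) - 1L
  tail_counts <- withSeed(seed,
    mc_ambient_tail_counts(as.numeric(ambient), as.integer(ut),
                           as.numeric(obs_ll), as.integer(grp),
                           as.integer(niters)))
  data.frame(total = total, logprob = obs_ll,
             pvalue = (1 + tail_counts) / (1 + niters),
             limited = tail_counts == 0L,
             row.names = colnames(counts))
}

#' Empty-droplet detection by the ambient-pool Monte-Carlo test
#'
#' Distinguishes droplets containing real cells from empty droplets that
#' carry only ambient RNA. Barcodes with totals at or below `lower` form the
#' ambient pool; every barcode above `lower` is tested against the ambient
#' multinomial model ([emptyDropsTest()]), p-values are BH-adjusted across
#' tested barcodes (per sample), and a barcode is called a cell when its
#' q-value is at most `fdr` or its total reaches `retain` (by default the
#' barcode-rank knee, so large cells cannot be lost). Applied to each
#' sample separately.
#'
#' @param exp Droplet-level `QCExperiment`.
#' @param lower ambient-pool threshold.
#' @param niters Monte-Carlo iterations.
#' @param fdr q-value threshold for the cell call.
#' @param retain count threshold above which barcodes are always called
#'   cells; `NULL` uses the per-sample barcode-rank knee; `Inf` disables.
#' @param seed integer seed; generated (and logged) when missing.
#' @return The experiment with columns `dropletUtils_emptyDrops_total`,
#'   `_logprob`, `_pvalue`, `_fdr`, `_limited`, `_is_cell` appended
#'   (NA for untested barcodes) and a provenance entry.
#' @export
runEmptyDrops <- function(exp, lower = 100, niters = 10000, fdr = 0.01,
                          retain = NULL, seed = NULL) {
  if (matrixLevel(exp) != "Droplet")
    stopf("empty-droplet detection runs on the Droplet matrix")
  if (niters < 100) stopf("niters must be at least 100")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  res <- perSampleMetrics(exp, function(sub) {
    counts <- SummarizedExperiment::assay(sub, "counts")
    total <- Matrix::colSums(counts)
    ambient <- ambientProfile(sub, lower = lower)
    tested <- which(total > lower)
    n <- ncol(sub)
    out <- list(dropletUtils_emptyDrops_total = total,
                dropletUtils_emptyDrops_logprob = rep(NA_real_, n),
                dropletUtils_emptyDrops_pvalue = rep(NA_real_, n),
                dropletUtils_emptyDrops_fdr = rep(NA_real_, n),
                dropletUtils_emptyDrops_limited = rep(NA, n),
                dropletUtils_emptyDrops_is_cell = rep(NA, n))
    if (!length(tested)) return(out)
    td <- emptyDropsTest(counts[, tested, drop = FALSE], ambient,
                         niters = niters,
                         seed = deriveSeed(seed, sub$sample[1]))
    qv <- p.adjust(td$pvalue, method = "BH")
    ret <- retain
    if (is.null(ret))
      ret <- tryCatch(barcodeRanks(sub, lower = lower)$knee_total,
                      error = function(e) Inf)
    out$dropletUtils_emptyDrops_logprob[tested] <- td$logprob
    out$dropletUtils_emptyDrops_pvalue[tested] <- td$pvalue
    out$dropletUtils_emptyDrops_fdr[tested] <- qv
    out$dropletUtils_emptyDrops_limited[tested] <- td$limited
    out$dropletUtils_emptyDrops_is_cell[tested] <-
      qv <= fdr | td$total >= ret
    out
  })
  for (nm in names(res))
    exp <- attachCellMetric(exp, nm, res[[nm]], overwrite = TRUE)
  logProvenance(exp, "runEmptyDrops",
                list(lower = lower, niters = niters, fdr = fdr,
                     retain = if (is.null(retain)) "auto-knee" else retain),
                seed = seed)
}

#' Filter a Droplet matrix down to its Cell matrix
#'
#' @param exp Droplet-level `QCExperiment` on which the requested method has
#'   already been run.
#' @param method `"emptydrops"` keeps barcodes called cells;
#'   `"barcoderanks_knee"` / `"barcoderanks_inflection"` keep barcodes with
#'   totals above the respective point.
#' @return Cell-level `QCExperiment`.
#' @export
filterToCells <- function(exp, method = c("emptydrops", "barcoderanks_knee",
                                          "barcoderanks_inflection")) {
  method <- match.arg(method)
  cd <- SummarizedExperiment::colData(exp)
  need <- switch(method,
                 emptydrops = "dropletUtils_emptyDrops_is_cell",
                 barcoderanks_knee = "dropletUtils_barcodeRank_knee",
                 barcoderanks_inflection = "dropletUtils_barcodeRank_inflection")
  if (!need %in% colnames(cd))
    stopf("column '%s' missing: run the %s step first", need,
          sub("_.*", "", method))
  keep <- switch(method,
                 emptydrops = !is.na(cd[[need]]) & cd[[need]],
                 barcoderanks_knee =
                   cd$dropletUtils_barcodeRank_total > cd[[need]],
                 barcoderanks_inflection =
                   cd$dropletUtils_barcodeRank_total > cd[[need]])
  new_level <- if (matrixLevel(exp) == "Droplet") "Cell" else matrixLevel(exp)
  out <- subsetCells(exp, as.logical(keep), new_level)
  logProvenance(out, "filterToCells", list(method = method,
                                           kept = sum(keep)))
}
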