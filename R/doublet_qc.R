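# -- shared helpers -----------------------------------------------------------

# counts-per-10k + log1p normalization, returning a dense cells x genes
# matrix restricted to the `n_var` most variable genes (variance of the log
# values).
normalizedFeatures <- function(counts, n_var = 2000L) {
  libs <- Matrix::colSums(counts)
  libs[libs == 0] <- 1
  norm <- Matrix::t(Matrix::t(counts) * (1e4 / libs))
  norm@x <- log1p(norm@x)
  v <- rowVarsSparse(norm)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_var, nrow(norm)))]
  as.matrix(Matrix::t(norm[sort(keep), , drop = FALSE]))
}

rowVarsSparse <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  (Matrix::rowSums(m^2) - n * mu^2) / pmax(n - 1, 1)
}

pcaEmbed <- function(features, n_pcs = 30L) {
  n_pcs <- min(n_pcs, ncol(features) - 1L, nrow(features) - 1L)
  prcomp(features, center = TRUE, scale. = FALSE,
         rank. = n_pcs)$x[, seq_len(n_pcs), drop = FALSE]
}

# Score threshold from a two-component Gaussian mixture (boundary at equal
# posterior of the upper component); falls back to the (1 - expected_rate)
# quantile when the mixture is degenerate (fit failure, indistinct
# components, or a call fraction outside (0, 50%]).
mixtureThreshold <- function(scores, expected_rate = 0.05) {
  fallback <- function() {
    thr <- as.numeric(quantile(scores, 1 - expected_rate, names = FALSE))
    list(threshold = thr, method = "quantile")
  }
  if (length(unique(scores)) < 5L)
    return(list(threshold = Inf, method = "degenerate"))
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(scores, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback())
  mu <- fit$parameters$mean
  upper <- which.max(mu)
  if (abs(diff(mu)) < 1e-8) return(fallback())
  grid <- sort(unique(scores))
  post <- predict(fit, grid)$z[, upper]
  cand <- grid[post >= 0.5 & grid > min(mu)]
  if (!length(cand)) return(fallback())
  thr <- min(cand)
  frac <- mean(scores >= thr)
  if (frac <= 0 || frac > 0.5) return(fallback())
  list(threshold = thr, method = "mixture")
}

doubletResult <- function(algorithm, score, threshold, parameters = list(),
                          threshold_method = NA_character_) {
  stopifnot(all(is.finite(score)))
  structure(list(algorithm = algorithm, score = score,
                 threshold = threshold, call = score >= threshold,
                 threshold_method = threshold_method,
                 parameters = parameters),
            class = "DoubletResult")
}

simulateDoublets <- function(counts, n_sim) {
  n <- ncol(counts)
  i1 <- sample.int(n, n_sim, replace = TRUE)
  i2 <- vapply(i1, function(a) {
    b <- sample.int(n, 1L)
    while (b == a) b <- sample.int(n, 1L)
    b
  }, integer(1))
  counts[, i1, drop = FALSE] + counts[, i2, drop = FALSE]
}

# -- simulation + kNN scorer --------------------------------------------------

#' Doublet score from simulated doublets and k-nearest neighbours
#'
#' Simulates artificial doublets by summing the raw counts of random cell
#' pairs, embeds observed and simulated profiles jointly (library-size
#' normalization, log1p, PCA), and scores each observed cell by the fraction
#' of simulated doublets among its k nearest neighbours, corrected for the
#' simulated:observed ratio so the score estimates the doublet probability.
#' The call threshold comes from a two-component mixture fit to the scores
#' (quantile fallback).
#'
#' @param exp single-sample Cell-level `QCExperiment` with at least 50
#'   cells.
#' @param sim_ratio simulated doublets per observed cell.
#' @param n_pcs number of principal components.
#' @param k neighbourhood size; default `round(sqrt(n))`.
#' @param expected_rate doublet rate used by the quantile fallback.
#' @param n_var number of top-variable genes in the feature space.
#' @param seed integer seed.
#' @return A `DoubletResult` (score, threshold, call).
#' @export
doubletKnn <- function(exp, sim_ratio = 1.0, n_pcs = 30L, k = NULL,
                       expected_rate = 0.05, n_var = 2000L, seed = 1L) {
  counts <- SummarizedExperiment::assay(exp, "counts")
  n <- ncol(counts)
  if (n < 50L) stopf("doublet simulation needs at least 50 cells (have %d)", n)
  k <- k %||% max(5L, round(sqrt(n)))
  if (k >= n) stopf("k = %d must be smaller than the number of cells", k)
  withSeed(seed, {
    n_sim <- max(1L, round(sim_ratio * n))
    sim <- simulateDoublets(counts, n_sim)
    feats <- normalizedFeatures(cbind(counts, sim), n_var = n_var)
    emb <- pcaEmbed(feats, n_pcs)
    obs_emb <- emb[seq_len(n), , drop = FALSE]
    nn <- FNN::get.knnx(emb, obs_emb, k = k + 1L)$nn.index
    q <- vapply(seq_len(n), function(i) {
      idx <- nn[i, ]
      idx <- idx[idx != i][seq_len(k)]
      mean(idx > n)
    }, numeric(1))
    r <- n_sim / (n_sim + n)
    score <- q * (1 - r) / (q * (1 - r) + (1 - q) * r)
    names(score) <- colnames(counts)
    thr <- mixtureThreshold(score, expected_rate)
    doubletResult("knn", score, thr$threshold,
                  list(sim_ratio = sim_ratio, n_pcs = n_pcs, k = k,
                       expected_rate = expected_rate, seed = seed),
                  thr$method)
  })
}

# -- binarized co-expression scorer -------------------------------------------

#' Doublet score from binarized gene-pair co-expression
#'
#' Binarizes each gene at its per-gene count quantile (median by default;
#' genes whose threshold is zero binarize at count > 0), ranks gene pairs by
#' how much less often they are co-expressed than expected under
#' independence (binomial lower-tail deviation), and scores each cell by the
#' exclusivity-weighted number of top pairs it co-expresses. Deterministic.
#'
#' @param exp single-sample Cell-level `QCExperiment`.
#' @param n_top_pairs number of most mutually-exclusive pairs summed.
#' @param binarize_quantile per-gene binarization quantile.
#' @param n_genes number of most variably-binarized genes considered for
#'   pairing.
#' @param expected_rate doublet rate used by the quantile fallback.
#' @return A `DoubletResult`.
#' @export
doubletCxds <- function(exp, n_top_pairs = 500L, binarize_quantile = 0.5,
                        n_genes = 500L, expected_rate = 0.05) {
  counts <- SummarizedExperiment::assay(exp, "counts")
  n <- ncol(counts)
  dense <- as.matrix(counts)
  thr <- apply(dense, 1L, quantile, probs = binarize_quantile, names = FALSE)
  B <- dense > thr
  p <- rowMeans(B)
  keep <- which(p > 0 & p < 1)
  if (length(keep) < 2L)
    stopf("degenerate binarization: fewer than 2 variable genes")
  keep <- keep[order(p[keep] * (1 - p[keep]),
                     decreasing = TRUE)][seq_len(min(n_genes, length(keep)))]
  B <- B[keep, , drop = FALSE]
  p <- p[keep]
  co <- tcrossprod(B * 1)           # observed co-expression counts
  pij <- tcrossprod(matrix(p, ncol = 1))
  iu <- which(upper.tri(co))
  w <- -stats::pbinom(co[iu], n, pij[iu], lower.tail = TRUE, log.p = TRUE)
  top <- iu[order(w, decreasing = TRUE)[seq_len(min(n_top_pairs,
                                                    length(iu)))]]
  wtop <- -stats::pbinom(co[top], n, pij[top], lower.tail = TRUE,
                         log.p = TRUE)
  ri <- (top - 1L) %% nrow(co) + 1L
  ci <- (top - 1L) %/% nrow(co) + 1L
  both <- (B[ri, , drop = FALSE] & B[ci, , drop = FALSE]) * 1
  score <- as.vector(crossprod(both, wtop))
  names(score) <- colnames(counts)
  thr2 <- mixtureThreshold(score, expected_rate)
  doubletResult("cxds", score, thr2$threshold,
                list(n_top_pairs = n_top_pairs,
                     binarize_quantile = binarize_quantile,
                     n_genes = n_genes), thr2$method)
}

# -- classifier-boosted scorer ------------------------------------------------

#' Doublet score from a gradient-boosted classifier
#'
#' Labels observed cells 0 and simulated doublets 1, trains a
#' gradient-boosted tree classifier on normalized top-variable-gene features
#' with internal cross-validation, and scores each observed cell by its
#' out-of-fold predicted doublet probability.
#'
#' @inheritParams doubletKnn
#' @param nrounds boosting rounds.
#' @param nfold cross-validation folds.
#' @return A `DoubletResult`.
#' @export
doubletBcds <- function(exp, sim_ratio = 1.0, n_var = 2000L, nrounds = 100L,
                        nfold = 5L, expected_rate = 0.05, seed = 1L) {
  counts <- SummarizedExperiment::assay(exp, "counts")
  n <- ncol(counts)
  if (n < 100L) stopf("classifier training needs at least 100 cells (have %d)",
                      n)
  withSeed(seed, {
    n_sim <- max(1L, round(sim_ratio * n))
    sim <- simulateDoublets(counts, n_sim)
    feats <- normalizedFeatures(cbind(counts, sim), n_var = n_var)
    label <- c(rep(0, n), rep(1, n_sim))
    cv <- xgboost::xgb.cv(
      params = list(objective = "binary:logistic", eta = 0.3, max_depth = 6,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(feats, label = label),
      nrounds = nrounds, nfold = nfold, prediction = TRUE, verbose = 0)
    pred <- cv$cv_predict$pred %||% cv$pred
    score <- as.numeric(pred)[seq_len(n)]
    names(score) <- colnames(counts)
    thr <- mixtureThreshold(score, expected_rate)
    doubletResult("bcds", score, thr$threshold,
                  list(sim_ratio = sim_ratio, nrounds = nrounds,
                       nfold = nfold, seed = seed), thr$method)
  })
}

# -- hybrid and consensus -----------------------------------------------------

minmax <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Hybrid of the co-expression and classifier doublet scores
#'
#' @param cxds,bcds `DoubletResult`s for the same cells.
#' @param expected_rate doublet rate used by the quantile fallback.
#' @return A `DoubletResult` whose score is the sum of the two
#'   min-max-normalized component scores (range 0-2), with a re-derived
#'   threshold.
#' @export
doubletHybrid <- function(cxds, bcds, expected_rate = 0.05) {
  stopifnot(length(cxds$score) == length(bcds$score))
  score <- minmax(cxds$score) + minmax(bcds$score)
  names(score) <- names(cxds$score)
  thr <- mixtureThreshold(score, expected_rate)
  doubletResult("hybrid", score, thr$threshold,
                list(components = c(cxds$algorithm, bcds$algorithm)),
                thr$method)
}

#' Consensus doublet call across algorithms
#'
#' @param results list of `DoubletResult`s (or logical call vectors) over
#'   the same cells.
#' @param min_votes minimum number of algorithms calling doublet.
#' @return Logical per-cell consensus call.
#' @export
doubletConsensus <- function(results, min_votes = 2L) {
  calls <- lapply(results, function(r)
    if (inherits(r, "DoubletResult")) r$call else as.logical(r))
  votes <- Reduce(`+`, calls)
  votes >= min_votes
}

# -- per-sample pipeline wrappers ---------------------------------------------

runDoubletAlgo <- function(exp, algo, fun, params, seed = NA) {
  if (!matrixLevel(exp) %in% c("Cell", "FilteredCell"))
    stopf("doublet detection runs on the Cell or FilteredCell matrix")
  thresholds <- list()
  res <- perSampleMetrics(exp, function(sub) {
    dr <- fun(sub)
    thresholds[[sub$sample[1]]] <<- dr$threshold
    setNames(list(unname(dr$score), unname(dr$call)),
             paste0(algo, c("_doublet_score", "_doublet_call")))
  })
  for (nm in names(res))
    exp <- attachCellMetric(exp, nm, res[[nm]], overwrite = TRUE)
  logProvenance(exp, paste0("runDoublet_", algo),
                c(params, list(thresholds = thresholds)), seed = seed)
}

#' Run doublet detection and attach results
#'
#' Per-sample wrappers around [doubletKnn()], [doubletCxds()],
#' [doubletBcds()], [doubletHybrid()] and [doubletConsensus()] that append
#' `<algo>_doublet_score` / `<algo>_doublet_call` columns (and
#' `doublet_consensus_call`) to the cell annotations with provenance.
#'
#' @param exp Cell- or FilteredCell-level `QCExperiment`.
#' @param seed integer seed (stochastic scorers).
#' @param ... passed to the corresponding scorer.
#' @return The annotated experiment.
#' @export
runDoubletKNN <- function(exp, seed = 1L, ...) {
  runDoubletAlgo(exp, "knn", function(sub)
    doubletKnn(sub, seed = deriveSeed(seed, paste0("knn_", sub$sample[1])),
               ...),
    list(...), seed = seed)
}

#' @rdname runDoubletKNN
#' @export
runCxds <- function(exp, ...) {
  runDoubletAlgo(exp, "cxds", function(sub) doubletCxds(sub, ...), list(...))
}

#' @rdname runDoubletKNN
#' @export
runBcds <- function(exp, seed = 1L, ...) {
  runDoubletAlgo(exp, "bcds", function(sub)
    doubletBcds(sub, seed = deriveSeed(seed, paste0("bcds_", sub$sample[1])),
                ...),
    list(...), seed = seed)
}

#' @rdname runDoubletKNN
#' @param expected_rate doublet rate used by the quantile fallback.
#' @export
runCxdsBcdsHybrid <- function(exp, expected_rate = 0.05) {
  cd <- SummarizedExperiment::colData(exp)
  for (need in c("cxds_doublet_score", "bcds_doublet_score"))
    if (!need %in% colnames(cd))
      stopf("column '%s' missing: run the component scorer first", need)
  runDoubletAlgo(exp, "hybrid", function(sub) {
    scd <- SummarizedExperiment::colData(sub)
    doubletHybrid(
      doubletResult("cxds", setNames(scd$cxds_doublet_score, colnames(sub)),
                    Inf),
      doubletResult("bcds", setNames(scd$bcds_doublet_score, colnames(sub)),
                    Inf),
      expected_rate)
  }, list(expected_rate = expected_rate))
}

#' @rdname runDoubletKNN
#' @param algorithms algorithm prefixes whose `_doublet_call` columns vote.
#' @param min_votes minimum votes for a consensus doublet.
#' @export
runDoubletConsensus <- function(exp, algorithms = c("knn", "cxds", "bcds"),
                                min_votes = 2L) {
  cd <- SummarizedExperiment::colData(exp)
  cols <- paste0(algorithms, "_doublet_call")
  miss <- setdiff(cols, colnames(cd))
  if (length(miss)) stopf("missing doublet call column(s): %s",
                          paste(miss, collapse = ", "))
  consensus <- doubletConsensus(lapply(cols, function(cc) cd[[cc]]),
                                min_votes = min_votes)
  exp <- attachCellMetric(exp, "doublet_consensus_call", consensus,
                          overwrite = TRUE)
  logProvenance(exp, "runDoubletConsensus",
                list(algorithms = algorithms, min_votes = min_votes))
}
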