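#' Estimate and remove ambient RNA contamination
#'
#' Models each cell's counts as a multinomial mixture of an ambient RNA
#' profile shared by all cells and the native expression profile of the
#' cell's cluster: gene g in cell c has probability
#' `theta_c * eta_g + (1 - theta_c) * phi_{k(c), g}`, where `theta_c` is the
#' cell's contamination fraction. Parameters are estimated by
#' maximum-likelihood EM with a small Dirichlet smoothing prior on the
#' profiles; the posterior ambient responsibility of every observed count
#' splits the matrix into native and contaminating parts exactly.
#'
#' When no cluster labels are given they are derived by library-size
#' normalization, PCA and k-means, with k chosen by average silhouette
#' width over k = 2..10. A single cluster (user-supplied) is an error: with
#' one cluster the ambient profile is statistically indistinguishable from
#' native expression.
#'
#' @param exp Cell- or FilteredCell-level `QCExperiment` (single or
#'   multi-sample; samples are processed independently).
#' @param clusters optional per-cell labels overriding cluster derivation.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the mean absolute change of theta.
#' @param alpha Dirichlet smoothing pseudo-count for profile estimates.
#' @param seed integer seed (cluster derivation).
#' @return `decontX()` (single sample) returns a `DecontResult` list:
#'   `contamination` (theta per cell), `cluster`, `native_counts` (sparse,
#'   real-valued), `ambient_dist`, `converged`, `n_iterations`, and the
#'   per-iteration penalized `log_likelihood` trace (non-decreasing).
#' @export
decontX <- function(exp, clusters = NULL, max_iter = 500L, tol = 1e-4,
                    alpha = 1e-2, seed = 1L) {
  counts <- as(SummarizedExperiment::assay(exp, "counts"), "CsparseMatrix")
  G <- nrow(counts); n <- ncol(counts)
  if (is.null(clusters)) {
    clusters <- deriveClusters(counts, seed = seed)
  } else {
    if (length(clusters) != n) stopf("one cluster label per cell required")
    clusters <- as.integer(factor(clusters))
    if (length(unique(clusters)) < 2L)
      stopf(paste("a single cluster cannot be decontaminated: the ambient",
                  "profile is indistinguishable from native expression"))
  }
  K <- max(clusters)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stopf("cells with zero counts cannot be modelled")

  ii <- counts@i + 1L
  jj <- rep.int(seq_len(n), diff(counts@p))
  xx <- counts@x
  zz <- clusters[jj]

  eta <- as.vector(Matrix::rowSums(counts)) + alpha
  eta <- eta / sum(eta)
  phi <- vapply(seq_len(K), function(k) {
    v <- Matrix::rowSums(counts[, clusters == k, drop = FALSE]) + alpha
    v / sum(v)
  }, numeric(G))
  theta <- rep(0.1, n)

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    amb <- theta[jj] * eta[ii]
    nat <- (1 - theta[jj]) * phi[cbind(ii, zz)]
    mix <- amb + nat
    r <- amb / mix
    # penalized observed-data log-likelihood (Dirichlet smoothing terms)
    ll <- sum(xx * log(mix)) + alpha * (sum(log(eta)) + sum(log(phi)))
    loglik <- c(loglik, ll)
    amb_counts <- xx * r
    theta_new <- as.vector(rowsum(amb_counts, jj, reorder = TRUE)) / totals
    nat_counts <- xx - amb_counts
    phi_num <- as.matrix(Matrix::sparseMatrix(
      i = ii, j = zz, x = nat_counts, dims = c(G, K))) + alpha
    phi <- sweep(phi_num, 2, colSums(phi_num), "/")
    eta_num <- numeric(G)
    agg <- rowsum(amb_counts, ii)
    eta_num[as.integer(rownames(agg))] <- agg[, 1]
    eta <- (eta_num + alpha) / sum(eta_num + alpha)
    delta <- mean(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warnf("EM did not converge in %d iterations (last delta %.2g)",
          max_iter, mean(abs(delta)))

  amb <- theta[jj] * eta[ii]
  nat <- (1 - theta[jj]) * phi[cbind(ii, zz)]
  r <- amb / (amb + nat)
  native <- Matrix::sparseMatrix(i = ii, j = jj, x = xx * (1 - r),
                                 dims = dim(counts),
                                 dimnames = dimnames(counts))
  theta <- as.vector(rowsum(xx * r, jj)) / totals
  structure(list(contamination = setNames(theta, colnames(counts)),
                 cluster = setNames(clusters, colnames(counts)),
                 native_counts = native,
                 ambient_dist = setNames(eta, rownames(counts)),
                 converged = converged, n_iterations = iter,
                 log_likelihood = loglik),
            class = "DecontResult")
}

# Normalize -> PCA -> k-means, k chosen by mean silhouette width over 2..10.
deriveClusters <- function(counts, n_pcs = 30L, k_range = 2:10, seed = 1L) {
  withSeed(seed, {
    feats <- normalizedFeatures(counts, n_var = 2000L)
    emb <- pcaEmbed(feats, n_pcs)
    d <- dist(emb)
    best <- NULL; best_sil <- -Inf
    for (k in k_range) {
      if (k >= nrow(emb)) break
      km <- kmeans(emb, centers = k, nstart = 5, iter.max = 50)
      sil <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
      if (sil > best_sil) { best_sil <- sil; best <- km$cluster }
    }
    if (is.null(best)) stopf("cluster derivation failed")
    as.integer(best)
  })
}

#' @rdname decontX
#' @return `runDecontX()` returns the experiment with columns
#'   `decontX_contamination` and `decontX_clusters`, the decontaminated
#'   matrix as assay `decontX_counts`, and a provenance entry.
#' @export
runDecontX <- function(exp, clusters = NULL, max_iter = 500L, tol = 1e-4,
                       alpha = 1e-2, seed = 1L) {
  if (!matrixLevel(exp) %in% c("Cell", "FilteredCell"))
    stopf("decontamination runs on the Cell or FilteredCell matrix")
  smp <- exp$sample
  theta <- numeric(ncol(exp)); clus <- integer(ncol(exp))
  native <- SummarizedExperiment::assay(exp, "counts") * 0
  iters <- list()
  for (s in unique(smp)) {
    idx <- which(smp == s)
    res <- decontX(exp[, idx],
                   clusters = if (!is.null(clusters)) clusters[idx],
                   max_iter = max_iter, tol = tol, alpha = alpha,
                   seed = deriveSeed(seed, paste0("decontX_", s)))
    theta[idx] <- res$contamination
    clus[idx] <- res$cluster
    native[, idx] <- res$native_counts
    iters[[s]] <- res$n_iterations
  }
  exp <- attachCellMetric(exp, "decontX_contamination", theta,
                          overwrite = TRUE)
  exp <- attachCellMetric(exp, "decontX_clusters", clus, overwrite = TRUE)
  SummarizedExperiment::assay(exp, "decontX_counts") <- native
  logProvenance(exp, "runDecontX",
                list(max_iter = max_iter, tol = tol, alpha = alpha,
                     user_clusters = !is.null(clusters),
                     n_iterations = iters), seed = seed)
}

#' Two-dimensional embedding for QC visualization
#'
#' UMAP of the normalized, PCA-reduced matrix, stored in the experiment's
#' reduced dimensions as `decontX_UMAP` and used by the cell QC report
#' scatterplots.
#'
#' @param exp Cell- or FilteredCell-level `QCExperiment`.
#' @param n_pcs number of principal components fed to UMAP.
#' @param n_neighbors UMAP neighbourhood size.
#' @param seed integer seed.
#' @return The experiment with the embedding attached.
#' @export
runDecontXUMAP <- function(exp, n_pcs = 30L, n_neighbors = 15L, seed = 1L) {
  counts <- SummarizedExperiment::assay(exp, "counts")
  emb <- matrix(NA_real_, ncol(exp), 2L,
                dimnames = list(colnames(exp), c("UMAP1", "UMAP2")))
  for (s in unique(exp$sample)) {
    idx <- which(exp$sample == s)
    feats <- normalizedFeatures(counts[, idx, drop = FALSE], n_var = 2000L)
    pcs <- pcaEmbed(feats, n_pcs)
    sd2 <- deriveSeed(seed, paste0("umap_", s))
    emb[idx, ] <- withSeed(sd2,
      uwot::umap(pcs, n_neighbors = min(n_neighbors, length(idx) - 1L),
                 n_threads = 1, n_sgd_threads = 1, seed = sd2))
  }
  SingleCellExperiment::reducedDim(exp, "decontX_UMAP") <- emb
  logProvenance(exp, "runDecontXUMAP",
                list(n_pcs = n_pcs, n_neighbors = n_neighbors), seed = seed)
}
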