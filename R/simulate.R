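#' Simulation settings for droplet-level fixture data
#'
#' Defines the generative model used throughout the test-suite: cell-type
#' expression profiles drawn from a Dirichlet distribution, an ambient RNA
#' profile equal to the equal-weight mixture of the type profiles, empty
#' droplets sampling pure ambient RNA at small library sizes, singlets
#' sampling a per-cell mixture `(1 - theta) * type + theta * ambient` (theta
#' is the cell's ambient contamination fraction), and heterotypic doublets
#' formed by summing two independent singlet draws from distinct types.
#'
#' Defaults emulate a small droplet run: 500 genes, 3 cell types with 300
#' cells each, 20,000 empty droplets at a log-normal ~10-count library size,
#' cells at ~5,000 counts, 8% doublets, and contamination Beta(2, 18)
#' (mean 0.10, the typical magnitude seen in real droplet data).
#'
#' @param n_genes number of genes.
#' @param n_cell_types number of distinct cell types.
#' @param cells_per_type singlets per type.
#' @param n_empty_droplets empty droplets.
#' @param empty_total_meanlog,empty_total_sdlog log-normal parameters of the
#'   empty-droplet library size.
#' @param cell_total_meanlog,cell_total_sdlog log-normal parameters of the
#'   cell library size.
#' @param doublet_fraction fraction of cell-containing barcodes that are
#'   doublets.
#' @param contamination_shape1,contamination_shape2 Beta parameters of the
#'   per-cell contamination fraction.
#' @param type_profile_concentration Dirichlet concentration of the type
#'   profiles (smaller = more distinct types).
#' @param seed integer seed.
#' @return A list of class `SimulationSpec`.
#' @export
simulationSpec <- function(n_genes = 500L, n_cell_types = 3L,
                           cells_per_type = 300L,
                           n_empty_droplets = 20000L,
                           empty_total_meanlog = log(10),
                           empty_total_sdlog = 0.5,
                           cell_total_meanlog = log(5000),
                           cell_total_sdlog = 0.3,
                           doublet_fraction = 0.08,
                           contamination_shape1 = 2,
                           contamination_shape2 = 18,
                           type_profile_concentration = 0.5,
                           seed = 20240101L) {
  spec <- as.list(environment())
  stopifnot(spec$doublet_fraction >= 0, spec$doublet_fraction < 1,
            spec$n_genes >= 2, spec$n_cell_types >= 1)
  class(spec) <- "SimulationSpec"
  spec
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# Multinomial draws for many columns with per-column sizes and a list of
# per-column probability vectors, returned as a sparse genes x n matrix.
rmultinomCols <- function(sizes, probs) {
  n <- length(sizes)
  stopifnot(is.list(probs), length(probs) == n)
  G <- length(probs[[1]])
  ii <- vector("list", n); xx <- vector("list", n)
  for (j in seq_len(n)) {
    cnt <- as.vector(rmultinom(1L, sizes[j], probs[[j]]))
    nz <- which(cnt > 0L)
    ii[[j]] <- nz; xx[[j]] <- cnt[nz]
  }
  lens <- lengths(ii)
  Matrix::sparseMatrix(i = unlist(ii), j = rep.int(seq_len(n), lens),
                       x = as.numeric(unlist(xx)), dims = c(G, n))
}

#' Simulate a droplet-level experiment with known ground truth
#'
#' @param spec a [simulationSpec()].
#' @param sample_name sample label stored in the `sample` annotation.
#' @return A list with `experiment` (Droplet-level `QCExperiment`) and
#'   `truth`, a list holding the per-barcode `labels`
#'   (`"empty"`/`"singlet"`/`"doublet"`), `type` assignments, true
#'   contamination `theta` (NA for empties), the `ambient` profile and the
#'   `type_profiles` matrix.
#' @export
simulateDropletData <- function(spec = simulationSpec(),
                                sample_name = "sim1") {
  stopifnot(inherits(spec, "SimulationSpec"))
  withSeed(spec$seed, {
    G <- spec$n_genes; K <- spec$n_cell_types
    phi <- vapply(seq_len(K), function(k)
      rdirichlet1(rep(spec$type_profile_concentration, G)), numeric(G))
    ambient <- rowMeans(phi)
    n_sing <- K * spec$cells_per_type
    n_dbl <- round(spec$doublet_fraction / (1 - spec$doublet_fraction) *
                     n_sing)
    n_emp <- spec$n_empty_droplets

    # empties: pure ambient at small totals
    emp_tot <- pmax(1L, round(rlnorm(n_emp, spec$empty_total_meanlog,
                                     spec$empty_total_sdlog)))
    emp_mat <- if (n_emp > 0)
      rmultinomCols(emp_tot, replicate(n_emp, ambient, simplify = FALSE))
    else Matrix::Matrix(0, G, 0, sparse = TRUE)

    # singlets: contaminated mixture draws
    sing_type <- rep(seq_len(K), each = spec$cells_per_type)
    sing_tot <- pmax(10L, round(rlnorm(n_sing, spec$cell_total_meanlog,
                                       spec$cell_total_sdlog)))
    theta_s <- rbeta(n_sing, spec$contamination_shape1,
                     spec$contamination_shape2)
    sing_probs <- lapply(seq_len(n_sing), function(j)
      (1 - theta_s[j]) * phi[, sing_type[j]] + theta_s[j] * ambient)
    sing_mat <- rmultinomCols(sing_tot, sing_probs)

    # heterotypic doublets: sum of two independent singlet draws of
    # distinct types
    if (n_dbl > 0) {
      dbl_types <- if (K == 1L) matrix(1L, n_dbl, 2L) else
        t(vapply(seq_len(n_dbl), function(j)
          sort(sample.int(K, 2L)), integer(2)))
      dbl_tot1 <- pmax(10L, round(rlnorm(n_dbl, spec$cell_total_meanlog,
                                         spec$cell_total_sdlog)))
      dbl_tot2 <- pmax(10L, round(rlnorm(n_dbl, spec$cell_total_meanlog,
                                         spec$cell_total_sdlog)))
      th1 <- rbeta(n_dbl, spec$contamination_shape1,
                   spec$contamination_shape2)
      th2 <- rbeta(n_dbl, spec$contamination_shape1,
                   spec$contamination_shape2)
      p1 <- lapply(seq_len(n_dbl), function(j)
        (1 - th1[j]) * phi[, dbl_types[j, 1]] + th1[j] * ambient)
      p2 <- lapply(seq_len(n_dbl), function(j)
        (1 - th2[j]) * phi[, dbl_types[j, 2]] + th2[j] * ambient)
      dbl_mat <- rmultinomCols(dbl_tot1, p1) + rmultinomCols(dbl_tot2, p2)
      theta_d <- (th1 * dbl_tot1 + th2 * dbl_tot2) / (dbl_tot1 + dbl_tot2)
    } else {
      dbl_mat <- Matrix::Matrix(0, G, 0, sparse = TRUE)
      dbl_types <- matrix(integer(0), 0, 2)
      theta_d <- numeric(0)
    }

    counts <- cbind(emp_mat, sing_mat, dbl_mat)
    n_all <- ncol(counts)
    barcodes <- sprintf("BC%06d", seq_len(n_all))
    genes <- sprintf("GENE%04d", seq_len(G))
    dimnames(counts) <- list(genes, barcodes)
    labels <- c(rep("empty", n_emp), rep("singlet", n_sing),
                rep("doublet", n_dbl))
    type <- c(rep(NA_character_, n_emp), as.character(sing_type),
              if (n_dbl > 0) paste(dbl_types[, 1], dbl_types[, 2], sep = "+"))
    theta <- c(rep(NA_real_, n_emp), theta_s, theta_d)

    exp <- QCExperiment(counts, level = "Droplet", sample = sample_name)
    exp <- logProvenance(exp, "simulateDropletData",
                         parameters = unclass(spec), seed = spec$seed)
    rownames(phi) <- genes
    list(experiment = exp,
         truth = list(labels = labels, type = type, theta = theta,
                      ambient = setNames(ambient, genes),
                      type_profiles = phi, barcodes = barcodes))
  })
}

#' Simulate a Cell-level experiment (no empty droplets)
#'
#' Convenience wrapper around [simulateDropletData()] with zero empty
#' droplets, returning the matrix at Cell level: the standard fixture for
#' doublet and decontamination testing.
#'
#' @inheritParams simulateDropletData
#' @return As [simulateDropletData()] but with a Cell-level experiment.
#' @export
simulateCellData <- function(spec = simulationSpec(n_empty_droplets = 0L),
                             sample_name = "sim1") {
  spec$n_empty_droplets <- 0L
  sim <- simulateDropletData(spec, sample_name)
  S4Vectors::metadata(sim$experiment)$level <- "Cell"
  sim
}
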