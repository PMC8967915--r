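#' Per-sample QC summary table
#'
#' Builds the standard per-sample summary: matrix dimensions, mean/median
#' counts and features, per-algorithm doublet counts and percentages, and
#' mean/median contamination percentages. Metrics whose annotation columns
#' are absent are rendered as `NA`.
#'
#' @param cell Cell- or FilteredCell-level `QCExperiment`.
#' @param droplet optional Droplet-level `QCExperiment` for droplet counts.
#' @return A data.frame with a `metric` column and one column per sample.
#' @export
summarizeQC <- function(cell, droplet = NULL) {
  cd <- SummarizedExperiment::colData(cell)
  samples <- unique(cell$sample)
  algo_names <- c(knn = "KNN", cxds = "CXDS", bcds = "BCDS",
                  hybrid = "SCDS Hybrid")
  algos <- names(algo_names)[paste0(names(algo_names), "_doublet_call") %in%
                               colnames(cd)]
  metric_rows <- function(s) {
    idx <- cell$sample == s
    scd <- cd[idx, , drop = FALSE]
    counts <- SummarizedExperiment::assay(cell, "counts")[, idx,
                                                          drop = FALSE]
    get <- function(col, f) if (col %in% colnames(scd))
      f(scd[[col]][!is.na(scd[[col]])]) else NA_real_
    vals <- c(
      `Total number of genes detected` = sum(Matrix::rowSums(counts) > 0),
      `Number of droplets, Droplet matrix` = if (!is.null(droplet))
        sum(droplet$sample == s) else NA_real_,
      `Number of cells, Cell matrix` = sum(idx),
      `Mean counts` = get("total", mean),
      `Median counts` = get("total", median),
      `Mean features detected` = get("detected", mean),
      `Median features detected` = get("detected", median))
    for (a in algos) {
      calls <- scd[[paste0(a, "_doublet_call")]]
      calls <- calls[!is.na(calls)]
      vals[sprintf("%s, Number of doublets", algo_names[[a]])] <- sum(calls)
      vals[sprintf("%s, Percentage of doublets", algo_names[[a]])] <-
        round(100 * sum(calls) / max(length(calls), 1L), 2)
    }
    if ("doublet_consensus_call" %in% colnames(scd)) {
      calls <- scd$doublet_consensus_call
      vals["Consensus, Number of doublets"] <- sum(calls, na.rm = TRUE)
      vals["Consensus, Percentage of doublets"] <-
        round(100 * sum(calls, na.rm = TRUE) / sum(!is.na(calls)), 2)
    }
    if ("decontX_contamination" %in% colnames(scd)) {
      vals["DecontX, Mean contamination percentage"] <-
        round(100 * mean(scd$decontX_contamination), 2)
      vals["DecontX, Median contamination percentage"] <-
        round(100 * median(scd$decontX_contamination), 2)
    }
    vals
  }
  cols <- lapply(samples, metric_rows)
  out <- data.frame(metric = names(cols[[1]]), check.names = FALSE)
  for (i in seq_along(samples)) out[[samples[i]]] <- unname(cols[[i]])
  out
}

#' Write a QC summary table as TSV
#' @param summary data.frame from [summarizeQC()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummaryTSV <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- HTML templating ----------------------------------------------------------

# ggplot -> base64 <img> tag (self-contained reports, no external files)
plotToImg <- function(p, width = 6, height = 4) {
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp, width = width * 96, height = height * 96, res = 96,
                 type = "cairo")
  print(p)
  grDevices::dev.off()
  b64 <- base64enc::base64encode(tmp)
  unlink(tmp)
  sprintf('<img src="data:image/png;base64,%s" width="%d"/>', b64,
          width * 96)
}

htmlTable <- function(df) {
  df[] <- lapply(df, function(x) trimws(as.character(x)))
  head <- paste0("<tr>", paste0("<th>", colnames(df), "</th>",
                                collapse = ""), "</tr>")
  rows <- apply(df, 1L, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  paste0("<table border='1' cellpadding='4' cellspacing='0'>", head,
         paste(rows, collapse = "\n"), "</table>")
}

provenanceTable <- function(exp) {
  prov <- provenance(exp)
  if (!length(prov)) return("<p>No provenance entries.</p>")
  df <- data.frame(
    operation = vapply(prov, `[[`, "", "operation"),
    parameters = vapply(prov, function(e)
      gsub(",", ", ", gsub("[\n ]+", " ",
                           yaml::as.yaml(e$parameters))), ""),
    seed = vapply(prov, function(e)
      as.character(e$seed %||% NA), ""))
  htmlTable(df)
}

htmlPage <- function(title, body) {
  sprintf(paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'/>",
    "<title>%s</title>",
    "<style>body{font-family:sans-serif;margin:2em;}",
    "h1,h2{color:#2c3e50;} table{border-collapse:collapse;}",
    "th{background:#eee;}</style></head>\n",
    "<body>\n<h1>%s</h1>\n<p class='timestamp'>Generated: %s</p>\n%s\n",
    "</body></html>\n"),
    title, title, format(Sys.time(), "%Y-%m-%d %H:%M:%S"), body)
}

#' Droplet QC HTML report
#'
#' Self-contained HTML with, per sample, the log-log barcode-rank curve
#' with knee and inflection points and the total-count versus ambient
#' log-probability scatter coloured by the cell call, plus the provenance
#' parameter table. Rendering never mutates the experiment.
#'
#' @param droplet Droplet-level `QCExperiment` with droplet-QC columns.
#' @param out_path output HTML path.
#' @return `out_path`, invisibly.
#' @export
reportDropletQC <- function(droplet, out_path) {
  cd <- SummarizedExperiment::colData(droplet)
  need <- c("dropletUtils_barcodeRank_rank", "dropletUtils_barcodeRank_total",
            "dropletUtils_barcodeRank_knee",
            "dropletUtils_barcodeRank_inflection",
            "dropletUtils_emptyDrops_logprob",
            "dropletUtils_emptyDrops_is_cell")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    stopf("droplet-QC columns missing: %s", paste(miss, collapse = ", "))
  sections <- vapply(unique(droplet$sample), function(s) {
    scd <- as.data.frame(cd[droplet$sample == s, , drop = FALSE])
    knee <- scd$dropletUtils_barcodeRank_knee[1]
    infl <- scd$dropletUtils_barcodeRank_inflection[1]
    df <- data.frame(rank = scd$dropletUtils_barcodeRank_rank,
                     total = scd$dropletUtils_barcodeRank_total)
    df <- df[df$total > 0, ]
    p1 <- ggplot2::ggplot(df, ggplot2::aes(x = rank, y = total)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::geom_hline(yintercept = knee, linetype = 2,
                          colour = "dodgerblue") +
      ggplot2::geom_hline(yintercept = infl, linetype = 2,
                          colour = "darkgreen") +
      ggplot2::labs(title = "Barcode rank curve", x = "Rank",
                    y = "Total UMI counts") +
      ggplot2::theme_bw()
    sdf <- data.frame(total = scd$dropletUtils_emptyDrops_total,
                      logprob = scd$dropletUtils_emptyDrops_logprob,
                      is_cell = factor(ifelse(
                        is.na(scd$dropletUtils_emptyDrops_is_cell), "untested",
                        ifelse(scd$dropletUtils_emptyDrops_is_cell, "cell",
                               "empty"))))
    sdf <- sdf[!is.na(sdf$logprob), ]
    p2 <- ggplot2::ggplot(sdf, ggplot2::aes(x = total, y = -logprob,
                                            colour = is_cell)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.7) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(title = "Ambient-model test",
                    x = "Total UMI counts",
                    y = "-log ambient probability") +
      ggplot2::theme_bw()
    paste0("<h2>Sample: ", s, "</h2>\n",
           sprintf("<p>Knee: %.0f counts; inflection: %.0f counts.</p>",
                   knee, infl),
           plotToImg(p1), "\n", plotToImg(p2))
  }, character(1))
  body <- paste0(paste(sections, collapse = "\n"),
                 "\n<h2>Parameters</h2>\n", provenanceTable(droplet))
  writeLines(htmlPage("Droplet QC report", body), out_path)
  invisible(out_path)
}

#' Cell QC HTML report
#'
#' Self-contained HTML with per-sample violin plots of the per-cell
#' metrics, one section per doublet algorithm (score violin by call, and
#' score on the embedding when one is present), a decontamination section
#' when contamination has been estimated, and the embedded summary table.
#'
#' @param cell Cell- or FilteredCell-level `QCExperiment`.
#' @param out_path output HTML path.
#' @param droplet optional Droplet experiment for the summary table.
#' @return `out_path`, invisibly.
#' @export
reportCellQC <- function(cell, out_path, droplet = NULL) {
  cd <- as.data.frame(SummarizedExperiment::colData(cell))
  if (!"total" %in% colnames(cd))
    stopf("cell-QC columns missing: run the per-cell QC step first")
  violin <- function(col, title) {
    df <- data.frame(sample = cd$sample, value = cd[[col]])
    ggplot2::ggplot(df, ggplot2::aes(x = sample, y = value)) +
      ggplot2::geom_violin(fill = "skyblue") +
      ggplot2::labs(title = title, x = NULL, y = col) +
      ggplot2::theme_bw()
  }
  emb <- if (length(SingleCellExperiment::reducedDimNames(cell)))
    SingleCellExperiment::reducedDim(
      cell, SingleCellExperiment::reducedDimNames(cell)[1]) else NULL
  embPlot <- function(col, title) {
    df <- data.frame(D1 = emb[, 1], D2 = emb[, 2], value = cd[[col]])
    ggplot2::ggplot(df, ggplot2::aes(x = D1, y = D2, colour = value)) +
      ggplot2::geom_point(size = 0.6) +
      ggplot2::labs(title = title) + ggplot2::theme_bw()
  }
  parts <- c("<h2>Per-cell metrics</h2>",
             plotToImg(violin("total", "Total UMI counts per cell")),
             plotToImg(violin("detected", "Genes detected per cell")))
  for (col in grep("_percent$", colnames(cd), value = TRUE))
    parts <- c(parts, plotToImg(violin(col, col)))
  for (a in c("knn", "cxds", "bcds", "hybrid")) {
    sc <- paste0(a, "_doublet_score")
    if (!sc %in% colnames(cd)) next
    parts <- c(parts, sprintf("<h2>Doublets: %s</h2>", a),
               plotToImg(violin(sc, sprintf("%s doublet score", a))))
    if (!is.null(emb)) parts <- c(parts, plotToImg(
      embPlot(sc, sprintf("%s doublet score", a))))
  }
  if ("decontX_contamination" %in% colnames(cd)) {
    parts <- c(parts, "<h2>Ambient RNA contamination</h2>",
               plotToImg(violin("decontX_contamination",
                                "Contamination fraction")))
    if (!is.null(emb))
      parts <- c(parts, plotToImg(embPlot("decontX_contamination",
                                          "Contamination fraction")))
  }
  summ <- summarizeQC(cell, droplet)
  parts <- c(parts, "<h2>Summary</h2>", htmlTable(summ),
             "<h2>Parameters</h2>", provenanceTable(cell))
  writeLines(htmlPage("Cell QC report", paste(parts, collapse = "\n")),
             out_path)
  invisible(out_path)
}
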