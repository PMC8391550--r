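## Report bundle: figures (confusion heatmaps, ROC panels, metric bar charts
## with standard-error bars and significance brackets) and CSV tables.

utils::globalVariables(c("predicted", "truth", "value", "fpr", "tpr", "class",
                         "configuration", "mean_", "se_", "y", "yend", "x",
                         "xend", "label", "xa", "xb", "stars"))

confusionHeatmap <- function(report) {
  nm <- report@pooledConfusion$normalized
  df <- expand.grid(truth = rownames(nm), predicted = colnames(nm))
  df$value <- as.vector(nm)
  ggplot2::ggplot(df, ggplot2::aes(predicted, truth, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", value)), size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2C7BB6", limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(nm))) +
    ggplot2::labs(title = report@configuration, x = "predicted class",
                  y = "true class", fill = "row prop.") +
    ggplot2::theme_minimal(base_size = 9)
}

rocPanel <- function(report) {
  df <- do.call(rbind, lapply(names(report@roc), function(cl) {
    r <- report@roc[[cl]]
    data.frame(class = sprintf("%s (AUC %.3f)", cl, r$auc), fpr = r$fpr, tpr = r$tpr)
  }))
  ggplot2::ggplot(df, ggplot2::aes(fpr, tpr, color = class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, color = "grey60") +
    ggplot2::labs(title = report@configuration, x = "false positive rate",
                  y = "true positive rate") +
    ggplot2::theme_minimal(base_size = 9)
}

metricBarChart <- function(reports, metric, comparisons = NULL) {
  df <- do.call(rbind, lapply(reports, function(r) {
    s <- r@summary[r@summary$metric == metric, ]
    data.frame(configuration = r@configuration, class = s$class,
               mean_ = s$mean, se_ = s$se)
  }))
  df$class <- factor(df$class, levels = unique(df$class))
  p <- ggplot2::ggplot(df, ggplot2::aes(class, mean_, fill = configuration)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.85), width = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_ - se_, ymax = mean_ + se_),
                           position = ggplot2::position_dodge(width = 0.85),
                           width = 0.25, linewidth = 0.3) +
    ggplot2::labs(y = metric, x = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1.18)) +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(comparisons)) {
    sig <- comparisons[comparisons$stars != "" & !is.na(comparisons$p), , drop = FALSE]
    if (nrow(sig)) {
      configs <- vapply(reports, function(r) r@configuration, character(1))
      nC <- length(configs); dodge <- 0.85
      sig$xc <- match(sig$class, levels(df$class))
      sig$xa <- sig$xc + (match(sig$modelA, configs) - (nC + 1) / 2) * dodge / nC
      sig$xb <- sig$xc + (match(sig$modelB, configs) - (nC + 1) / 2) * dodge / nC
      sig$y <- 1.02 + 0.05 * (seq_len(nrow(sig)) %% 3)
      p <- p +
        ggplot2::geom_segment(data = sig, inherit.aes = FALSE, linewidth = 0.3,
                              ggplot2::aes(x = xa, xend = xb, y = y, yend = y)) +
        ggplot2::geom_text(data = sig, inherit.aes = FALSE, size = 3,
                           ggplot2::aes(x = (xa + xb) / 2, y = y + 0.02, label = stars))
    }
  }
  p
}

#' Render the full comparison report
#'
#' Writes, for a set of cross-validated model configurations: one confusion
#' heatmap and one ROC panel per configuration, grouped bar charts of
#' DSC/sensitivity/specificity with one-standard-error bars and paired
#' t-test significance brackets (* p < 0.05, ** p < 0.01), a summary table
#' CSV (per class, per model: mean, sd and standard error of each metric),
#' the pairwise t-test table, and a JSON metrics bundle.
#'
#' @param reports list of [CVReport-class] objects.
#' @param outDir output directory (created if missing).
#' @return named list of the file paths written, invisibly.
#' @export
renderReport <- function(reports, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  names(reports) <- vapply(reports, function(r) r@configuration, character(1))
  paths <- list()

  for (r in reports) {
    tag <- gsub("[^A-Za-z0-9]", "_", tolower(r@configuration))
    f1 <- file.path(outDir, sprintf("confusion_%s.png", tag))
    grDevices::png(f1, width = 900, height = 760, res = 150)
    print(confusionHeatmap(r)); grDevices::dev.off()
    f2 <- file.path(outDir, sprintf("roc_%s.png", tag))
    grDevices::png(f2, width = 1000, height = 760, res = 150)
    print(rocPanel(r)); grDevices::dev.off()
    paths[[sprintf("confusion_%s", tag)]] <- f1
    paths[[sprintf("roc_%s", tag)]] <- f2
  }

  # summary table: one row per (model, metric), one column per class
  tab <- do.call(rbind, lapply(reports, function(r) {
    s <- r@summary
    s$configuration <- r@configuration
    s
  }))
  wide <- do.call(rbind, lapply(split(tab, list(tab$configuration, tab$metric)),
    function(g) {
      row <- data.frame(configuration = g$configuration[1L], metric = g$metric[1L])
      for (i in seq_len(nrow(g)))
        row[[g$class[i]]] <- sprintf("%.3f ± %.3f", g$mean[i], g$sd[i])
      row
    }))
  wide <- wide[order(wide$metric, wide$configuration), ]
  fTab <- file.path(outDir, "summary_table.csv")
  write.csv(wide, fTab, row.names = FALSE)
  paths$summary_table <- fTab

  comparisons <- list()
  for (metric in c("dsc", "sensitivity", "specificity")) {
    cmp <- if (length(reports) > 1L) compareModels(reports, metric) else NULL
    comparisons[[metric]] <- cmp
    fBar <- file.path(outDir, sprintf("bars_%s.png", metric))
    grDevices::png(fBar, width = 1400, height = 700, res = 150)
    print(metricBarChart(reports, metric, cmp)); grDevices::dev.off()
    paths[[sprintf("bars_%s", metric)]] <- fBar
  }
  cmpAll <- do.call(rbind, comparisons)
  if (!is.null(cmpAll)) {
    fCmp <- file.path(outDir, "pairwise_tests.csv")
    write.csv(cmpAll, fCmp, row.names = FALSE)
    paths$pairwise_tests <- fCmp
  }

  bundle <- lapply(reports, function(r) list(
    configuration = r@configuration, seed = r@seed,
    nFolds = length(r@folds),
    pooledConfusionNormalized = unname(apply(r@pooledConfusion$normalized, 1L,
                                             function(x) round(unname(x), 6L),
                                             simplify = FALSE)),
    auc = lapply(r@roc, function(x) round(x$auc, 6L)),
    summary = r@summary))
  fJson <- file.path(outDir, "metrics.json")
  jsonlite::write_json(bundle, fJson, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$metrics_json <- fJson
  invisible(paths)
}
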