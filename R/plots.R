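#' Plot a group-mean connectivity matrix
#'
#' @param mat Square matrix (e.g. one entry of `results$group_mean_z`), or
#'   an `fc_conn` (its z matrix is drawn).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_connectivity_matrix <- function(mat, title = "Mean Fisher-z connectivity") {
  if (inherits(mat, "fc_conn")) mat <- mat$z
  nodes <- attr(mat, "nodes") %||% seq_len(nrow(mat))
  df <- expand.grid(i = seq_len(nrow(mat)), j = seq_len(ncol(mat)))
  df$z <- as.vector(mat)
  df$ch_i <- nodes[df$i]; df$ch_j <- nodes[df$j]
  ggplot(df, aes(x = .data$j, y = .data$i, fill = .data$z)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_viridis_c(name = "z") +
    coord_equal() +
    labs(title = title, x = "channel index", y = "channel index") +
    theme_minimal()
}

#' Plot edge counts across the threshold sweep by group
#'
#' @param results An `fc_results` object (or a tibble shaped like its
#'   `edge_profiles` entry).
#' @return A ggplot object.
#' @export
plot_edge_profile <- function(results) {
  df <- if (inherits(results, "fc_results")) results$edge_profiles else results
  ggplot(df, aes(x = .data$threshold, y = .data$n_edges,
                 colour = .data$group)) +
    geom_jitter(width = 0.005, height = 0, alpha = 0.6, size = 1) +
    stat_summary(fun = mean, geom = "line") +
    labs(x = "threshold", y = "number of edges", colour = NULL) +
    theme_minimal()
}

#' Plot global metric AUCs by group
#'
#' @param results An `fc_results` object.
#' @return A ggplot object (boxplots per metric, free scales).
#' @export
plot_global_auc <- function(results) {
  df <- if (inherits(results, "fc_results")) results$global_auc else results
  ggplot(df, aes(x = .data$group, y = .data$auc, fill = .data$group)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    geom_jitter(width = 0.1, height = 0, size = 0.8) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = "AUC over thresholds", fill = NULL) +
    theme_minimal()
}

#' Scatter plot of a nodal metric AUC against a CRS-R scale
#'
#' @param results An `fc_results` object.
#' @param clinical The cohort clinical table.
#' @param metric,region,scale Which region-averaged metric and CRS-R scale
#'   to draw (e.g. `"ncp"`, `"R_DLPFC"`, `"auditory"`).
#' @return A ggplot object.
#' @export
plot_crsr_scatter <- function(results, clinical, metric = "ncp",
                              region = "R_DLPFC", scale = "auditory") {
  vals <- results$nodal_roi_auc %>%
    filter(.data$metric == !!metric, .data$region == !!region,
           .data$group == "MCS")
  clin <- as_tibble(clinical)
  df <- left_join(vals, clin[, c("id", scale)], by = "id")
  ggplot(df, aes(x = .data[[scale]], y = .data$value)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    labs(x = paste("CRS-R", scale), y = paste(toupper(metric), region, "AUC")) +
    theme_minimal()
}

#' Default plots for pipeline results
#'
#' @param object An `fc_results` object.
#' @param which `"edges"`, `"auc"` or `"matrix"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot fc_results
#' @export
autoplot.fc_results <- function(object, which = c("edges", "auc", "matrix"),
                                ...) {
  which <- match.arg(which)
  switch(which,
         edges = plot_edge_profile(object),
         auc = plot_global_auc(object),
         matrix = plot_connectivity_matrix(object$group_mean_z[[1]]))
}

#' Render the standard report figures to files
#'
#' Writes the group-mean matrices, the edge-count profile, the global AUC
#' comparison, and (when patients and a significant nodal metric exist) the
#' CRS-R correlation scatter, as PNG files.
#'
#' @param results An `fc_results` object.
#' @param clinical The cohort clinical table.
#' @param dir Output directory.
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(results, clinical, dir, width = 6, height = 5,
                          dpi = 150) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  sv <- function(plot, name) {
    f <- file.path(dir, name)
    ggsave(f, plot, width = width, height = height, dpi = dpi)
    files <<- c(files, f)
  }
  for (g in names(results$group_mean_z)) {
    sv(plot_connectivity_matrix(results$group_mean_z[[g]],
                                title = paste("Mean z,", g)),
       sprintf("mean_matrix_%s.png", g))
  }
  sv(plot_edge_profile(results), "edge_profile.png")
  sv(plot_global_auc(results), "global_auc.png")
  sig <- results$nodal_comparison[results$nodal_comparison$significant, ]
  if (nrow(sig) > 0 && !is.null(results$correlations) &&
      nrow(results$correlations) > 0) {
    sv(plot_crsr_scatter(results, clinical, metric = sig$metric[1],
                         region = sig$region[1]),
       "crsr_scatter.png")
  }
  invisible(files)
}
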