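# internal: ggsave wrapper that renders .svg through grDevices (cairo)
save_figure <- function(path, plot, width, height) {
  if (grepl("\\.svg$", path)) {
    ggplot2::ggsave(path, plot, width = width, height = height,
                    device = grDevices::svg)
  } else {
    ggplot2::ggsave(path, plot, width = width, height = height)
  }
  invisible(path)
}

#' Cluster population shares
#'
#' Fraction of the sample assigned to each cluster, with a flag on clusters
#' whose share falls strictly below a minimum; excessively small shares
#' mark an inadequate solution regardless of model fit.
#'
#' @param partition Integer cluster labels.
#' @param flag_below Minimum adequate share, default 0.05.
#' @return Data frame with columns `cluster`, `count`, `share`, `flagged`;
#'   shares sum to 1.
#' @examples
#' population_shares(rep(c(1, 2), c(97, 3)))
#' @export
population_shares <- function(partition, flag_below = 0.05) {
  if (length(partition) == 0L) stop("empty partition")
  counts <- tabulate(partition, nbins = max(partition))
  keep <- counts > 0
  share <- counts / length(partition)
  data.frame(cluster = which(keep), count = counts[keep],
             share = share[keep], flagged = share[keep] < flag_below)
}

#' Discriminative power of each item for a partition
#'
#' For every item, the log ratio between the evidence that the item is
#' relevant for the clustering and the evidence that it is irrelevant,
#' given the best partition: the exact integrated multinomial marginal
#' likelihood of the item computed per cluster versus pooled, each under a
#' symmetric Dirichlet(1/2) prior and evaluated by log-Gamma sums. Larger
#' values mean the item separates the clusters more; an item independent of
#' the partition typically scores below 0.
#'
#' @param data An `lcca_data` object with no missing cells.
#' @param partition Integer cluster labels (at least 2 distinct clusters).
#' @param prior Dirichlet concentration, default 0.5.
#' @return Named numeric vector of per-item values. For a single-cluster
#'   partition the clustered and pooled marginals coincide, so every value
#'   is exactly 0.
#' @export
discriminative_power <- function(data, partition, prior = 0.5) {
  check_complete(data, "discriminative_power()")
  partition <- as.integer(partition)
  if (length(partition) != data$n) stop("`partition` must label every observation")
  log_marginal <- function(counts, a) {
    m <- length(counts)
    lgamma(m * a) - lgamma(sum(counts) + m * a) +
      sum(lgamma(counts + a) - lgamma(a))
  }
  out <- vapply(seq_len(data$J), function(j) {
    m_j <- data$n_categories[j]
    pooled <- tabulate(data$codes[, j], nbins = m_j)
    lm_clust <- sum(vapply(unique(partition), function(k) {
      log_marginal(tabulate(data$codes[partition == k, j], nbins = m_j), prior)
    }, 0))
    lm_clust - log_marginal(pooled, prior)
  }, 0)
  stats::setNames(out, data$item_names)
}

#' Combined criterion plot for cluster-number selection
#'
#' Two aligned panels over the class-count range: the BIC curve (with the
#' elbow candidate marked) and the ASW curve (defined from `K = 2`), with
#' vertical lines at the minimal-BIC and minimal-ICL class counts. This
#' plot, rather than any single criterion, is the primary instrument for
#' choosing candidate solutions.
#'
#' @param sel An `lcca_selection` object.
#' @param path Optional output path (`.png` or `.svg`); written with
#'   `ggplot2::ggsave` when given.
#' @param width,height Device size in inches.
#' @return The plot object (invisibly when `path` is given).
#' @export
selection_plot <- function(sel, path = NULL, width = 7, height = 6) {
  tab <- sel$table
  if (all(is.na(tab$bic))) stop("selection table has no successful fits")
  ks <- tab$K
  p_bic <- ggplot2::ggplot(tab, ggplot2::aes(x = K, y = bic)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = sel$best_bic_k, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = sel$best_icl_k, linetype = "dotdash") +
    ggplot2::scale_x_continuous(breaks = ks) +
    ggplot2::labs(y = "BIC", x = "number of clusters",
                  title = "BIC (dotted: min BIC, dot-dash: min ICL)") +
    ggplot2::theme_minimal()
  if (!is.na(sel$elbow_k))
    p_bic <- p_bic + ggplot2::geom_point(
      data = tab[tab$K == sel$elbow_k, , drop = FALSE],
      shape = 1, size = 4, colour = "red", na.rm = TRUE)
  p_asw <- ggplot2::ggplot(tab[tab$K >= 2, , drop = FALSE],
                           ggplot2::aes(x = K, y = asw)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = sel$best_bic_k, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = sel$best_icl_k, linetype = "dotdash") +
    ggplot2::scale_x_continuous(breaks = ks, limits = range(ks)) +
    ggplot2::labs(y = "ASW", x = "number of clusters",
                  title = "Average silhouette width") +
    ggplot2::theme_minimal()
  p <- patchwork::wrap_plots(p_bic, p_asw, ncol = 1)
  if (!is.null(path)) {
    save_figure(path, p, width, height)
    return(invisible(p))
  }
  p
}

#' Item-probability plot for a fitted solution
#'
#' Shows the class-conditional category probabilities `alpha_kjh` per item,
#' one panel per class. Classes are displayed in order of their mean item
#' score so that ordinal structure reads left to right.
#'
#' @param fit An `lcca_fit` object.
#' @param order_classes Order panels by mean item score (default `TRUE`).
#' @return A ggplot object.
#' @export
item_probability_plot <- function(fit, order_classes = TRUE) {
  model <- fit$model
  J <- length(model$item_probs[[1]])
  rows <- list()
  mean_score <- numeric(model$K)
  for (k in seq_len(model$K)) {
    sc <- 0
    for (j in seq_len(J)) {
      a <- model$item_probs[[k]][[j]]
      sc <- sc + sum(seq_along(a) * a)
      rows[[length(rows) + 1L]] <- data.frame(
        class = k, item = model$item_names[j], category = seq_along(a),
        probability = a)
    }
    mean_score[k] <- sc / J
  }
  df <- do.call(rbind, rows)
  ord <- if (order_classes) order(mean_score) else seq_len(model$K)
  df$class <- factor(df$class, levels = ord,
                     labels = paste0("class ", ord,
                                     " (share ", sprintf("%.2f", model$weights[ord]), ")"))
  ggplot2::ggplot(df, ggplot2::aes(x = category, y = probability,
                                   colour = item, group = item)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_x_continuous(breaks = sort(unique(df$category))) +
    ggplot2::labs(title = "Item probabilities by class",
                  y = "probability", x = "response category") +
    ggplot2::theme_minimal()
}

#' Silhouette plot for a partition
#'
#' Sorted per-observation silhouette widths grouped by cluster, with the
#' per-cluster mean in the strip label; negative bars indicate observations
#' closer to another cluster than to their own.
#'
#' @param data An `lcca_data` object with no missing cells.
#' @param partition Integer cluster labels.
#' @return A ggplot object.
#' @export
silhouette_plot <- function(data, partition) {
  s <- silhouette_widths(data, partition)
  df <- data.frame(cluster = partition, s = s)
  df <- df[order(df$cluster, -df$s), ]
  df$pos <- seq_len(nrow(df))
  means <- tapply(df$s, df$cluster, mean)
  df$cluster <- factor(df$cluster,
                       labels = sprintf("cluster %s (mean %.2f)",
                                        names(means), means))
  ggplot2::ggplot(df, ggplot2::aes(x = pos, y = s, fill = cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = mean(s), linetype = "dashed") +
    ggplot2::labs(title = sprintf("Silhouette plot (ASW = %.3f)", mean(s)),
                  x = NULL, y = "silhouette width") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Two-dimensional principal-component view of a partition
#'
#' Projects the one-hot (indicator) expansion of the categorical data onto
#' its first two principal components, coloured by cluster. Such
#' projections compress more than two dimensions of structure into the
#' plane and can be misleading; silhouette values are the more reliable
#' separation diagnostic, so the caveat is printed on the figure itself.
#'
#' @param data An `lcca_data` object with no missing cells.
#' @param partition Integer cluster labels.
#' @return A ggplot object.
#' @export
pca_plot <- function(data, partition) {
  check_complete(data, "pca_plot()")
  onehot <- do.call(cbind, lapply(seq_len(data$J), function(j) {
    m <- data$n_categories[j]
    out <- matrix(0, data$n, m)
    out[cbind(seq_len(data$n), data$codes[, j])] <- 1
    out
  }))
  pc <- stats::prcomp(onehot, center = TRUE, scale. = FALSE)
  df <- data.frame(PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                   cluster = factor(partition))
  ggplot2::ggplot(df, ggplot2::aes(x = PC1, y = PC2, colour = cluster)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(title = "Principal-component view of the clusters",
                  caption = paste("2-D projections of higher-dimensional data",
                                  "can be misleading; prefer silhouette values.")) +
    ggplot2::theme_minimal()
}

#' Write the standard post-selection figures for a fitted solution
#'
#' Produces the item-probability plot, the silhouette plot and the
#' principal-component view for a fit, writing them under a directory.
#'
#' @param data An `lcca_data` object with no missing cells.
#' @param fit An `lcca_fit` object fitted on `data`.
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"svg"`.
#' @return Named character vector of the files written.
#' @export
cluster_figures <- function(data, fit, dir, format = c("png", "svg")) {
  format <- match.arg(format)
  if (fit$n != data$n) stop("fit and data disagree on the number of observations")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    item_probabilities = file.path(dir, paste0("item_probabilities.", format)),
    silhouette = file.path(dir, paste0("silhouette.", format)),
    pca = file.path(dir, paste0("pca.", format)))
  save_figure(paths[["item_probabilities"]], item_probability_plot(fit), 8, 6)
  save_figure(paths[["silhouette"]], silhouette_plot(data, fit$partition), 8, 5)
  save_figure(paths[["pca"]], pca_plot(data, fit$partition), 7, 6)
  paths
}

#' Post-selection diagnostic report for a chosen solution
#'
#' Bundles the diagnostics consulted after candidate class counts are
#' shortlisted: population shares (with small-share flags), per-item
#' discriminative power, and per-observation silhouette widths; optionally
#' writes the standard figures.
#'
#' @param data An `lcca_data` object with no missing cells.
#' @param fit An `lcca_fit` for the chosen `K`.
#' @param flag_below Minimum adequate population share, default 0.05.
#' @param figure_dir Optional directory; when given, [cluster_figures()]
#'   is called and the paths recorded.
#' @param format Figure format, `"png"` or `"svg"`.
#' @return An object of class `lcca_report`: list with `K`, `shares`,
#'   `discriminative_power`, `silhouette`, `asw` and `figures`.
#' @export
cluster_report <- function(data, fit, flag_below = 0.05, figure_dir = NULL,
                           format = "png") {
  shares <- population_shares(fit$partition, flag_below = flag_below)
  dp <- discriminative_power(data, fit$partition)
  s <- silhouette_widths(data, fit$partition)
  figures <- if (!is.null(figure_dir))
    cluster_figures(data, fit, figure_dir, format = format) else character(0)
  structure(
    list(K = fit$K, shares = shares, discriminative_power = dp,
         silhouette = s, asw = mean(s), figures = figures),
    class = "lcca_report"
  )
}

#' @export
print.lcca_report <- function(x, ...) {
  cat("Cluster report for K =", x$K, "\n")
  cat("population shares:\n")
  print(x$shares, row.names = FALSE)
  cat(sprintf("ASW: %.3f\n", x$asw))
  cat("discriminative power (descending):\n")
  dp <- sort(x$discriminative_power, decreasing = TRUE)
  print(round(dp, 3))
  if (length(x$figures)) cat("figures:", paste(x$figures, collapse = ", "), "\n")
  invisible(x)
}
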