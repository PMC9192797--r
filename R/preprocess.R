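#' Summarise missingness in a categorical dataset
#'
#' Exact cell counts of missing values overall, per item and per row, plus
#' the indices of rows in which every item is missing (candidates for
#' removal before imputation).
#'
#' @param data An `lcca_data` object.
#' @return An object of class `missingness_report`: list with
#'   `overall_fraction`, `per_item_fraction` (named), `per_row_fraction`,
#'   `all_missing_rows`, `n_missing_cells` and `n_cells`.
#' @export
missingness_summary <- function(data) {
  miss <- is.na(data$codes)
  per_item <- colSums(miss)
  per_row <- rowSums(miss)
  structure(
    list(overall_fraction = sum(miss) / (data$n * data$J),
         per_item_fraction = stats::setNames(per_item / data$n, data$item_names),
         per_row_fraction = per_row / data$J,
         all_missing_rows = which(per_row == data$J),
         n_missing_cells = sum(miss),
         n_cells = data$n * data$J),
    class = "missingness_report"
  )
}

#' @export
print.missingness_report <- function(x, ...) {
  cat(sprintf("Missing cells: %d of %d (%.4f of the dataset)\n",
              x$n_missing_cells, x$n_cells, x$overall_fraction))
  cat(length(x$all_missing_rows), "rows with 100% missing items\n")
  invisible(x)
}

#' Drop rows in which every item is missing
#'
#' @param data An `lcca_data` object.
#' @return List with `data` (rows removed, original order preserved),
#'   `dropped` (count) and `dropped_rows` (original indices).
#' @export
drop_empty_rows <- function(data) {
  empty <- which(rowSums(is.na(data$codes)) == data$J)
  if (length(empty) == 0L)
    return(list(data = data, dropped = 0L, dropped_rows = integer(0)))
  keep <- setdiff(seq_len(data$n), empty)
  out <- data
  out$codes <- data$codes[keep, , drop = FALSE]
  out$n <- length(keep)
  list(data = out, dropped = length(empty), dropped_rows = empty)
}

#' One-way intraclass correlation coefficient for a grouped variable
#'
#' ICC(1) from a one-way random-effects ANOVA:
#' `(MSB - MSW) / (MSB + (nbar - 1) * MSW)` with `nbar` the average group
#' size; negative estimates are clipped to 0. Used as a multilevel screen:
#' ordinal item codes are treated as numeric scores, and small values
#' (conventionally below ~0.05-0.10) indicate that single-level clustering
#' is defensible.
#'
#' @param values Numeric (or integer-coded) observations; missing values
#'   are dropped pairwise with their group labels.
#' @param group_labels Grouping factor (e.g. school); at least 2 groups.
#' @return ICC in `[0, 1]`.
#' @examples
#' icc_per_variable(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
#' @export
icc_per_variable <- function(values, group_labels) {
  keep <- !is.na(values) & !is.na(group_labels)
  values <- as.numeric(values[keep])
  g <- factor(group_labels[keep])
  if (nlevels(g) < 2L) stop("need at least 2 groups for an ICC")
  if (length(values) <= nlevels(g)) stop("need replication within groups")
  # warnings about exact fits are irrelevant here: only mean squares are used
  ms <- suppressWarnings(anova(stats::lm(values ~ g))[["Mean Sq"]])
  msb <- ms[1]
  msw <- ms[2]
  nbar <- length(values) / nlevels(g)
  if (msb + (nbar - 1) * msw == 0) return(0)
  max(0, (msb - msw) / (msb + (nbar - 1) * msw))
}

#' Multilevel screen across all items of a dataset
#'
#' Computes [icc_per_variable()] for every item against a grouping label
#' and warns when any ICC exceeds an advisory ceiling, above which a
#' multilevel model (out of scope here) should be considered.
#'
#' @param data An `lcca_data` object.
#' @param group_labels Group label per observation.
#' @param ceiling Advisory ICC ceiling, default 0.10.
#' @return Named numeric vector of per-item ICCs.
#' @export
icc_screen <- function(data, group_labels, ceiling = 0.10) {
  iccs <- vapply(seq_len(data$J), function(j)
    icc_per_variable(data$codes[, j], group_labels), 0)
  names(iccs) <- data$item_names
  if (any(iccs > ceiling))
    warning("ICC above ", ceiling, " for: ",
            paste(names(iccs)[iccs > ceiling], collapse = ", "),
            "; consider a multilevel model")
  iccs
}

#' Impute missing categories by chained tree ensembles
#'
#' Iterative chained imputation: missing cells are initialised at the item
#' mode, then each incomplete item in turn is predicted from all other
#' items by a random-forest classifier fitted on the rows where the item is
#' observed, cycling until the imputed assignments stabilise or a cap of
#' `max_cycles` cycles is reached. Observed cells are never altered, every
#' imputed code lies in `1..m_j`, and the result is deterministic given the
#' seed.
#'
#' @param data An `lcca_data` object without all-missing rows (run
#'   [drop_empty_rows()] first) or all-missing items.
#' @param seed Integer seed.
#' @param max_cycles Cycle cap, default 10.
#' @param num_trees Trees per forest, default 100.
#' @return A complete `lcca_data` object.
#' @export
impute_missing <- function(data, seed = 1L, max_cycles = 10, num_trees = 100) {
  miss <- is.na(data$codes)
  if (!any(miss)) return(data)
  if (any(rowSums(miss) == data$J))
    stop("all-missing rows present; run drop_empty_rows() first")
  n_obs_item <- colSums(!miss)
  if (any(n_obs_item == 0L))
    stop("item with zero observed cells: ",
         paste(data$item_names[n_obs_item == 0L], collapse = ", "))

  codes <- data$codes
  # mode initialisation
  for (j in which(colSums(miss) > 0L)) {
    tab <- tabulate(codes[!miss[, j], j], nbins = data$n_categories[j])
    codes[miss[, j], j] <- which.max(tab)
  }
  items <- order(colSums(miss))
  items <- items[colSums(miss)[items] > 0L]
  set.seed(seed)
  forest_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, max_cycles * length(items)),
    max_cycles, length(items))
  for (cycle in seq_len(max_cycles)) {
    prev <- codes[miss]
    for (ii in seq_along(items)) {
      j <- items[ii]
      df <- as.data.frame(lapply(seq_len(data$J), function(jj)
        factor(codes[, jj], levels = seq_len(data$n_categories[jj]))))
      names(df) <- paste0("v", seq_len(data$J))
      train <- df[!miss[, j], -j, drop = FALSE]
      train$.resp <- df[!miss[, j], j, drop = TRUE]
      rf <- ranger::ranger(
        dependent.variable.name = ".resp", data = train,
        num.trees = num_trees, seed = forest_seeds[cycle, ii],
        num.threads = 1, respect.unordered.factors = "order",
        verbose = FALSE)
      pred <- stats::predict(rf, data = df[miss[, j], -j, drop = FALSE],
                             num.threads = 1)$predictions
      codes[miss[, j], j] <- as.integer(as.character(pred))
    }
    if (identical(codes[miss], prev)) break
  }
  out <- data
  out$codes <- codes
  out
}

#' Category frequencies per item
#'
#' Exact counts and proportions of each response category for every item
#' (proportions over non-missing cells; missing tallied separately), with a
#' flag on categories whose proportion falls below a threshold. Intended to
#' support decisions such as whether extreme response options are
#' underrepresented enough to justify merging categories.
#'
#' @param data An `lcca_data` object.
#' @param flag_below Proportion threshold for flagging, default 0.05.
#' @return A data frame with columns `item`, `category`, `label`, `count`,
#'   `proportion`, `flagged`, plus a `missing` attribute holding per-item
#'   missing counts.
#' @export
category_frequencies <- function(data, flag_below = 0.05) {
  rows <- lapply(seq_len(data$J), function(j) {
    obs <- data$codes[!is.na(data$codes[, j]), j]
    cnt <- tabulate(obs, nbins = data$n_categories[j])
    data.frame(item = data$item_names[j],
               category = seq_len(data$n_categories[j]),
               label = data$levels[[j]],
               count = cnt,
               proportion = if (length(obs)) cnt / length(obs) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- !is.na(out$proportion) & out$proportion < flag_below
  attr(out, "missing") <- stats::setNames(colSums(is.na(data$codes)),
                                          data$item_names)
  out
}

#' Missingness overview plot
#'
#' Per-item missing fractions as a bar panel next to the counts of the most
#' frequent missingness patterns, in the style of aggregation plots used to
#' eyeball whether missingness concentrates in particular items or row
#' patterns.
#'
#' @param data An `lcca_data` object.
#' @param max_patterns Number of most frequent patterns to show, default 10.
#' @return A patchwork/ggplot object.
#' @export
missingness_plot <- function(data, max_patterns = 10) {
  rep_ <- missingness_summary(data)
  item_df <- data.frame(item = factor(data$item_names, levels = data$item_names),
                        fraction = as.numeric(rep_$per_item_fraction))
  p1 <- ggplot2::ggplot(item_df, ggplot2::aes(x = item, y = fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(y = "fraction missing", x = NULL,
                  title = "Missingness per item") +
    ggplot2::theme_minimal()
  pat <- apply(is.na(data$codes), 1, function(r)
    paste(ifelse(r, "x", "."), collapse = ""))
  tp <- sort(table(pat), decreasing = TRUE)
  tp <- tp[seq_len(min(max_patterns, length(tp)))]
  pat_df <- data.frame(pattern = factor(names(tp), levels = rev(names(tp))),
                       count = as.integer(tp))
  p2 <- ggplot2::ggplot(pat_df, ggplot2::aes(x = count, y = pattern)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "rows", y = NULL,
                  title = "Most frequent missingness patterns") +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p1, p2)
}
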