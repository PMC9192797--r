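#' Encode a table of categorical observations for latent class analysis
#'
#' Converts a rectangular table of categorical or ordinal responses (rows =
#' observations, columns = items) into the integer-coded representation used
#' throughout the package. Each item's levels are mapped to codes
#' `1..m_j`; empty cells, `NA` and the string `"NA"` are treated as missing.
#'
#' @param x A data frame or matrix. Columns may hold integer codes, factors
#'   or character labels; each column must have at least 2 and at most 15
#'   distinct non-missing levels.
#' @param category_order Optional named list giving, for some or all items,
#'   the level labels in the order that should receive codes `1, 2, ...`
#'   (e.g. a Likert order from *strongly agree* to *strongly disagree*).
#'   Items not listed are coded in sorted level order.
#' @param item_names Optional character vector of item names; defaults to
#'   the column names of `x`.
#'
#' @return An object of class `lcca_data`: a list with elements
#'   \describe{
#'     \item{codes}{integer matrix `n x J`, `NA` where missing}
#'     \item{n_categories}{integer vector `m_1..m_J`}
#'     \item{levels}{list of the original level labels per item, in code order}
#'     \item{item_names}{character vector of length `J`}
#'     \item{n, J}{dimensions}
#'   }
#'
#' @examples
#' tab <- data.frame(a = c("agree", "disagree"), b = c(1L, 2L))
#' d <- lcca_data(tab)
#' d$codes
#' @export
lcca_data <- function(x, category_order = NULL, item_names = NULL) {
  if (is.matrix(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.data.frame(x)) stop("`x` must be a data frame or matrix")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("`x` must have at least one row and one column")
  J <- ncol(x)
  if (is.null(item_names)) item_names <- colnames(x)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(J))
  if (length(item_names) != J) stop("`item_names` must have one entry per column")

  codes <- matrix(NA_integer_, nrow(x), J)
  lvls <- vector("list", J)
  for (j in seq_len(J)) {
    col <- x[[j]]
    if (is.factor(col)) col <- as.character(col)
    miss <- is.na(col) | (is.character(col) & (trimws(as.character(col)) == "" |
                                                 trimws(as.character(col)) == "NA"))
    obs <- col[!miss]
    lev <- sort(unique(as.character(obs)), method = "radix")
    if (is.numeric(col)) {
      lev_num <- sort(unique(obs))
      lev <- as.character(lev_num)
    }
    if (length(lev) < 2L)
      stop("column '", item_names[j], "' has fewer than 2 distinct levels (degenerate item)")
    if (length(lev) > 15L)
      stop("column '", item_names[j], "' has more than 15 distinct levels; not categorical?")
    ord <- category_order[[item_names[j]]]
    if (!is.null(ord)) {
      ord <- as.character(ord)
      if (!setequal(ord, lev))
        stop("category_order for '", item_names[j],
             "' does not match the observed levels")
      lev <- ord
    }
    codes[!miss, j] <- match(as.character(obs), lev)
    lvls[[j]] <- lev
  }
  structure(
    list(codes = codes, n_categories = vapply(lvls, length, 1L),
         levels = lvls, item_names = item_names,
         n = nrow(x), J = J),
    class = "lcca_data"
  )
}

#' Construct an `lcca_data` object directly from integer codes
#'
#' Lower-level constructor used by the simulator and tests; skips label
#' mapping. Codes must lie in `1..m_j` or be `NA`.
#'
#' @param codes Integer matrix (`NA` = missing).
#' @param n_categories Integer vector of category counts per item; defaults
#'   to the observed column maxima.
#' @param item_names Optional item names.
#' @return An `lcca_data` object.
#' @export
lcca_data_from_codes <- function(codes, n_categories = NULL, item_names = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  J <- ncol(codes)
  if (is.null(n_categories)) {
    n_categories <- apply(codes, 2, function(v) max(v, na.rm = TRUE))
  }
  n_categories <- as.integer(n_categories)
  if (length(n_categories) != J) stop("`n_categories` must have one entry per item")
  if (any(n_categories < 2L)) stop("every item needs at least 2 categories")
  for (j in seq_len(J)) {
    v <- codes[, j]
    bad <- !is.na(v) & (v < 1L | v > n_categories[j])
    if (any(bad)) stop("codes for item ", j, " outside 1..", n_categories[j])
  }
  if (is.null(item_names)) item_names <- colnames(codes)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(J))
  structure(
    list(codes = codes,
         n_categories = n_categories,
         levels = lapply(n_categories, function(m) as.character(seq_len(m))),
         item_names = item_names, n = nrow(codes), J = J),
    class = "lcca_data"
  )
}

#' Decode an `lcca_data` object back to its original labels
#'
#' Inverse of [lcca_data()]: returns a data frame with the original level
#' labels (numeric columns are restored to numeric) and `NA` for missing
#' cells.
#'
#' @param x An `lcca_data` object.
#' @param row.names,optional,... Passed for S3 compatibility; ignored.
#' @return A data frame with `n` rows and `J` columns.
#' @export
as.data.frame.lcca_data <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- vector("list", x$J)
  for (j in seq_len(x$J)) {
    lab <- x$levels[[j]][x$codes[, j]]
    num <- suppressWarnings(as.numeric(x$levels[[j]]))
    if (!anyNA(num)) lab <- num[x$codes[, j]]
    out[[j]] <- lab
  }
  names(out) <- x$item_names
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @export
print.lcca_data <- function(x, ...) {
  cat("Categorical dataset:", x$n, "observations x", x$J, "items\n")
  cat("categories per item:", paste(x$n_categories, collapse = ", "), "\n")
  nm <- sum(is.na(x$codes))
  cat(sprintf("missing cells: %d (%.3f of the table)\n", nm, nm / (x$n * x$J)))
  invisible(x)
}

#' Read a categorical dataset from a delimited text file
#'
#' Reads a CSV with a header row (integer codes or string levels; missing =
#' empty cell or `NA`) and encodes it with [lcca_data()].
#'
#' @param path File path.
#' @param category_order Passed to [lcca_data()].
#' @param sep Field separator, default comma.
#' @return An `lcca_data` object.
#' @export
read_lcca_csv <- function(path, category_order = NULL, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"),
                           check.names = FALSE)
  lcca_data(raw, category_order = category_order)
}

# internal: stop unless data has no missing cells
check_complete <- function(data, what = "this operation") {
  if (anyNA(data$codes))
    stop("missing values present; ", what,
         " requires complete data (impute first, see impute_missing())")
  invisible(TRUE)
}

# internal: validate that a model matches a dataset's item structure
check_model_data <- function(model, data) {
  if (length(model$item_probs[[1]]) != data$J ||
      !identical(as.integer(vapply(model$item_probs[[1]], length, 1L)),
                 as.integer(data$n_categories)))
    stop("model item structure does not match the dataset's category counts")
  invisible(TRUE)
}
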