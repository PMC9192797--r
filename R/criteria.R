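#' Number of free parameters of a latent class model
#'
#' `nu = (K - 1) + K * sum_j (m_j - 1)`: mixture weights plus one
#' multinomial per class and item.
#'
#' @param K Number of classes.
#' @param n_categories Integer vector `m_1..m_J` (all at least 2).
#' @return The parameter count `nu`.
#' @export
n_free_params <- function(K, n_categories) {
  if (K < 1) stop("`K` must be at least 1")
  if (any(n_categories < 2)) stop("every item needs at least 2 categories")
  (K - 1) + K * sum(n_categories - 1)
}

#' Bayesian Information Criterion (deviance scale)
#'
#' `BIC = -2 * loglik + nu * log(n)`; smaller is better.
#'
#' @param loglik Maximised log-likelihood.
#' @param nu Free-parameter count (see [n_free_params()]).
#' @param n Number of observations.
#' @return The BIC value.
#' @export
bic <- function(loglik, nu, n) {
  if (n < 1) stop("`n` must be at least 1")
  -2 * loglik + nu * log(n)
}

#' Entropy of a responsibility matrix
#'
#' `EN = -sum_ik tau_ik log tau_ik` with `0 log 0 = 0`; zero for a fully
#' deterministic (one-hot) classification, and larger the more the classes
#' overlap.
#'
#' @param tau Responsibility matrix with normalised rows.
#' @return Non-negative entropy.
#' @export
responsibilities_entropy <- function(tau) {
  tau <- as.matrix(tau)
  tl <- tau * log(tau)
  tl[tau == 0] <- 0
  -sum(tl)
}

#' Integrated Completed Likelihood criterion (deviance scale)
#'
#' `ICL = BIC + 2 * EN`: the BIC plus an entropy penalty on the
#' responsibilities, so poorly separated solutions are penalised. Smaller
#' is better; `ICL >= BIC` always.
#'
#' @param bic_value BIC on the deviance scale.
#' @param entropy_value Responsibility entropy (non-negative).
#' @return The ICL value.
#' @export
icl <- function(bic_value, entropy_value) {
  if (entropy_value < 0) stop("entropy must be non-negative")
  bic_value + 2 * entropy_value
}

#' Simple-matching (normalised Hamming) dissimilarity between two observations
#'
#' The proportion of items on which two category-code vectors disagree;
#' ranges over `[0, 1]`, is symmetric and zero on identical vectors.
#'
#' @param obs_i,obs_j Equal-length vectors of category codes, no missing.
#' @return Dissimilarity in `[0, 1]`.
#' @export
hamming_dissimilarity <- function(obs_i, obs_j) {
  if (length(obs_i) != length(obs_j)) stop("vectors must have equal length")
  if (anyNA(obs_i) || anyNA(obs_j)) stop("missing codes not allowed")
  mean(obs_i != obs_j)
}

#' Per-observation silhouette widths on the simple-matching dissimilarity
#'
#' For observation `i` in cluster `c`, `a(i)` is its mean dissimilarity to
#' the other members of `c` and `b(i)` the smallest mean dissimilarity to
#' any other cluster; `s(i) = (b - a) / max(a, b)`. Members of singleton
#' clusters get `s(i) = 0`. Computed from per-cluster category counts in
#' `O(nJK)` rather than from the full pairwise matrix.
#'
#' @param data An `lcca_data` object with no missing cells.
#' @param partition Integer cluster labels, at least 2 non-empty clusters.
#' @return Numeric vector of silhouette values in `[-1, 1]`.
#' @export
silhouette_widths <- function(data, partition) {
  check_complete(data, "silhouette computation")
  partition <- as.integer(partition)
  if (length(partition) != data$n) stop("`partition` must label every observation")
  sizes <- tabulate(partition)
  labs <- which(sizes > 0)
  if (length(labs) < 2L) stop("silhouette undefined for a single cluster")
  K <- max(partition)
  n <- data$n
  # S[i, c] = sum of dissimilarities from i to all members of cluster c
  S <- matrix(0, n, K)
  for (j in seq_len(data$J)) {
    cnt <- matrix(0, data$n_categories[j], K)
    tab <- table(factor(data$codes[, j], levels = seq_len(data$n_categories[j])),
                 factor(partition, levels = seq_len(K)))
    cnt[] <- tab
    S <- S + matrix(sizes[seq_len(K)], n, K, byrow = TRUE) -
      cnt[data$codes[, j], , drop = FALSE]
  }
  S <- S / data$J
  own <- S[cbind(seq_len(n), partition)]
  a <- own / pmax(sizes[partition] - 1, 1)
  Smean <- sweep(S, 2, pmax(sizes[seq_len(K)], 1), "/")
  Smean[, sizes[seq_len(K)] == 0] <- Inf
  Smean[cbind(seq_len(n), partition)] <- Inf
  b <- apply(Smean, 1, min)
  s <- (b - a) / pmax(a, b)
  s[!is.finite(s)] <- 0          # a = b = 0: coincident points across clusters
  s[sizes[partition] == 1L] <- 0
  s
}

#' Average silhouette width of a partition
#'
#' Mean of [silhouette_widths()] over all observations; lies in `[-1, 1]`,
#' with larger values indicating better-separated clusters. Undefined for a
#' single cluster (an error is raised; cluster-number tables leave the cell
#' empty at `K = 1`).
#'
#' @inheritParams silhouette_widths
#' @return The ASW value.
#' @export
average_silhouette_width <- function(data, partition) {
  mean(silhouette_widths(data, partition))
}

#' Elbow candidate of a criterion curve
#'
#' Formalises the visual elbow heuristic: the elbow is the interior `K`
#' where the curve flattens, i.e. where the drop-off in successive
#' improvements, `(BIC(K-1) - BIC(K)) - (BIC(K) - BIC(K+1))`, is largest
#' *relative to the improvement that remains*. The score is the second
#' forward difference divided by the magnitude of the following
#' improvement, which makes the heuristic scale-free: an unscaled second
#' difference is dominated by the (always steep) first drops of a BIC
#' curve, while the visual elbow sits where further classes stop paying.
#' Ties go to the smallest `K`. Advisory only: the criterion plot remains
#' the primary instrument.
#'
#' @param bic_by_k Numeric criterion values over consecutive class counts
#'   (at least 3).
#' @param k Class counts the values belong to; defaults to `1..length`.
#' @return The elbow candidate `K`.
#' @examples
#' elbow_candidate(c(100, 80, 40, 38, 37))   # flattens after K = 3
#' @export
elbow_candidate <- function(bic_by_k, k = seq_along(bic_by_k)) {
  if (length(bic_by_k) < 3L) stop("need at least 3 criterion values")
  if (length(k) != length(bic_by_k)) stop("`k` must match `bic_by_k`")
  d <- -diff(bic_by_k)                       # improvement entering each K
  eps <- 1e-8 * max(abs(d), 1e-12)
  score <- (d[-length(d)] - d[-1]) / pmax(abs(d[-1]), eps)
  k[1L + which.max(score)]
}

#' Model-fit and separation criteria across a range of class counts
#'
#' Fits a latent class model for each `K` in `k_min..k_max` and tabulates
#' the log-likelihood, free-parameter count, BIC, responsibility entropy,
#' ICL and average silhouette width of the MAP partition (left empty at
#' `K = 1`, where a silhouette is undefined). Also records the
#' argmin-BIC and argmin-ICL class counts and the elbow candidate of the
#' BIC curve.
#'
#' @param data An `lcca_data` object with no missing cells.
#' @param k_min,k_max Range of class counts, default 1 to 10.
#' @param restarts,tol,max_iter Passed to [fit_em()].
#' @param seed Integer seed; each `K` receives its own derived substream.
#' @param keep_fits Keep the per-`K` `lcca_fit` objects in the result
#'   (default `TRUE`; needed by the reporting functions).
#' @return An object of class `lcca_selection`: list with `table` (a data
#'   frame with columns `K, loglik, nu, bic, entropy, icl, asw`),
#'   `best_bic_k`, `best_icl_k`, `best_asw_k`, `elbow_k`, `seed` and
#'   (optionally) `fits`. A `K` whose fit fails is kept as a row of `NA`s
#'   rather than aborting the table.
#' @examples
#' d <- simulate_ordinal_clusters(simulation_spec(K = 2, n_total = 300, seed = 3))
#' sel <- selection_table(d$data, k_min = 1, k_max = 3, restarts = 3, seed = 1)
#' sel$table
#' @export
selection_table <- function(data, k_min = 1, k_max = 10, restarts = 20,
                            seed = 1L, tol = 1e-6, max_iter = 1000,
                            keep_fits = TRUE) {
  check_complete(data, "selection_table()")
  if (k_min < 1 || k_max < k_min) stop("need 1 <= k_min <= k_max")
  if (k_max > data$n) stop("`k_max` cannot exceed the number of observations")
  ks <- seq.int(k_min, k_max)
  set.seed(seed)
  k_seeds <- sample.int(.Machine$integer.max - 1L, length(ks))
  nu <- vapply(ks, n_free_params, 0, n_categories = data$n_categories)
  tab <- data.frame(K = ks, loglik = NA_real_, nu = nu, bic = NA_real_,
                    entropy = NA_real_, icl = NA_real_, asw = NA_real_)
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    fit <- tryCatch(
      fit_em(data, K = ks[i], restarts = restarts, seed = k_seeds[i],
             tol = tol, max_iter = max_iter),
      error = function(e) {
        warning("fit failed for K = ", ks[i], ": ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) next
    fits[[i]] <- fit
    en <- responsibilities_entropy(fit$responsibilities)
    tab$loglik[i] <- fit$loglik
    tab$bic[i] <- bic(fit$loglik, nu[i], data$n)
    tab$entropy[i] <- en
    tab$icl[i] <- icl(tab$bic[i], en)
    if (ks[i] >= 2L && length(unique(fit$partition)) >= 2L)
      tab$asw[i] <- average_silhouette_width(data, fit$partition)
  }
  ok <- !is.na(tab$bic)
  elbow_k <- if (sum(ok) >= 3L && all(diff(which(ok)) == 1L))
    elbow_candidate(tab$bic[ok], k = tab$K[ok]) else NA_integer_
  structure(
    list(table = tab,
         best_bic_k = if (any(ok)) tab$K[which.min(tab$bic)] else NA_integer_,
         best_icl_k = if (any(ok)) tab$K[which.min(tab$icl)] else NA_integer_,
         best_asw_k = if (any(!is.na(tab$asw)))
           tab$K[which.max(tab$asw)] else NA_integer_,
         elbow_k = elbow_k,
         seed = seed,
         fits = if (keep_fits) fits else NULL),
    class = "lcca_selection"
  )
}

#' @export
print.lcca_selection <- function(x, ...) {
  cat("Cluster-number selection table\n")
  print(format(x$table, digits = 6), row.names = FALSE)
  cat(sprintf("minimal BIC at K = %s; minimal ICL at K = %s; max ASW at K = %s; BIC elbow at K = %s\n",
              x$best_bic_k, x$best_icl_k, x$best_asw_k, x$elbow_k))
  invisible(x)
}

#' Export a selection table to CSV
#'
#' @param sel An `lcca_selection` object.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_selection_csv <- function(sel, path) {
  utils::write.csv(sel$table, path, row.names = FALSE)
  invisible(path)
}

#' Export a selection table to JSON
#'
#' Writes the per-`K` criteria together with the argmin-BIC, argmin-ICL,
#' max-ASW and elbow class counts.
#'
#' @param sel An `lcca_selection` object.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_selection_json <- function(sel, path) {
  jsonlite::write_json(
    list(table = sel$table, best_bic_k = sel$best_bic_k,
         best_icl_k = sel$best_icl_k, best_asw_k = sel$best_asw_k,
         elbow_k = sel$elbow_k, seed = sel$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
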