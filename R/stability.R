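#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement, chance-corrected: 1 iff the partitions are
#' identical up to relabelling, about 0 for independent partitions, and
#' possibly negative for systematic disagreement. Computed from the
#' contingency table of the two labelings.
#'
#' @param z1,z2 Equal-length label vectors (length at least 2).
#' @return The ARI (at most 1).
#' @export
adjusted_rand_index <- function(z1, z2) {
  if (length(z1) != length(z2)) stop("partitions must have equal length")
  n <- length(z1)
  if (n < 2L) stop("need at least 2 observations")
  tab <- table(z1, z2)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)        # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Jaccard coefficient between two partitions
#'
#' Over all pairs of observations, the number of pairs co-clustered in both
#' partitions divided by the number co-clustered in at least one:
#' `J = n11 / (n11 + n10 + n01)`. Equals 1 iff the partitions are identical
#' up to relabelling; by convention `J = 1` when no pair is co-clustered in
#' either partition.
#'
#' @inheritParams adjusted_rand_index
#' @return The Jaccard coefficient in `[0, 1]`.
#' @export
jaccard_partition_coefficient <- function(z1, z2) {
  if (length(z1) != length(z2)) stop("partitions must have equal length")
  if (length(z1) < 2L) stop("need at least 2 observations")
  tab <- table(z1, z2)
  n11 <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))          # co-clustered in z1
  b <- sum(choose(colSums(tab), 2))          # co-clustered in z2
  denom <- a + b - n11
  if (denom == 0) return(1)
  n11 / denom
}

#' Bootstrap stability assessment of a cluster solution
#'
#' Judges whether a `K`-class solution generalises beyond the sample at
#' hand: a reference model is fitted on the full data, then for each of `B`
#' bootstrap replicates the rows are resampled with replacement, a fresh
#' `K`-class model is fitted on the resample, every *original* observation
#' is classified under the replicate model, and the resulting partition is
#' compared with the reference partition by the adjusted Rand index and the
#' Jaccard coefficient. High means (near 1) indicate a stable solution.
#'
#' @param data An `lcca_data` object with no missing cells.
#' @param K Number of classes (`K >= 2`).
#' @param B Number of bootstrap replicates, default 100.
#' @param seed Integer seed; the reference fit, the resampling and every
#'   replicate fit draw from substreams derived from it.
#' @param restarts Restarts for the reference fit (default 20).
#' @param replicate_restarts Random restarts for each replicate fit;
#'   defaults to `max(5, restarts %/% 4)` for tractability. Every
#'   replicate additionally tries an EM run warm-started from the
#'   reference model and keeps whichever solution has the higher
#'   likelihood, so a poor random restart cannot masquerade as
#'   instability.
#' @param tol,max_iter Passed to [fit_em()].
#' @param classify_smoothing Weight of the uniform distribution mixed into
#'   each replicate model's item probabilities before the full sample is
#'   classified (default 1e-3). A resample can miss every carrier of a rare
#'   category, leaving that category's fitted probability at the numerical
#'   floor; without this step a single such cell would dominate the class
#'   log-odds and flip rare response patterns between replicates, which is
#'   resampling-noise artefact rather than instability of the solution.
#' @return An object of class `lcca_stability`: list with `K`, `B`,
#'   `ari_values`, `jaccard_values` (length `B` each), `ari_mean`,
#'   `jaccard_mean`, `reference_fit` and `seed`.
#' @examples
#' d <- simulate_ordinal_clusters(simulation_spec(K = 2, n_total = 200, seed = 5))
#' st <- bootstrap_stability(d$data, K = 2, B = 5, seed = 1, restarts = 4)
#' st$ari_mean
#' @export
bootstrap_stability <- function(data, K, B = 100, seed = 1L, restarts = 20,
                                replicate_restarts = max(5, restarts %/% 4),
                                tol = 1e-6, max_iter = 1000,
                                classify_smoothing = 1e-3) {
  check_complete(data, "bootstrap_stability()")
  if (K < 2L) stop("stability assessment needs K >= 2")
  if (B < 1L) stop("`B` must be at least 1")
  set.seed(seed)
  ref_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  draw_seeds <- sample.int(.Machine$integer.max - 1L, B)
  fit_seeds <- sample.int(.Machine$integer.max - 1L, B)

  ref_fit <- fit_em(data, K = K, restarts = restarts, seed = ref_seed,
                    tol = tol, max_iter = max_iter)
  z_ref <- ref_fit$partition

  ari <- numeric(B)
  jac <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(draw_seeds[b])
    idx <- sample.int(data$n, data$n, replace = TRUE)
    boot <- lcca_data_from_codes(data$codes[idx, , drop = FALSE],
                                 n_categories = data$n_categories,
                                 item_names = data$item_names)
    rep_fit <- tryCatch(
      fit_em(boot, K = K, restarts = replicate_restarts, seed = fit_seeds[b],
             tol = tol, max_iter = max_iter),
      error = function(e) stop("replicate ", b, " failed to fit: ",
                               conditionMessage(e)))
    # the reference parameters are one more candidate start: with few
    # random restarts a replicate can land in a poor local optimum, which
    # would read as instability when it is only an optimisation failure
    warm <- tryCatch(
      fit_em_warm(boot, ref_fit$model, tol = tol, max_iter = max_iter),
      lcca_degenerate_class = function(e) NULL, error = function(e) NULL)
    if (!is.null(warm) && warm$loglik > rep_fit$loglik) rep_fit <- warm
    z_b <- map_partition(e_step(uniform_mix(rep_fit$model, classify_smoothing),
                                data))
    ari[b] <- adjusted_rand_index(z_ref, z_b)
    jac[b] <- jaccard_partition_coefficient(z_ref, z_b)
  }
  structure(
    list(K = K, B = B, ari_values = ari, jaccard_values = jac,
         ari_mean = mean(ari), jaccard_mean = mean(jac),
         reference_fit = ref_fit, seed = seed),
    class = "lcca_stability"
  )
}

# internal: mix every item-probability vector with a uniform distribution
uniform_mix <- function(model, lambda) {
  if (lambda <= 0) return(model)
  ip <- lapply(model$item_probs, function(cl)
    lapply(cl, function(a) (1 - lambda) * a + lambda / length(a)))
  lcca_model(model$weights, ip, item_names = model$item_names)
}

#' @export
print.lcca_stability <- function(x, ...) {
  cat(sprintf("Bootstrap stability for K = %d (%d replicates)\n", x$K, x$B))
  cat(sprintf("mean ARI: %.3f   mean Jaccard: %.3f\n", x$ari_mean, x$jaccard_mean))
  invisible(x)
}

#' Export a stability result to JSON
#'
#' Writes `K`, `B`, the per-replicate ARI and Jaccard values, their means
#' and the seed.
#'
#' @param st An `lcca_stability` object.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_stability_json <- function(st, path) {
  jsonlite::write_json(
    list(K = st$K, B = st$B, ari_values = st$ari_values,
         jaccard_values = st$jaccard_values, ari_mean = st$ari_mean,
         jaccard_mean = st$jaccard_mean, seed = st$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export per-replicate stability values to CSV
#'
#' @param st An `lcca_stability` object.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_stability_csv <- function(st, path) {
  utils::write.csv(
    data.frame(replicate = seq_len(st$B), ARI = st$ari_values,
               Jaccard = st$jaccard_values),
    path, row.names = FALSE)
  invisible(path)
}
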