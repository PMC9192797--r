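#' Fit a latent class cluster model by EM with random restarts
#'
#' Maximises the multinomial-mixture log-likelihood by
#' expectation-maximisation. Each restart is initialised from random
#' per-observation responsibilities drawn from a symmetric Dirichlet(1);
#' the best restart by final log-likelihood is returned. Internally the EM
#' runs on the table of distinct response patterns with multiplicities,
#' which is equivalent to per-row EM but much faster on survey-style data.
#'
#' @param data An `lcca_data` object with no missing cells.
#' @param K Number of latent classes (`K >= 1`).
#' @param restarts Number of random restarts (default 20).
#' @param seed Integer seed; per-restart substreams are derived from it, so
#'   the result is fully deterministic given `(data, K, restarts, seed)`.
#' @param tol Relative log-likelihood change below which EM stops
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations per restart (default 1000).
#' @param smoothing Additive M-step smoothing, default 1e-10; keeps item
#'   probabilities strictly positive so the log-likelihood stays finite on
#'   sparse categories while leaving the EM updates maximum-likelihood to
#'   numerical precision (the trace stays non-decreasing).
#'
#' @details A restart whose classes collapse (total responsibility of a
#'   class below 1e-8) is abandoned and re-initialised, up to 3 extra
#'   attempts, rather than silently reducing `K`.
#'
#' @return An object of class `lcca_fit`: list with `model` (an
#'   [lcca_model()]), `loglik`, `loglik_trace` (non-decreasing),
#'   `responsibilities` (`n x K`, rows sum to 1), `partition` (MAP labels,
#'   ties to the lowest class index), `converged`, `n_restarts_used`,
#'   `seed` and `K`.
#'
#' @examples
#' d <- simulate_ordinal_clusters(simulation_spec(K = 2, n_total = 200, seed = 7))
#' fit <- fit_em(d$data, K = 2, restarts = 5, seed = 1)
#' fit$loglik
#' @export
fit_em <- function(data, K, restarts = 20, seed = 1L, tol = 1e-6,
                   max_iter = 1000, smoothing = 1e-10) {
  check_complete(data, "fit_em()")
  K <- as.integer(K)
  if (K < 1L) stop("`K` must be at least 1")
  if (K > data$n) stop("`K` cannot exceed the number of observations")
  if (restarts < 1L) stop("`restarts` must be at least 1")
  agg <- pattern_aggregate(data$codes)
  if (nrow(agg$patterns) == 1L && K > 1L)
    warning("all rows are identical; classes beyond the first are redundant")

  if (K == 1L) {
    res <- em_single(agg, K = 1L, n = data$n, m = data$n_categories,
                     init_seed = seed, tol = tol, max_iter = 1L,
                     smoothing = smoothing)
    res$converged <- TRUE              # K = 1 is an exact one-step solution
    return(finish_fit(res, agg, data, K, restarts_used = 1L, seed = seed))
  }

  set.seed(seed)
  main_seeds <- sample.int(.Machine$integer.max - 1L, restarts)
  retry_seeds <- sample.int(.Machine$integer.max - 1L, 3L * restarts)
  retry_ptr <- 0L

  best <- NULL
  used <- 0L
  for (r in seq_len(restarts)) {
    res <- NULL
    s <- main_seeds[r]
    for (attempt in 0:3) {
      cand <- tryCatch(
        em_single(agg, K, n = data$n, m = data$n_categories, init_seed = s,
                  tol = tol, max_iter = max_iter, smoothing = smoothing),
        lcca_degenerate_class = function(e) NULL
      )
      if (!is.null(cand)) { res <- cand; break }
      retry_ptr <- retry_ptr + 1L
      if (retry_ptr > length(retry_seeds)) break
      s <- retry_seeds[retry_ptr]
    }
    if (is.null(res)) next
    used <- used + 1L
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best))
    stop("all EM restarts collapsed to a degenerate class; reduce K")
  finish_fit(best, agg, data, K, restarts_used = used, seed = seed)
}

# internal: one EM run on the aggregated pattern table.
# Tau_w holds responsibilities multiplied by pattern counts (U x K);
# init_Tau, when given, supplies it directly (warm start) instead of the
# random per-row Dirichlet(1) initialisation.
em_single <- function(agg, K, n, m, init_seed, tol, max_iter, smoothing,
                      init_Tau = NULL) {
  U <- nrow(agg$patterns)
  if (!is.null(init_Tau)) {
    Tau_w <- init_Tau
  } else {
    set.seed(init_seed)
    if (K == 1L) {
      Tau_w <- matrix(agg$counts, U, 1L)
    } else {
      E <- matrix(stats::rexp(n * K), n, K)
      E <- E / rowSums(E)
      Tau_w <- rowsum(E, group = agg$index)    # groups 1..U, already in order
    }
  }
  J <- ncol(agg$patterns)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  alphas <- vector("list", J)
  for (iter in seq_len(max_iter)) {
    cls_tot <- colSums(Tau_w)
    if (any(cls_tot < 1e-8)) {
      cond <- structure(class = c("lcca_degenerate_class", "error", "condition"),
                        list(message = "degenerate class", call = NULL))
      stop(cond)
    }
    L <- matrix(rep(log(cls_tot / n), each = U), U, K)
    for (j in seq_len(J)) {
      cnt <- matrix(0, m[j], K)
      rs <- rowsum(Tau_w, group = agg$patterns[, j])
      cnt[as.integer(rownames(rs)), ] <- rs
      alphas[[j]] <- sweep(cnt + smoothing, 2, cls_tot + m[j] * smoothing, "/")
      L <- L + log(alphas[[j]])[agg$patterns[, j], , drop = FALSE]
    }
    lse <- row_logsumexp(L)
    ll <- sum(agg$counts * lse)
    P <- exp(L - lse)
    Tau_w <- P * agg$counts
    trace <- c(trace, ll)
    if (iter > 1L && abs(ll - ll_prev) <= tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  list(loglik = ll, trace = trace, P = P, weights = colSums(Tau_w) / n,
       alphas = alphas, converged = converged)
}

# internal: EM run warm-started from an existing model's responsibilities
fit_em_warm <- function(data, model, tol = 1e-6, max_iter = 1000,
                        smoothing = 1e-10) {
  agg <- pattern_aggregate(data$codes)
  L <- class_log_density(model, agg$patterns)
  P <- exp(L - row_logsumexp(L))
  res <- em_single(agg, model$K, n = data$n, m = data$n_categories,
                   init_seed = 0L, tol = tol, max_iter = max_iter,
                   smoothing = smoothing, init_Tau = P * agg$counts)
  finish_fit(res, agg, data, model$K, restarts_used = 1L,
             seed = NA_integer_)
}

# internal: assemble the public lcca_fit object from an em_single result
finish_fit <- function(res, agg, data, K, restarts_used, seed) {
  item_probs <- rep(list(vector("list", data$J)), K)
  for (j in seq_len(data$J))
    for (k in seq_len(K)) item_probs[[k]][[j]] <- res$alphas[[j]][, k]
  model <- lcca_model(res$weights / sum(res$weights), item_probs,
                      item_names = data$item_names)
  tau <- res$P[agg$index, , drop = FALSE]
  structure(
    list(model = model, loglik = res$loglik, loglik_trace = res$trace,
         responsibilities = tau, partition = max.col(tau, ties.method = "first"),
         converged = res$converged, n_restarts_used = restarts_used,
         seed = seed, K = K, n = data$n),
    class = "lcca_fit"
  )
}

#' @export
print.lcca_fit <- function(x, ...) {
  cat("Latent class fit: K =", x$K, " n =", x$n, "\n")
  cat(sprintf("log-likelihood: %.4f (%s after %d iterations, best of %d restarts)\n",
              x$loglik, if (x$converged) "converged" else "not converged",
              length(x$loglik_trace), x$n_restarts_used))
  cat("class shares:",
      paste(sprintf("%.3f", tabulate(x$partition, x$K) / x$n), collapse = " "), "\n")
  invisible(x)
}

#' Serialise a fitted model to JSON
#'
#' Writes mixture weights, item-probability tables, the log-likelihood, the
#' MAP partition and the seed, so a fit can be archived or inspected outside
#' R.
#'
#' @param fit An `lcca_fit` object.
#' @param path Output file path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_fit_json <- function(fit, path = NULL) {
  payload <- list(
    K = fit$K,
    weights = fit$model$weights,
    item_probs = lapply(fit$model$item_probs, function(cl) {
      names(cl) <- fit$model$item_names
      cl
    }),
    loglik = fit$loglik,
    converged = fit$converged,
    partition = fit$partition,
    seed = fit$seed
  )
  if (is.null(path))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
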