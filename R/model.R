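#' Construct a latent class model
#'
#' A latent class cluster model for categorical items is a finite mixture of
#' products of multinomial distributions: observation `x` belongs to class
#' `k` with prior probability `pi_k`, and given the class its items are
#' independent with `P(x_j = h | k) = alpha_kjh`.
#'
#' @param weights Numeric vector of mixture proportions `pi_1..pi_K`;
#'   strictly positive, summing to 1 (within 1e-12).
#' @param item_probs List over classes; each element a list over items of
#'   probability vectors `alpha_kj.` (each summing to 1 within 1e-12,
#'   strictly positive).
#' @param item_names Optional item names.
#' @return An object of class `lcca_model`.
#' @export
lcca_model <- function(weights, item_probs, item_names = NULL) {
  K <- length(weights)
  if (K < 1L) stop("need at least one class")
  if (abs(sum(weights) - 1) > 1e-12) stop("mixture weights must sum to 1")
  if (any(weights <= 0)) stop("mixture weights must be strictly positive")
  if (length(item_probs) != K) stop("`item_probs` must have one element per class")
  J <- length(item_probs[[1]])
  for (k in seq_len(K)) {
    if (length(item_probs[[k]]) != J) stop("all classes must have the same items")
    for (j in seq_len(J)) {
      a <- item_probs[[k]][[j]]
      if (abs(sum(a) - 1) > 1e-12)
        stop("item probabilities for class ", k, ", item ", j, " must sum to 1")
      if (any(a < 0)) stop("negative item probability")
    }
  }
  if (is.null(item_names)) item_names <- paste0("item", seq_len(J))
  structure(list(K = K, weights = as.numeric(weights), item_probs = item_probs,
                 item_names = item_names,
                 n_categories = vapply(item_probs[[1]], length, 1L)),
            class = "lcca_model")
}

#' @export
print.lcca_model <- function(x, ...) {
  cat("Latent class model:", x$K, "classes,", length(x$item_probs[[1]]), "items\n")
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

# internal: per-item log-probability matrices, m_j x K
log_item_prob_matrices <- function(model) {
  J <- length(model$item_probs[[1]])
  lapply(seq_len(J), function(j) {
    log(vapply(model$item_probs, function(cl) cl[[j]],
               numeric(length(model$item_probs[[1]][[j]]))))
  })
}

# internal: U x K matrix of per-class log joint density log(pi_k) + sum_j log alpha
class_log_density <- function(model, codes) {
  U <- nrow(codes)
  L <- matrix(rep(log(model$weights), each = U), U, model$K)
  logA <- log_item_prob_matrices(model)
  for (j in seq_along(logA)) {
    lj <- logA[[j]][codes[, j], , drop = FALSE]
    L <- L + lj
  }
  L
}

# internal: row-wise log-sum-exp
row_logsumexp <- function(L) {
  mx <- L[cbind(seq_len(nrow(L)), max.col(L, ties.method = "first"))]
  mx + log(rowSums(exp(L - mx)))
}

#' Log-likelihood of a latent class model
#'
#' Evaluates the observed-data log-likelihood
#' `sum_i log sum_k pi_k prod_j alpha_{kj, x_ij}` on complete data.
#'
#' @param model An `lcca_model`.
#' @param data An `lcca_data` object with no missing cells.
#' @return A single finite number, invariant to observation order.
#' @export
log_likelihood <- function(model, data) {
  check_model_data(model, data)
  check_complete(data, "log_likelihood()")
  agg <- pattern_aggregate(data$codes)
  L <- class_log_density(model, agg$patterns)
  sum(agg$counts * row_logsumexp(L))
}

#' E-step: posterior class responsibilities
#'
#' Computes, in log space, `tau_ik` proportional to
#' `pi_k prod_j alpha_{kj, x_ij}`, normalised over classes per observation.
#'
#' @inheritParams log_likelihood
#' @return An `n x K` matrix whose rows sum to 1.
#' @export
e_step <- function(model, data) {
  check_model_data(model, data)
  check_complete(data, "e_step()")
  agg <- pattern_aggregate(data$codes)
  L <- class_log_density(model, agg$patterns)
  P <- exp(L - row_logsumexp(L))
  P[agg$index, , drop = FALSE]
}

#' M-step: maximum-likelihood update from responsibilities
#'
#' Updates mixture weights `pi_k = mean_i tau_ik` and item probabilities
#' `alpha_kjh = (sum_{i: x_ij = h} tau_ik + eps) / (sum_i tau_ik + m_j eps)`,
#' with a small smoothing constant `eps` keeping every probability strictly
#' positive.
#'
#' @param tau `n x K` responsibility matrix with normalised rows.
#' @param data An `lcca_data` object with no missing cells.
#' @param smoothing Additive smoothing `eps`, default `1e-10`.
#' @return An `lcca_model`.
#' @export
m_step <- function(tau, data, smoothing = 1e-10) {
  check_complete(data, "m_step()")
  tau <- as.matrix(tau)
  if (nrow(tau) != data$n) stop("`tau` must have one row per observation")
  cls_tot <- colSums(tau)
  if (any(cls_tot < 1e-8))
    stop("degenerate class: total responsibility below 1e-8 (restart signal)")
  K <- ncol(tau)
  item_probs <- rep(list(vector("list", data$J)), K)
  for (j in seq_len(data$J)) {
    m_j <- data$n_categories[j]
    cnt <- matrix(0, m_j, K)
    rs <- rowsum(tau, group = data$codes[, j])
    cnt[as.integer(rownames(rs)), ] <- rs
    a <- sweep(cnt + smoothing, 2, cls_tot + m_j * smoothing, "/")
    for (k in seq_len(K)) item_probs[[k]][[j]] <- a[, k]
  }
  lcca_model(cls_tot / sum(cls_tot), item_probs, item_names = data$item_names)
}

#' MAP partition from a fitted model
#'
#' Assigns each observation to its highest-responsibility class; ties break
#' toward the lowest class index.
#'
#' @param fit An `lcca_fit` object, or a responsibility matrix.
#' @return Integer vector of class labels in `1..K`.
#' @export
map_partition <- function(fit) {
  tau <- if (is.matrix(fit)) fit else fit$responsibilities
  max.col(tau, ties.method = "first")
}

# internal: collapse rows of a complete code matrix to unique patterns
pattern_aggregate <- function(codes) {
  key <- do.call(paste, c(as.data.frame(codes), sep = "\r"))
  ukey <- unique(key)
  index <- match(key, ukey)
  first <- match(ukey, key)
  list(patterns = codes[first, , drop = FALSE],
       counts = as.numeric(tabulate(index, nbins = length(ukey))),
       index = index)
}
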